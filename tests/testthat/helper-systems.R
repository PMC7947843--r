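# shared fixtures built in code

# small alignment from explicit rows
aln <- function(..., id = "L1") {
  rows <- list(...)
  m <- do.call(rbind, lapply(rows, function(s) strsplit(s, "")[[1]]))
  rownames(m) <- names(rows)
  locus_aln(m, id = id)
}

# deterministic random locus over ACGT(+gaps)
random_locus <- function(n_taxa, n_sites, seed = 1, gap_p = 0, id = "L1") {
  set.seed(seed)
  states <- c("A", "C", "G", "T")
  m <- matrix(sample(states, n_taxa * n_sites, replace = TRUE), n_taxa,
              dimnames = list(paste0("t", seq_len(n_taxa)), NULL))
  if (gap_p > 0) m[runif(length(m)) < gap_p] <- "-"
  locus_aln(m, id = id)
}

# random unrooted tree with branch lengths
random_tree <- function(n, seed = 1, min_bl = 0.02, max_bl = 0.5) {
  set.seed(seed)
  tr <- ape::unroot(ape::rtree(n))
  tr$edge.length <- runif(nrow(tr$edge), min_bl, max_bl)
  tr
}

# the 12-taxon H1/H2 system with moderate ILS used across integration tests
default_system <- function(t_focal = 0.5, subst_scale = 0.05) {
  example_system(n_per_clade = 3, t_focal = t_focal, subst_scale = subst_scale)
}
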