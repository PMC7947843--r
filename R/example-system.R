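#' A canonical synthetic incongruence study system
#'
#' Builds the study design used throughout the package's examples and tests:
#' three focal clades X, Y, Z plus an outgroup clade O, with two competing
#' hypotheses about the focal node -- H1: X sister to Y; H2: X sister to Z --
#' and a true species tree following H1 whose focal internal branch length
#' (in coalescent units) controls the amount of incomplete lineage sorting.
#' Short focal branches produce high gene-tree discordance and hence
#' realistic incongruence among analyses.
#'
#' @param n_per_clade taxa per clade (total is 4x this).
#' @param t_focal focal internal branch length in coalescent units; the
#'   probability that a gene tree is concordant at the focal node is
#'   1 - (2/3) exp(-t_focal).
#' @param clade_height height of each clade subtree in coalescent units.
#' @param clade_stem private stem above each clade before the focal node, in
#'   coalescent units; long stems let within-clade lineages finish sorting,
#'   so the constraint clades are (almost) always monophyletic in gene trees,
#'   as the well-established groups of empirical constraint sets are.
#' @param subst_scale substitutions/site per coalescent unit.
#' @return list with `model` (a [species_tree_model()] following H1),
#'   `hypotheses` (list of H1 and H2 [constraint_hyp()]s), `outgroup`
#'   (outgroup labels), and `clades`.
#' @export
example_system <- function(n_per_clade = 3, t_focal = 0.5, clade_height = 1,
                           clade_stem = 2, subst_scale = 0.05) {
  stopifnot(n_per_clade >= 1, t_focal >= 0)
  clades <- list(X = paste0("x", seq_len(n_per_clade)),
                 Y = paste0("y", seq_len(n_per_clade)),
                 Z = paste0("z", seq_len(n_per_clade)),
                 O = paste0("o", seq_len(n_per_clade)))
  # caterpillar clade fragment; returns the fragment (no stem) and its height
  clade_frag <- function(taxa, height) {
    n <- length(taxa)
    if (n == 1) return(list(s = taxa, h = 0))
    f <- taxa[1]; cur <- 0
    for (i in 2:n) {
      h <- height * (i - 1) / (n - 1)
      f <- sprintf("(%s:%g,%s:%g)", f, h - cur, taxa[i], h)
      cur <- h
    }
    list(s = f, h = height)
  }
  fX <- clade_frag(clades$X, clade_height)
  fY <- clade_frag(clades$Y, clade_height)
  fZ <- clade_frag(clades$Z, clade_height)
  fO <- clade_frag(clades$O, clade_height)
  d1 <- clade_height + clade_stem   # X+Y join
  d2 <- d1 + t_focal                # ... + Z (the focal branch has length t_focal)
  d3 <- d2 + 1                      # root (+ O)
  nwk <- sprintf("(((%s:%g,%s:%g):%g,%s:%g):%g,%s:%g):0;",
                 fX$s, d1 - fX$h, fY$s, d1 - fY$h,
                 d2 - d1, fZ$s, d2 - fZ$h,
                 d3 - d2, fO$s, d3 - fO$h)
  model <- species_tree_model(nwk, subst_scale = subst_scale)
  cs <- function(x) paste(x, collapse = ",")
  h1 <- constraint_hyp("H1", sprintf("(((%s),(%s)),(%s),(%s));",
                                     cs(clades$X), cs(clades$Y),
                                     cs(clades$Z), cs(clades$O)))
  h2 <- constraint_hyp("H2", sprintf("(((%s),(%s)),(%s),(%s));",
                                     cs(clades$X), cs(clades$Z),
                                     cs(clades$Y), cs(clades$O)))
  list(model = model, hypotheses = list(h1, h2), outgroup = clades$O,
       clades = clades)
}

#' Canonical heterogeneous UCE-like locus profile
#'
#' The package's reference conditions for studying within-locus partitioning:
#' a slow, compositionally distinct core (GC-balanced, low transition bias,
#' near-invariant) inside flanks that are AT-rich, transition-biased and
#' carry strong site-to-site rate variation of their own (gamma shape 0.3),
#' with the per-site rate rising linearly from the core boundary to the
#' alignment edge.  This is the kind of process heterogeneity that makes a
#' separate substitution model per segment pay off; scalar rate differences
#' alone are absorbed by a single discrete-gamma model.
#'
#' @param length locus length in sites.
#' @return a [locus_profile()].
#' @export
example_het_profile <- function(length = 420) {
  locus_profile(
    length = length, core_fraction = 1 / 3, core_mult = 0.05, flank_mult = 1,
    gradient = "linear",
    model = subst_model("HKY85", freqs = c(.35, .15, .15, .35), kappa = 6,
                        alpha = 0.3),
    core_model = subst_model("HKY85", freqs = c(.2, .3, .3, .2), kappa = 1.5,
                             alpha = NULL))
}
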