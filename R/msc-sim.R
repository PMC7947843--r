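#' Species-tree model for multispecies-coalescent simulation
#'
#' Wraps a rooted, binary, ultrametric species tree whose branch lengths are
#' in coalescent units (time / 2N generations) together with a substitution
#' scale converting coalescent units to expected substitutions per site.
#' Internal branch lengths control the intensity of incomplete lineage
#' sorting: for an internal branch of length t, the two concordant rooted
#' triplets around it are recovered with probability 1 - (2/3) exp(-t).
#'
#' @param topology rooted binary `phylo` (newick string accepted) with branch
#'   lengths in coalescent units; must be ultrametric.
#' @param subst_scale expected substitutions per site per coalescent unit,
#'   applied uniformly to all branches when sequences are simulated.
#' @return an object of class `species_tree_model`.
#' @export
species_tree_model <- function(topology, subst_scale = 0.03) {
  if (is.character(topology)) topology <- ape::read.tree(text = topology)
  if (!inherits(topology, "phylo")) stop("topology must be a phylo tree")
  if (!ape::is.rooted(topology) || !ape::is.binary(topology))
    stop("species tree must be rooted and binary")
  if (is.null(topology$edge.length) || any(topology$edge.length < 0))
    stop("species tree needs nonnegative branch lengths (coalescent units)")
  if (length(topology$tip.label) < 3) stop("species tree needs >= 3 taxa")
  if (anyDuplicated(topology$tip.label)) stop("duplicated taxon labels")
  if (!ape::is.ultrametric(topology, tol = 1e-6))
    stop("species tree must be ultrametric in coalescent units")
  if (subst_scale <= 0) stop("subst_scale must be positive")
  structure(list(tree = topology, subst_scale = subst_scale),
            class = "species_tree_model")
}

#' @export
print.species_tree_model <- function(x, ...) {
  cat(sprintf("<species_tree_model> %d taxa, height %.3g coalescent units, %g subst/site/cu\n",
              length(x$tree$tip.label),
              max(ape::node.depth.edgelength(x$tree)), x$subst_scale))
  invisible(x)
}

# node ages (0 at tips) for an ultrametric rooted tree
.node_ages <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  max(depth[seq_along(tree$tip.label)]) - depth
}

# simulate one gene tree under the MSC; returns a rooted phylo in coalescent
# units (one sampled lineage per species)
.msc_one <- function(tree, ages) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  root <- ntip + 1L
  # gene-tree bookkeeping: lineage ids; tips 1..ntip, internals appended
  g_parent_age <- numeric(0)
  g_left <- integer(0); g_right <- integer(0)
  next_id <- ntip
  merge_in_branch <- function(lins, t0, t1) {
    # coalesce among `lins` from age t0 up to age t1 (may be Inf)
    repeat {
      k <- length(lins)
      if (k < 2) return(lins)
      wait <- stats::rexp(1, rate = k * (k - 1) / 2)
      if (t0 + wait > t1) return(lins)
      t0 <- t0 + wait
      pair <- sample.int(k, 2)
      next_id <<- next_id + 1L
      g_parent_age[next_id - ntip] <<- t0
      g_left[next_id - ntip] <<- lins[pair[1]]
      g_right[next_id - ntip] <<- lins[pair[2]]
      lins <- c(lins[-pair], next_id)
    }
  }
  active <- vector("list", nnode)
  postord <- rev(.preorder_nodes(tree))
  for (v in postord) {
    if (v <= ntip) { active[[v]] <- v; next }
    lins <- unlist(lapply(kids[[as.character(v)]], function(c) active[[c]]))
    t1 <- if (v == root) Inf else ages[.parent_of(tree, v)]
    active[[v]] <- merge_in_branch(lins, ages[v], t1)
  }
  # assemble phylo: internal ids ntip+1.., root = last merge; renumber so the
  # deepest (last) merge becomes ntip+1 as ape expects
  n_int <- next_id - ntip
  stopifnot(n_int == ntip - 1)
  node_age <- c(rep(0, ntip), g_parent_age[seq_len(n_int)])
  old_int <- ntip + seq_len(n_int)
  new_id <- integer(next_id)
  new_id[seq_len(ntip)] <- seq_len(ntip)
  new_id[old_int] <- ntip + 1L + (n_int - seq_len(n_int))  # reverse creation order
  edge <- matrix(0L, 2 * n_int, 2)
  elen <- numeric(2 * n_int)
  r <- 0L
  for (i in seq_len(n_int)) {
    p <- ntip + i
    for (ch in c(g_left[i], g_right[i])) {
      r <- r + 1L
      edge[r, ] <- c(new_id[p], new_id[ch])
      elen[r] <- node_age[p] - node_age[ch]
    }
  }
  out <- list(edge = edge, edge.length = elen, tip.label = tree$tip.label,
              Nnode = n_int)
  class(out) <- "phylo"
  out
}

.preorder_nodes <- function(tree) {
  ntip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  out <- integer(0)
  stack <- ntip + 1L
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    out <- c(out, v)
    if (v > ntip) stack <- c(stack, rev(kids[[as.character(v)]]))
  }
  out
}

.parent_of <- function(tree, v) tree$edge[tree$edge[, 2] == v, 1]

#' Simulate gene trees under the multispecies coalescent
#'
#' One lineage is sampled per species; within each species-tree branch,
#' lineages coalesce at rate k(k-1)/2 per coalescent unit, and uncoalesced
#' lineages are passed to the parent branch (completing above the root).
#'
#' @param model a [species_tree_model()].
#' @param n_genes number of gene trees.
#' @param seed integer seed (per-gene seeds are derived from it, so gene i is
#'   reproducible independently).
#' @return a `multiPhylo` list of rooted gene trees with branch lengths in
#'   coalescent units.
#' @export
simulate_gene_trees <- function(model, n_genes, seed = 1) {
  stopifnot(inherits(model, "species_tree_model"), n_genes >= 1)
  ages <- .node_ages(model$tree)
  seeds <- .derive_seeds(seed, n_genes)
  out <- vector("list", n_genes)
  for (i in seq_len(n_genes))
    out[[i]] <- .with_seed(seeds[i], .msc_one(model$tree, ages))
  class(out) <- "multiPhylo"
  out
}

#' UCE-like locus profile
#'
#' Describes how one locus evolves along its gene tree: a conserved central
#' core evolving at `core_mult` times the branch-length rate, flanked by
#' regions whose per-site rate increases linearly from `core_mult` at the
#' core boundary to `flank_mult` at the alignment edge.
#'
#' @param length locus length in sites.
#' @param core_fraction proportion of sites in the core, strictly in (0,1);
#'   the core is centered.
#' @param core_mult rate multiplier of core sites (slow).
#' @param flank_mult rate multiplier at the outer flank edge; must exceed
#'   `core_mult`.
#' @param gradient flank rate shape: `"linear"` (rate rises linearly from
#'   `core_mult` at the core boundary to `flank_mult` at the alignment edge)
#'   or `"step"` (flanks constant at `flank_mult`).
#' @param model substitution model used to simulate flank sites (rate
#'   variation across sites comes from the core/flank profile itself).
#' @param core_model optional distinct substitution model for core sites;
#'   ultraconserved cores differ from their flanks not only in rate but in
#'   composition and substitution process, and this is what makes a separate
#'   per-segment model pay off.  `NULL` uses `model` everywhere.
#' @param missing_p per-taxon-per-locus missingness probability used by
#'   [inject_missing_taxa()] defaults.
#' @return an object of class `locus_profile`.
#' @export
locus_profile <- function(length = 600, core_fraction = 1 / 3, core_mult = 0.05,
                          flank_mult = 1.0, gradient = c("linear", "step"),
                          model = subst_model("HKY85", freqs = c(.3, .2, .2, .3),
                                              kappa = 2.5, alpha = NULL),
                          core_model = NULL, missing_p = 0) {
  gradient <- match.arg(gradient)
  if (core_fraction <= 0 || core_fraction >= 1)
    stop("core_fraction must be strictly between 0 and 1")
  if (core_mult < 0 || core_mult >= flank_mult)
    stop("core_mult must be >= 0 and below flank_mult (cores are slower)")
  if (missing_p < 0 || missing_p >= 1) stop("missing_p must be in [0, 1)")
  structure(list(length = as.integer(length), core_fraction = core_fraction,
                 core_mult = core_mult, flank_mult = flank_mult,
                 gradient = gradient, model = model, core_model = core_model,
                 missing_p = missing_p),
            class = "locus_profile")
}

#' Core breakpoints implied by a locus profile
#'
#' @param profile a [locus_profile()].
#' @return integer breakpoints `c(l, r)`, 0-based half-open: sites `[l, r)`
#'   are the core.
#' @export
profile_breakpoints <- function(profile) {
  L <- profile$length
  core_len <- round(L * profile$core_fraction)
  l <- floor((L - core_len) / 2)
  c(l = l, r = l + core_len)
}

# per-site rate multipliers for a profile (length L vector)
.profile_rates <- function(profile) {
  L <- profile$length
  bp <- profile_breakpoints(profile)
  l <- bp[[1]]; r <- bp[[2]]
  rate <- rep(profile$core_mult, L)
  dm <- profile$flank_mult - profile$core_mult
  if (identical(profile$gradient, "step")) {
    if (l > 0) rate[seq_len(l)] <- profile$flank_mult
    if (r < L) rate[(r + 1):L] <- profile$flank_mult
    return(rate)
  }
  if (l > 0) {
    i <- seq_len(l)  # 1-based site index in left flank
    rate[i] <- profile$core_mult + dm * (l + 1 - i) / l
  }
  if (r < L) {
    i <- (r + 1):L
    rate[i] <- profile$core_mult + dm * (i - r) / (L - r)
  }
  rate
}

#' Simulate a locus alignment along a gene tree
#'
#' Sites evolve independently down the (rooted) gene tree under the profile's
#' substitution model; each site's branch lengths are multiplied by its
#' core/flank rate multiplier.  Gene-tree branch lengths must already be in
#' expected substitutions per site (see [scale_gene_tree()]).
#'
#' @param gene_tree rooted or unrooted `phylo` with branch lengths in
#'   substitutions/site.
#' @param profile a [locus_profile()].
#' @param seed integer seed.
#' @return a list with `locus` (a [locus_aln()]) and `breakpoints` (0-based
#'   half-open core bounds).
#' @export
simulate_locus_alignment <- function(gene_tree, profile, seed = 1) {
  if (is.null(gene_tree$edge.length)) stop("gene tree must have branch lengths")
  tree <- gene_tree
  ntip <- length(tree$tip.label)
  rates <- .profile_rates(profile)
  L <- profile$length
  bp <- profile_breakpoints(profile)
  is_core <- seq_len(L) > bp[[1]] & seq_len(L) <= bp[[2]]
  eg_flank <- .model_eigen(profile$model)
  eg_core <- if (is.null(profile$core_model)) eg_flank
             else .model_eigen(profile$core_model)
  segs <- list(list(sites = which(!is_core), eg = eg_flank),
               list(sites = which(is_core), eg = eg_core))
  states <- c("A", "C", "G", "T")
  .with_seed(seed, {
    # within-segment site-to-site rate variation: when a segment's model has a
    # gamma shape, each site additionally draws an iid Gamma(alpha, alpha)
    # multiplier (continuous, not discretized)
    a_flank <- profile$model$alpha
    a_core <- if (is.null(profile$core_model)) a_flank else profile$core_model$alpha
    if (!is.null(a_flank) && any(!is_core))
      rates[!is_core] <- rates[!is_core] *
        stats::rgamma(sum(!is_core), a_flank, a_flank)
    if (!is.null(a_core) && any(is_core))
      rates[is_core] <- rates[is_core] *
        stats::rgamma(sum(is_core), a_core, a_core)
    node_state <- matrix(0L, ntip + tree$Nnode, L)
    root <- ntip + 1L
    for (sg in segs)
      node_state[root, sg$sites] <- sample.int(4, length(sg$sites),
                                               replace = TRUE, prob = sg$eg$pi)
    # preorder so parents are assigned before children
    ord <- .preorder_nodes(tree)
    elen <- numeric(ntip + tree$Nnode)
    elen[tree$edge[, 2]] <- tree$edge.length
    for (v in ord) {
      if (v == root) next
      p <- .parent_of(tree, v)
      t <- elen[v]
      ps <- node_state[p, ]
      cs <- integer(L)
      for (sg in segs) {
        if (!length(sg$sites)) next
        eg <- sg$eg
        # per-site transition rows, grouped by parent state; for state a the
        # probability row over children states at site j is
        # (U[a,] * exp(lambda * t * rate_j)) %*% Uinv
        E <- exp(outer(eg$lambda, t * rates[sg$sites]))   # 4 x |sites|
        for (a in 1:4) {
          jj <- which(ps[sg$sites] == a)
          if (!length(jj)) next
          j <- sg$sites[jj]
          probs <- t(eg$U[a, ] * E[, jj, drop = FALSE]) %*% eg$Uinv  # |j| x 4
          probs[probs < 0] <- 0
          cum <- probs %*% upper.tri(diag(4), diag = TRUE)
          u <- stats::runif(length(j)) * cum[, 4]
          cs[j] <- 1L + as.integer(u > cum[, 1]) + as.integer(u > cum[, 2]) +
            as.integer(u > cum[, 3])
        }
      }
      node_state[v, ] <- cs
    }
    seq <- matrix(states[node_state[seq_len(ntip), , drop = FALSE]], nrow = ntip,
                  dimnames = list(tree$tip.label, NULL))
    list(locus = locus_aln(seq, id = "locus"),
         breakpoints = profile_breakpoints(profile))
  })
}

#' Scale a coalescent-unit gene tree to substitutions per site
#'
#' @param tree a `phylo` in coalescent units.
#' @param subst_scale substitutions/site per coalescent unit.
#' @return the tree with scaled branch lengths.
#' @export
scale_gene_tree <- function(tree, subst_scale) {
  tree$edge.length <- tree$edge.length * subst_scale
  tree
}

#' Simulate a complete UCE-like dataset
#'
#' Draws one multispecies-coalescent gene tree per locus from the species
#' tree, scales it to substitutions/site, and simulates a core/flank locus
#' alignment along it.  Per-locus seeds are derived from `seed` by one seed
#' draw, so each locus is independently reproducible.
#'
#' @param model a [species_tree_model()].
#' @param n_loci number of loci.
#' @param profile a [locus_profile()] shared by all loci.
#' @param seed integer master seed.
#' @param id_prefix locus id prefix (ids are `prefix0001`, ...).
#' @return an object of class `synthetic_dataset`: list with `loci`,
#'   `gene_trees` (coalescent units), `breakpoints` (n_loci x 2, 0-based
#'   half-open), `model`, and `profile`.
#' @export
simulate_dataset <- function(model, n_loci, profile = locus_profile(), seed = 1,
                             id_prefix = "uce-") {
  stopifnot(inherits(model, "species_tree_model"), n_loci >= 1)
  gts <- simulate_gene_trees(model, n_loci, seed = seed)
  seeds <- .derive_seeds(seed + 1L, n_loci)
  loci <- vector("list", n_loci)
  bps <- matrix(0L, n_loci, 2, dimnames = list(NULL, c("l", "r")))
  for (i in seq_len(n_loci)) {
    sim <- simulate_locus_alignment(scale_gene_tree(gts[[i]], model$subst_scale),
                                    profile, seed = seeds[i])
    sim$locus$id <- sprintf("%s%04d", id_prefix, i)
    loci[[i]] <- sim$locus
    bps[i, ] <- sim$breakpoints
  }
  names(loci) <- vapply(loci, function(x) x$id, "")
  structure(list(loci = loci, gene_trees = gts, breakpoints = bps,
                 model = model, profile = profile),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d loci x %d taxa, %d sites each\n",
              length(x$loci), length(x$model$tree$tip.label),
              x$profile$length))
  invisible(x)
}

#' Remove taxa from loci at random (missing-data regimes)
#'
#' Each taxon is dropped from each locus independently with probability
#' `p_missing`, but never below `min_taxa` taxa per locus (candidates beyond
#' the floor are retained in random order).  The gene-tree truth is left
#' untouched.
#'
#' @param dataset a [simulate_dataset()] result.
#' @param p_missing drop probability in [0, 1).
#' @param min_taxa minimum taxa retained per locus (>= 4).
#' @param seed integer seed.
#' @return the dataset with taxa removed from `loci`.
#' @export
inject_missing_taxa <- function(dataset, p_missing, min_taxa = 4, seed = 1) {
  if (p_missing < 0 || p_missing >= 1) stop("p_missing must be in [0, 1)")
  if (min_taxa < 4) stop("min_taxa must be >= 4")
  if (p_missing == 0) return(dataset)
  seeds <- .derive_seeds(seed, length(dataset$loci))
  for (i in seq_along(dataset$loci)) {
    loc <- dataset$loci[[i]]
    taxa <- locus_taxa(loc)
    drop <- .with_seed(seeds[i], {
      d <- which(stats::runif(length(taxa)) < p_missing)
      if (length(taxa) - length(d) < min_taxa)
        d <- d[sample.int(length(d), max(length(taxa) - min_taxa, 0))]
      d
    })
    if (length(drop)) {
      loc$seq <- loc$seq[-drop, , drop = FALSE]
      dataset$loci[[i]] <- loc
    }
  }
  dataset
}

#' Write a synthetic dataset to disk
#'
#' Per-locus FASTA alignments, true gene trees as newick, a truth table
#' (breakpoints and per-locus taxon coverage) as TSV, and a JSON manifest.
#'
#' @param dataset a [simulate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (loc in dataset$loci)
    write_locus(loc, file.path(dir, paste0(loc$id, ".fasta")), format = "fasta")
  ape::write.tree(dataset$gene_trees, file.path(dir, "true_gene_trees.nwk"))
  ape::write.tree(dataset$model$tree, file.path(dir, "species_tree.nwk"))
  truth <- data.frame(locus = names(dataset$loci),
                      core_start = dataset$breakpoints[, "l"],
                      core_end = dataset$breakpoints[, "r"],
                      n_taxa = vapply(dataset$loci, function(x) nrow(x$seq), 0L))
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- list(n_loci = length(dataset$loci),
                   n_taxa = length(dataset$model$tree$tip.label),
                   locus_length = dataset$profile$length,
                   core_fraction = dataset$profile$core_fraction,
                   core_mult = dataset$profile$core_mult,
                   flank_mult = dataset$profile$flank_mult,
                   subst_scale = dataset$model$subst_scale)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
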