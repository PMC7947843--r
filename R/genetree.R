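#' @useDynLib phylotriage, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# evaluate expr under a temporary RNG seed (global stream restored afterwards)
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

# derive a stream of per-item seeds from one master seed (stated counter
# scheme: the master seed seeds one draw of n integers below 2^31 - 1)
.derive_seeds <- function(seed, n) {
  .with_seed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}

# ---- tree plumbing ---------------------------------------------------------

# ensure a tree is unrooted, binary-internal, has edge lengths, and its tips
# match the alignment taxa
.prep_tree <- function(tree, taxa = NULL, default_bl = 0.05) {
  if (!inherits(tree, "phylo")) stop("expected a 'phylo' tree")
  if (!is.null(taxa)) {
    if (!setequal(tree$tip.label, taxa))
      stop("tree tips do not match alignment taxa")
  }
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree, random = FALSE)
  if (ape::is.rooted(tree) && length(tree$tip.label) > 2) tree <- ape::unroot(tree)
  if (is.null(tree$edge.length)) tree$edge.length <- rep(default_bl, nrow(tree$edge))
  tree$edge.length[!is.finite(tree$edge.length) | tree$edge.length < 1e-8] <- 1e-8
  tree
}

# phylo from engine output, preserving tip labels (indices unchanged)
.tree_from_engine <- function(res, tip_label) {
  ntip <- length(tip_label)
  tr <- list(edge = res$edge, edge.length = as.numeric(res$edge_len),
             tip.label = tip_label, Nnode = max(res$edge) - ntip)
  class(tr) <- "phylo"
  attr(tr, "order") <- "cladewise"
  tr
}

# tip-label sets below each internal node (own post-order; independent of
# ape's edge-order conventions)
.clade_sets <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  sets <- vector("list", nnode)
  for (i in seq_len(ntip)) sets[[i]] <- tree$tip.label[i]
  visit <- function(v) {
    if (v <= ntip) return(sets[[v]])
    out <- unlist(lapply(kids[[as.character(v)]], visit), use.names = FALSE)
    sets[[v]] <<- out
    out
  }
  root <- setdiff(unique(tree$edge[, 1]), tree$edge[, 2])[1]
  visit(root)
  sets
}

# canonical string keys for the non-trivial splits of an unrooted tree
.tree_splits <- function(tree) {
  ntip <- length(tree$tip.label)
  labs <- tree$tip.label
  sets <- .clade_sets(tree)
  keys <- character(0)
  for (v in (ntip + 1):(ntip + tree$Nnode)) {
    side <- sets[[v]]
    if (is.null(side) || length(side) < 2 || length(side) > ntip - 2) next
    if (!(labs[1] %in% side)) side <- setdiff(labs, side)
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

# ---- likelihood wrappers ---------------------------------------------------

#' Phylogenetic log-likelihood of a locus on a tree
#'
#' Felsenstein pruning under a reversible substitution model, with gaps and
#' ambiguity codes treated as (partially) missing states.
#'
#' @param tree a `phylo` tree whose tips equal the locus taxa; branch lengths
#'   in expected substitutions per site.
#' @param model a [subst_model()].
#' @param locus a [locus_aln()].
#' @param per_site if `TRUE`, also return the per-site log-likelihood vector.
#' @return the log-likelihood (numeric scalar), with attribute `site_loglik`
#'   when `per_site = TRUE`.
#' @export
tree_loglik <- function(tree, model, locus, per_site = FALSE) {
  tree <- .prep_tree(tree, locus_taxa(locus))
  cp <- compress_patterns(locus)
  bl <- .make_block(cp$patterns, cp$weights, model, tree$tip.label)
  res <- .eng_loglik(tree$edge, tree$edge.length, length(tree$tip.label),
                     list(bl), per_site)
  out <- res$loglik
  if (per_site) attr(out, "site_loglik") <- res$pattern_loglik[cp$index]
  out
}

#' Optimize branch lengths by maximum likelihood
#'
#' Cycles one-branch-at-a-time Brent optimization (bounds 1e-8 to 10
#' substitutions/site) until the log-likelihood improves by less than `tol`
#' or `max_passes` full passes are reached.  The log-likelihood never
#' decreases.
#'
#' @inheritParams tree_loglik
#' @param max_passes maximum optimization passes over all branches.
#' @param tol convergence tolerance on the log-likelihood.
#' @return the tree with optimized branch lengths; attribute `loglik` holds
#'   the final log-likelihood.
#' @export
optim_branch_lengths <- function(tree, model, locus, max_passes = 20, tol = 1e-6) {
  tree <- .prep_tree(tree, locus_taxa(locus))
  cp <- compress_patterns(locus)
  bl <- .make_block(cp$patterns, cp$weights, model, tree$tip.label)
  res <- .eng_optim_edges(tree$edge, tree$edge.length, length(tree$tip.label),
                          list(bl), max_passes, tol, FALSE)
  out <- .tree_from_engine(res, tree$tip.label)
  attr(out, "loglik") <- res$loglik
  out
}

#' Neighbor-joining starting tree from JC-corrected distances
#'
#' @param locus a [locus_aln()].
#' @return an unrooted `phylo` with nonnegative branch lengths.
#' @export
nj_start_tree <- function(locus) {
  cp <- compress_patterns(locus)
  .nj_from_patterns(cp$patterns, cp$weights)
}

# NJ on JC-corrected distances computed from weighted site patterns
.nj_from_patterns <- function(patterns, weights) {
  taxa <- rownames(patterns)
  n <- length(taxa)
  base <- patterns %in% c("A", "C", "G", "T")
  dim(base) <- dim(patterns)
  D <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      valid <- base[i, ] & base[j, ]
      nv <- sum(weights * valid)
      p <- if (nv > 0) sum(weights * (valid & patterns[i, ] != patterns[j, ])) / nv
           else NA_real_
      d <- if (!is.finite(p)) NA_real_
           else if (p >= 0.74) 5 else -0.75 * log(1 - 4 * p / 3)
      D[i, j] <- D[j, i] <- d
    }
  }
  D[!is.finite(D)] <- max(D[is.finite(D)], 0.5) * 1.5
  tr <- ape::nj(stats::as.dist(D))
  tr$edge.length[tr$edge.length < 1e-8] <- 1e-8
  .prep_tree(tr, taxa)
}

# optimize free model parameters (kappa / GTR exchangeabilities / alpha) with
# branch lengths fixed, by quasi-Newton search on log scale
.fit_params_fixed_edges <- function(tree, model, blockmaker) {
  par <- numeric(0)
  if (model$name == "HKY85") par <- log(model$kappa)
  if (model$name == "GTR") par <- log(pmax(model$rates[1:5], 1e-3))
  if (!is.null(model$alpha)) par <- c(par, log(model$alpha))
  if (!length(par)) return(model)
  mkmodel <- function(p) {
    m <- model
    i <- 0
    if (model$name == "HKY85") { m$kappa <- exp(p[1]); i <- 1 }
    if (model$name == "GTR") { m$rates <- c(exp(p[1:5]), 1); i <- 5 }
    if (!is.null(model$alpha)) m$alpha <- min(max(exp(p[i + 1]), 0.05), 50)
    m
  }
  negll <- function(p) {
    bl <- blockmaker(mkmodel(p))
    -.eng_loglik(tree$edge, tree$edge.length, length(tree$tip.label),
                 list(bl), FALSE)$loglik
  }
  fit <- try(stats::nlminb(par, negll, control = list(iter.max = 60)), silent = TRUE)
  if (inherits(fit, "try-error")) return(model)
  mkmodel(fit$par)
}

#' Fit a substitution model to a locus on a fixed topology
#'
#' Alternates branch-length optimization and model-parameter estimation
#' (base frequencies are empirical; kappa / GTR exchangeabilities and the
#' gamma shape are optimized by maximum likelihood).
#'
#' @param locus a [locus_aln()].
#' @param name model family: `"JC69"`, `"HKY85"` or `"GTR"`.
#' @param gamma use discrete-gamma rate variation (4 categories)?
#' @param tree optional fixed topology (defaults to the NJ starting tree).
#' @param rounds alternation rounds.
#' @return a fitted [subst_model()]; attributes `loglik` and `tree` hold the
#'   final fit.
#' @export
fit_model <- function(locus, name = "HKY85", gamma = TRUE, tree = NULL, rounds = 2) {
  if (is.null(tree)) tree <- nj_start_tree(locus)
  tree <- .prep_tree(tree, locus_taxa(locus))
  cp <- compress_patterns(locus)
  freqs <- if (name == "JC69") rep(0.25, 4) else .empirical_freqs(locus$seq)
  model <- subst_model(name, freqs = freqs, alpha = if (gamma) 0.5 else NULL)
  blockmaker <- function(m) .make_block(cp$patterns, cp$weights, m, tree$tip.label)
  for (r in seq_len(rounds)) {
    res <- .eng_optim_edges(tree$edge, tree$edge.length, length(tree$tip.label),
                            list(blockmaker(model)), 10, 1e-5, FALSE)
    tree <- .tree_from_engine(res, tree$tip.label)
    model <- .fit_params_fixed_edges(tree, model, blockmaker)
  }
  res <- .eng_optim_edges(tree$edge, tree$edge.length, length(tree$tip.label),
                          list(blockmaker(model)), 10, 1e-6, FALSE)
  attr(model, "loglik") <- res$loglik
  attr(model, "tree") <- .tree_from_engine(res, tree$tip.label)
  model
}

#' Small-set substitution model selection by BIC
#'
#' Scores JC69, HKY85 and GTR, each with and without discrete-gamma rate
#' variation, on the fixed neighbor-joining starting topology and returns the
#' BIC argmin, `BIC = -2 lnL + k log(n_sites)` with `k` counting branch
#' lengths plus free model parameters.
#'
#' @param locus a [locus_aln()].
#' @param names model families to score.
#' @return the winning fitted [subst_model()]; attribute `bic_table` reports
#'   all candidates.
#' @export
select_model <- function(locus, names = c("JC69", "HKY85", "GTR")) {
  tree <- nj_start_tree(locus)
  S <- n_sites(locus)
  nb <- nrow(tree$edge)
  cands <- expand.grid(name = names, gamma = c(FALSE, TRUE),
                       stringsAsFactors = FALSE)
  fits <- vector("list", nrow(cands))
  bic <- numeric(nrow(cands))
  for (i in seq_len(nrow(cands))) {
    m <- fit_model(locus, cands$name[i], cands$gamma[i], tree = tree)
    k <- nb + switch(cands$name[i], JC69 = 0, HKY85 = 4, GTR = 8) +
      as.integer(cands$gamma[i])
    bic[i] <- -2 * attr(m, "loglik") + k * log(S)
    fits[[i]] <- m
  }
  best <- which.min(bic)
  out <- fits[[best]]
  attr(out, "bic_table") <- data.frame(model = cands$name, gamma = cands$gamma,
                                       loglik = vapply(fits, attr, 0, "loglik"),
                                       bic = bic)
  out
}

# ---- constraints -----------------------------------------------------------

#' Topological constraint hypothesis
#'
#' A labelled backbone: a (possibly multifurcating) tree whose clades must be
#' monophyletic, with the stated relationships among them, while relationships
#' inside each clade are left free.
#'
#' @param label short hypothesis label (e.g. `"H1"`).
#' @param backbone a `phylo` tree (newick string also accepted); it must cover
#'   every taxon of any locus it is applied to (after pruning).
#' @return an object of class `constraint_hyp`.
#' @export
constraint_hyp <- function(label, backbone) {
  if (is.character(backbone)) backbone <- ape::read.tree(text = backbone)
  if (!inherits(backbone, "phylo")) stop("backbone must be a phylo tree")
  structure(list(label = label, backbone = backbone), class = "constraint_hyp")
}

#' @export
print.constraint_hyp <- function(x, ...) {
  cat(sprintf("<constraint_hyp> %s over %d taxa\n", x$label,
              length(x$backbone$tip.label)))
  invisible(x)
}

# prune a backbone to a taxon set; NULL if fewer than 4 taxa survive
.prune_backbone <- function(constraint, taxa) {
  keep <- intersect(constraint$backbone$tip.label, taxa)
  if (length(keep) < 4) return(NULL)
  bb <- ape::keep.tip(constraint$backbone, keep)
  if (!all(taxa %in% bb$tip.label))
    stop(sprintf("constraint %s does not cover locus taxa: %s", constraint$label,
                 paste(setdiff(taxa, bb$tip.label), collapse = ", ")))
  bb
}

# 0/1 matrix of required splits (rows) over tips in `tips` order; NULL if the
# pruned backbone carries no non-trivial split
.constraint_masks <- function(constraint, tips) {
  bb <- .prune_backbone(constraint, tips)
  if (is.null(bb)) return(NULL)
  bb <- ape::unroot(bb)
  ntip <- length(tips)
  bp <- ape::prop.part(bb)
  labs <- attr(bp, "labels")
  rows <- list()
  for (s in bp) {
    if (length(s) < 2 || length(s) > ntip - 2) next
    rows[[length(rows) + 1]] <- as.numeric(tips %in% labs[s])
  }
  if (!length(rows)) return(NULL)
  unique(do.call(rbind, rows))
}

# deterministic-but-content-addressed seed for a constrained start: identical
# backbones give identical resolutions (so indistinguishable hypotheses yield
# identical searches)
.backbone_seed <- function(seed, backbone) {
  key <- paste(sort(.tree_splits(ape::unroot(ape::multi2di(backbone, random = FALSE)))),
               collapse = ";")
  h <- sum(utf8ToInt(key) * (seq_along(utf8ToInt(key)) %% 97 + 1))
  (as.integer(seed %% 1e6) * 1009L + as.integer(h %% 1e6)) %% 2147483587L + 1L
}

# random resolution of a pruned backbone, usable as a constrained start
.constrained_start <- function(constraint, tips, seed = NULL, default_bl = 0.05) {
  bb <- .prune_backbone(constraint, tips)
  if (is.null(bb)) stop("constraint cannot be applied to this taxon set")
  tr <- .with_seed(seed, ape::multi2di(bb, random = TRUE))
  tr$edge.length <- rep(default_bl, nrow(tr$edge))
  .prep_tree(tr, tips)
}

# ---- tree search -----------------------------------------------------------

# internal: shared search driver over one or more blocks
.search_blocks <- function(start, blocks, ntip, constraints = NULL,
                           max_sweeps = 10, min_impr = 1e-4, opt_rmult = FALSE,
                           opt_passes = 2) {
  .eng_search(start$edge, start$edge.length, ntip, blocks, constraints,
              max_sweeps, min_impr, opt_rmult, opt_passes)
}

#' Maximum-likelihood gene-tree search by NNI hill climbing
#'
#' Hill-climbs over nearest-neighbor-interchange rearrangements with
#' branch-length re-optimization, optionally restricted to topologies
#' compatible with a backbone constraint (checked by bipartition
#' compatibility; incompatible moves are rejected).  Accepted moves never
#' decrease the log-likelihood.
#'
#' @param locus a [locus_aln()].
#' @param model a fitted [subst_model()]; if `NULL`, an HKY85+G model is
#'   fitted first.
#' @param start optional starting tree; defaults to the NJ starting tree
#'   (unconstrained) or a seeded random resolution of the backbone
#'   (constrained).
#' @param constraint optional [constraint_hyp()].
#' @param nstarts number of starting trees (extra starts are random
#'   perturbations or re-resolutions, seeded).
#' @param seed integer seed for start generation.
#' @param max_sweeps maximum NNI sweeps.
#' @return the best tree found; attributes `loglik` and `model`.
#' @export
nni_search <- function(locus, model = NULL, start = NULL, constraint = NULL,
                       nstarts = 1, seed = 1, max_sweeps = 10) {
  taxa <- locus_taxa(locus)
  if (length(taxa) > 60 && !is.null(constraint))
    stop("constrained search supports at most 60 taxa")
  if (is.null(model)) model <- fit_model(locus, "HKY85", gamma = TRUE)
  cp <- compress_patterns(locus)
  cons <- if (!is.null(constraint)) .constraint_masks(constraint, taxa) else NULL
  seeds <- .derive_seeds(if (!is.null(constraint))
    .backbone_seed(seed, .prune_backbone(constraint, taxa)) else seed, nstarts)
  starts <- vector("list", nstarts)
  for (i in seq_len(nstarts)) {
    if (!is.null(constraint)) {
      starts[[i]] <- .constrained_start(constraint, taxa, seeds[i])
    } else if (i == 1 && !is.null(start)) {
      starts[[i]] <- .prep_tree(start, taxa)
    } else if (i == 1) {
      starts[[i]] <- nj_start_tree(locus)
    } else {
      base <- if (!is.null(start)) .prep_tree(start, taxa) else nj_start_tree(locus)
      starts[[i]] <- .with_seed(seeds[i], phangorn::rNNI(base, moves = 2))
      starts[[i]] <- .prep_tree(starts[[i]], taxa)
    }
  }
  if (!is.null(start) && !is.null(constraint)) starts[[1]] <- .prep_tree(start, taxa)
  best <- NULL
  for (i in seq_len(nstarts)) {
    st <- starts[[i]]
    blocks <- list(.make_block(cp$patterns, cp$weights, model, st$tip.label))
    consi <- if (!is.null(constraint)) .constraint_masks(constraint, st$tip.label) else NULL
    res <- .search_blocks(st, blocks, length(taxa), consi, max_sweeps)
    if (is.null(best) || res$loglik > attr(best, "loglik")) {
      best <- .tree_from_engine(res, st$tip.label)
      attr(best, "loglik") <- res$loglik
    }
  }
  attr(best, "model") <- model
  best
}

#' Per-site log-likelihoods for a set of trees
#'
#' @param trees a list of `phylo` trees (or a `multiPhylo`), all spanning the
#'   locus taxa, with branch lengths already optimized.
#' @param model a [subst_model()] used for every tree.
#' @param locus a [locus_aln()].
#' @param tree_labels optional row labels.
#' @return a K x S matrix of per-site log-likelihoods (class
#'   `site_lnl_matrix`), with attribute `loglik` giving each tree's total.
#' @export
per_site_loglik <- function(trees, model, locus, tree_labels = NULL) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  S <- n_sites(locus)
  out <- matrix(NA_real_, length(trees), S)
  for (i in seq_along(trees)) {
    ll <- tree_loglik(trees[[i]], model, locus, per_site = TRUE)
    out[i, ] <- attr(ll, "site_loglik")
  }
  rownames(out) <- tree_labels %||% names(trees) %||%
    paste0("tree", seq_along(trees))
  attr(out, "loglik") <- rowSums(out)
  attr(out, "locus_id") <- locus$id
  class(out) <- c("site_lnl_matrix", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- bootstrap -------------------------------------------------------------

#' Nonparametric bootstrap branch supports
#'
#' Resamples sites with replacement, re-estimates each replicate's tree de
#' novo (NJ start on the resampled data, NNI hill climb, model parameters
#' held fixed at their ML estimates), and reports for each internal branch
#' of the ML tree the percentage of replicates displaying that bipartition.
#'
#' @param locus a [locus_aln()].
#' @param model fitted [subst_model()] (parameters are held fixed across
#'   replicates).
#' @param ml_tree the maximum-likelihood tree whose branches are annotated.
#' @param replicates number of bootstrap replicates.
#' @param seed integer seed.
#' @param scheme optional [partition_scheme()]; when given, sites are
#'   resampled within each segment and each segment keeps its own model
#'   (see [partitioned_search()]).
#' @param segment_models per-segment models (required with `scheme`).
#' @param max_sweeps NNI sweeps per replicate.
#' @return `ml_tree` with supports (0-100) as `node.label`; attribute
#'   `support_table` maps each internal split to its support.
#' @export
bootstrap_supports <- function(locus, model, ml_tree, replicates = 100, seed = 1,
                               scheme = NULL, segment_models = NULL,
                               max_sweeps = 5) {
  stopifnot(replicates >= 1)
  taxa <- locus_taxa(locus)
  ml_tree <- .prep_tree(ml_tree, taxa)
  if (is.null(scheme)) {
    parts <- list(locus)
    models <- list(model)
  } else {
    parts <- partition_locus(locus, scheme)
    models <- segment_models %||% rep(list(model), length(parts))
  }
  cps <- lapply(parts, compress_patterns)
  blocks0 <- mapply(function(cp, m) .make_block(cp$patterns, cp$weights, m,
                                                ml_tree$tip.label),
                    cps, models, SIMPLIFY = FALSE)
  keys_ml <- .tree_splits(ml_tree)
  tally <- stats::setNames(numeric(length(keys_ml)), keys_ml)
  seeds <- .derive_seeds(seed, replicates)
  # site-level resampling shared across analysis modes: for a given locus and
  # seed, replicate r draws the same sites whether or not the locus is
  # partitioned, so paired comparisons of supports are common-random-number
  # paired and replicate noise largely cancels
  n_sites_block <- vapply(cps, function(cp) length(cp$index), 0L)
  S_total <- sum(n_sites_block)
  block_of_site <- rep(seq_along(cps), times = n_sites_block)
  for (r in seq_len(replicates)) {
    counts <- .with_seed(seeds[r],
      as.integer(stats::rmultinom(1, S_total, rep(1 / S_total, S_total))))
    blocks <- blocks0
    wr_all <- list()
    for (j in seq_along(blocks)) {
      cnt_j <- counts[block_of_site == j]
      wr <- as.numeric(rowsum(cnt_j, cps[[j]]$index))
      wr_all[[j]] <- wr
      keep <- wr > 0  # unsampled patterns contribute nothing
      blocks[[j]]$weights <- wr[keep]
      blocks[[j]]$tipstate <- blocks0[[j]]$tipstate[, keep, drop = FALSE]
    }
    # de novo start for every replicate (avoids the ML-start bias that
    # inflates support when the likelihood surface is flat)
    start <- .nj_from_patterns(
      do.call(cbind, lapply(cps, `[[`, "patterns"))[ml_tree$tip.label, , drop = FALSE],
      unlist(wr_all))
    start_blocks <- lapply(blocks, function(b) {
      b$tipstate <- b$tipstate[match(start$tip.label, ml_tree$tip.label), ,
                               drop = FALSE]
      b
    })
    res <- .search_blocks(start, start_blocks, length(taxa), NULL, max_sweeps,
                          min_impr = 1e-3, opt_rmult = length(blocks) > 1,
                          opt_passes = 1)
    keys <- .tree_splits(.tree_from_engine(res, start$tip.label))
    hit <- keys_ml %in% keys
    tally[hit] <- tally[hit] + 1
  }
  supp <- 100 * tally / replicates
  out <- .annotate_supports(ml_tree, supp)
  attr(out, "support_table") <- supp
  out
}

# write per-split supports onto node labels of the (unrooted) tree
.annotate_supports <- function(tree, supp) {
  ntip <- length(tree$tip.label)
  labs <- rep("", tree$Nnode)
  plabs <- tree$tip.label
  sets <- .clade_sets(tree)
  for (v in (ntip + 1):(ntip + tree$Nnode)) {
    side <- sets[[v]]
    if (is.null(side) || length(side) < 2 || length(side) > ntip - 2) next
    if (!(plabs[1] %in% side)) side <- setdiff(plabs, side)
    key <- paste(sort(side), collapse = "|")
    if (key %in% names(supp)) labs[v - ntip] <- sprintf("%g", supp[[key]])
  }
  tree$node.label <- labs
  tree
}

# ---- partitioned models ----------------------------------------------------

#' Partitioned (edge-linked proportional) log-likelihood
#'
#' All segments share the tree topology and branch lengths; each segment has
#' its own substitution model and a proportional rate multiplier on the
#' shared branch lengths.  The total log-likelihood is the sum over segments.
#'
#' @param segments list of `list(locus = , model = )` pairs sharing a taxon
#'   set.
#' @param tree shared `phylo` tree.
#' @param optimize optimize shared branch lengths and segment rate
#'   multipliers?
#' @return log-likelihood; when `optimize = TRUE`, attributes `tree` and
#'   `rmult` carry the optimized fit.
#' @export
partitioned_loglik <- function(segments, tree, optimize = FALSE) {
  taxa <- locus_taxa(segments[[1]]$locus)
  for (s in segments) if (!setequal(locus_taxa(s$locus), taxa))
    stop("segments do not share a taxon set")
  tree <- .prep_tree(tree, taxa)
  blocks <- lapply(segments, function(s) {
    cp <- compress_patterns(s$locus)
    .make_block(cp$patterns, cp$weights, s$model, tree$tip.label,
                rmult = s$rmult %||% 1)
  })
  if (!optimize) {
    return(.eng_loglik(tree$edge, tree$edge.length, length(taxa), blocks, FALSE)$loglik)
  }
  res <- .eng_optim_edges(tree$edge, tree$edge.length, length(taxa), blocks,
                          20, 1e-6, TRUE)
  out <- res$loglik
  attr(out, "tree") <- .tree_from_engine(res, tree$tip.label)
  attr(out, "rmult") <- res$rmult
  out
}

#' Partitioned NNI tree search
#'
#' NNI hill climbing under the edge-linked proportional partitioned model of
#' [partitioned_loglik()].
#'
#' @inheritParams partitioned_loglik
#' @param start starting tree (defaults to NJ on the concatenated segments).
#' @param constraint optional [constraint_hyp()].
#' @param max_sweeps maximum NNI sweeps.
#' @return best tree; attributes `loglik` and `rmult`.
#' @export
partitioned_search <- function(segments, start = NULL, constraint = NULL,
                               max_sweeps = 10) {
  taxa <- locus_taxa(segments[[1]]$locus)
  if (is.null(start)) {
    concat <- locus_aln(do.call(cbind, lapply(segments, function(s) s$locus$seq)),
                        id = "concat")
    start <- nj_start_tree(concat)
  }
  start <- .prep_tree(start, taxa)
  blocks <- lapply(segments, function(s) {
    cp <- compress_patterns(s$locus)
    .make_block(cp$patterns, cp$weights, s$model, start$tip.label,
                rmult = s$rmult %||% 1)
  })
  cons <- if (!is.null(constraint)) .constraint_masks(constraint, start$tip.label) else NULL
  res <- .search_blocks(start, blocks, length(taxa), cons, max_sweeps,
                        opt_rmult = TRUE)
  out <- .tree_from_engine(res, start$tip.label)
  attr(out, "loglik") <- res$loglik
  attr(out, "rmult") <- res$rmult
  out
}
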