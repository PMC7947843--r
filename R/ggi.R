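#' Configuration for gene genealogy interrogation (GGI)
#'
#' GGI asks, locus by locus, which of a set of predefined genealogical
#' hypotheses is best supported: constrained gene trees are estimated under
#' each hypothesis (plus, in the modified version, an unconstrained tree),
#' their per-site log-likelihoods are compared with the approximately
#' unbiased (AU) test, and a locus supports a hypothesis significantly when
#' that hypothesis's tree is best by total log-likelihood *and* its AU
#' p-value exceeds the threshold.
#'
#' @param hypotheses list of [constraint_hyp()] (K >= 2).
#' @param include_unconstrained also estimate and test an unconstrained gene
#'   tree (the "modified" GGI)?
#' @param scales multiscale bootstrap resampling factors (must include 1).
#' @param replicates RELL bootstrap replicates per scale.
#' @param threshold AU significance threshold (best tree's p must exceed it).
#' @param model substitution model family for tree estimation and site
#'   likelihoods (`"GTR"` with gamma by default).
#' @param gamma use discrete-gamma rate variation?
#' @param nstarts starting trees per search.
#' @param seed master seed.
#' @return an object of class `ggi_config`.
#' @export
ggi_config <- function(hypotheses, include_unconstrained = FALSE,
                       scales = seq(0.5, 1.4, by = 0.1), replicates = 1000,
                       threshold = 0.95, model = "GTR", gamma = TRUE,
                       nstarts = 2, seed = 1) {
  stopifnot(length(hypotheses) >= 2, all(scales > 0), any(abs(scales - 1) < 1e-9),
            threshold > 0, threshold < 1, replicates >= 1)
  labels <- vapply(hypotheses, function(h) h$label, "")
  if (anyDuplicated(labels)) stop("duplicate hypothesis labels")
  structure(list(hypotheses = hypotheses, labels = labels,
                 include_unconstrained = include_unconstrained,
                 scales = scales, replicates = as.integer(replicates),
                 threshold = threshold, model = model, gamma = gamma,
                 nstarts = as.integer(nstarts), seed = as.integer(seed)),
            class = "ggi_config")
}

#' Multiscale RELL bootstrap proportions
#'
#' For each scale r, draws `round(r * S)` site indices with replacement and
#' sums each tree's per-site log-likelihoods (resampling estimated
#' log-likelihoods); the tree with the largest resampled total wins the
#' replicate, ties broken uniformly at random.  BP is the winning fraction.
#'
#' @param site_lnl K x S matrix of per-site log-likelihoods (rows = trees).
#' @param scales resampling factors.
#' @param replicates replicates per scale.
#' @param seed integer seed.
#' @return K x length(scales) matrix of bootstrap proportions; columns sum
#'   to 1.
#' @export
rell_bootstrap <- function(site_lnl, scales = seq(0.5, 1.4, by = 0.1),
                           replicates = 1000, seed = 1) {
  site_lnl <- unclass(site_lnl)
  K <- nrow(site_lnl); S <- ncol(site_lnl)
  if (K < 2) stop("need at least 2 trees")
  if (S < 10) stop("need at least 10 sites")
  if (any(!is.finite(site_lnl))) stop("non-finite site log-likelihoods")
  bp <- matrix(0, K, length(scales),
               dimnames = list(rownames(site_lnl), sprintf("%g", scales)))
  .with_seed(seed, {
    for (si in seq_along(scales)) {
      m <- max(1L, round(scales[si] * S))
      W <- stats::rmultinom(replicates, m, rep(1 / S, S))  # S x replicates
      tot <- site_lnl %*% W                                # K x replicates
      win <- max.col(t(tot), ties.method = "random")
      bp[, si] <- tabulate(win, nbins = K) / replicates
    }
  })
  bp
}

#' AU test p-values from multiscale bootstrap proportions
#'
#' Fits z(r) = d*sqrt(r) + c/sqrt(r), with z(r) the probit of 1 - BP(r), by
#' weighted least squares (binomial weights), and reports
#' p_AU = 1 - Phi(d - c) per tree.  BP values are clipped to
#' `[1/(10*replicates), 1 - 1/(10*replicates)]` before the probit transform.
#' A tree whose BP is degenerate (identically 1 or identically 0 across
#' scales) is flagged and given p 1 or 0 respectively.
#'
#' @param bp K x n_scales matrix from [rell_bootstrap()].
#' @param scales the resampling factors (column order of `bp`).
#' @param replicates replicates per scale (for clipping and weights).
#' @return data.frame with `tree`, `c`, `d`, `p_au`, `degenerate`.
#' @export
au_pvalue <- function(bp, scales = as.numeric(colnames(bp)), replicates = 1000) {
  stopifnot(ncol(bp) == length(scales))
  eps <- 1 / (10 * replicates)
  out <- data.frame(tree = rownames(bp) %||% paste0("tree", seq_len(nrow(bp))),
                    c = NA_real_, d = NA_real_, p_au = NA_real_,
                    degenerate = FALSE)
  for (i in seq_len(nrow(bp))) {
    b <- bp[i, ]
    usable <- b > 0 & b < 1
    if (sum(usable) < 2) {
      if (all(b >= 0.5)) {
        out$p_au[i] <- 1.0
      } else {
        out$p_au[i] <- 0.0
      }
      out$degenerate[i] <- TRUE
      next
    }
    bc <- pmin(pmax(b, eps), 1 - eps)
    z <- stats::qnorm(1 - bc)
    X <- cbind(d = sqrt(scales), c = 1 / sqrt(scales))
    w <- replicates * stats::dnorm(z)^2 / (bc * (1 - bc))
    fit <- stats::lm.wfit(X, z, w)
    d <- fit$coefficients[["d"]]; cc <- fit$coefficients[["c"]]
    out$c[i] <- cc; out$d[i] <- d
    out$p_au[i] <- 1 - stats::pnorm(d - cc)
  }
  out
}

#' GGI test for one locus
#'
#' Runs one constrained gene-tree search per hypothesis (plus an
#' unconstrained search in the modified version), computes the per-site
#' log-likelihood matrix of the resulting trees under a shared model, and
#' applies the multiscale RELL bootstrap and AU test.  The best tree is the
#' one with the highest total log-likelihood; the locus supports it
#' significantly iff its AU p exceeds the configured threshold.
#'
#' Constrained starts are seeded from the backbone content, so hypotheses
#' with identical (pruned) backbones yield identical searches and identical
#' site-likelihood rows.
#'
#' @param locus a [locus_aln()].
#' @param config a [ggi_config()].
#' @param seed per-locus seed (defaults to the config seed).
#' @param model optional pre-fitted [subst_model()] for this locus.
#' @return an object of class `au_test_result`, or `NULL` (with a message
#'   attribute) when the locus must be skipped; fields: `locus_id`, `labels`,
#'   `bp`, `au` (the [au_pvalue()] table), `loglik`, `best`, `significant`,
#'   `trees`.
#' @export
ggi_locus_test <- function(locus, config, seed = config$seed, model = NULL) {
  taxa <- locus_taxa(locus)
  if (length(taxa) < 4) return(.ggi_skip(locus$id, "fewer than 4 taxa"))
  for (h in config$hypotheses) {
    bb <- tryCatch(.prune_backbone(h, taxa), error = function(e) NULL)
    if (is.null(bb) || is.null(.constraint_masks(h, taxa)))
      return(.ggi_skip(locus$id,
                       sprintf("hypothesis %s has < 2 constraint clades after pruning",
                               h$label)))
  }
  if (is.null(model))
    model <- fit_model(locus, config$model, gamma = config$gamma)
  trees <- list()
  labels <- character(0)
  for (h in config$hypotheses) {
    trees[[length(trees) + 1]] <-
      nni_search(locus, model, constraint = h, nstarts = config$nstarts,
                 seed = seed)
    labels <- c(labels, h$label)
  }
  if (config$include_unconstrained) {
    trees[[length(trees) + 1]] <-
      nni_search(locus, model, nstarts = config$nstarts, seed = seed)
    labels <- c(labels, "unconstrained")
  }
  names(trees) <- labels
  slm <- per_site_loglik(trees, model, locus, tree_labels = labels)
  bp <- rell_bootstrap(slm, config$scales, config$replicates, seed = seed)
  au <- au_pvalue(bp, config$scales, config$replicates)
  tot <- attr(slm, "loglik")
  best <- which.max(tot)
  structure(list(locus_id = locus$id, labels = labels, bp = bp, au = au,
                 loglik = tot, best = labels[best],
                 significant = au$p_au[best] > config$threshold,
                 trees = trees),
            class = "au_test_result")
}

.ggi_skip <- function(id, reason) {
  structure(list(locus_id = id, skipped = TRUE, reason = reason),
            class = "ggi_skip")
}

#' @export
print.au_test_result <- function(x, ...) {
  cat(sprintf("<au_test_result> %s: best=%s (p_AU=%.3f%s)\n", x$locus_id,
              x$best, x$au$p_au[match(x$best, x$labels)],
              if (x$significant) ", significant" else ""))
  invisible(x)
}

#' Run GGI over a locus collection
#'
#' @param loci list of [locus_aln()].
#' @param config a [ggi_config()].
#' @param models optional named list of pre-fitted per-locus models.
#' @return list with `results` (per-locus [ggi_locus_test()] outputs),
#'   `skipped` (ids and reasons), and `tally` (a [ggi_tally()] summary).
#' @export
ggi_run <- function(loci, config, models = NULL) {
  seeds <- .derive_seeds(config$seed, length(loci))
  results <- list(); skipped <- list()
  for (i in seq_along(loci)) {
    r <- ggi_locus_test(loci[[i]], config, seed = seeds[i],
                        model = models[[loci[[i]]$id]])
    if (inherits(r, "ggi_skip")) skipped[[length(skipped) + 1]] <- r
    else results[[length(results) + 1]] <- r
  }
  list(results = results, skipped = skipped,
       tally = ggi_tally(results, config))
}

#' Tally GGI results per hypothesis
#'
#' Counts, over all tested loci and over loci with significant support
#' (best tree's AU p above the threshold), how many loci support each
#' hypothesis, with percentages relative to the total number tested.
#'
#' @param results list of [ggi_locus_test()] results.
#' @param config the [ggi_config()] used.
#' @return data.frame with `hypothesis`, `n_all`, `pct_all`, `n_signif`,
#'   `pct_signif`; attribute `n_loci` gives the total.
#' @export
ggi_tally <- function(results, config) {
  labels <- config$labels
  if (config$include_unconstrained) labels <- c(labels, "unconstrained")
  n <- length(results)
  best <- vapply(results, function(r) r$best, "")
  sig <- vapply(results, function(r) isTRUE(r$significant), NA)
  out <- data.frame(
    hypothesis = labels,
    n_all = vapply(labels, function(l) sum(best == l), 0L),
    n_signif = vapply(labels, function(l) sum(best == l & sig), 0L))
  out$pct_all <- if (n > 0) 100 * out$n_all / n else 0
  out$pct_signif <- if (n > 0) 100 * out$n_signif / n else 0
  out <- out[, c("hypothesis", "n_all", "pct_all", "n_signif", "pct_signif")]
  attr(out, "n_loci") <- n
  out
}

#' Select gene trees for the final summary species tree
#'
#' Keeps, per locus, the best tree when it is either the unconstrained tree
#' or the constrained tree of `keep_hypothesis`; loci whose best tree is any
#' other hypothesis are discarded.
#'
#' @param results list of [ggi_locus_test()] results from the modified GGI
#'   (unconstrained trees included).
#' @param keep_hypothesis hypothesis label to keep.
#' @return `multiPhylo` of selected gene trees (one per kept locus), named by
#'   locus id; attribute `n_discarded` counts dropped loci.
#' @export
select_gene_trees <- function(results, keep_hypothesis) {
  labels_all <- unique(unlist(lapply(results, function(r) r$labels)))
  if (!keep_hypothesis %in% labels_all)
    stop("unknown hypothesis: ", keep_hypothesis)
  keep <- vapply(results, function(r) r$best %in% c(keep_hypothesis, "unconstrained"),
                 NA)
  trees <- lapply(results[keep], function(r) r$trees[[r$best]])
  names(trees) <- vapply(results[keep], function(r) r$locus_id, "")
  class(trees) <- "multiPhylo"
  attr(trees, "n_discarded") <- sum(!keep)
  trees
}
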