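#' Pipeline configuration
#'
#' Collects the knobs of the full incongruence-diagnosis design: taxon
#' completeness regimes, the five-criterion locus filter, within-locus
#' partitioning, gene-tree estimation settings, and the GGI stage.
#'
#' @param completeness completeness thresholds defining the datasets
#'   (defaults to the conventional 75p and 90p regimes).
#' @param criteria filtering criteria for strategy 1.
#' @param k loci retained per criterion (the "k best" selection).
#' @param min_len minimum segment length for entropy partitioning.
#' @param model_name substitution model family for gene trees.
#' @param gamma discrete-gamma rate variation for gene trees?
#' @param select_models run per-locus BIC model selection instead of a fixed
#'   family?
#' @param bootstrap_replicates bootstrap replicates for gene-tree supports
#'   (0 disables supports).
#' @param hypotheses list of [constraint_hyp()] used both to classify result
#'   trees and as the GGI constraint set (NULL skips classification/GGI).
#' @param ggi_replicates RELL replicates per scale in the GGI stage.
#' @param ggi_unconstrained run the modified GGI (with unconstrained trees)?
#' @param outgroup optional outgroup taxa for rooted renderings.
#' @param seed master seed.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(completeness = c(0.75, 0.90),
                            criteria = c("avg_bootstrap", "clocklikeness", "gc",
                                         "npis", "saturation"),
                            k = 600, min_len = 50,
                            model_name = "HKY85", gamma = TRUE,
                            select_models = FALSE,
                            bootstrap_replicates = 100,
                            hypotheses = NULL,
                            ggi_replicates = 1000,
                            ggi_unconstrained = TRUE,
                            outgroup = NULL, seed = 1) {
  stopifnot(all(completeness > 0), all(completeness <= 1), k >= 1, min_len >= 1)
  structure(list(completeness = completeness, criteria = criteria, k = k,
                 min_len = min_len, model_name = model_name, gamma = gamma,
                 select_models = select_models,
                 bootstrap_replicates = bootstrap_replicates,
                 hypotheses = hypotheses, ggi_replicates = ggi_replicates,
                 ggi_unconstrained = ggi_unconstrained,
                 outgroup = outgroup, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as JSON
#'
#' The configuration round-trips through a flat JSON file; constraint
#' hypotheses are stored as labelled newick strings.
#'
#' @param config a [pipeline_config()].
#' @param path file path.
#' @return `write_pipeline_config()` returns `path` invisibly;
#'   `read_pipeline_config()` returns the reconstructed [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  if (!is.null(x$hypotheses))
    x$hypotheses <- lapply(x$hypotheses, function(h)
      list(label = h$label, backbone = ape::write.tree(h$backbone)))
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  hyps <- NULL
  if (!is.null(x$hypotheses) && length(x$hypotheses))
    hyps <- lapply(seq_len(nrow(x$hypotheses)), function(i)
      constraint_hyp(x$hypotheses$label[i], x$hypotheses$backbone[i]))
  pipeline_config(completeness = x$completeness, criteria = x$criteria,
                  k = x$k, min_len = x$min_len, model_name = x$model_name,
                  gamma = x$gamma, select_models = x$select_models,
                  bootstrap_replicates = x$bootstrap_replicates,
                  hypotheses = hyps, ggi_replicates = x$ggi_replicates,
                  ggi_unconstrained = x$ggi_unconstrained,
                  outgroup = unlist(x$outgroup), seed = x$seed)
}

# loci list from a synthetic_dataset or a plain list
.as_loci <- function(x) {
  if (inherits(x, "synthetic_dataset")) x$loci else x
}

#' Estimate one gene tree (optionally partitioned) with supports
#'
#' The single-locus work unit of the pipeline: fits a substitution model,
#' hill-climbs the topology, and (optionally) annotates nonparametric
#' bootstrap supports.  With `partition = TRUE` the locus is first split at
#' its entropy breakpoints and analyzed under the edge-linked partitioned
#' model with one substitution model per segment; loci too short to split
#' fall back to the unpartitioned analysis and are flagged.
#'
#' @param locus a [locus_aln()].
#' @param partition partition the locus at its entropy breakpoints?
#' @param min_len minimum segment length for partitioning.
#' @param model_name,gamma,select_models model settings (see
#'   [pipeline_config()]).
#' @param bootstrap_replicates bootstrap replicates (0 = no supports).
#' @param seed integer seed.
#' @return the gene tree (`phylo`) with supports in `node.label` (when
#'   bootstrapped) and attributes `loglik`, `model` (or `segment_models`),
#'   `scheme`, and `partitioned`.
#' @export
estimate_gene_tree <- function(locus, partition = FALSE, min_len = 50,
                               model_name = "HKY85", gamma = TRUE,
                               select_models = FALSE,
                               bootstrap_replicates = 0, seed = 1) {
  if (!partition) {
    model <- if (select_models) select_model(locus)
             else fit_model(locus, model_name, gamma = gamma)
    ml <- nni_search(locus, model, seed = seed)
    if (bootstrap_replicates > 0)
      ml <- .keep_attrs(bootstrap_supports(locus, model, ml,
                                           replicates = bootstrap_replicates,
                                           seed = seed), ml)
    attr(ml, "model") <- model
    attr(ml, "partitioned") <- FALSE
    return(ml)
  }
  scheme <- best_breakpoints(entropy_profile(locus), min_len = min_len,
                             locus_id = locus$id)
  if (isTRUE(scheme$unpartitionable)) {
    out <- estimate_gene_tree(locus, partition = FALSE, model_name = model_name,
                              gamma = gamma, select_models = select_models,
                              bootstrap_replicates = bootstrap_replicates,
                              seed = seed)
    attr(out, "scheme") <- scheme
    return(out)
  }
  segs <- partition_locus(locus, scheme)
  start <- nj_start_tree(locus)
  seg_models <- lapply(segs, function(s) {
    if (select_models) select_model(s)
    else fit_model(s, model_name, gamma = gamma, tree = start)
  })
  segments <- mapply(function(s, m) list(locus = s, model = m), segs, seg_models,
                     SIMPLIFY = FALSE)
  ml <- partitioned_search(segments, start = start)
  # re-estimate each segment's parameters on the joint tree (mirroring the
  # alternation the single-model fit gets), then polish the joint fit
  seg_models <- mapply(function(s, m, r) {
    tr <- ml
    tr$edge.length <- tr$edge.length * r
    cp <- compress_patterns(s)
    .fit_params_fixed_edges(tr, m, function(mm)
      .make_block(cp$patterns, cp$weights, mm, tr$tip.label))
  }, segs, seg_models, attr(ml, "rmult"), SIMPLIFY = FALSE)
  segments <- mapply(function(s, m) list(locus = s, model = m), segs, seg_models,
                     SIMPLIFY = FALSE)
  ml <- partitioned_search(segments, start = ml)
  if (bootstrap_replicates > 0)
    ml <- .keep_attrs(bootstrap_supports(locus, seg_models[[1]], ml,
                                         replicates = bootstrap_replicates,
                                         seed = seed, scheme = scheme,
                                         segment_models = seg_models), ml)
  attr(ml, "segment_models") <- seg_models
  attr(ml, "scheme") <- scheme
  attr(ml, "partitioned") <- TRUE
  ml
}

.keep_attrs <- function(new, old) {
  for (a in c("loglik", "rmult")) attr(new, a) <- attr(old, a)
  new
}

#' Maximum-likelihood tree for a concatenated supermatrix
#'
#' Treats the supermatrix as one alignment under a single fitted model (a
#' deliberate desk-scale simplification of fully partitioned concatenated
#' analysis).
#'
#' @param sm a [concatenate()] result.
#' @param model_name,gamma model settings.
#' @param seed integer seed.
#' @return the ML tree with attribute `loglik`.
#' @export
concat_ml_tree <- function(sm, model_name = "HKY85", gamma = TRUE, seed = 1) {
  loc <- locus_aln(sm$seq, id = "supermatrix")
  model <- fit_model(loc, model_name, gamma = gamma)
  nni_search(loc, model, seed = seed)
}

#' Classify a result tree against competing hypotheses
#'
#' Prunes the tree to each hypothesis's backbone taxa and reports the label
#' of the first hypothesis whose non-trivial splits are all displayed;
#' `"other"` when none matches.
#'
#' @param tree a `phylo`.
#' @param hypotheses list of [constraint_hyp()].
#' @return a hypothesis label or `"other"`.
#' @export
classify_tree <- function(tree, hypotheses) {
  for (h in hypotheses) {
    taxa <- intersect(h$backbone$tip.label, tree$tip.label)
    if (length(taxa) < 4) next
    sub <- ape::unroot(ape::keep.tip(tree, taxa))
    hb <- ape::unroot(ape::keep.tip(h$backbone, taxa))
    need <- .tree_splits(hb)
    if (length(need) && all(need %in% .tree_splits(sub))) return(h$label)
  }
  "other"
}

#' Baseline analyses: concatenated ML and summary species tree
#'
#' For each completeness regime: filter the loci, estimate unpartitioned
#' gene trees with bootstrap supports, build the concatenated ML tree and
#' the quartet summary species tree, and classify both against the
#' configured hypotheses.
#'
#' @param data a [simulate_dataset()] result or list of [locus_aln()].
#' @param config a [pipeline_config()].
#' @return list (one element per completeness regime) with `loci`,
#'   `gene_trees`, `concat_tree`, `species_tree`, and a `report` data.frame.
#' @export
run_baseline <- function(data, config) {
  loci <- .as_loci(data)
  total_taxa <- length(unique(unlist(lapply(loci, locus_taxa))))
  seeds <- .derive_seeds(config$seed, length(loci))
  names(seeds) <- names(loci)
  out <- list()
  for (th in config$completeness) {
    dsname <- sprintf("%dp", round(100 * th))
    sel <- filter_by_completeness(loci, total_taxa, th)
    if (!length(sel)) stop("no loci pass completeness ", th)
    gts <- lapply(names(sel), function(id)
      estimate_gene_tree(sel[[id]], partition = FALSE,
                         model_name = config$model_name, gamma = config$gamma,
                         select_models = config$select_models,
                         bootstrap_replicates = config$bootstrap_replicates,
                         seed = seeds[[id]]))
    names(gts) <- names(sel)
    concat_tree <- concat_ml_tree(concatenate(sel), config$model_name,
                                  config$gamma, seed = config$seed)
    qt <- quartet_table(gts)
    st <- search_species_tree(qt, gene_trees = gts, seed = config$seed)
    report <- .classify_rows(dsname, concat_tree, st$tree, config)
    out[[dsname]] <- list(loci = sel, gene_trees = gts,
                          concat_tree = concat_tree, species_tree = st,
                          report = report)
  }
  out
}

.classify_rows <- function(dsname, concat_tree, species_tree, config,
                           method_suffix = "") {
  if (is.null(config$hypotheses)) return(NULL)
  data.frame(
    dataset = dsname,
    method = paste0(c("concat_ml", "summary"), method_suffix),
    hypothesis = c(classify_tree(concat_tree, config$hypotheses),
                   classify_tree(species_tree, config$hypotheses)))
}

#' Strategy 1: five-criterion locus filtering
#'
#' Computes the five per-locus statistics from the baseline gene trees,
#' selects the best `k` loci per criterion, re-runs the concatenated ML and
#' summary analyses on each filtered set, and classifies the results.
#'
#' @param baseline output of [run_baseline()].
#' @param config a [pipeline_config()].
#' @return list per completeness regime with `stats`, `selections`, and a
#'   `report` data.frame (5 criteria x 2 methods rows each).
#' @export
run_strategy1 <- function(baseline, config) {
  out <- list()
  for (dsname in names(baseline)) {
    bl <- baseline[[dsname]]
    stats <- do.call(rbind, lapply(names(bl$loci), function(id)
      locus_stats(bl$loci[[id]], bl$gene_trees[[id]])))
    k <- min(config$k, length(bl$loci))
    selections <- list(); reports <- list()
    for (crit in config$criteria) {
      ids <- tryCatch(rank_and_select(stats, crit, k), error = function(e) NULL)
      if (is.null(ids)) next
      sel <- bl$loci[ids]
      concat_tree <- concat_ml_tree(concatenate(sel), config$model_name,
                                    config$gamma, seed = config$seed)
      gts <- bl$gene_trees[ids]
      st <- search_species_tree(quartet_table(gts), gene_trees = gts,
                                seed = config$seed)
      selections[[crit]] <- ids
      reports[[crit]] <- .classify_rows(paste0(dsname, "-", crit), concat_tree,
                                        st$tree, config)
    }
    out[[dsname]] <- list(stats = stats, selections = selections,
                          report = do.call(rbind, reports))
  }
  out
}

#' Strategy 2: partitioned gene-tree analyses
#'
#' Re-estimates every gene tree with the locus split into left flank, core
#' and right flank at its entropy breakpoints (separate substitution model
#' per segment), rebuilds the summary species trees from the partitioned
#' gene trees, and tests per dataset whether partitioning improved the mean
#' bootstrap support of the gene trees (paired one-sided Wilcoxon,
#' Holm-corrected across datasets).
#'
#' @param baseline output of [run_baseline()].
#' @param config a [pipeline_config()].
#' @return list with per-regime `gene_trees` (partitioned), `species_tree`,
#'   `report`, and a family-wide `support_test` table.
#' @export
run_strategy2 <- function(baseline, config) {
  out <- list(); pairs <- list()
  seeds <- .derive_seeds(config$seed + 1L, sum(lengths(lapply(baseline, `[[`, "loci"))))
  si <- 0L
  for (dsname in names(baseline)) {
    bl <- baseline[[dsname]]
    gts <- list()
    for (id in names(bl$loci)) {
      si <- si + 1L
      gts[[id]] <- estimate_gene_tree(bl$loci[[id]], partition = TRUE,
                                      min_len = config$min_len,
                                      model_name = config$model_name,
                                      gamma = config$gamma,
                                      select_models = config$select_models,
                                      bootstrap_replicates = config$bootstrap_replicates,
                                      seed = seeds[si])
    }
    st <- search_species_tree(quartet_table(gts), gene_trees = gts,
                              seed = config$seed)
    pairs[[dsname]] <- list(
      before = vapply(bl$gene_trees, mean_support, 0),
      after = vapply(gts, mean_support, 0))
    report <- if (!is.null(config$hypotheses))
      data.frame(dataset = dsname, method = "summary_partitioned",
                 hypothesis = classify_tree(st$tree, config$hypotheses))
    out[[dsname]] <- list(gene_trees = gts, species_tree = st, report = report)
  }
  out$support_test <- support_test_table(pairs)
  out
}

#' Strategy 3: gene genealogy interrogation and the final species tree
#'
#' Runs GGI over the loci, keeps the best-constrained gene trees of the
#' winning hypothesis together with all best-unconstrained gene trees, and
#' summarizes them into the final species tree.
#'
#' @param data a [simulate_dataset()] result or list of [locus_aln()].
#' @param config a [pipeline_config()] with `hypotheses` set.
#' @param keep_hypothesis hypothesis whose constrained trees are kept for
#'   the final summary; default: the hypothesis with the most significant
#'   support.
#' @return list with `ggi` (tally and per-locus results), `selected_trees`,
#'   `species_tree`, and `report`.
#' @export
run_strategy3 <- function(data, config, keep_hypothesis = NULL) {
  if (is.null(config$hypotheses) || length(config$hypotheses) < 2)
    stop("strategy 3 needs at least 2 hypotheses")
  loci <- .as_loci(data)
  gcfg <- ggi_config(config$hypotheses,
                     include_unconstrained = config$ggi_unconstrained,
                     replicates = config$ggi_replicates,
                     model = if (config$model_name == "JC69") "JC69" else "GTR",
                     gamma = config$gamma, seed = config$seed)
  ggi <- ggi_run(loci, gcfg)
  tal <- ggi$tally
  if (is.null(keep_hypothesis)) {
    cand <- tal[tal$hypothesis != "unconstrained", ]
    keep_hypothesis <- cand$hypothesis[which.max(cand$n_signif)]
  }
  trees <- select_gene_trees(ggi$results, keep_hypothesis)
  st <- search_species_tree(quartet_table(trees), gene_trees = trees,
                            seed = config$seed)
  report <- data.frame(dataset = "ggi_selected", method = "summary",
                       hypothesis = classify_tree(st$tree, config$hypotheses))
  list(ggi = ggi, keep_hypothesis = keep_hypothesis, selected_trees = trees,
       species_tree = st, report = report)
}

#' Run the full incongruence-diagnosis pipeline
#'
#' Baseline analyses, strategy 1 (locus filtering), strategy 2 (partitioned
#' gene trees) and strategy 3 (GGI), returning a congruence report of the
#' hypothesis recovered by every dataset x method combination.
#'
#' @param data a [simulate_dataset()] result or list of [locus_aln()].
#' @param config a [pipeline_config()].
#' @return list with `baseline`, `strategy1`, `strategy2`, `strategy3`, and
#'   the combined `congruence_report` data.frame.
#' @export
run_pipeline <- function(data, config) {
  baseline <- run_baseline(data, config)
  s1 <- run_strategy1(baseline, config)
  s2 <- run_strategy2(baseline, config)
  s3 <- if (!is.null(config$hypotheses)) run_strategy3(data, config)
  rows <- c(lapply(baseline, `[[`, "report"),
            lapply(s1, `[[`, "report"),
            lapply(s2[names(baseline)], `[[`, "report"),
            list(if (!is.null(s3)) s3$report))
  list(baseline = baseline, strategy1 = s1, strategy2 = s2, strategy3 = s3,
       congruence_report = do.call(rbind, rows[!vapply(rows, is.null, NA)]))
}
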