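#' GC proportion of a locus
#'
#' (#G + #C) / (#A + #C + #G + #T) over all cells; gaps and ambiguity codes
#' are excluded from both numerator and denominator.
#'
#' @param locus a [locus_aln()].
#' @return proportion in [0, 1], or `NA` when the locus has no unambiguous
#'   bases (such loci rank last).
#' @export
gc_proportion <- function(locus) {
  seq <- locus$seq
  gc <- sum(seq == "G" | seq == "C")
  at <- sum(seq == "A" | seq == "T")
  if (gc + at == 0) return(NA_real_)
  gc / (gc + at)
}

#' Number of parsimony-informative sites
#'
#' A site is parsimony-informative when at least two distinct unambiguous
#' states each occur in at least two sequences; gaps and ambiguity codes are
#' treated as missing.
#'
#' @param locus a [locus_aln()].
#' @return integer count.
#' @export
count_informative_sites <- function(locus) {
  seq <- locus$seq
  counts <- rbind(colSums(seq == "A"), colSums(seq == "C"),
                  colSums(seq == "G"), colSums(seq == "T"))
  sum(colSums(counts >= 2) >= 2)
}

#' Clocklikeness of a gene tree
#'
#' How closely the gene tree approximates an ultrametric tree: the population
#' variance of root-to-tip path lengths (in (substitutions/site)^2) after
#' midpoint rooting.  Zero iff the tree is ultrametric after midpoint
#' rooting; lower is more clock-like.
#'
#' @param tree a `phylo` with branch lengths.
#' @param rooting `"midpoint"` (default) or `"asis"` to keep the tree's own
#'   root (useful for fixed-root checks).
#' @return nonnegative variance.
#' @export
clocklikeness <- function(tree, rooting = c("midpoint", "asis")) {
  rooting <- match.arg(rooting)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (rooting == "midpoint") tree <- phangorn::midpoint(tree)
  ntip <- length(tree$tip.label)
  depths <- ape::node.depth.edgelength(tree)[seq_len(ntip)]
  mean((depths - mean(depths))^2)
}

#' Saturation regression slope of a locus
#'
#' Ordinary least squares through the origin of pairwise uncorrected
#' p-distances (y) on patristic distances (x) over all taxon pairs:
#' slope = sum(xy) / sum(x^2).  Higher slopes mean less saturation.  Pairs
#' with no overlapping unambiguous sites are skipped.
#'
#' @param locus a [locus_aln()].
#' @param tree the locus gene tree (covering the locus taxa).
#' @return the slope, or 0 when all patristic distances are zero (the locus
#'   then ranks last).
#' @export
saturation_slope <- function(locus, tree) {
  taxa <- locus_taxa(locus)
  if (!all(taxa %in% tree$tip.label)) stop("tree does not cover locus taxa")
  tree <- ape::keep.tip(tree, taxa)
  x <- as.matrix(stats::cophenetic(tree))[taxa, taxa]
  y <- as.matrix(ape::dist.dna(ape::as.DNAbin(locus$seq), model = "raw",
                               pairwise.deletion = TRUE))[taxa, taxa]
  lo <- lower.tri(x)
  xs <- x[lo]; ys <- y[lo]
  ok <- is.finite(xs) & is.finite(ys)
  xs <- xs[ok]; ys <- ys[ok]
  if (!length(xs) || sum(xs^2) == 0) return(0)
  sum(xs * ys) / sum(xs^2)
}

#' Mean internal-branch support of a gene tree
#'
#' Arithmetic mean of the numeric internal-branch supports stored as node
#' labels, on the 0-100 scale.
#'
#' @param tree a `phylo` with supports in `node.label`.
#' @return mean support, or `NA` when no support values are present.
#' @export
mean_support <- function(tree) {
  if (is.null(tree$node.label)) return(NA_real_)
  v <- suppressWarnings(as.numeric(tree$node.label))
  v <- v[is.finite(v)]
  if (!length(v)) return(NA_real_)
  mean(v)
}

#' The five per-locus filtering statistics
#'
#' @param locus a [locus_aln()].
#' @param tree the locus gene tree with branch lengths and (optionally)
#'   bootstrap supports as node labels.
#' @return one-row data.frame: `locus`, `avg_bootstrap`, `clocklikeness`,
#'   `gc`, `npis`, `saturation`.
#' @export
locus_stats <- function(locus, tree) {
  data.frame(locus = locus$id,
             avg_bootstrap = mean_support(tree),
             clocklikeness = clocklikeness(tree),
             gc = gc_proportion(locus),
             npis = count_informative_sites(locus),
             saturation = saturation_slope(locus, tree))
}

# fixed best-is direction per criterion
.criterion_direction <- c(avg_bootstrap = "high", clocklikeness = "low",
                          gc = "low", npis = "high", saturation = "high")

#' Select the k best loci under one filtering criterion
#'
#' Ranks loci by the named statistic in its fixed direction (high is best for
#' average bootstrap, nPIS and saturation slope; low is best for
#' clocklikeness and GC), breaking ties by ascending locus id, and returns
#' the ids of the best `k`.  Loci with a missing statistic are excluded from
#' that criterion's ranking.
#'
#' @param stats data.frame as produced by rbinding [locus_stats()] rows.
#' @param criterion one of `avg_bootstrap`, `clocklikeness`, `gc`, `npis`,
#'   `saturation`.
#' @param k number of loci to select (default 600).
#' @return character vector of `k` locus ids, best first.
#' @export
rank_and_select <- function(stats, criterion, k = 600) {
  criterion <- match.arg(criterion, names(.criterion_direction))
  if (k <= 0) stop("k must be positive")
  v <- stats[[criterion]]
  ok <- is.finite(v)
  if (sum(ok) < k)
    stop(sprintf("k = %d exceeds the %d loci with a defined %s statistic (shortfall %d)",
                 k, sum(ok), criterion, k - sum(ok)))
  s <- stats[ok, , drop = FALSE]
  v <- v[ok]
  if (.criterion_direction[[criterion]] == "low") v <- -v
  ord <- order(-v, s$locus)
  s$locus[ord][seq_len(k)]
}

#' Paired one-sided Wilcoxon signed-rank test of support improvement
#'
#' Tests whether `after` supports exceed `before` supports (one-sided,
#' after > before) with the normal approximation, continuity and tie
#' corrections, and zero differences dropped -- the "nonexact" Wilcoxon
#' convention of `wilcox.test(exact = FALSE)`.
#'
#' @param before,after paired per-locus mean supports (same locus order).
#' @return the raw p-value (1.0 when all differences are zero).
#' @export
paired_support_test <- function(before, after) {
  stopifnot(length(before) == length(after))
  d <- after - before
  if (all(d == 0)) return(1.0)
  suppressWarnings(
    stats::wilcox.test(after, before, paired = TRUE, alternative = "greater",
                       exact = FALSE, correct = TRUE)$p.value)
}

#' Holm-adjusted support-improvement table across datasets
#'
#' Runs [paired_support_test()] per dataset and applies the Bonferroni-Holm
#' step-down adjustment across the family.
#'
#' @param pairs named list; each element is a list with numeric `before` and
#'   `after` vectors, paired by locus.
#' @return data.frame with `dataset`, `mean_before`, `mean_after`, `p_raw`,
#'   `p_holm`.
#' @export
support_test_table <- function(pairs) {
  p <- vapply(pairs, function(x) paired_support_test(x$before, x$after), 0)
  data.frame(dataset = names(pairs),
             mean_before = vapply(pairs, function(x) mean(x$before, na.rm = TRUE), 0),
             mean_after = vapply(pairs, function(x) mean(x$after, na.rm = TRUE), 0),
             p_raw = p,
             p_holm = stats::p.adjust(p, method = "holm"),
             row.names = NULL)
}
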