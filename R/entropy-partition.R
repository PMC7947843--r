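#' Shannon entropy of one alignment column
#'
#' Entropy (bits) of the base frequencies among unambiguous A/C/G/T states in
#' the column; gaps and ambiguity codes are excluded.  An all-missing column
#' has entropy 0 by definition.
#'
#' @param column character vector of states over taxa.
#' @return entropy in bits, in [0, 2].
#' @export
site_entropy <- function(column) {
  counts <- tabulate(match(column, c("A", "C", "G", "T")), nbins = 4)
  n <- sum(counts)
  if (n == 0) return(0)
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

#' Per-site entropy profile of a locus
#'
#' @param locus a [locus_aln()].
#' @return numeric vector of per-site entropies (bits), one per column.
#' @export
entropy_profile <- function(locus) {
  seq <- locus$seq
  counts <- rbind(colSums(seq == "A"), colSums(seq == "C"),
                  colSums(seq == "G"), colSums(seq == "T"))
  n <- colSums(counts)
  p <- sweep(counts, 2, pmax(n, 1), "/")
  plogp <- p * log2(p)
  plogp[!is.finite(plogp)] <- 0
  h <- -colSums(plogp)
  h[n == 0] <- 0
  h
}

#' Optimal core/flank breakpoints for an entropy profile
#'
#' Finds the 0-based half-open boundaries (l, r) defining segments
#' `[0,l)`, `[l,r)`, `[r,L)` that minimize the total within-segment sum of
#' squared deviations of per-site entropy about the segment means, subject to
#' every segment having at least `min_len` sites.  The search is exhaustive
#' over all admissible pairs using prefix sums (O(L^2)); ties are broken by
#' the smallest l, then the smallest r.
#'
#' @param profile numeric entropy profile (from [entropy_profile()]).
#' @param min_len minimum segment length in sites.
#' @param locus_id id recorded in the returned scheme.
#' @return a [partition_scheme()]; when `L < 3 * min_len` the locus is
#'   flagged unpartitionable (treated as a single segment downstream).
#' @export
best_breakpoints <- function(profile, min_len = 50, locus_id = "locus") {
  L <- length(profile)
  if (L < 3 * min_len) {
    return(partition_scheme(locus_id, NA_integer_, NA_integer_, L,
                            objective = NA_real_, min_len = min_len,
                            unpartitionable = TRUE))
  }
  s1 <- c(0, cumsum(profile))
  s2 <- c(0, cumsum(profile^2))
  sse <- function(i, j) {  # segment of sites (i, j], 0-based boundaries
    n <- j - i
    (s2[j + 1] - s2[i + 1]) - (s1[j + 1] - s1[i + 1])^2 / n
  }
  best <- c(obj = Inf, l = NA, r = NA)
  for (l in min_len:(L - 2 * min_len)) {
    r <- (l + min_len):(L - min_len)
    tot <- pmax(sse(0, l) + sse(l, r) + sse(r, L), 0)
    # numerical ties (within 1e-9) resolve to the smallest r, then smallest l
    j <- which(tot < min(tot) + 1e-9)[1]
    if (tot[j] < best[["obj"]] - 1e-9) best <- c(obj = tot[j], l = l, r = r[j])
  }
  partition_scheme(locus_id, best[["l"]], best[["r"]], L,
                   objective = best[["obj"]], min_len = min_len)
}

#' Core/flank partition scheme for one locus
#'
#' @param locus_id locus identifier.
#' @param l,r 0-based half-open segment boundaries: segments are `[0,l)`
#'   (left flank), `[l,r)` (core), `[r,L)` (right flank).
#' @param L locus length in sites.
#' @param objective summed within-segment SSE of the entropy profile.
#' @param min_len minimum segment length used in the search.
#' @param unpartitionable flag for loci too short to split.
#' @return an object of class `partition_scheme`.
#' @export
partition_scheme <- function(locus_id, l, r, L, objective = NA_real_,
                             min_len = 50, unpartitionable = FALSE) {
  if (!unpartitionable) {
    stopifnot(min_len <= l, l + min_len <= r, r + min_len <= L)
  }
  structure(list(locus_id = locus_id, l = as.integer(l), r = as.integer(r),
                 L = as.integer(L), objective = objective,
                 min_len = as.integer(min_len),
                 unpartitionable = unpartitionable),
            class = "partition_scheme")
}

#' @export
print.partition_scheme <- function(x, ...) {
  if (isTRUE(x$unpartitionable)) {
    cat(sprintf("<partition_scheme> %s: unpartitionable (L=%d < 3*%d)\n",
                x$locus_id, x$L, x$min_len))
  } else {
    cat(sprintf("<partition_scheme> %s: [0,%d) [%d,%d) [%d,%d), SSE=%.4g\n",
                x$locus_id, x$l, x$l, x$r, x$r, x$L, x$objective))
  }
  invisible(x)
}

#' Split a locus into left flank, core, and right flank
#'
#' Column `j` (0-based) belongs to the core iff `l <= j < r` (half-open
#' convention).  Segment ids are suffixed `_Lflank`, `_core`, `_Rflank`, and
#' each segment carries its 1-based inclusive charset range as attribute
#' `charset`.
#'
#' @param locus a [locus_aln()].
#' @param scheme a [partition_scheme()] for this locus.
#' @return list of three [locus_aln()] segments (or a length-one list with
#'   the whole locus when the scheme is unpartitionable).
#' @export
partition_locus <- function(locus, scheme) {
  if (scheme$L != n_sites(locus))
    stop("scheme length does not match locus length")
  if (isTRUE(scheme$unpartitionable)) {
    out <- list(locus)
    attr(out[[1]], "charset") <- c(1L, n_sites(locus))
    return(out)
  }
  l <- scheme$l; r <- scheme$r; L <- scheme$L
  segs <- list(
    Lflank = seq_len(l),
    core = (l + 1L):r,
    Rflank = (r + 1L):L)
  out <- vector("list", 3)
  for (i in seq_along(segs)) {
    sub <- locus_aln(locus$seq[, segs[[i]], drop = FALSE],
                     id = paste0(locus$id, "_", names(segs)[i]))
    attr(sub, "charset") <- c(min(segs[[i]]), max(segs[[i]]))
    out[[i]] <- sub
  }
  names(out) <- names(segs)
  out
}
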