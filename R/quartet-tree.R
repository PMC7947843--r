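#' Quartet topology counts over gene trees
#'
#' For every 4-taxon subset, counts how many gene trees display each of the
#' three unrooted quartet topologies.  A gene tree missing any taxon of a
#' quartet contributes nothing to that quartet; gene trees displaying a
#' quartet as unresolved (zero-length internal path) are skipped for it.
#'
#' Topologies are indexed against the taxa of the quartet sorted
#' alphabetically (t1 < t2 < t3 < t4): column 1 is t1t2|t3t4, column 2 is
#' t1t3|t2t4, column 3 is t1t4|t2t3.
#'
#' @param gene_trees list of `phylo` (or `multiPhylo`).
#' @param taxa taxon set (default: union over gene trees).
#' @return an object of class `quartet_table`: counts matrix (quartets x 3)
#'   with rownames `t1|t2|t3|t4`; attributes `taxa` and `n_genes`.
#' @export
quartet_table <- function(gene_trees, taxa = NULL) {
  stopifnot(length(gene_trees) >= 1)
  if (is.null(taxa)) taxa <- sort(unique(unlist(lapply(gene_trees,
                                                       function(t) t$tip.label))))
  taxa <- sort(taxa)
  n <- length(taxa)
  if (n < 4) stop("need at least 4 taxa")
  combs <- utils::combn(n, 4)
  keys <- apply(combs, 2, function(q) paste(taxa[q], collapse = "|"))
  counts <- matrix(0L, ncol(combs), 3, dimnames = list(keys, c("12|34", "13|24", "14|23")))
  for (tr in gene_trees) {
    pres <- taxa %in% tr$tip.label
    D <- .tip_dists(tr)
    idx <- match(taxa, rownames(D))
    ok <- pres[combs[1, ]] & pres[combs[2, ]] & pres[combs[3, ]] & pres[combs[4, ]]
    if (!any(ok)) next
    a <- idx[combs[1, ok]]; b <- idx[combs[2, ok]]
    c2 <- idx[combs[3, ok]]; d <- idx[combs[4, ok]]
    s1 <- D[cbind(a, b)] + D[cbind(c2, d)]
    s2 <- D[cbind(a, c2)] + D[cbind(b, d)]
    s3 <- D[cbind(a, d)] + D[cbind(b, c2)]
    m <- pmin(s1, s2, s3)
    t1 <- s1 <= m + 1e-12; t2 <- s2 <= m + 1e-12; t3 <- s3 <= m + 1e-12
    resolved <- (t1 + t2 + t3) == 1  # four-point condition: unique minimum
    w <- which(ok)
    counts[w[resolved & t1], 1] <- counts[w[resolved & t1], 1] + 1L
    counts[w[resolved & t2], 2] <- counts[w[resolved & t2], 2] + 1L
    counts[w[resolved & t3], 3] <- counts[w[resolved & t3], 3] + 1L
  }
  structure(counts, taxa = taxa, n_genes = length(gene_trees),
            class = c("quartet_table", "matrix"))
}

# pairwise path-length distances between tips (unit branch lengths when
# absent, so topology alone decides quartets)
.tip_dists <- function(tree) {
  if (is.null(tree$edge.length)) tree$edge.length <- rep(1, nrow(tree$edge))
  tree$edge.length[tree$edge.length <= 0] <- 1e-9
  D <- as.matrix(stats::cophenetic(tree))
  D
}

# quartet topology index (1..3) displayed by a tree for given sorted-quartet
# row keys; NA when the quartet is missing or unresolved
.induced_quartets <- function(tree, taxa, combs) {
  D <- .tip_dists(tree)
  idx <- match(taxa, rownames(D))
  a <- idx[combs[1, ]]; b <- idx[combs[2, ]]
  c2 <- idx[combs[3, ]]; d <- idx[combs[4, ]]
  out <- rep(NA_integer_, ncol(combs))
  ok <- !is.na(a) & !is.na(b) & !is.na(c2) & !is.na(d)
  s1 <- D[cbind(a[ok], b[ok])] + D[cbind(c2[ok], d[ok])]
  s2 <- D[cbind(a[ok], c2[ok])] + D[cbind(b[ok], d[ok])]
  s3 <- D[cbind(a[ok], d[ok])] + D[cbind(b[ok], c2[ok])]
  m <- pmin(s1, s2, s3)
  pick <- ifelse(s1 <= m + 1e-12, 1L, ifelse(s2 <= m + 1e-12, 2L, 3L))
  uniq <- (s1 <= m + 1e-12) + (s2 <= m + 1e-12) + (s3 <= m + 1e-12) == 1
  pick[!uniq] <- NA_integer_
  out[ok] <- pick
  out
}

#' Quartet score of a candidate species topology
#'
#' The number of gene-tree quartets (from a [quartet_table()]) agreeing with
#' the quartets induced by the candidate topology; the criterion maximized by
#' quartet-based summary species-tree methods.  Invariant to candidate
#' rooting.
#'
#' @param candidate `phylo` spanning the table's taxa.
#' @param table a [quartet_table()].
#' @return integer score.
#' @export
quartet_score <- function(candidate, table) {
  taxa <- attr(table, "taxa")
  if (!all(taxa %in% candidate$tip.label)) stop("candidate does not span the taxa")
  n <- length(taxa)
  combs <- utils::combn(n, 4)
  ind <- .induced_quartets(candidate, taxa, combs)
  ok <- !is.na(ind)
  sum(table[cbind(which(ok), ind[ok])])
}

#' Search for the maximum-quartet-support species tree
#'
#' Exhaustive over all unrooted topologies for n <= 8 taxa; for larger n, NNI
#' hill climbing from a greedy starting tree (majority-rule consensus of the
#' gene trees when available, otherwise random) with seeded random restarts.
#'
#' @param table a [quartet_table()].
#' @param gene_trees optional gene trees used for the consensus start and for
#'   branch annotation.
#' @param restarts random restarts for the hill climb.
#' @param seed integer seed.
#' @return an object of class `species_tree_result`: list with `tree`
#'   (unrooted topology), `score`, and (when `gene_trees` is given)
#'   `branches` from [branch_support()].
#' @export
search_species_tree <- function(table, gene_trees = NULL, restarts = 5, seed = 1) {
  taxa <- attr(table, "taxa")
  n <- length(taxa)
  if (n < 4) stop("need at least 4 taxa")
  if (n <= 8) {
    cands <- phangorn::allTrees(n, rooted = FALSE, tip.label = taxa)
    scores <- vapply(cands, quartet_score, 0, table = table)
    best <- cands[[which.max(scores)]]
    best_score <- max(scores)
  } else {
    starts <- .st_starts(taxa, gene_trees, restarts, seed)
    best <- NULL; best_score <- -Inf
    for (st in starts) {
      res <- .st_hill_climb(st, table)
      if (res$score > best_score) { best <- res$tree; best_score <- res$score }
    }
  }
  out <- list(tree = best, score = best_score, taxa = taxa)
  if (!is.null(gene_trees)) out$branches <- branch_support(best, gene_trees)
  class(out) <- "species_tree_result"
  out
}

#' @export
print.species_tree_result <- function(x, ...) {
  cat(sprintf("<species_tree_result> %d taxa, quartet score %d\n",
              length(x$taxa), x$score))
  invisible(x)
}

.st_starts <- function(taxa, gene_trees, restarts, seed) {
  starts <- list()
  if (!is.null(gene_trees)) {
    full <- Filter(function(t) setequal(t$tip.label, taxa), gene_trees)
    if (length(full) >= 2) {
      cons <- tryCatch(ape::consensus(full, p = 0.5), error = function(e) NULL)
      if (!is.null(cons))
        starts[[1]] <- .with_seed(seed, ape::multi2di(ape::unroot(cons), random = TRUE))
    }
  }
  seeds <- .derive_seeds(seed + 1L, restarts)
  for (i in seq_len(restarts))
    starts[[length(starts) + 1]] <-
      .with_seed(seeds[i], ape::unroot(ape::rtree(length(taxa), tip.label = sample(taxa))))
  starts
}

.st_hill_climb <- function(tree, table) {
  tree$edge.length <- NULL
  cur <- quartet_score(tree, table)
  repeat {
    nb0 <- phangorn::nni(tree)
    # index via [[ so compressed multiPhylo tip labels are restored
    nb <- lapply(seq_along(nb0), function(i) nb0[[i]])
    sc <- vapply(nb, quartet_score, 0, table = table)
    if (max(sc) <= cur) break
    tree <- nb[[which.max(sc)]]
    cur <- max(sc)
  }
  list(tree = tree, score = cur)
}

#' Quartet frequencies, support and coalescent lengths per branch
#'
#' For each internal branch of the species topology, quartets with one taxon
#' drawn from each of the four subtrees around the branch are tallied over
#' the gene trees: q1 is the normalized frequency of the arrangement the
#' species tree displays, q2 and q3 the two alternatives.  The branch length
#' in coalescent units follows the multispecies-coalescent inversion
#' d = -ln(1.5 * (1 - q1)), zero (flagged) when q1 < 1/3 and capped at `cap`
#' as q1 approaches 1.  Support is q1 itself (`method = "freq"`) or the MSC
#' posterior probability of the displayed arrangement under a uniform prior
#' over the three resolutions and an exponential branch-length prior
#' (`method = "localpp"`).
#'
#' @param topology unrooted species topology (`phylo`).
#' @param gene_trees gene trees (need not all span all taxa).
#' @param method `"freq"` or `"localpp"`.
#' @param cap cap on d in coalescent units.
#' @param max_quartets per-branch quartet cap; exact enumeration when the
#'   number of around-branch quartets is at most this, else a seeded sample.
#' @param seed integer seed for quartet sampling.
#' @return data.frame, one row per internal branch: `split`, `q1`, `q2`,
#'   `q3`, `m` (mean resolved gene count per quartet), `support`, `d`,
#'   `flagged`.
#' @export
branch_support <- function(topology, gene_trees, method = c("freq", "localpp"),
                           cap = 9, max_quartets = 100, seed = 1) {
  method <- match.arg(method)
  topology <- .prep_tree(topology, default_bl = 1)
  taxa <- sort(unique(unlist(lapply(gene_trees, function(t) t$tip.label))))
  Ds <- lapply(gene_trees, .tip_dists)
  ntip <- length(topology$tip.label)
  sets <- .clade_sets(topology)
  kids <- split(topology$edge[, 2], topology$edge[, 1])
  root <- setdiff(unique(topology$edge[, 1]), topology$edge[, 2])[1]
  rows <- list()
  for (v in (ntip + 1):(ntip + topology$Nnode)) {
    if (v == root) next
    ch <- kids[[as.character(v)]]
    if (length(ch) != 2) next
    below <- sets[[v]]
    if (length(below) < 2 || length(below) > ntip - 2) next
    A <- sets[[ch[1]]]; B <- sets[[ch[2]]]
    u <- topology$edge[topology$edge[, 2] == v, 1]
    sibs <- setdiff(kids[[as.character(u)]], v)
    C <- sets[[sibs[1]]]
    D4 <- setdiff(topology$tip.label, c(A, B, C))
    if (!length(D4)) next
    qs <- .branch_quartets(A, B, C, D4, max_quartets, seed + v)
    agg <- c(0, 0, 0); mtot <- 0
    for (q in qs) {
      cnt <- .quartet_counts_genes(q, Ds)
      agg <- agg + cnt
      mtot <- mtot + sum(cnt)
    }
    nq <- length(qs)
    tot <- sum(agg)
    q123 <- if (tot > 0) agg / tot else c(NA, NA, NA)
    m <- if (nq > 0) mtot / nq else 0
    d <- .coal_length(q123[1], cap)
    supp <- if (method == "freq") q123[1] else .local_pp(agg[1], agg[2], agg[3], nq)
    rows[[length(rows) + 1]] <- data.frame(
      split = paste(sort(below), collapse = "|"),
      q1 = q123[1], q2 = q123[2], q3 = q123[3], m = m,
      support = supp, d = d$d, flagged = d$flagged)
  }
  do.call(rbind, rows)
}

# all (or a seeded sample of) one-from-each-subtree quartets; each quartet is
# list(a, b, c, d) of tip labels (a,b around one side; c,d the other)
.branch_quartets <- function(A, B, C, D, max_quartets, seed) {
  total <- length(A) * length(B) * length(C) * length(D)
  if (total <= max_quartets) {
    out <- list()
    for (a in A) for (b in B) for (c2 in C) for (d in D)
      out[[length(out) + 1]] <- c(a, b, c2, d)
    return(out)
  }
  .with_seed(seed, {
    lapply(seq_len(max_quartets), function(i)
      c(sample(A, 1), sample(B, 1), sample(C, 1), sample(D, 1)))
  })
}

# counts over gene trees of (ab|cd, ac|bd, ad|bc) for one labelled quartet
.quartet_counts_genes <- function(q, Ds) {
  cnt <- c(0L, 0L, 0L)
  for (D in Ds) {
    if (!all(q %in% rownames(D))) next
    s1 <- D[q[1], q[2]] + D[q[3], q[4]]
    s2 <- D[q[1], q[3]] + D[q[2], q[4]]
    s3 <- D[q[1], q[4]] + D[q[2], q[3]]
    m <- min(s1, s2, s3)
    hits <- c(s1, s2, s3) <= m + 1e-12
    if (sum(hits) == 1) cnt[which(hits)] <- cnt[which(hits)] + 1L
  }
  cnt
}

# MSC inversion q1 -> coalescent units
.coal_length <- function(q1, cap) {
  if (!is.finite(q1)) return(list(d = NA_real_, flagged = TRUE))
  if (q1 < 1 / 3) return(list(d = 0, flagged = TRUE))
  d <- -log(1.5 * (1 - q1))
  if (!is.finite(d) || d > cap) d <- cap
  list(d = max(d, 0), flagged = FALSE)
}

# posterior of the displayed quartet under the MSC with uniform prior over
# the three resolutions and Exp(1) prior on the internal length
.local_pp <- function(n1, n2, n3, nq) {
  # use per-quartet average counts to avoid pseudo-inflating the sample size
  if (nq > 0) { n1 <- n1 / nq; n2 <- n2 / nq; n3 <- n3 / nq }
  lik <- function(ni, nj, nk) {
    f <- function(t) {
      q <- 1 - (2 / 3) * exp(-t)
      exp(ni * log(q) + (nj + nk) * log((1 - q) / 2) -
            (ni + nj + nk) * log(1 / 3)) * exp(-t)
    }
    stats::integrate(f, 0, 25, rel.tol = 1e-8)$value
  }
  l1 <- lik(n1, n2, n3); l2 <- lik(n2, n1, n3); l3 <- lik(n3, n1, n2)
  l1 / (l1 + l2 + l3)
}

#' Root a species tree on an outgroup
#'
#' @param tree unrooted `phylo` (or a `species_tree_result`).
#' @param outgroup character vector of outgroup taxa; they must form a clade
#'   in the unrooted topology.
#' @return rooted `phylo`.
#' @export
root_with_outgroup <- function(tree, outgroup) {
  if (inherits(tree, "species_tree_result")) tree <- tree$tree
  labs <- tree$tip.label
  if (!all(outgroup %in% labs))
    stop("outgroup taxa absent from tree: ",
         paste(setdiff(outgroup, labs), collapse = ", "))
  if (setequal(outgroup, labs)) stop("outgroup cannot be the whole taxon set")
  og <- sort(outgroup)
  comp <- sort(setdiff(labs, outgroup))
  splits <- lapply(.clade_sets(tree), sort)
  is_clade <- length(og) == 1 || length(comp) == 1 ||
    any(vapply(splits, function(s) identical(s, og) || identical(s, comp), NA))
  if (!is_clade)
    stop("outgroup is not monophyletic in the unrooted topology: ",
         paste(outgroup, collapse = ", "))
  # rooting on the complement of a clade places the root on the same branch
  side <- if (length(comp) < length(og)) comp else og
  ape::root(tree, outgroup = side, resolve.root = TRUE)
}
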