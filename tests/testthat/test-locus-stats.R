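# the five filtering statistics, ranking, and the Wilcoxon/Holm machinery

test_that("GC proportion handles pure, mixed and degenerate loci", {
  expect_equal(gc_proportion(aln(a = "ATAT", b = "TATA")), 0)
  expect_equal(gc_proportion(aln(a = "GCGC", b = "CGCG")), 1)
  expect_equal(gc_proportion(aln(a = "ACGT")), 0.5)
  # gaps/ambiguities excluded from both sides of the ratio
  expect_equal(gc_proportion(aln(a = "AC-N", b = "A--N")), 1 / 3)
  expect_true(is.na(gc_proportion(aln(a = "NN--", b = "--NN"))))
})

test_that("parsimony-informative sites follow the two-by-two rule", {
  expect_equal(count_informative_sites(aln(a = "AAAA", b = "AAAA", c = "AAAA",
                                           d = "AAAA")), 0)
  # site 1 informative; site 2 singleton; site 3 has A only once
  expect_equal(count_informative_sites(aln(a = "AAA", b = "ACN", c = "TAT",
                                           d = "TAT")), 1)
  L <- 17
  all_inf <- aln(a = strrep("A", L), b = strrep("A", L),
                 c = strrep("T", L), d = strrep("T", L))
  expect_equal(count_informative_sites(all_inf), L)
})

test_that("clocklikeness is the variance of root-to-tip depths", {
  # ultrametric: zero
  t1 <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  expect_equal(clocklikeness(t1), 0)
  # fixed-root check: depths (2,3,2) -> population variance 2/9
  t2 <- ape::read.tree(text = "((A:1,B:2):1,C:2);")
  expect_equal(clocklikeness(t2, rooting = "asis"), 2 / 9)
  # homogeneity: scaling branches by c scales the variance by c^2
  t3 <- t2
  t3$edge.length <- t3$edge.length * 3
  expect_equal(clocklikeness(t3), 9 * clocklikeness(t2), tolerance = 1e-12)
})

test_that("saturation slope matches the through-origin least-squares oracle", {
  # y = x exactly: slope 1 (p-distance equal to patristic distance by design)
  tr <- ape::read.tree(text = "((A:0.05,B:0.05):0.05,(C:0.05,D:0.05):0.05);")
  # craft an alignment whose p-distances equal patristic distances:
  # use a long alignment with exact mismatch fractions
  L <- 1000
  base <- strrep("A", L)
  flip <- function(s, idx, to) {
    v <- strsplit(s, "")[[1]]; v[idx] <- to; paste(v, collapse = "")
  }
  # A-B differ at 100 sites (0.1); A-C,A-D,B-C,B-D at 150 (0.15); C-D at 100
  a <- base
  b <- flip(base, 1:100, "T")
  c2 <- flip(base, 101:250, "G")
  d <- flip(base, c(101:200, 251:300), "C")
  loc <- aln(A = a, B = b, C = c2, D = d)
  x <- as.matrix(stats::cophenetic(tr))
  y <- as.matrix(ape::dist.dna(ape::as.DNAbin(loc$seq), model = "raw"))
  lo <- lower.tri(x)
  oracle <- sum(x[lo] * y[rownames(x), colnames(x)][lo]) / sum(x[lo]^2)
  expect_equal(saturation_slope(loc, tr), oracle, tolerance = 1e-10)

  # random instances against the closed form
  for (s in 1:3) {
    tr6 <- random_tree(6, seed = s)
    loc6 <- random_locus(6, 200, seed = s)
    x <- as.matrix(stats::cophenetic(tr6))[locus_taxa(loc6), locus_taxa(loc6)]
    y <- as.matrix(ape::dist.dna(ape::as.DNAbin(loc6$seq), model = "raw",
                                 pairwise.deletion = TRUE))[locus_taxa(loc6),
                                                            locus_taxa(loc6)]
    lo <- lower.tri(x)
    expect_equal(saturation_slope(loc6, tr6), sum(x[lo] * y[lo]) / sum(x[lo]^2),
                 tolerance = 1e-10)
  }
})

test_that("mean support averages internal-branch labels on the 0-100 scale", {
  tr <- ape::read.tree(text = "((A,B)100,(C,D)100);")
  expect_equal(mean_support(tr), 100)
  tr2 <- ape::read.tree(text = "((A,B)80,((C,D)60,E));")
  expect_equal(mean_support(tr2), 70)
  tr3 <- ape::read.tree(text = "((A,B),(C,D));")
  expect_true(is.na(mean_support(tr3)))
})

test_that("rank_and_select is deterministic with documented tie-breaking", {
  stats <- data.frame(locus = c("l1", "l2", "l3", "l4", "l5"),
                      gc = c(.2, .4, .4, .1, .5),
                      npis = c(10, 20, 20, 5, 1),
                      avg_bootstrap = NA_real_, clocklikeness = NA_real_,
                      saturation = NA_real_)
  # gc is best-low; tie between l2/l3 broken by ascending id
  expect_equal(rank_and_select(stats, "gc", 3), c("l4", "l1", "l2"))
  # npis best-high
  expect_equal(rank_and_select(stats, "npis", 2), c("l2", "l3"))
  # k = n returns everything in order
  expect_equal(length(rank_and_select(stats, "gc", 5)), 5)
  # guards: k = 0 and k beyond defined values
  expect_error(rank_and_select(stats, "gc", 0), "positive")
  expect_error(rank_and_select(stats, "avg_bootstrap", 1), "shortfall")
})

test_that("statistics are invariant to taxon order", {
  loc <- random_locus(6, 150, seed = 11, gap_p = 0.05)
  tr <- random_tree(6, seed = 11)
  perm <- sample(6)
  locp <- locus_aln(loc$seq[perm, ], id = loc$id)
  expect_equal(gc_proportion(locp), gc_proportion(loc))
  expect_equal(count_informative_sites(locp), count_informative_sites(loc))
  expect_equal(saturation_slope(locp, tr), saturation_slope(loc, tr),
               tolerance = 1e-12)
})

test_that("nonexact Wilcoxon matches the exact enumeration oracle", {
  # n = 15 all-positive unit-ish differences: compare against exhaustive
  # 2^15 sign-flip enumeration of the signed-rank statistic
  set.seed(42)
  d <- abs(rnorm(15)) + 0.1
  before <- rnorm(15)
  after <- before + d
  p_norm <- paired_support_test(before, after)
  ranks <- rank(abs(d))
  W <- sum(ranks[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), 15))
  Wnull <- as.matrix(signs) %*% ranks
  p_exact <- mean(Wnull >= W)
  expect_lt(abs(p_norm - p_exact), 0.005)
  # identical vectors: p = 1
  expect_equal(paired_support_test(1:5, 1:5), 1.0)
})

test_that("Holm adjustment steps down across the dataset family", {
  pairs <- list(
    d1 = list(before = c(0, 0, 0, 1, 2, 3, 4, 5, 6, 7),
              after = c(0, 0, 0, 1, 2, 3, 4, 5, 6, 7) + 2),
    d2 = list(before = rep(50, 10), after = rep(50, 10)))
  tab <- support_test_table(pairs)
  expect_equal(tab$p_holm, stats::p.adjust(tab$p_raw, "holm"))
  # hand Holm check on the documented example
  expect_equal(stats::p.adjust(c(0.01, 0.04), "holm"), c(0.02, 0.04))
  expect_equal(tab$p_raw[2], 1.0)
})
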