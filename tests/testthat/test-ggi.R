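# gene genealogy interrogation: RELL bootstrap, AU test, tallies

test_that("RELL bootstrap proportions behave at the extremes", {
  set.seed(1)
  S <- 100
  # tree 1 strictly better at every site: BP1 = 1 everywhere
  m <- rbind(t1 = rnorm(S), t2 = rnorm(S) - 0.5)
  m[1, ] <- m[2, ] + 0.2
  bp <- rell_bootstrap(m, replicates = 200, seed = 3)
  expect_true(all(bp["t1", ] == 1))
  # identical rows: symmetric tie, BP about 1/2 each
  m2 <- rbind(a = rnorm(S), b = 0)
  m2["b", ] <- m2["a", ]
  bp2 <- rell_bootstrap(m2, replicates = 400, seed = 3)
  expect_true(all(abs(bp2["a", ] - 0.5) < 3 * sqrt(0.25 / 400)))
  # columns sum to one exactly
  m3 <- rbind(rnorm(S), rnorm(S), rnorm(S))
  bp3 <- rell_bootstrap(m3, replicates = 100, seed = 5)
  expect_true(all(abs(colSums(bp3) - 1) < 1e-12))
  # determinism and input validation
  expect_identical(rell_bootstrap(m3, replicates = 50, seed = 9),
                   rell_bootstrap(m3, replicates = 50, seed = 9))
  m3[1, 1] <- NA
  expect_error(rell_bootstrap(m3), "non-finite")
})

test_that("AU p-values recover known (c, d) and handle degeneracy", {
  scales <- seq(0.5, 1.4, by = 0.1)
  # inverse-model round trip: BP(r) = 1 - Phi(d sqrt(r) + c / sqrt(r))
  for (cd in list(c(0.3, -0.5), c(-0.2, 0.4), c(0.1, 0.1))) {
    cc <- cd[1]; d <- cd[2]
    bp <- matrix(1 - pnorm(d * sqrt(scales) + cc / sqrt(scales)), 1,
                 dimnames = list("x", NULL))
    fit <- au_pvalue(bp, scales, replicates = 1e9)  # negligible clipping
    expect_lt(abs(fit$c - cc), 1e-3)
    expect_lt(abs(fit$d - d), 1e-3)
    expect_lt(abs(fit$p_au - (1 - pnorm(d - cc))), 1e-3)
  }
  # degenerate paths
  ones <- matrix(1, 1, 10); zeros <- matrix(0, 1, 10)
  f1 <- au_pvalue(ones, scales, 1000)
  f0 <- au_pvalue(zeros, scales, 1000)
  expect_equal(f1$p_au, 1.0); expect_true(f1$degenerate)
  expect_equal(f0$p_au, 0.0); expect_true(f0$degenerate)
})

test_that("AU p is monotone under growing dominance", {
  set.seed(7)
  S <- 200
  base <- rnorm(S)
  p_prev <- -1
  for (adv in c(0.02, 0.05, 0.1, 0.2)) {
    m <- rbind(win = base + adv, lose = base + rnorm(S, 0, 0.05))
    bp <- rell_bootstrap(m, replicates = 500, seed = 11)
    p <- au_pvalue(bp, replicates = 500)$p_au[1]
    expect_gte(p + 0.02, p_prev)  # never drops materially
    p_prev <- p
  }
  expect_gt(p_prev, 0.9)
})

test_that("per-locus GGI picks the generating hypothesis on strong signal", {
  sys <- default_system(t_focal = 3)  # little ILS at the focal node
  cfg <- ggi_config(sys$hypotheses, replicates = 300, seed = 5, nstarts = 1)
  ds <- simulate_dataset(sys$model, 8,
                         locus_profile(length = 1000, gradient = "step"),
                         seed = 17)
  wins <- signif_wins <- 0
  for (loc in ds$loci) {
    r <- ggi_locus_test(loc, cfg)
    wins <- wins + (r$best == "H1")
    signif_wins <- signif_wins + (r$best == "H1" && r$significant)
  }
  expect_gte(wins, 7)
  expect_gte(signif_wins, 6)
})

test_that("low-information loci rarely reach significance", {
  sys <- default_system(t_focal = 0.2, subst_scale = 0.002)
  cfg <- ggi_config(sys$hypotheses, replicates = 300, seed = 5, nstarts = 1)
  ds <- simulate_dataset(sys$model, 10, locus_profile(length = 60,
                                                      core_fraction = 0.4),
                         seed = 23)
  n_sig <- 0
  for (loc in ds$loci) {
    r <- ggi_locus_test(loc, cfg)
    n_sig <- n_sig + isTRUE(r$significant)
  }
  expect_lte(n_sig, 2)
})

test_that("indistinguishable hypotheses yield identical rows and no winners", {
  sys <- default_system()
  dup <- constraint_hyp("H1copy", ape::write.tree(sys$hypotheses[[1]]$backbone))
  cfg <- ggi_config(list(sys$hypotheses[[1]], dup), replicates = 300, seed = 5,
                    nstarts = 1)
  ds <- simulate_dataset(sys$model, 4, locus_profile(length = 300), seed = 29)
  for (loc in ds$loci) {
    r <- ggi_locus_test(loc, cfg)
    slm <- per_site_loglik(r$trees, attr(r$trees[[1]], "model") %||%
                             fit_model(loc, "GTR"), loc)
    expect_equal(r$loglik[[1]], r$loglik[[2]], tolerance = 1e-8)
    expect_false(r$significant)
  }
})

test_that("tallies, percentages and tree selection count correctly", {
  mk <- function(id, best, p, labels = c("H1", "H2", "unconstrained")) {
    structure(list(locus_id = id, labels = labels,
                   au = data.frame(tree = labels,
                                   p_au = ifelse(labels == best, p, 0.2)),
                   loglik = stats::setNames(ifelse(labels == best, -10, -20),
                                            labels),
                   best = best, significant = p > 0.95,
                   trees = stats::setNames(
                     rep(list(ape::rtree(4)), length(labels)), labels)),
              class = "au_test_result")
  }
  results <- list(mk("l1", "H1", 0.99), mk("l2", "H1", 0.97),
                  mk("l3", "H1", 0.80), mk("l4", "H1", 0.96),
                  mk("l5", "H2", 0.50), mk("l6", "H2", 0.99))
  cfg <- ggi_config(default_system()$hypotheses, include_unconstrained = TRUE)
  tal <- ggi_tally(results, cfg)
  expect_equal(tal$n_all[tal$hypothesis == "H1"], 4L)
  expect_equal(tal$n_all[tal$hypothesis == "H2"], 2L)
  expect_equal(tal$n_signif[tal$hypothesis == "H1"], 3L)
  expect_equal(tal$n_signif[tal$hypothesis == "H2"], 1L)
  expect_equal(tal$pct_all, 100 * tal$n_all / 6)
  expect_equal(tal$pct_signif, 100 * tal$n_signif / 6)
  # empty significant set: zero rows, no division error
  none <- list(mk("l1", "H1", 0.5))
  tal0 <- ggi_tally(none, cfg)
  expect_equal(sum(tal0$n_signif), 0L)

  # selection: unconstrained x1 + H1 x4 kept, H2 x2 discarded ... on a mix
  results2 <- c(results, list(mk("l7", "unconstrained", 0.99)))
  sel <- select_gene_trees(results2, "H1")
  expect_equal(length(sel), 5)
  expect_equal(attr(sel, "n_discarded"), 2L)
  expect_setequal(names(sel), c("l1", "l2", "l3", "l4", "l7"))
  all_h1 <- select_gene_trees(results[1:4], "H1")
  expect_equal(length(all_h1), 4)
  expect_error(select_gene_trees(results, "H9"), "unknown")
})
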