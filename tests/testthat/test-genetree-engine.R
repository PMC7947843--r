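# maximum-likelihood engine: pruning likelihood, optimization, search

test_that("pattern compression is lossless", {
  loc <- random_locus(5, 80, seed = 1, gap_p = 0.1)
  cp <- compress_patterns(loc)
  expect_equal(sum(cp$weights), 80)
  expect_identical(cp$patterns[, cp$index], loc$seq)
  # all-identical columns collapse to one pattern
  inv <- aln(a = "AAAA", b = "CCCC")
  expect_equal(compress_patterns(inv)$weights, 4)
  # all-distinct columns stay distinct
  dis <- aln(a = "ACGT", b = "AAAA")
  expect_equal(compress_patterns(dis)$weights, rep(1, 4))
})

test_that("two-taxon JC likelihood matches the closed form", {
  m <- subst_model("JC69")
  for (t in c(0.05, 0.3, 1.2)) {
    tr <- ape::read.tree(text = sprintf("(A:%g,B:%g);", t / 2, t / 2))
    same <- aln(A = "A", B = "A")
    diff <- aln(A = "A", B = "C")
    expect_equal(tree_loglik(tr, m, same),
                 log(0.25 * (0.25 + 0.75 * exp(-4 * t / 3))), tolerance = 1e-10)
    expect_equal(tree_loglik(tr, m, diff),
                 log(0.25 * (0.25 - 0.25 * exp(-4 * t / 3))), tolerance = 1e-10)
  }
})

test_that("pruning equals brute-force enumeration on 5-taxon instances", {
  m <- subst_model("JC69")
  for (s in 1:20) {
    tr <- random_tree(5, seed = s, min_bl = 0.02, max_bl = 0.8)
    loc <- random_locus(5, 6, seed = 100 + s)
    expect_equal(tree_loglik(tr, m, loc), enum_loglik_jc(tr, loc$seq),
                 tolerance = 1e-8)
  }
})

test_that("zero-length tree on identical sequences gives L log 1/4", {
  tr <- ape::read.tree(text = "((A:0,B:0):0,(C:0,D:0):0);")
  loc <- aln(A = "ACGTACGT", B = "ACGTACGT", C = "ACGTACGT", D = "ACGTACGT")
  expect_equal(tree_loglik(tr, subst_model("JC69"), loc), 8 * log(0.25),
               tolerance = 1e-6)
})

test_that("likelihood is invariant to taxon order and matches phangorn", {
  skip_if_not_installed("phangorn")
  tr <- random_tree(7, seed = 3)
  loc <- random_locus(7, 150, seed = 3, gap_p = 0.05)
  m <- subst_model("GTR", freqs = c(.4, .1, .2, .3),
                   rates = c(.5, 2, .8, 1.2, 3, 1), alpha = 0.6)
  l1 <- tree_loglik(tr, m, loc)
  locp <- locus_aln(loc$seq[sample(7), ], id = loc$id)
  expect_equal(tree_loglik(tr, m, locp), l1, tolerance = 1e-9)
  fit <- phangorn::pml(tr, phangorn::phyDat(loc$seq), bf = m$freqs,
                       Q = m$rates, shape = 0.6, k = 4)
  expect_equal(l1, fit$logLik, tolerance = 1e-6)
})

test_that("branch-length optimization recovers the JC closed-form MLE", {
  # 2 taxa, p-hat differing sites -> t = -(3/4) log(1 - 4 p / 3)
  L <- 500; ndiff <- 60
  seqA <- rep("A", L)
  seqB <- c(rep("C", ndiff), rep("A", L - ndiff))
  loc <- locus_aln(rbind(A = seqA, B = seqB), id = "jc")
  tr <- ape::read.tree(text = "(A:0.3,B:0.3);")
  opt <- optim_branch_lengths(tr, subst_model("JC69"), loc)
  p <- ndiff / L
  expect_equal(sum(opt$edge.length), -0.75 * log(1 - 4 * p / 3),
               tolerance = 1e-4)
})

test_that("optimization is monotone and idempotent at the optimum", {
  m <- subst_model("HKY85", kappa = 2, alpha = 0.8)
  for (s in 1:5) {
    tr <- random_tree(6, seed = s)
    loc <- random_locus(6, 120, seed = 200 + s)
    before <- tree_loglik(tr, m, loc)
    opt <- optim_branch_lengths(tr, m, loc)
    expect_gte(attr(opt, "loglik"), before)
    # restarting at the optimum changes nothing beyond tolerance
    opt2 <- optim_branch_lengths(opt, m, loc)
    expect_lt(abs(attr(opt2, "loglik") - attr(opt, "loglik")), 1e-3)
  }
})

test_that("NNI search recovers well-supported 6-taxon topologies", {
  skip_if_not_installed("phangorn")
  hits <- 0
  for (s in 1:20) {
    set.seed(s)
    tr <- ape::unroot(ape::rtree(6))
    tr$edge.length <- runif(nrow(tr$edge), 0.3, 0.6)
    sim <- phangorn::simSeq(tr, l = 1000)
    loc <- locus_aln(toupper(as.character(sim)), id = "s")
    fit <- nni_search(loc, fit_model(loc, "JC69", gamma = FALSE), seed = s)
    hits <- hits + (phangorn::RF.dist(ape::unroot(fit), tr) == 0)
  }
  expect_gte(hits, 18)
})

test_that("constrained searches always satisfy the backbone", {
  sys <- default_system()
  ds <- simulate_dataset(sys$model, 3, locus_profile(length = 300), seed = 13)
  h1 <- sys$hypotheses[[1]]
  need <- paste(sort(c(sys$clades$X, sys$clades$Y)), collapse = "|")
  for (loc in ds$loci) {
    m <- fit_model(loc, "HKY85")
    con <- nni_search(loc, m, constraint = h1, seed = 3)
    sp <- phylotriage:::.tree_splits(con)
    expect_true(need %in% sp)  # the defining H1 bipartition is displayed
    expect_true(paste(sort(sys$clades$X), collapse = "|") %in% sp)
    # unconstrained search never does worse than the constrained one
    un <- nni_search(loc, m, seed = 3)
    expect_gte(attr(un, "loglik"), attr(con, "loglik") - 1e-6)
  }
  # incompatible constraint (taxa absent) errors
  bad <- constraint_hyp("bad", "((q1,q2),(q3,q4),(q5,q6));")
  expect_error(nni_search(ds$loci[[1]], fit_model(ds$loci[[1]], "JC69"),
                          constraint = bad))
})

test_that("BIC model selection follows the formula and recovers truth", {
  skip_if_not_installed("phangorn")
  # formula check on reported table
  loc <- random_locus(5, 100, seed = 5)
  sel <- select_model(loc, names = c("JC69", "HKY85"))
  tab <- attr(sel, "bic_table")
  nb <- nrow(nj_start_tree(loc)$edge)
  k <- unname(c(JC69 = 0, HKY85 = 4)[tab$model]) + nb + as.integer(tab$gamma)
  expect_equal(tab$bic, -2 * tab$loglik + k * log(100), tolerance = 1e-9)

  # JC-simulated data pick JC in most replicates
  jc_hits <- 0
  for (s in 1:10) {
    set.seed(s)
    tr <- ape::unroot(ape::rtree(6)); tr$edge.length <- runif(9, .05, .3)
    sim <- phangorn::simSeq(tr, l = 800)
    loc <- locus_aln(toupper(as.character(sim)), id = "jc")
    jc_hits <- jc_hits + (select_model(loc)$name == "JC69")
  }
  expect_gte(jc_hits, 8)

  # strong gamma rate variation picks a +G model (sequences simulated with
  # the package generator: near-homogeneous core/flank rates, gamma 0.25)
  g_model <- subst_model("HKY85", freqs = c(.4, .1, .1, .4), kappa = 4,
                         alpha = 0.25)
  prof <- locus_profile(length = 800, core_fraction = 0.4, core_mult = 0.99,
                        flank_mult = 1, gradient = "step", model = g_model,
                        core_model = g_model)
  g_hits <- 0
  for (s in 1:10) {
    set.seed(s)
    tr <- ape::rtree(6)
    tr$edge.length <- runif(nrow(tr$edge), .1, .5)
    loc <- simulate_locus_alignment(tr, prof, seed = s)$locus
    g_hits <- g_hits + !is.null(select_model(loc)$alpha)
  }
  expect_gte(g_hits, 8)
})

test_that("partitioned likelihood nests and beats the unpartitioned fit", {
  sys <- default_system()
  ds <- simulate_dataset(sys$model, 6, example_het_profile(length = 420),
                         seed = 19)
  bic_wins <- 0
  for (loc in ds$loci) {
    tr <- nj_start_tree(loc)
    m <- fit_model(loc, "HKY85", tree = tr)
    sch <- partition_scheme(loc$id, 140, 280, 420, min_len = 50)
    segs <- lapply(partition_locus(loc, sch), function(s)
      list(locus = s, model = fit_model(s, "HKY85", tree = tr)))
    # identical models and unit multipliers equal the unpartitioned value
    segs_same <- lapply(partition_locus(loc, sch), function(s)
      list(locus = s, model = m, rmult = 1))
    expect_equal(partitioned_loglik(segs_same, tr), tree_loglik(tr, m, loc),
                 tolerance = 1e-8)
    # optimized partitioned fit >= optimized unpartitioned fit (nesting)
    lu <- attr(optim_branch_lengths(tr, m, loc), "loglik")
    lp <- as.numeric(partitioned_loglik(segs, tr, optimize = TRUE))
    expect_gte(lp, lu - 1e-4)
    # BIC: 2 extra models + 2 free multipliers vs a shared model
    k_extra <- 2 * 5 + 2
    bic_wins <- bic_wins + ((-2 * lp + k_extra * log(420)) < (-2 * lu))
  }
  expect_gte(bic_wins, 5)
})

test_that("per-site log-likelihood rows sum to the totals", {
  loc <- random_locus(5, 60, seed = 9)
  m <- subst_model("HKY85", kappa = 3, alpha = 0.7)
  t1 <- random_tree(5, seed = 1)
  t2 <- random_tree(5, seed = 2)
  slm <- per_site_loglik(list(a = t1, b = t2, a2 = t1), m, loc)
  expect_equal(dim(slm), c(3, 60))
  expect_equal(unname(attr(slm, "loglik")),
               unname(c(tree_loglik(t1, m, loc), tree_loglik(t2, m, loc),
                        tree_loglik(t1, m, loc))), tolerance = 1e-8)
  expect_equal(rowSums(slm), attr(slm, "loglik"), tolerance = 1e-8)
  # duplicated tree gives identical rows
  expect_equal(unname(slm[1, ]), unname(slm[3, ]))
})

test_that("bootstrap supports behave at the extremes and are reproducible", {
  # every site the same informative pattern: the displayed split gets 100
  loc <- aln(A = strrep("A", 40), B = strrep("A", 40),
             C = strrep("T", 40), D = strrep("T", 40))
  m <- subst_model("JC69")
  ml <- nni_search(loc, m, seed = 1)
  bs <- bootstrap_supports(loc, m, ml, replicates = 20, seed = 1)
  expect_equal(unname(attr(bs, "support_table")), 100)
  # a single replicate yields supports in {0, 100}
  loc2 <- random_locus(6, 100, seed = 10)
  m2 <- fit_model(loc2, "JC69", gamma = FALSE)
  ml2 <- nni_search(loc2, m2, seed = 1)
  b1 <- bootstrap_supports(loc2, m2, ml2, replicates = 1, seed = 5)
  expect_true(all(attr(b1, "support_table") %in% c(0, 100)))
  # identical seeds give identical supports
  b2 <- bootstrap_supports(loc2, m2, ml2, replicates = 25, seed = 7)
  b3 <- bootstrap_supports(loc2, m2, ml2, replicates = 25, seed = 7)
  expect_identical(attr(b2, "support_table"), attr(b3, "support_table"))
})
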