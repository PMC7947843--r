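# multispecies-coalescent simulator

triplet_concordance <- function(gts) {
  mean(vapply(gts, function(g) {
    d <- stats::cophenetic(g)
    d["A", "B"] < d["A", "C"] && d["A", "B"] < d["B", "C"]
  }, NA))
}

test_that("triplet topology frequencies follow the MSC", {
  # t = 0: hard polytomy, each rooted triplet 1/3
  m0 <- species_tree_model("((A:1,B:1):0,C:1);", subst_scale = 0.05)
  g0 <- simulate_gene_trees(m0, 1500, seed = 4)
  expect_lt(abs(triplet_concordance(g0) - 1 / 3), 3 * sqrt(2 / 9 / 1500))

  # t = 1: analytic concordance 1 - (2/3) e^-1
  m1 <- species_tree_model("((A:1,B:1):1,C:2);", subst_scale = 0.05)
  g1 <- simulate_gene_trees(m1, 3000, seed = 4)
  expect_lt(abs(triplet_concordance(g1) - (1 - (2 / 3) * exp(-1))), 0.02)

  # t -> infinity: no ILS
  m20 <- species_tree_model("((A:1,B:1):20,C:21);", subst_scale = 0.05)
  g20 <- simulate_gene_trees(m20, 200, seed = 4)
  expect_equal(triplet_concordance(g20), 1)
})

test_that("gene-tree simulation is deterministic per seed and validates input", {
  m <- species_tree_model("((A:1,B:1):1,C:2);")
  a <- simulate_gene_trees(m, 10, seed = 99)
  b <- simulate_gene_trees(m, 10, seed = 99)
  expect_identical(ape::write.tree(a), ape::write.tree(b))
  expect_equal(length(a), 10)
  # non-binary or negative-length species trees are rejected
  expect_error(species_tree_model("((A:1,B:1,C:1):1,D:2);"), "binary")
  expect_error(species_tree_model("((A:1,B:1):-1,C:0);"), "nonnegative")
})

test_that("locus alignments respect the core/flank profile", {
  st <- ape::compute.brlen(ape::stree(16, "balanced"), 1)
  m <- species_tree_model(st, subst_scale = 0.05)
  gt <- simulate_gene_trees(m, 1, seed = 1)[[1]]

  # zero-rate core: core columns identical across taxa
  prof0 <- locus_profile(length = 300, core_fraction = 1 / 3, core_mult = 0,
                         gradient = "step")
  sim0 <- simulate_locus_alignment(scale_gene_tree(gt, 0.05), prof0, seed = 2)
  expect_equal(sim0$breakpoints, c(l = 100, r = 200))
  core_cols <- sim0$locus$seq[, 101:200]
  expect_true(all(apply(core_cols, 2, function(col) length(unique(col)) == 1)))
  expect_equal(n_sites(sim0$locus), 300)

  # canonical 600-site profile: centered core at (200, 400)
  expect_equal(profile_breakpoints(locus_profile(length = 600,
                                                 core_fraction = 1 / 3)),
               c(l = 200, r = 400))

  # slow core: mean entropy in core below flanks, across loci
  ds <- simulate_dataset(m, 20, locus_profile(), seed = 6)
  ce <- fe <- numeric(20)
  for (i in 1:20) {
    h <- entropy_profile(ds$loci[[i]])
    ce[i] <- mean(h[201:400]); fe[i] <- mean(h[c(1:200, 401:600)])
  }
  expect_true(all(ce < fe))

  # determinism per seed
  sim_a <- simulate_locus_alignment(scale_gene_tree(gt, 0.05), prof0, seed = 7)
  sim_b <- simulate_locus_alignment(scale_gene_tree(gt, 0.05), prof0, seed = 7)
  expect_identical(sim_a$locus$seq, sim_b$locus$seq)
})

test_that("profile validation enforces its invariants", {
  expect_error(locus_profile(core_fraction = 0), "strictly between")
  expect_error(locus_profile(core_fraction = 1), "strictly between")
  expect_error(locus_profile(core_mult = 1, flank_mult = 0.5), "slower")
  expect_error(locus_profile(missing_p = 1), "missing_p")
})

test_that("missing-taxon injection honors rate and floor", {
  set.seed(20)
  st <- ape::rcoal(20, tip.label = paste0("t", 1:20))
  st$edge.length <- st$edge.length / max(ape::node.depth.edgelength(st)) * 4
  m <- species_tree_model(st, subst_scale = 0.05)
  ds <- simulate_dataset(m, 100, locus_profile(length = 60, core_fraction = 0.34),
                         seed = 3)
  # p = 0: unchanged
  expect_identical(inject_missing_taxa(ds, 0, seed = 1)$loci, ds$loci)
  # p = 0.2: retained fraction near 0.8
  ds2 <- inject_missing_taxa(ds, 0.2, min_taxa = 4, seed = 5)
  kept <- sum(vapply(ds2$loci, function(x) nrow(x$seq), 0)) / (100 * 20)
  expect_lt(abs(kept - 0.8), 0.03)
  # heavy missingness never drops below the floor
  ds3 <- inject_missing_taxa(ds, 0.9, min_taxa = 4, seed = 5)
  expect_true(all(vapply(ds3$loci, function(x) nrow(x$seq), 0) >= 4))
  # p = 1 is invalid
  expect_error(inject_missing_taxa(ds, 1), "p_missing")
})

test_that("datasets round-trip through their on-disk layout", {
  sys <- default_system()
  ds <- simulate_dataset(sys$model, 3, locus_profile(length = 180), seed = 8)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  loci <- read_loci(list.files(dir, pattern = "fasta$", full.names = TRUE))
  expect_equal(length(loci), 3)
  expect_identical(loci[[1]]$seq, ds$loci[[1]]$seq)
  gts <- ape::read.tree(file.path(dir, "true_gene_trees.nwk"))
  expect_equal(length(gts), 3)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(manifest$n_loci, 3)
})
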