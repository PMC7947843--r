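# locus I/O, completeness filtering, concatenation

test_that("FASTA and NEXUS round-trip matrices and labels", {
  loc <- random_locus(6, 120, seed = 2, gap_p = 0.05, id = "rt")
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "rt.fasta")
  nx <- file.path(dir, "rt.nex")
  write_locus(loc, fa, "fasta")
  write_locus(loc, nx, "nexus")
  expect_identical(read_loci(fa, "fasta")[[1]]$seq, loc$seq)
  expect_identical(read_loci(nx, "nexus")[[1]]$seq, loc$seq)
})

test_that("interleaved NEXUS reads the same matrix as sequential", {
  loc <- random_locus(4, 60, seed = 3, id = "il")
  dir <- withr::local_tempdir()
  seqs <- apply(loc$seq, 1, paste, collapse = "")
  # hand-write an interleaved block in two 30-column chunks
  il <- file.path(dir, "il.nex")
  writeLines(c("#NEXUS", "BEGIN DATA;",
               "  DIMENSIONS NTAX=4 NCHAR=60;",
               "  FORMAT DATATYPE=DNA MISSING=? GAP=- INTERLEAVE=YES;",
               "  MATRIX",
               paste(names(seqs), substr(seqs, 1, 30)),
               "",
               paste(names(seqs), substr(seqs, 31, 60)),
               "  ;", "END;"), il)
  expect_identical(read_loci(il, "nexus")[[1]]$seq, loc$seq)
})

test_that("malformed files raise format errors naming the culprit", {
  dir <- withr::local_tempdir()
  bad <- file.path(dir, "bad.fasta")
  writeLines(c(">a", "ACGTAC", ">b", "ACG"), bad)
  expect_error(read_loci(bad, "fasta"), "bad.fasta.*'b'")
  empty <- file.path(dir, "empty.fasta")
  file.create(empty)
  expect_error(read_loci(empty, "fasta"), "empty")
})

test_that("completeness filtering is inclusive, order-preserving, idempotent", {
  mk <- function(id, n) random_locus(n, 10, seed = n, id = id)
  # boundary: 15/20 = 0.75 retained at 0.75, dropped at 0.90
  l15 <- mk("a", 15)
  expect_equal(length(filter_by_completeness(list(l15), 20, 0.75)), 1)
  expect_equal(length(filter_by_completeness(list(l15), 20, 0.90)), 0)
  # synthetic set with known coverages vs direct counting
  set.seed(9)
  ns <- sample(5:20, 100, replace = TRUE)
  loci <- lapply(seq_along(ns), function(i) mk(sprintf("L%03d", i), ns[i]))
  for (th in c(0.75, 0.90)) {
    got <- vapply(filter_by_completeness(loci, 20, th), function(x) x$id, "")
    expect_identical(got, sprintf("L%03d", which(ns / 20 >= th)))
    # idempotence
    expect_equal(length(filter_by_completeness(filter_by_completeness(loci, 20, th),
                                               20, th)),
                 length(got))
  }
  expect_error(filter_by_completeness(loci, 20, 0), "threshold")
})

test_that("concatenation lays out charsets and gap-fills absent taxa", {
  l1 <- random_locus(4, 100, seed = 1, id = "A")
  l2 <- random_locus(4, 200, seed = 2, id = "B")
  l3 <- random_locus(4, 300, seed = 3, id = "C")
  # drop taxon t4 from locus B
  l2$seq <- l2$seq[1:3, , drop = FALSE]
  sm <- concatenate(list(l1, l2, l3))
  expect_equal(ncol(sm$seq), 600)
  expect_equal(sm$charsets$start, c(1, 101, 301))
  expect_equal(sm$charsets$end, c(100, 300, 600))
  expect_true(all(sm$seq["t4", 101:300] == "-"))
  expect_true(all(sm$seq["t1", 101:300] == l2$seq["t1", ]))
  # case-colliding taxon labels are rejected
  lx <- random_locus(3, 10, seed = 4, id = "D")
  rownames(lx$seq)[1] <- "T1"
  expect_error(concatenate(list(l1, lx)), "case")
})

test_that("core/flank schemes triple the charsets and match breakpoints", {
  loci <- lapply(1:3, function(i) random_locus(4, 180, seed = i,
                                               id = paste0("L", i)))
  schemes <- lapply(loci, function(l)
    partition_scheme(l$id, 60, 120, 180, objective = 0, min_len = 50))
  names(schemes) <- vapply(loci, function(x) x$id, "")
  sm <- concatenate(loci, schemes)
  expect_equal(nrow(sm$charsets), 9)
  expect_equal(sm$charsets$start[1:3], c(1, 61, 121))
  expect_equal(sm$charsets$end[1:3], c(60, 120, 180))
  expect_equal(sm$charsets$start[4], 181)
  expect_equal(ncol(sm$seq), sum(vapply(loci, n_sites, 0L)))
  # NEXUS + RAxML sidecar files are written and re-readable
  dir <- withr::local_tempdir()
  write_supermatrix_nexus(sm, file.path(dir, "sm.nex"))
  expect_true(any(grepl("charset L1_core = 61-120;",
                        readLines(file.path(dir, "sm.nex")))))
  write_raxml_partitions(sm$charsets, file.path(dir, "parts.txt"))
  expect_equal(length(readLines(file.path(dir, "parts.txt"))), 9)
})
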