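test_that("k-mer index canonicalizes and records postings", {
  t1 <- rand_dna(21)
  s1 <- make_sample("A", stats::setNames(t1, "t1"))
  idx <- build_kmer_index(list(s1), k = 21)
  expect_equal(nrow(kmer_postings(idx, t1)), 1L)

  # a transcript and its reverse complement have identical canonical sets
  set.seed(4)
  t2 <- rand_dna(60)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(t2)))
  expect_equal(canonical_kmers(t2, 21), canonical_kmers(rc, 21))

  # a shared k-length substring yields two postings
  core <- rand_dna(21)
  sa <- make_sample("A", stats::setNames(paste0(rand_dna(30), core), "a1"))
  sb <- make_sample("B", stats::setNames(paste0(core, rand_dna(30)), "b1"))
  idx2 <- build_kmer_index(list(sa, sb), k = 21)
  expect_equal(nrow(kmer_postings(idx2, core)), 2L)

  # k-mers containing N are skipped
  expect_equal(length(canonical_kmers(paste0(rand_dna(10), "N",
                                             rand_dna(10)), 21)), 0L)

  # too-short transcripts contribute nothing, with a warning
  s3 <- make_sample("C", stats::setNames(rand_dna(10), "c1"))
  expect_warning(build_kmer_index(list(s3), k = 21), "shorter")

  expect_error(build_kmer_index(list(s1), k = 20),
               class = "derepool_config_error")
})

test_that("read attribution follows the max-share and tie rules deterministically", {
  set.seed(9)
  tA <- rand_dna(200)
  tB <- rand_dna(200)
  sA <- make_sample("A", stats::setNames(tA, "a1"))
  sB <- make_sample("B", stats::setNames(c(tB, tA), c("b1", "b2")))
  idx <- build_kmer_index(list(sA, sB), k = 21)

  # read from a unique transcript: full count there
  rd <- substr(tB, 50, 149)
  cn <- attribute_reads(idx, rd)
  expect_equal(unname(cn), c(0, 1, 0))

  # read matching two identical transcripts: half each (a1 == b2)
  rd2 <- substr(tA, 50, 149)
  cn2 <- attribute_reads(idx, rd2)
  expect_equal(unname(cn2), c(0.5, 0, 0.5))

  # random read: unattributed
  cn3 <- attribute_reads(idx, rand_dna(100))
  expect_equal(sum(cn3), 0)

  # attribution is independent of read order
  reads <- vapply(1:50, function(i) {
    src <- sample(c(tA, tB), 1)
    p <- sample(100, 1)
    substr(src, p, p + 99)
  }, "")
  expect_equal(attribute_reads(idx, reads),
               attribute_reads(idx, rev(reads)))
})

test_that("expression is TPM-like: length-normalized, summing to one million", {
  expect_equal(quantify_expression(5, 700), 1e6)
  expect_equal(quantify_expression(c(3, 3), c(500, 500)), c(5e5, 5e5))
  expect_equal(quantify_expression(c(10, 5), c(2000, 1000)), c(5e5, 5e5))
  expect_equal(quantify_expression(c(0, 0), c(100, 100)), c(0, 0))

  set.seed(2)
  cn <- runif(20) * 10
  ln <- sample(200:900, 20)
  expect_equal(sum(quantify_expression(cn, ln)), 1e6, tolerance = 1e-9)
})

test_that("each read-sample's attributed expression sums to one million", {
  set.seed(17)
  mk <- function(id) {
    tr <- rand_dna_set(5, c(150, 300))
    names(tr) <- paste0(id, "_", names(tr))
    reads <- vapply(1:60, function(i) {
      src <- tr[[sample(5, 1)]]
      p <- sample(nchar(src) - 99, 1)
      substr(src, p, p + 99)
    }, "")
    make_sample(id, tr, reads)
  }
  samples <- list(mk("A"), mk("B"))
  cc <- cross_contamination(samples)
  for (sid in c("A", "B")) {
    expect_equal(sum(cc$expr[, sid]), 1e6, tolerance = 1e-6)
  }
})

test_that("transcript classification applies the ratio rule in order", {
  catalog <- data.frame(owner_sample = c("S", "S", "S", "S"),
                        transcript_id = c("t1", "t2", "t3", "t4"),
                        length = rep(500L, 4), stringsAsFactors = FALSE)
  expr <- cbind(S = c(10, 10, 0.01, 10), O = c(30, 0, 0.02, 15))
  v <- classify_transcripts(expr, catalog, R = 2, min_expr = 1)
  expect_equal(v$category, c("crosscontam", "clean", "lowexp", "dubious"))
  expect_equal(v$donor_sample, c("O", NA, NA, NA))

  expect_error(classify_transcripts(expr, catalog, R = 1),
               class = "derepool_config_error")
})

test_that("cross-contamination matrix is a percentage of the owner's transcripts", {
  owners <- c(rep("B", 100), rep("A", 10))
  verdicts <- data.frame(
    owner_sample = owners,
    transcript_id = sprintf("t%03d", seq_along(owners)),
    category = c(rep("crosscontam", 12), rep("clean", 85),
                 rep("dubious", 3), rep("clean", 10)),
    donor_sample = c(rep("A", 12), rep(NA, 98)),
    stringsAsFactors = FALSE)
  m <- cross_contam_matrix(verdicts, c("A", "B"))
  expect_equal(m["A", "B"], 12)
  expect_equal(m["B", "A"], 0)
  expect_equal(diag(m), c(A = 0, B = 0))
  expect_true(all(colSums(m) <= 100))

  verdicts0 <- verdicts
  verdicts0$category <- "clean"
  expect_true(all(cross_contam_matrix(verdicts0, c("A", "B")) == 0))

  expect_error(cross_contam_matrix(verdicts, c("A", "B", "C")),
               class = "derepool_consistency_error")
})
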