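make_cc_matrix <- function(ids, edges = list()) {
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (e in edges) m[e[[1]], e[[2]]] <- as.numeric(e[[3]])
  m
}

test_that("pooling partitions samples by genus and relatedness", {
  sam <- data.frame(sample_id = c("A1", "A2", "A3", "B1", "C1", "C2"),
                    genus = c("Ga", "Ga", "Ga", "Gb", "Gc", "Gc"),
                    stringsAsFactors = FALSE)
  m <- make_cc_matrix(sam$sample_id,
                      list(list("A1", "A2", 12), list("A2", "A1", 3),
                           list("C1", "C2", 5), list("C2", "C1", 5)))
  p <- build_pools(sam, m, threshold_pct = 10)

  expect_equal(sort(p$pools$kind[p$pools$pool_id == "Gb_1"]),
               "singleton_unique_genus")
  ga <- p$membership[p$membership$sample_id %in% c("A1", "A2"), "pool_id"]
  expect_equal(unique(ga), "Ga_1")
  expect_equal(p$pools$kind[p$pools$pool_id == "Ga_1"], "combined")
  expect_equal(p$membership$kind[p$membership$sample_id == "A3"],
               "singleton_unrelated")
  expect_equal(unique(p$pools$kind[grepl("^Gc", p$pools$pool_id)]),
               "singleton_unrelated")

  # partition: every sample in exactly one pool
  expect_equal(sort(p$membership$sample_id), sort(sam$sample_id))
  expect_equal(sum(p$pools$n_members), nrow(sam))

  # under min rule the 12/3 pair is no longer an edge
  pmin_ <- build_pools(sam, m, threshold_pct = 10, rule = "min")
  expect_false(any(pmin_$pools$kind == "combined"))

  # invariant to input order
  set.seed(6)
  p2 <- build_pools(sam[sample(nrow(sam)), ], m, threshold_pct = 10)
  expect_equal(p2$pools, p$pools)
  expect_equal(p2$membership, p$membership)

  expect_error(build_pools(rbind(sam, data.frame(sample_id = "Z9",
                                                 genus = "Gz")), m, 10),
               class = "derepool_consistency_error")
})

test_that("transitive relatedness pools whole components", {
  sam <- data.frame(sample_id = c("A1", "A2", "A3"), genus = "Ga",
                    stringsAsFactors = FALSE)
  m <- make_cc_matrix(sam$sample_id,
                      list(list("A1", "A2", 15), list("A2", "A3", 15)))
  p <- build_pools(sam, m, 10)
  expect_equal(p$pools$n_members, 3L)
  expect_equal(p$pools$kind, "combined")
})

test_that("pool merging conserves and renames transcripts", {
  tr1 <- Biostrings::DNAStringSet(stats::setNames(
    vapply(1:10, function(i) rand_dna(50), ""), sprintf("x%02d", 1:10)))
  tr2 <- Biostrings::DNAStringSet(stats::setNames(
    vapply(1:20, function(i) rand_dna(50), ""), sprintf("y%02d", 1:20)))
  merged <- merge_pool("Ga_1", list(S1 = tr1, S2 = tr2))
  expect_equal(length(merged), 30L)
  expect_true(all(grepl("^Ga_1\\.(S1\\.x|S2\\.y)", names(merged))))
  expect_equal(as.character(merged[["Ga_1.S1.x01"]]),
               as.character(tr1[["x01"]]))

  single <- merge_pool("Gb_1", list(S3 = tr1))
  expect_equal(as.character(single), unname(as.character(tr1)),
               ignore_attr = TRUE)

  expect_error(merge_pool("Gc_1", list()), class = "derepool_config_error")
})

test_that("pairwise identity uses the shorter-sequence denominator", {
  x <- "ACGTACGTACGTACGTACGT"
  expect_equal(pairwise_identity(x, x), 100)
  y <- x
  substr(y, 10, 10) <- "A"  # interior substitution: full span stays optimal
  expect_equal(pairwise_identity(x, y), 95)

  long <- rand_dna(60)
  expect_equal(pairwise_identity(long, substr(long, 16, 45)), 100)
})

test_that("greedy dereplication matches the brute-force oracle and conserves input", {
  set.seed(31)
  seqs <- rep(rand_dna(120), 5)
  names(seqs) <- sprintf("c%d", 1:5)
  d <- dereplicate(seqs, 95)
  expect_equal(length(d$representatives), 1L)
  expect_equal(nrow(d$clusters), 5L)

  # 96% pair joins at threshold 95, splits at 97
  a <- rand_dna(200)
  b <- substitute_n(a, 8)
  pair <- c(p1 = a, p2 = b)
  expect_equal(length(dereplicate(pair, 95)$representatives), 1L)
  expect_equal(length(dereplicate(pair, 97)$representatives), 2L)

  # unrelated sequences: all singletons, identical to the oracle
  set.seed(32)
  rnd <- rand_dna_set(30, c(100, 100))
  d30 <- dereplicate(rnd, 95)
  expect_equal(length(d30$representatives), 30L)
  orc <- derep_oracle(rnd, 95)
  expect_equal(d30$representatives, orc$reps)

  # conservation: |reps| + sum(size - 1) = n
  sizes <- table(d30$clusters$cluster)
  expect_equal(length(d30$representatives) + sum(sizes - 1), 30L)

  # idempotence: dereplicating representatives yields only singletons
  reps <- rnd[d30$representatives]
  d2 <- dereplicate(reps, 95)
  expect_equal(length(d2$representatives), length(reps))
})

test_that("the word prefilter never rejects a pair the DP accepts at 95%", {
  set.seed(33)
  for (i in 1:500) {
    len <- sample(100:160, 1)
    a <- rand_dna(len)
    n_sub <- sample.int(max(1, floor(0.05 * len)), 1)
    b <- substitute_n(a, n_sub)
    idp <- pairwise_identity(a, b)
    if (idp < 95) next
    need <- derepool:::required_words(min(nchar(a), nchar(b)), 95, 8)
    shared <- sum(derepool:::word_set(a, 8) %in% derepool:::word_set(b, 8))
    expect_gte(shared, need)
  }
})
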