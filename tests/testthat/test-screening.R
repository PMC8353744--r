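test_that("Tukey fence flags only values strictly above Q3 + k*IQR", {
  est <- data.frame(unit_id = paste0("u", 1:5), phylum = "P",
                    contamination_pct = c(1, 2, 2, 3, 30),
                    stringsAsFactors = FALSE)
  o <- detect_outliers(est)
  expect_equal(unique(o$fence_upper), 4.5)  # Q1=2, Q3=3, IQR=1
  expect_equal(o$unit_id[o$flagged], "u5")

  # all-equal values: IQR 0, fence = Q3, nothing strictly above
  est2 <- est
  est2$contamination_pct <- rep(7, 5)
  expect_false(any(detect_outliers(est2)$flagged))

  # small phyla are unfenced and never flagged
  o3 <- detect_outliers(est[1:3, ])
  expect_false(any(o3$fenced))
  expect_false(any(o3$flagged))

  expect_equal(nrow(detect_outliers(est[0, ])), 0L)
})

test_that("fences are per phylum, order-invariant and monotone in fence_k", {
  set.seed(41)
  est <- data.frame(
    unit_id = paste0("u", 1:12),
    phylum = rep(c("P", "Q"), each = 6),
    contamination_pct = c(runif(5, 0, 5), 40, runif(5, 10, 20), 90),
    stringsAsFactors = FALSE)
  o <- detect_outliers(est)
  o_perm <- detect_outliers(est[sample(12), ])
  expect_equal(o[order(o$unit_id), "flagged"],
               o_perm[order(o_perm$unit_id), "flagged"],
               ignore_attr = TRUE)
  # per-phylum fences differ
  expect_true(o$fence_upper[o$phylum == "P"][1] !=
              o$fence_upper[o$phylum == "Q"][1])

  for (k in c(0.5, 1.5, 3, 10)) {
    flags_lo <- detect_outliers(est, fence_k = k)$flagged
    flags_hi <- detect_outliers(est, fence_k = k + 1)$flagged
    expect_true(all(flags_lo | !flags_hi))  # raising k never adds flags
  }

  # NA metric values are excluded from fencing and never flagged
  est$contamination_pct[1] <- NA
  o_na <- detect_outliers(est)
  expect_false(o_na$flagged[o_na$unit_id == "u1"])
  expect_false(o_na$fenced[o_na$unit_id == "u1"])
})

test_that("quartiles agree with a sort-and-interpolate oracle", {
  set.seed(42)
  for (i in 1:100) {
    x <- runif(sample(4:30, 1), 0, 50)
    expect_equal(stats::quantile(x, 0.25, type = 7, names = FALSE),
                 quartile_oracle(x, 0.25))
    expect_equal(stats::quantile(x, 0.75, type = 7, names = FALSE),
                 quartile_oracle(x, 0.75))
  }
})

test_that("completeness classifies markers as complete, fragmented or missing", {
  spec <- synthetic_spec(n_phyla = 1, genera_per_phylum = 1,
                         samples_per_genus = 1, n_marker_families = 6,
                         seed = 13)
  db <- generate_marker_db(spec)
  full <- vapply(db$residues, reverse_translate, "")
  names(full) <- sprintf("t%d", seq_along(full))

  # full-length copies of all markers: 100% complete
  r <- assess_completeness(Biostrings::DNAStringSet(full), db, "u1")
  expect_equal(r$pct_complete, 100)
  expect_equal(r$n_missing, 0L)

  # nothing marker-like: everything missing
  r0 <- assess_completeness(
    Biostrings::DNAStringSet(c(t1 = rand_dna(300))), db, "u2")
  expect_equal(r0$n_missing, r0$n_markers)
  expect_equal(r0$pct_complete, 0)

  # one marker truncated to half its reference: fragmented
  half <- full
  half[1] <- substr(half[1], 1, floor(nchar(half[1]) / 2))
  r2 <- assess_completeness(Biostrings::DNAStringSet(half), db, "u3")
  expect_equal(r2$n_fragmented, 1L)
  expect_equal(r2$n_complete, r2$n_markers - 1L)

  expect_error(assess_completeness(Biostrings::DNAStringSet(full), db[0, ]),
               class = "derepool_config_error")
})
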