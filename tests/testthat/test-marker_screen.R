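test_that("six-frame translation follows the standard code and strand symmetry", {
  expect_equal(translate_six_frames("ATGGCC")[["+1"]], "MA")
  expect_equal(translate_six_frames("ATGTAA")[["+1"]], "M*")
  expect_equal(translate_six_frames("AT")[["+1"]], "")

  set.seed(7)
  for (i in 1:20) {
    s <- rand_dna(sample(3:60, 1))
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    expect_equal(translate_six_frames(s)[["-1"]],
                 translate_six_frames(rc)[["+1"]])
  }

  # against Biostrings (plain translation, no init-codon special-casing)
  set.seed(8)
  for (i in 1:25) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), sample(6:60, 1),
                      replace = TRUE, prob = c(.24, .24, .24, .24, .04)),
               collapse = "")
    got <- translate_six_frames(s)
    d <- Biostrings::DNAString(s)
    w <- nchar(s)
    wl3 <- (w %/% 3) * 3
    exp <- as.character(Biostrings::translate(
      Biostrings::subseq(d, 1, wl3), if.fuzzy.codon = "X",
      no.init.codon = TRUE))
    expect_equal(got[["+1"]], exp)
  }
})

test_that("local protein alignment matches oracles and scores identity correctly", {
  b62 <- derepool:::blosum62()

  a30 <- rand_aa(30)
  self <- align_protein(a30, a30)
  diag_sum <- sum(diag(b62)[strsplit(a30, "")[[1]]])
  expect_equal(self$score, diag_sum)
  expect_equal(self$identity_pct, 100)

  expect_equal(align_protein("AAA", "WWW")$score, 0)

  # 25-mer with 2 substitutions: identity 92 over the full span
  set.seed(21)
  q <- rand_aa(25)
  r <- substitute_n(q, 2, alphabet = c("A","C","D","E","F","G","H","I","K",
                                       "L","M","N","P","Q","R","S","T","V",
                                       "W","Y"))
  al <- align_protein(q, r)
  expect_equal(al$identity_pct, 92)
  expect_equal(al$score,
               sw_score_oracle(q, r, b62, 11, 1))

  # full-DP oracle on random pairs, protein scoring
  set.seed(22)
  for (i in 1:60) {
    q <- rand_aa(sample(5:60, 1))
    s <- rand_aa(sample(5:60, 1))
    expect_equal(align_protein(q, s)$score,
                 sw_score_oracle(q, s, b62, 11, 1))
  }
})

test_that("screen_sample bins exact marker copies to their own phylum", {
  spec <- synthetic_spec(n_phyla = 2, genera_per_phylum = 1,
                         samples_per_genus = 1, n_marker_families = 10,
                         subst_rate = 0.3, seed = 5)
  db <- generate_marker_db(spec)
  own <- db[db$phylum == "Phy01", ]
  transcripts <- vapply(own$residues, reverse_translate, "")
  names(transcripts) <- sprintf("t%02d", seq_along(transcripts))
  s <- make_sample("S1", transcripts, phylum = "Phy01")
  hits <- screen_sample(s, db)
  expect_equal(nrow(hits), 10L)
  expect_true(all(hits$best_phylum == "Phy01"))
  expect_equal(sort(unique(hits$marker_id)), sort(unique(db$marker_id)))

  # transcripts with no marker similarity give no hits, and the
  # estimate is flagged unscorable
  s2 <- make_sample("S2", stats::setNames(rand_dna(300), "t1"),
                    phylum = "Phy01")
  h2 <- screen_sample(s2, db)
  expect_equal(nrow(h2), 0L)
  e2 <- estimate_contamination(h2, s2$taxonomy)
  expect_true(e2$unscorable)
  expect_true(is.na(e2$contamination_pct))

  expect_error(screen_sample(s, db[0, ]), class = "derepool_config_error")
})

test_that("contamination estimate counts foreign-phylum hits and ignores hit order", {
  hits <- data.frame(
    sample_id = "S1",
    transcript_id = sprintf("t%d", 1:10),
    marker_id = sprintf("RP%02d", 1:10),
    best_phylum = c(rep("PhyA", 8), "PhyB", "PhyB"),
    stringsAsFactors = FALSE)
  e <- estimate_contamination(hits, list(phylum = "PhyA"))
  expect_equal(e$n_hits, 10L)
  expect_equal(e$n_foreign, 2L)
  expect_equal(e$contamination_pct, 20)

  set.seed(3)
  e2 <- estimate_contamination(hits[sample(10), ], list(phylum = "PhyA"))
  expect_equal(e2$contamination_pct, e$contamination_pct)

  e3 <- estimate_contamination(hits[1:8, ], list(phylum = "PhyA"))
  expect_equal(e3$contamination_pct, 0)
})
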