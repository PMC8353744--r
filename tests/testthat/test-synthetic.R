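test_that("marker database generation counts, divergence and determinism", {
  spec <- synthetic_spec(n_phyla = 3, genera_per_phylum = 1,
                         samples_per_genus = 1, n_marker_families = 2,
                         seed = 10)
  db <- generate_marker_db(spec)
  expect_equal(nrow(db), 6L)  # 2 families x 3 phyla
  expect_equal(length(unique(db$marker_id)), 2L)

  spec0 <- synthetic_spec(n_phyla = 3, genera_per_phylum = 1,
                          samples_per_genus = 1, n_marker_families = 2,
                          subst_rate = 0, seed = 10)
  db0 <- generate_marker_db(spec0)
  for (fam in unique(db0$marker_id)) {
    expect_equal(length(unique(db0$residues[db0$marker_id == fam])), 1L)
  }

  expect_equal(generate_marker_db(spec), db)
})

test_that("same seed gives byte-identical datasets", {
  spec <- synthetic_spec(n_phyla = 1, genera_per_phylum = 2,
                         samples_per_genus = 1, transcripts_per_sample = 20,
                         reads_per_sample = 200, marker_copies = 4,
                         n_marker_families = 4, seed = 77)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_dataset(spec, d1)
  generate_dataset(spec, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_equal(f1, list.files(d2, recursive = TRUE))
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("truth tables record exactly what was planted", {
  plan <- data.frame(donor = "Genus01_s01", recipient = "Genus02_s01",
                     fraction = 0.15, depth_mult = 10)
  spec <- synthetic_spec(n_phyla = 2, genera_per_phylum = 1,
                         samples_per_genus = 1, transcripts_per_sample = 40,
                         reads_per_sample = 400, marker_copies = 5,
                         n_marker_families = 5, duplicate_fraction = 0.1,
                         foreign_marker_fraction = c(Genus01_s01 = 0.4),
                         cross_contam_plan = plan, seed = 55)
  dir <- withr::local_tempdir()
  gen <- generate_dataset(spec, dir)

  expect_equal(nrow(gen$truth$planted_crosscontam), floor(0.15 * 40))
  expect_equal(nrow(gen$truth$planted_foreign), round(0.4 * 5))
  # both samples plant duplicates
  expect_equal(nrow(gen$truth$planted_duplicates), 2L * floor(0.1 * 40))

  # every sample holds exactly the configured number of transcripts
  man <- read_manifest(file.path(dir, "manifest.tsv"))
  for (i in seq_len(nrow(man))) {
    expect_equal(length(read_fasta(man$fasta[i])), 40L)
  }

  # planted cross-contaminants are verbatim donor sequences
  don <- read_fasta(man$fasta[man$sample_id == "Genus01_s01"])
  rec <- read_fasta(man$fasta[man$sample_id == "Genus02_s01"])
  tc <- gen$truth$planted_crosscontam
  expect_equal(as.character(rec[tc$transcript_id]),
               as.character(don[tc$donor_transcript_id]),
               ignore_attr = TRUE)

  # planted duplicates carry the advertised identity
  td <- gen$truth$planted_duplicates
  own <- read_fasta(man$fasta[man$sample_id == td$sample_id[1]])
  idp <- pairwise_identity(own[[td$dup_id[1]]], own[[td$source_id[1]]])
  expect_equal(idp, td$identity_pct[1], tolerance = 0.5)

  expect_error(
    generate_dataset(synthetic_spec(
      transcripts_per_sample = 20, marker_copies = 5,
      foreign_marker_fraction = 0.01, seed = 1), withr::local_tempdir()),
    class = "derepool_config_error")
})

test_that("a zero-planting dataset is a clean negative control", {
  # coverage deep enough (~100 reads/transcript) that expression ratios
  # on marker transcripts shared between same-phylum samples sit near 1
  spec <- synthetic_spec(n_phyla = 1, genera_per_phylum = 2,
                         samples_per_genus = 1, transcripts_per_sample = 30,
                         reads_per_sample = 3000, marker_copies = 5,
                         n_marker_families = 5, seed = 21)
  dir <- withr::local_tempdir()
  gen <- generate_dataset(spec, dir)
  man <- read_manifest(file.path(dir, "manifest.tsv"))
  db <- read_marker_db(file.path(dir, "markers.faa"))
  samples <- lapply(seq_len(nrow(man)), function(i) load_sample(man[i, ]))

  for (s in samples) {
    e <- estimate_contamination(screen_sample(s, db), s$taxonomy)
    expect_equal(e$contamination_pct, 0)
  }
  cc <- cross_contamination(samples)
  expect_true(all(cc$matrix == 0))
  expect_equal(sum(cc$verdicts$category == "crosscontam"), 0L)
})

test_that("reverse translation is deterministic and re-translates to the input", {
  aa <- "MKVLITAAGW"
  nt <- reverse_translate(aa)
  expect_equal(nchar(nt), 30L)
  expect_equal(translate_six_frames(nt)[["+1"]], aa)
  expect_equal(reverse_translate(aa), nt)
})
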