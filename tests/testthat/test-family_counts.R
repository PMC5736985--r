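test_that("count matrix TSV reads back with metadata and round-trips exactly", {
  fx <- write_counts_fixture()
  tbl <- read_count_matrix(fx$counts, fx$meta)
  expect_s3_class(tbl, "tbl_df")
  expect_equal(sum(tbl$count[tbl$family == "A1"]), 2)
  expect_equal(tbl$count[tbl$family == "C2" & tbl$species_id == "FOC"], 3)
  expect_true(tbl$hematophagous[tbl$species_id == "FOC"][1])

  dir <- withr::local_tempdir()
  write_count_matrix(tbl, file.path(dir, "c.tsv"), file.path(dir, "m.tsv"))
  back <- read_count_matrix(file.path(dir, "c.tsv"), file.path(dir, "m.tsv"))
  expect_equal(back, tbl)
  # bit-exact TSV dialect
  expect_identical(readLines(file.path(dir, "c.tsv")), readLines(fx$counts))
})

test_that("malformed count files are rejected with informative errors", {
  dir <- withr::local_tempdir()
  meta <- file.path(dir, "meta.tsv")
  writeLines(c("species_id\ttaxon_group\thematophagous",
               "FOC\tHemiptera\t1", "SP01\tDiptera\t0"), meta)
  bad <- file.path(dir, "bad.tsv")

  writeLines(c("family\tFOC\tSP01", "A1\t1"), bad)
  expect_error(read_count_matrix(bad, meta), "ragged.*line 2")

  writeLines(c("family\tFOC\tSP01", "A1\t1\t-2"), bad)
  expect_error(read_count_matrix(bad, meta), "non-negative integers")

  writeLines(c("family\tFOC\tSP01", "A1\t1\tx"), bad)
  expect_error(read_count_matrix(bad, meta), "non-integer")

  writeLines(c("family\tFOC\tSP01", "A1\t1\t1", "A1\t0\t0"), bad)
  expect_error(read_count_matrix(bad, meta), "duplicate family")

  writeLines(c("family\tFOC\tFOC", "A1\t1\t1"), bad)
  expect_error(read_count_matrix(bad, meta), "duplicate species")
})

test_that("transcript sharing collapses records: 14 M17 models with one shared pair give 13 genes", {
  recs <- make_gene_records(14, family = "M17")
  recs$gene_id[1:2] <- c("RPRC014323", "RPRC010866")
  recs$transcript_id[1:2] <- "T_shared"
  merged <- merge_genes_by_transcript(recs)
  expect_equal(nrow(merged), 13)
  expect_true("RPRC010866" %in% merged$gene_id)  # smallest member id survives
  expect_false("RPRC014323" %in% merged$gene_id)
})

test_that("gene merging follows group arithmetic, keeps no-op inputs, and is idempotent", {
  # 23 records with 5 disjoint shared pairs -> 18
  recs <- make_gene_records(23)
  for (k in 1:5) recs$transcript_id[c(2 * k - 1, 2 * k)] <- paste0("T", k)
  merged <- merge_genes_by_transcript(recs)
  expect_equal(nrow(merged), 18)
  expect_equal(merge_genes_by_transcript(merged), merged)

  # all-distinct transcripts: unchanged
  solo <- make_gene_records(6, transcript = paste0("T", 1:6))
  expect_equal(nrow(merge_genes_by_transcript(solo)), 6)

  # flags OR-combined, truncated AND-combined
  recs <- make_gene_records(2, transcript = c("T1", "T1"))
  recs$truncated <- c(TRUE, FALSE)
  recs$signal_peptide <- c(FALSE, TRUE)
  m <- merge_genes_by_transcript(recs)
  expect_false(m$truncated)
  expect_true(m$signal_peptide)

  # same transcript, different family: inconsistent annotation
  recs <- make_gene_records(2, transcript = c("T1", "T1"))
  recs$family_id <- c("A1", "C2")
  expect_error(merge_genes_by_transcript(recs), "inconsistent annotation")
})

test_that("tabulate_counts matches an independent tally and zero-fills", {
  meta <- make_meta(4)
  withr::with_seed(42, {
    recs <- tibble::tibble(
      gene_id = sprintf("G%03d", 1:60),
      species_id = sample(meta$species_id, 60, replace = TRUE),
      family_id = sample(c("A1", "C1", "S1"), 60, replace = TRUE),
      transcript_id = "", truncated = FALSE, signal_peptide = FALSE,
      topology = "unknown"
    )
  })
  tbl <- tabulate_counts(recs, meta)
  # brute-force hash tally
  for (i in seq_len(nrow(tbl))) {
    expect_equal(tbl$count[i],
                 sum(recs$family_id == as.character(tbl$family[i]) &
                       recs$species_id == as.character(tbl$species_id[i])))
  }
  expect_equal(sum(tbl$count), nrow(recs))

  empty <- tabulate_counts(recs[0, ], meta, families = c("A1", "C1"))
  expect_true(all(empty$count == 0))
  expect_equal(nrow(empty), 2 * nrow(meta))

  recs$species_id[1] <- "NOPE"
  expect_error(tabulate_counts(recs, meta), "unknown species")
})

test_that("family code validation accepts MEROPS-style and compound tokens", {
  expect_true(all(is_family_code(c("A1", "S24", "M12B", "C64/C85", "U9"))))
  expect_false(any(is_family_code(c("1A", "a1", "", "A1/", "X9"))))
})
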