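make_contig_tbl <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(rows)
}

cg <- function(gene_id, contig_id, order_index, taxon = "metazoa",
               introns = 0L, candidate = FALSE, family = NA_character_) {
  tibble::tibble(gene_id = gene_id, contig_id = contig_id,
                 order_index = as.integer(order_index),
                 best_hit_taxon = taxon, intron_count = as.integer(introns),
                 is_candidate = candidate, family_id = family)
}

test_that("neighbors are contig-restricted, ordered, and window-limited", {
  genes <- make_contig_tbl(
    cg("lone", "c1", 1, candidate = TRUE),
    cg("up", "c2", 1), cg("mid", "c2", 2, candidate = TRUE), cg("dn", "c2", 3),
    cg(paste0("g", 1:5), "c3", 1:5)
  )
  expect_equal(nrow(neighbors_of("lone", genes)), 0)
  nb <- neighbors_of("mid", genes)
  expect_equal(nb$gene_id, c("up", "dn"))
  expect_lte(nrow(neighbors_of("g3", genes, window = 1)), 2)
  expect_equal(neighbors_of("g1", genes, window = 2)$gene_id, c("g2", "g3"))
  expect_error(neighbors_of("nope", genes), "not in table")
})

test_that("the verdict cascade reproduces the survey's exemplar cases", {
  # single bacterial neighbor, intron-free candidate: contamination suspect
  genes <- make_contig_tbl(
    cg("N6cand", "c1", 1, taxon = "bacteria", candidate = TRUE, family = "N6"),
    cg("stress", "c1", 2, taxon = "bacteria")
  )
  v <- classify_hgt_candidate(genes[1, ], neighbors_of("N6cand", genes))
  expect_equal(v$verdict, "contamination_suspect")

  # metazoan neighbors: genuine insertion
  genes <- make_contig_tbl(
    cg("S29cand", "c1", 2, taxon = "virus", candidate = TRUE, family = "S29"),
    cg("n1", "c1", 1), cg("n2", "c1", 3)
  )
  v <- classify_hgt_candidate(genes[1, ], neighbors_of("S29cand", genes))
  expect_equal(v$verdict, "genuine_insertion")

  # bacterial neighbors but the candidate has introns: conflicting evidence
  genes <- make_contig_tbl(
    cg("S24cand", "c1", 2, taxon = "bacteria", introns = 2,
       candidate = TRUE, family = "S24"),
    cg("duf", "c1", 1, taxon = "bacteria"), cg("atpase", "c1", 3,
                                               taxon = "bacteria")
  )
  v <- classify_hgt_candidate(genes[1, ], neighbors_of("S24cand", genes))
  expect_equal(v$verdict, "inconclusive")
  expect_true(v$conflicting_evidence)

  # no neighbors at all: inconclusive, without conflict
  lone <- cg("M74cand", "c9", 1, taxon = "bacteria", candidate = TRUE)
  v <- classify_hgt_candidate(lone, lone[0, ])
  expect_equal(v$verdict, "inconclusive")
  expect_false(v$conflicting_evidence)
})

test_that("verdicts ignore neighbor order and taxon-none neighbors, and metazoan evidence is monotone", {
  cand <- cg("cand", "c1", 3, taxon = "bacteria", introns = 0,
             candidate = TRUE)
  nbs <- make_contig_tbl(cg("a", "c1", 1, taxon = "bacteria"),
                         cg("b", "c1", 2, taxon = "virus"))
  v1 <- classify_hgt_candidate(cand, nbs)
  v2 <- classify_hgt_candidate(cand, nbs[2:1, ])
  expect_equal(v1$verdict, v2$verdict)

  with_none <- dplyr::bind_rows(nbs, cg("x", "c1", 4, taxon = "none"))
  expect_equal(classify_hgt_candidate(cand, with_none)$verdict, v1$verdict)

  # all-none neighborhood falls back to the no-neighbor rule
  only_none <- make_contig_tbl(cg("x", "c1", 4, taxon = "none"))
  expect_equal(classify_hgt_candidate(cand, only_none)$verdict,
               "inconclusive")

  # adding a metazoan neighbor always lands on genuine_insertion
  with_met <- dplyr::bind_rows(nbs, cg("m", "c1", 5, taxon = "metazoa"))
  expect_equal(classify_hgt_candidate(cand, with_met)$verdict,
               "genuine_insertion")
})

test_that("contig screening recovers planted verdicts exactly", {
  sim <- simulate_contigs(planted = rep(c("lone", "genuine", "contamination",
                                          "conflict"), each = 3),
                          seed = 77)
  res <- screen_contigs(sim$genes)
  expect_equal(nrow(res), 12)
  joined <- dplyr::left_join(sim$truth, tibble::as_tibble(res), by = "gene_id")
  expect_equal(joined$verdict, joined$expected_verdict)
  g <- glance(res)
  expect_equal(g$genuine_insertion, 3)
  expect_equal(g$contamination_suspect, 3)
  expect_equal(g$inconclusive, 6)
})

test_that("empty candidate sets and duplicate placements are handled", {
  genes <- cg(paste0("g", 1:3), "c1", 1:3)
  expect_equal(nrow(screen_contigs(genes)), 0)
  dup <- dplyr::bind_rows(cg("g1", "c1", 1), cg("g1", "c2", 1))
  expect_error(screen_contigs(dup), "duplicate gene_id")
  clash <- dplyr::bind_rows(cg("g1", "c1", 1), cg("g2", "c1", 1))
  expect_error(screen_contigs(clash), "duplicate \\(contig_id, order_index\\)")
})
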