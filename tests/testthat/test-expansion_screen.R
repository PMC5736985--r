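test_that("closest-rank percentile reproduces the published family thresholds", {
  expect_equal(percentile_linear(c(rep(0, 17), 1, 1), 0.9), 0.2)
  expect_equal(percentile_linear(c(rep(0, 16), 1, 3, 3), 0.9), 1.4)
  expect_equal(percentile_linear(c(rep(0, 18), 1), 0.9), 0)
})

test_that("percentile is monotone in q, bounded, and agrees with the type-7 quantile", {
  withr::with_seed(5, {
    for (rep in 1:20) {
      x <- rnbinom(sample(2:25, 1), size = 1.5, mu = 4)
      qs <- sort(runif(5))
      ps <- vapply(qs, function(q) percentile_linear(x, q), numeric(1))
      expect_true(all(diff(ps) >= -1e-12))
      expect_equal(percentile_linear(x, 0), min(x))
      expect_equal(percentile_linear(x, 1), max(x))
      for (q in qs) {
        expect_equal(percentile_linear(x, q),
                     unname(stats::quantile(x, q, type = 7)))
      }
    }
  })
  expect_error(percentile_linear(numeric(0), 0.9), "empty")
  expect_error(percentile_linear(1:3, 1.2), "\\[0, 1\\]")
})

test_that("percentile flagging is strict and uses the focal-included pool", {
  tbl <- reference_sporadic_counts()
  flags <- flag_p90_expanded(tbl, "RPRO")
  expect_equal(nrow(flags), 4)
  expect_true(all(flags$p90_flagged))
  expect_equal(flags$p90_threshold[flags$family == "N6"], 0.2)
  expect_equal(flags$p90_threshold[flags$family == "S24"], 1.4)
  expect_equal(flags$p90_threshold[flags$family == "M74"], 0)

  # equal counts everywhere: count == threshold, strictly-greater rule fails
  const <- tbl |> dplyr::mutate(count = 2L)
  expect_false(any(flag_p90_expanded(const, "RPRO")$p90_flagged))
  expect_error(flag_p90_expanded(tbl, "NOPE"), "focal species")
})

test_that("Venn classification of the published criterion sets singles out C2, M17 and S24", {
  sets <- reference_criterion_sets()
  venn <- venn_classify(sets$hema, sets$taxa, sets$p90)
  s <- attr(venn, "summary")
  expect_setequal(s$multi_criterion, c("C2", "M17", "S24"))
  expect_equal(venn$criterion_count[venn$family == "M17"], 3)
  regions <- attr(venn, "regions")
  expect_equal(sum(regions), 28)       # 5 + 20 + 7 minus overlaps
  expect_equal(unname(regions["all_three"]), 1)
  # splitting the compound C64/C85 token only grows the single-criterion set
  venn2 <- venn_classify(sets$hema, sets$taxa, sets$p90,
                         split_compound = TRUE)
  expect_equal(nrow(venn2), 29)
  expect_setequal(attr(venn2, "summary")$multi_criterion,
                  c("C2", "M17", "S24"))
})

test_that("Venn regions match an element-wise membership oracle on random sets", {
  withr::with_seed(9, {
    pool <- sprintf("F%02d", 1:20)
    for (rep in 1:20) {
      h <- sample(pool, sample(0:10, 1))
      t <- sample(pool, sample(0:10, 1))
      p <- sample(pool, sample(0:10, 1))
      venn <- venn_classify(h, t, p)
      fams <- union(union(h, t), p)
      oracle <- table(factor(
        paste0(as.integer(fams %in% h), as.integer(fams %in% t),
               as.integer(fams %in% p)),
        levels = c("100", "010", "001", "110", "101", "011", "111")))
      expect_equal(unname(attr(venn, "regions")),
                   as.integer(oracle))
    }
  })
  empty <- venn_classify(character(0), character(0), character(0))
  expect_equal(nrow(empty), 0)
  expect_equal(sum(attr(empty, "regions")), 0)
})

test_that("screen recovers planted expansions with the right criterion", {
  sim <- simulate_count_matrix(
    n_species = 19, n_families = 20,
    planted = tibble::tibble(family = c(3, 7), target = c("focal", "hema"),
                             fold = c(5, 5)),
    seed = 202
  )
  screen <- run_screen(sim$counts, focal = "FOC")
  focal_fam <- sim$truth$family[sim$truth$target == "focal"]
  hema_fam <- sim$truth$family[sim$truth$target == "hema"]
  expect_true(screen$p90_flagged[screen$family == focal_fam])
  expect_false(screen$hema_significant[screen$family == focal_fam])
  expect_true(screen$hema_significant[screen$family == hema_fam])
  expect_equal(screen$hema_direction[screen$family == hema_fam], "higher")
  g <- glance(screen)
  expect_equal(g$n_families, 20)
})

test_that("an all-constant matrix flags nothing", {
  sim <- simulate_count_matrix(n_species = 12, n_families = 5, seed = 1)
  tbl <- sim$counts |> dplyr::mutate(count = 3L)
  screen <- run_screen(tbl, focal = "FOC")
  expect_false(any(screen$p90_flagged))
  expect_false(any(screen$hema_significant))
  expect_false(any(screen$taxa_significant))
  expect_true(all(screen$criterion_count == 0))
})

test_that("screen reports serialise to TSV and JSON", {
  sim <- simulate_count_matrix(n_species = 10, n_families = 4, seed = 3)
  screen <- run_screen(sim$counts, focal = "FOC")
  dir <- withr::local_tempdir()
  paths <- write_screen_report(screen, dir)
  expect_true(all(file.exists(paths)))
  back <- readr::read_tsv(paths[1], show_col_types = FALSE)
  expect_equal(nrow(back), 4)
  venn_json <- jsonlite::read_json(paths[3])
  expect_named(venn_json, c("regions", "multi_criterion", "single_fraction"),
               ignore.order = TRUE)
})
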