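# Three-criterion screen for expanded peptidase families:
#   (1) Mann-Whitney U between hematophagous and non-hematophagous species,
#   (2) Kruskal-Wallis across taxonomic groups,
#   (3) focal count strictly above the family's 90th percentile across the
#       whole genome panel (focal included).
# A Venn classification summarises how the criteria overlap.

#' Percentile by linear interpolation between closest ranks
#'
#' Sorts `values` ascending and evaluates the quantile at
#' `h = q * (n - 1)`: `x[floor(h) + 1]` plus the fractional part of `h` times
#' the gap to the next order statistic (the "type 7" convention). With 19
#' genome counts per family this convention reproduces the survey's published
#' thresholds (e.g. 0.2 from seventeen 0s and two 1s at `q = 0.9`).
#'
#' @param values non-empty numeric vector.
#' @param q quantile in `[0, 1]`.
#' @return a single number; `q = 0` gives the minimum, `q = 1` the maximum.
#' @export
#' @examples
#' percentile_linear(c(rep(0, 17), 1, 1), 0.9)      # 0.2
#' percentile_linear(c(rep(0, 16), 1, 3, 3), 0.9)   # 1.4
percentile_linear <- function(values, q) {
  if (length(values) == 0) abort("percentile of an empty vector is undefined")
  if (!is.numeric(q) || length(q) != 1 || is.na(q) || q < 0 || q > 1) {
    abort("q must be a single value in [0, 1]")
  }
  x <- sort(as.numeric(values))
  n <- length(x)
  if (n == 1) return(x)
  h <- q * (n - 1)
  lo <- floor(h)
  frac <- h - lo
  if (lo + 1 >= n) return(x[n])
  x[lo + 1] + frac * (x[lo + 2] - x[lo + 1])
}

#' Flag families whose focal count exceeds the panel's 90th percentile
#'
#' A family is flagged when the focal species' count is strictly greater than
#' [percentile_linear()] of all counts of that family — the focal genome is
#' part of the percentile pool.
#'
#' @param tbl long count table (see [read_count_matrix()]).
#' @param focal focal species id (must be present in `tbl`).
#' @param q percentile level, default 0.9.
#' @return tibble with one row per family: `family`, `focal_count`,
#'   `p90_threshold`, `p90_flagged`.
#' @export
flag_p90_expanded <- function(tbl, focal, q = 0.9) {
  if (!focal %in% as.character(tbl$species_id)) {
    abort(paste0("focal species not in table: ", focal))
  }
  tbl |>
    group_by(.data$family) |>
    summarise(
      focal_count = .data$count[as.character(.data$species_id) == focal][1],
      p90_threshold = percentile_linear(.data$count, q),
      .groups = "drop"
    ) |>
    mutate(p90_flagged = .data$focal_count > .data$p90_threshold)
}

#' Classify families by which screening criteria flagged them
#'
#' Given the three family sets produced by the hematophagy test, the taxonomic
#' test and the percentile-90 rule, returns the per-family criterion count and
#' the cardinality of each Venn region.
#'
#' @param hema_set,taxa_set,p90_set character vectors of family ids.
#' @param split_compound split compound tokens such as `"C64/C85"` into their
#'   component families before classifying (default `FALSE`: a compound label
#'   is one family).
#' @return tibble with columns `family`, `in_hema`, `in_taxa`, `in_p90`,
#'   `criterion_count`, carrying attributes `regions` (named integer vector of
#'   the 7 Venn region sizes) and `summary` (list with `n_flagged`,
#'   `multi_criterion` families and `single_fraction`, the fraction of flagged
#'   families hit by exactly one criterion).
#' @export
venn_classify <- function(hema_set, taxa_set, p90_set,
                          split_compound = FALSE) {
  expand <- function(s) {
    s <- unique(as.character(s))
    if (split_compound) unique(unlist(strsplit(s, "/", fixed = TRUE))) else s
  }
  hema_set <- expand(hema_set); taxa_set <- expand(taxa_set)
  p90_set <- expand(p90_set)
  fams <- sort(unique(c(hema_set, taxa_set, p90_set)))
  tbl <- tibble(
    family = fams,
    in_hema = fams %in% hema_set,
    in_taxa = fams %in% taxa_set,
    in_p90 = fams %in% p90_set
  ) |>
    mutate(criterion_count = .data$in_hema + .data$in_taxa + .data$in_p90)
  regions <- c(
    hema_only = sum(tbl$in_hema & !tbl$in_taxa & !tbl$in_p90),
    taxa_only = sum(!tbl$in_hema & tbl$in_taxa & !tbl$in_p90),
    p90_only = sum(!tbl$in_hema & !tbl$in_taxa & tbl$in_p90),
    hema_taxa = sum(tbl$in_hema & tbl$in_taxa & !tbl$in_p90),
    hema_p90 = sum(tbl$in_hema & !tbl$in_taxa & tbl$in_p90),
    taxa_p90 = sum(!tbl$in_hema & tbl$in_taxa & tbl$in_p90),
    all_three = sum(tbl$in_hema & tbl$in_taxa & tbl$in_p90)
  )
  multi <- tbl$family[tbl$criterion_count >= 2]
  attr(tbl, "regions") <- regions
  attr(tbl, "summary") <- list(
    n_flagged = nrow(tbl),
    multi_criterion = multi,
    single_fraction = if (nrow(tbl) > 0)
      mean(tbl$criterion_count == 1) else NA_real_
  )
  class(tbl) <- c("pep_venn", class(tbl))
  tbl
}

#' Run the full three-criterion expansion screen
#'
#' For every family in the count table: a two-sided Mann-Whitney U test of
#' hematophagous vs non-hematophagous species (direction from the group
#' medians, mean ranks breaking a median tie), a Kruskal-Wallis test across
#' the taxonomic groups, and the strict percentile-90 flag for the focal
#' species.
#'
#' @param tbl long count table with `taxon_group` and `hematophagous`
#'   metadata.
#' @param focal focal species id.
#' @param alpha significance level for both rank tests (default 0.05).
#' @param q percentile level for the expansion flag (default 0.9).
#' @param mwu_method passed to [mann_whitney_u()].
#' @param p_adjust `"none"` (default; nominal per-family p-values) or `"BH"`
#'   for Benjamini-Hochberg adjustment before flagging.
#' @return tibble of class `pep_screen`, one row per family with test
#'   statistics, p-values, flags and the criterion count; the Venn
#'   classification of the flagged sets is attached as attribute `venn`.
#' @export
run_screen <- function(tbl, focal, alpha = 0.05, q = 0.9,
                       mwu_method = "auto", p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  if (!all(c("taxon_group", "hematophagous") %in% names(tbl))) {
    abort("count table must carry taxon_group and hematophagous metadata")
  }
  meta <- tbl[!duplicated(tbl$species_id), ]
  if (length(unique(meta$taxon_group)) < 2) {
    abort("need at least 2 taxon groups")
  }
  if (length(unique(meta$hematophagous)) < 2) {
    abort("need both hematophagous and non-hematophagous species")
  }
  one_family <- function(d) {
    a <- d$count[d$hematophagous]
    b <- d$count[!d$hematophagous]
    mwu <- mann_whitney_u(a, b, method = mwu_method)
    groups <- split(d$count, d$taxon_group)
    if (any(lengths(groups) == 0)) abort("a taxon group has zero species")
    kw <- kruskal_wallis(groups)
    dir <- if (median(a) > median(b)) "higher"
      else if (median(a) < median(b)) "lower"
      else if (mean(rank(d$count)[d$hematophagous]) >=
               mean(rank(d$count)[!d$hematophagous])) "higher" else "lower"
    tibble(
      hema_u = mwu$statistic, hema_p = mwu$p_value, hema_direction = dir,
      taxa_h = kw$statistic, taxa_p = kw$p_value
    )
  }
  per_family <- tbl |>
    group_by(.data$family) |>
    group_modify(~ one_family(.x)) |>
    ungroup()
  if (p_adjust == "BH") {
    per_family$hema_p <- stats::p.adjust(per_family$hema_p, method = "BH")
    per_family$taxa_p <- stats::p.adjust(per_family$taxa_p, method = "BH")
  }
  p90 <- flag_p90_expanded(tbl, focal, q)
  out <- left_join(per_family, p90, by = "family") |>
    mutate(
      hema_significant = .data$hema_p < alpha,
      taxa_significant = .data$taxa_p < alpha,
      criterion_count = .data$hema_significant + .data$taxa_significant +
        .data$p90_flagged
    ) |>
    select("family", "focal_count", "p90_threshold", "p90_flagged",
           "hema_u", "hema_p", "hema_direction", "hema_significant",
           "taxa_h", "taxa_p", "taxa_significant", "criterion_count")
  venn <- venn_classify(
    as.character(out$family[out$hema_significant]),
    as.character(out$family[out$taxa_significant]),
    as.character(out$family[out$p90_flagged])
  )
  structure(out, venn = venn, alpha = alpha, q = q, focal = focal,
            class = c("pep_screen", class(out)))
}

#' @method glance pep_screen
#' @export
glance.pep_screen <- function(x, ...) {
  venn <- attr(x, "venn")
  s <- attr(venn, "summary")
  tibble(
    n_families = nrow(x),
    n_hema = sum(x$hema_significant),
    n_taxa = sum(x$taxa_significant),
    n_p90 = sum(x$p90_flagged),
    n_flagged = s$n_flagged,
    n_multi_criterion = length(s$multi_criterion),
    single_fraction = s$single_fraction,
    alpha = attr(x, "alpha"),
    q = attr(x, "q")
  )
}

#' @method tidy pep_screen
#' @export
tidy.pep_screen <- function(x, ...) {
  out <- x
  attr(out, "venn") <- NULL
  class(out) <- setdiff(class(out), "pep_screen")
  as_tibble(out)
}

#' Write a screen report to TSV and JSON
#'
#' @param screen a `pep_screen` object from [run_screen()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_screen_report <- function(screen, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- file.path(dir, "screen_report.tsv")
  jsn <- file.path(dir, "screen_report.json")
  vjs <- file.path(dir, "venn_summary.json")
  readr::write_tsv(tidy(screen), tsv)
  jsonlite::write_json(tidy(screen), jsn, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  venn <- attr(screen, "venn")
  jsonlite::write_json(
    list(regions = as.list(attr(venn, "regions")),
         multi_criterion = attr(venn, "summary")$multi_criterion,
         single_fraction = attr(venn, "summary")$single_fraction),
    vjs, auto_unbox = TRUE, digits = NA
  )
  invisible(c(tsv, jsn, vjs))
}
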