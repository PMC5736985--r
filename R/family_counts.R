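# Data model and I/O for gene annotations and the species x family count table.
#
# A count table is kept in long ("tidy") form: one row per (family, species)
# cell, with per-species metadata joined in. The on-disk interchange format is
# a wide TSV (first column `family`, one column per species) plus a companion
# metadata TSV with columns `species_id`, `taxon_group`, `hematophagous`.

#' Valid MEROPS-style family codes
#'
#' A family code is one or more catalytic-type letters followed by digits,
#' optionally with a trailing subfamily letter (e.g. `"A1"`, `"M12B"`,
#' `"S24"`). Compound labels joining two families with `/` (e.g. `"C64/C85"`)
#' are accepted as a single token.
#'
#' @param x character vector of candidate codes.
#' @return logical vector.
#' @export
#' @examples
#' is_family_code(c("A1", "M12B", "C64/C85", "1A", ""))
is_family_code <- function(x) {
  one <- "[ACGMNSTPU][0-9]+[A-Z]?"
  grepl(paste0("^", one, "(/", one, ")?$"), x)
}

validate_species_meta <- function(meta) {
  need <- c("species_id", "taxon_group", "hematophagous")
  missing <- setdiff(need, names(meta))
  if (length(missing) > 0) {
    abort(paste0("species metadata is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(meta$species_id)) {
    abort(paste0("duplicate species_id in metadata: ",
                 paste(unique(meta$species_id[duplicated(meta$species_id)]),
                       collapse = ", ")))
  }
  if (any(!nzchar(meta$taxon_group) | is.na(meta$taxon_group))) {
    abort("taxon_group must be non-empty for every species")
  }
  if (!is.logical(meta$hematophagous) || anyNA(meta$hematophagous)) {
    abort("hematophagous must be TRUE/FALSE (1/0) with no missing values")
  }
  meta
}

validate_count_tbl <- function(tbl) {
  if (anyNA(tbl$count) || any(tbl$count < 0) || any(tbl$count != floor(tbl$count))) {
    bad <- tbl$family[which(is.na(tbl$count) | tbl$count < 0 |
                              tbl$count != floor(tbl$count))[1]]
    abort(paste0("counts must be non-negative integers (offending family: ",
                 bad, ")"))
  }
  dup <- duplicated(tbl[, c("family", "species_id")])
  if (any(dup)) {
    abort(paste0("duplicate (family, species) cell: ",
                 tbl$family[dup][1], " / ", tbl$species_id[dup][1]))
  }
  tbl
}

#' Read a species x family gene-count matrix with species metadata
#'
#' Reads the wide TSV interchange format (first column `family`, remaining
#' columns one per species) together with a metadata TSV (`species_id`,
#' `taxon_group`, `hematophagous` as 1/0), validates both, and returns the
#' table in long form ready for [run_screen()].
#'
#' @param counts_path path to the count TSV.
#' @param meta_path path to the species metadata TSV.
#' @return A tibble with columns `family`, `species_id`, `count`,
#'   `taxon_group`, `hematophagous`. Families and species keep file order.
#' @export
read_count_matrix <- function(counts_path, meta_path) {
  lines <- readLines(counts_path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) abort("count TSV needs a header row and >= 1 family row")
  cells <- strsplit(lines, "\t", fixed = TRUE)
  width <- length(cells[[1]])
  ragged <- which(lengths(cells) != width)
  if (length(ragged) > 0) {
    abort(paste0("ragged row in ", counts_path, ": line ", ragged[1],
                 " has ", lengths(cells)[ragged[1]], " fields, expected ", width))
  }
  header <- cells[[1]]
  if (header[1] != "family") abort("first column of the count TSV must be `family`")
  species <- header[-1]
  if (anyDuplicated(species)) abort("duplicate species column in count TSV")
  fams <- map_chr(cells[-1], 1)
  if (anyDuplicated(fams)) {
    abort(paste0("duplicate family row in count TSV: ",
                 fams[duplicated(fams)][1]))
  }
  raw <- map(cells[-1], ~ .x[-1])
  nums <- suppressWarnings(map(raw, as.numeric))
  bad_line <- which(map_lgl(nums, anyNA))
  if (length(bad_line) > 0) {
    abort(paste0("non-integer count in ", counts_path, ": line ",
                 bad_line[1] + 1))
  }
  meta <- readr::read_tsv(meta_path, show_col_types = FALSE,
                          progress = FALSE)
  meta$hematophagous <- as.logical(as.integer(meta$hematophagous))
  meta <- validate_species_meta(meta)
  unknown <- setdiff(species, meta$species_id)
  if (length(unknown) > 0) {
    abort(paste0("species in count TSV missing from metadata: ",
                 paste(unknown, collapse = ", ")))
  }
  tbl <- tibble(
    family = rep(fams, each = length(species)),
    species_id = rep(species, times = length(fams)),
    count = unlist(nums)
  )
  validate_count_tbl(tbl)
  tbl <- left_join(tbl, meta[, c("species_id", "taxon_group", "hematophagous")],
                   by = "species_id")
  tbl$family <- factor(tbl$family, levels = fams)
  tbl$species_id <- factor(tbl$species_id, levels = species)
  tbl
}

#' Write a count table back to the wide TSV interchange format
#'
#' Inverse of [read_count_matrix()]: `write_count_matrix()` then
#' `read_count_matrix()` reproduces the table exactly (same families, species,
#' counts and metadata).
#'
#' @param tbl long count table as returned by [read_count_matrix()] or
#'   [tabulate_counts()].
#' @param counts_path,meta_path output paths.
#' @return `tbl`, invisibly.
#' @export
write_count_matrix <- function(tbl, counts_path, meta_path) {
  fams <- if (is.factor(tbl$family)) levels(tbl$family) else unique(tbl$family)
  sps <- if (is.factor(tbl$species_id)) levels(tbl$species_id) else unique(tbl$species_id)
  wide <- matrix(0L, nrow = length(fams), ncol = length(sps),
                 dimnames = list(fams, sps))
  wide[cbind(as.character(tbl$family), as.character(tbl$species_id))] <-
    as.integer(tbl$count)
  lines <- c(
    paste(c("family", sps), collapse = "\t"),
    map_chr(fams, ~ paste(c(.x, wide[.x, ]), collapse = "\t"))
  )
  writeLines(lines, counts_path)
  meta <- tbl[!duplicated(tbl$species_id),
              c("species_id", "taxon_group", "hematophagous")]
  meta <- meta[match(sps, as.character(meta$species_id)), ]
  writeLines(c(
    "species_id\ttaxon_group\thematophagous",
    paste(sps, meta$taxon_group, as.integer(meta$hematophagous), sep = "\t")
  ), meta_path)
  invisible(tbl)
}

#' Read a per-gene annotation table
#'
#' Columns: `gene_id`, `species_id`, `family_id`, `transcript_id` (may be
#' empty), `truncated`, `signal_peptide`, `topology`.
#'
#' @param path TSV path.
#' @return tibble of gene records.
#' @export
read_gene_table <- function(path) {
  rec <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = "c"))
  need <- c("gene_id", "species_id", "family_id", "transcript_id",
            "truncated", "signal_peptide", "topology")
  missing <- setdiff(need, names(rec))
  if (length(missing) > 0) {
    abort(paste0("gene table missing column(s): ", paste(missing, collapse = ", ")))
  }
  rec$transcript_id[is.na(rec$transcript_id)] <- ""
  rec$truncated <- as.logical(as.integer(rec$truncated))
  rec$signal_peptide <- as.logical(as.integer(rec$signal_peptide))
  validate_gene_records(rec)
}

validate_gene_records <- function(records) {
  if (anyDuplicated(records$gene_id)) {
    abort(paste0("duplicate gene_id: ",
                 records$gene_id[duplicated(records$gene_id)][1]))
  }
  bad <- !is_family_code(records$family_id)
  if (any(bad)) {
    abort(paste0("invalid family code: ", records$family_id[bad][1]))
  }
  ok_topo <- c("cytoplasmic", "non_cytoplasmic", "transmembrane", "unknown")
  if (!all(records$topology %in% ok_topo)) {
    abort(paste0("topology must be one of: ", paste(ok_topo, collapse = ", ")))
  }
  as_tibble(records)
}

#' Merge gene records that code for the same transcript
#'
#' Genome assemblies sometimes split one gene across several predicted models;
#' when transcript evidence shows that several records code for a single
#' transcript they are collapsed to one gene. Records sharing a non-empty
#' `transcript_id` (within a species) become one record whose `gene_id` is the
#' lexicographically smallest member id; `signal_peptide` is OR-combined over
#' members, `truncated` AND-combined (the merged model is truncated only if
#' every fragment is), and `topology` is kept when members agree, otherwise
#' set to `"unknown"`. Records with an empty `transcript_id` are never merged.
#' The operation is idempotent.
#'
#' @param records tibble of gene records (see [read_gene_table()]).
#' @return tibble with one row per merged gene, in order of first appearance.
#' @export
#' @examples
#' recs <- tibble::tibble(
#'   gene_id = c("G2", "G1", "G3"), species_id = "sp1", family_id = "M17",
#'   transcript_id = c("T1", "T1", ""), truncated = c(TRUE, FALSE, FALSE),
#'   signal_peptide = c(FALSE, TRUE, FALSE), topology = "unknown"
#' )
#' merge_genes_by_transcript(recs)
merge_genes_by_transcript <- function(records) {
  records <- validate_gene_records(records)
  if (nrow(records) == 0) return(records)
  has_sp <- "species_id" %in% names(records)
  key <- ifelse(nzchar(records$transcript_id),
                paste0(if (has_sp) records$species_id else "", "\r",
                       records$transcript_id),
                paste0("solo\r", records$gene_id))
  grp_fam <- split(records$family_id, key)
  inconsistent <- names(grp_fam)[map_lgl(grp_fam, ~ length(unique(.x)) > 1)]
  if (length(inconsistent) > 0) {
    abort(paste0("records sharing transcript ",
                 sub("^.*\r", "", inconsistent[1]),
                 " carry different family codes: inconsistent annotation"))
  }
  records$.key <- key
  merged <- records |>
    mutate(.ord = dplyr::row_number()) |>
    group_by(.data$.key) |>
    summarise(
      gene_id = min(.data$gene_id),
      species_id = if (has_sp) dplyr::first(.data$species_id) else NA_character_,
      family_id = dplyr::first(.data$family_id),
      transcript_id = dplyr::first(.data$transcript_id),
      truncated = all(.data$truncated),
      signal_peptide = any(.data$signal_peptide),
      topology = if (length(unique(.data$topology)) == 1)
        .data$topology[1] else "unknown",
      .ord = min(.data$.ord),
      .groups = "drop"
    ) |>
    arrange(.data$.ord) |>
    select(-".key", -".ord")
  if (!has_sp) merged$species_id <- NULL
  merged
}

#' Tabulate merged gene records into a species x family count table
#'
#' @param records tibble of (already merged) gene records with `species_id`
#'   and `family_id` columns.
#' @param species_meta tibble with `species_id`, `taxon_group`,
#'   `hematophagous`; defines the species set (species with no records get
#'   all-zero counts).
#' @param families optional character vector fixing the family set and order;
#'   defaults to the families observed in `records`. A family absent from a
#'   species is a count of 0, not missing data.
#' @return long count tibble as from [read_count_matrix()].
#' @export
tabulate_counts <- function(records, species_meta, families = NULL) {
  species_meta <- validate_species_meta(species_meta)
  if (nrow(records) > 0) {
    validate_gene_records(records)
    unknown <- setdiff(records$species_id, species_meta$species_id)
    if (length(unknown) > 0) {
      abort(paste0("gene record references unknown species: ", unknown[1]))
    }
  }
  families <- families %||% unique(records$family_id)
  tbl <- tidyr::expand_grid(family = families,
                            species_id = species_meta$species_id)
  tallied <- records |>
    count(family = .data$family_id, .data$species_id, name = "count")
  tbl <- left_join(tbl, tallied, by = c("family", "species_id")) |>
    mutate(count = as.integer(ifelse(is.na(.data$count), 0L, .data$count))) |>
    left_join(species_meta[, c("species_id", "taxon_group", "hematophagous")],
              by = "species_id")
  tbl$family <- factor(tbl$family, levels = families)
  tbl$species_id <- factor(tbl$species_id, levels = species_meta$species_id)
  validate_count_tbl(tbl)
  tbl
}
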