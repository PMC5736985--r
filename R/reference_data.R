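# Accessors for the small reference tables shipped with the package.

#' Path to a file shipped in the package's extdata
#'
#' @param file file name; with no argument, lists available files.
#' @return a path (or a vector of file names).
#' @export
pepscreen_extdata <- function(file = NULL) {
  dir <- system.file("extdata", package = "pepscreen", mustWork = TRUE)
  if (is.null(file)) return(list.files(dir))
  path <- file.path(dir, file)
  if (!file.exists(path)) abort(paste0("no such extdata file: ", file))
  path
}

#' Published criterion sets of the R. prolixus peptidase survey
#'
#' The three family sets flagged, across 19 arthropod genomes, by the
#' hematophagy Mann-Whitney test, the taxonomic Kruskal-Wallis test and the
#' percentile-90 rule. Useful as input to [venn_classify()].
#'
#' @return named list of character vectors `hema`, `taxa`, `p90`.
#' @export
reference_criterion_sets <- function() {
  raw <- jsonlite::read_json(pepscreen_extdata("rhodnius_criterion_sets.json"))
  map(raw[c("hema", "taxa", "p90")], ~ unlist(.x))
}

#' Gene counts of the sporadic (microbe-typical) peptidase families
#'
#' Counts of families M74, N6, S24 and S29 across the 19-genome panel
#' (focal species `RPRO`), with species metadata. These families are absent
#' from most arthropod genomes, so one to three focal genes already exceed
#' the family's 90th percentile.
#'
#' @return long count tibble (see [read_count_matrix()]).
#' @export
reference_sporadic_counts <- function() {
  read_count_matrix(pepscreen_extdata("rhodnius_sporadic_family_counts.tsv"),
                    pepscreen_extdata("rhodnius_species_meta.tsv"))
}
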