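# Archetype-based profiling of A1 aspartic peptidases against pepsin A,
# renin and cathepsin D: conserved features (catalytic acidic dyad, six
# disulfide cysteines, the proline loop, the glycosylation triad) and
# substrate-binding subsite residues S4..S2'.

#' Load an archetype feature/subsite map
#'
#' With no argument, loads the map shipped with the package, which
#' transcribes the pepsin/renin/cathepsin D feature positions and subsite
#' residues of the three A1 archetypes. The shipped subsite coordinates are a
#' synthetic shared layout (see the JSON's own description); supply your own
#' file in the same schema to use real alignment coordinates.
#'
#' @param path optional path to a JSON map.
#' @return list of class `pep_archetype_map` with `features` (per archetype)
#'   and `subsites` (tibble: `subsite`, `coord`, `pepsin`, `renin`,
#'   `cathepsinD`).
#' @export
read_archetype_map <- function(path = NULL) {
  path <- path %||% system.file("extdata", "archetype_map_main_text.json",
                                package = "pepscreen", mustWork = TRUE)
  raw <- jsonlite::read_json(path)
  subsites <- imap(raw$subsites, function(rows, name) {
    tibble(
      subsite = name,
      coord = map_int(rows, ~ as.integer(.x$coord)),
      pepsin = map_chr(rows, "pepsin"),
      renin = map_chr(rows, "renin"),
      cathepsinD = map_chr(rows, "cathepsinD")
    )
  }) |> bind_rows()
  expected <- c(S4 = 3L, S3 = 8L, S2 = 9L, S1 = 9L, S1p = 5L, S2p = 5L)
  got <- table(factor(subsites$subsite, levels = names(expected)))
  if (!all(as.integer(got) == expected)) {
    abort("archetype map subsites must have sizes S4=3, S3=8, S2=9, S1=9, S1'=5, S2'=5")
  }
  features <- map(raw$features, function(f) {
    list(
      catalytic_positions = as.integer(unlist(f$catalytic_positions)),
      catalytic_residues = toupper(unlist(f$catalytic_residues)),
      cysteine_positions = as.integer(unlist(f$cysteine_positions)),
      first_proline = as.integer(f$first_proline),
      proline_loop_window = as.integer(unlist(f$proline_loop_window)),
      glyc_triad_positions = as.integer(unlist(f$glyc_triad_positions)),
      glyc_triad_residues = toupper(unlist(f$glyc_triad_residues))
    )
  })
  structure(list(features = features, subsites = subsites,
                 synthetic_coordinates = isTRUE(raw$synthetic_coordinates)),
            class = "pep_archetype_map")
}

query_chars <- function(query) {
  if (!is.character(query) || length(query) != 1) {
    abort("query must be a single (aligned) sequence string")
  }
  strsplit(toupper(query), "")[[1]]
}

#' Conserved A1 features of a query aligned to an archetype
#'
#' Counts, at the archetype's mapped positions, how many catalytic acidic
#' residues (Asp/Glu accepted — the literature labels the dyad variously),
#' disulfide cysteines, loop prolines and glycosylation-triad residues the
#' query retains. `query` must be aligned to the chosen archetype's residue
#' numbering (same coordinate system; gaps as `-`).
#'
#' @param query aligned sequence string.
#' @param map a `pep_archetype_map` (default: shipped map).
#' @param archetype `"cathepsinD"`, `"pepsin"` or `"renin"`.
#' @return one-row tibble: `archetype`, `catalytic_count` (0-2),
#'   `cysteines_present` (0-6), `proline_loop_count` (0-3),
#'   `glyc_triad_matches` (0-3), and `sequon_positions` (list-column: sequon
#'   scan of the ungapped query).
#' @export
conserved_feature_report <- function(query, map = read_archetype_map(),
                                     archetype = c("cathepsinD", "pepsin",
                                                   "renin")) {
  archetype <- match.arg(archetype)
  f <- map$features[[archetype]]
  q <- query_chars(query)
  needed <- max(f$catalytic_positions, f$cysteine_positions,
                f$proline_loop_window, f$glyc_triad_positions)
  if (length(q) < needed) {
    abort(paste0("aligned query (length ", length(q),
                 ") is shorter than the largest mapped position (", needed, ")"))
  }
  tibble(
    archetype = archetype,
    catalytic_count = sum(q[f$catalytic_positions] %in% c("D", "E")),
    cysteines_present = sum(q[f$cysteine_positions] == "C"),
    proline_loop_count = sum(q[f$proline_loop_window] == "P"),
    glyc_triad_matches = sum(q[f$glyc_triad_positions] ==
                               f$glyc_triad_residues),
    sequon_positions = list(scan_sequons(paste(q, collapse = "")))
  )
}

sharing_class <- function(residue, pep, ren, cat) {
  inp <- residue == pep; inr <- residue == ren; inc <- residue == cat
  if (inp && inr && inc) "all_three"
  else if (inp && inr) "pepsin+renin"
  else if (inr && inc) "renin+cathepsinD"
  else if (inp && inc) "pepsin+cathepsinD"
  else if (inp) "pepsin_only"
  else if (inr) "renin_only"
  else if (inc) "cathepsinD_only"
  else "novel"
}

#' Subsite sharing profile of a query against the three A1 archetypes
#'
#' For every substrate-binding subsite position, labels the query residue by
#' which archetypes carry the same residue there (8-way classification
#' including `novel`), and tallies per-subsite matches to each archetype.
#'
#' @param query sequence string aligned to the map's shared subsite
#'   coordinates.
#' @param map a `pep_archetype_map`.
#' @return tibble of class `pep_subsites`: `subsite`, `coord`,
#'   `query_residue`, the three archetype residues, and `sharing_class`;
#'   per-subsite per-archetype match counts attached as attribute `matches`.
#' @export
subsite_profile <- function(query, map = read_archetype_map()) {
  q <- query_chars(query)
  ss <- map$subsites
  if (max(ss$coord) > length(q)) {
    abort(paste0("aligned query (length ", length(q),
                 ") does not cover subsite coordinate ", max(ss$coord)))
  }
  out <- ss |>
    mutate(
      query_residue = q[.data$coord],
      sharing_class = purrr::pmap_chr(
        list(.data$query_residue, .data$pepsin, .data$renin,
             .data$cathepsinD), sharing_class)
    )
  matches <- out |>
    group_by(.data$subsite) |>
    summarise(
      n_positions = dplyr::n(),
      pepsin = sum(.data$query_residue == .data$pepsin),
      renin = sum(.data$query_residue == .data$renin),
      cathepsinD = sum(.data$query_residue == .data$cathepsinD),
      .groups = "drop"
    )
  structure(out, matches = matches,
            class = c("pep_subsites", class(out)))
}

#' Globally align a query to an archetype sequence
#'
#' Convenience stand-in for a curated alignment: Needleman-Wunsch global
#' alignment (BLOSUM62, affine gaps: open 10, extend 0.5) of the query
#' against an archetype sequence, returned in the archetype's coordinate
#' system (query characters at archetype positions; deletions as `-`,
#' query insertions dropped). Prefer a curated profile alignment for real
#' analyses.
#'
#' @param query,archetype_seq plain protein strings.
#' @return aligned query string, `nchar()` equal to the archetype length.
#' @export
align_to_archetype <- function(query, archetype_seq) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(gsub("-", "", toupper(query))),
    Biostrings::AAString(toupper(archetype_seq)),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5
  )
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  paste(pat[sub != "-"], collapse = "")
}

#' @method glance pep_subsites
#' @export
glance.pep_subsites <- function(x, ...) {
  m <- attr(x, "matches")
  tibble(
    n_positions = nrow(x),
    pepsin_matches = sum(m$pepsin),
    renin_matches = sum(m$renin),
    cathepsinD_matches = sum(m$cathepsinD),
    n_novel = sum(x$sharing_class == "novel")
  )
}
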