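# Genomic-neighborhood screen for horizontally transferred vs contaminant
# protease genes. A candidate gene from a microbe-typical family is judged by
# the taxonomic affinity of the other genes on its contig and by its own
# intron count: metazoan neighbors argue for a genuine genomic insertion,
# an all-microbial neighborhood with no introns argues for contamination,
# and introns inside an "all-microbial" neighborhood are flagged as
# conflicting evidence.

validate_contig_genes <- function(genes) {
  need <- c("gene_id", "contig_id", "order_index", "best_hit_taxon",
            "intron_count", "is_candidate")
  missing <- setdiff(need, names(genes))
  if (length(missing) > 0) {
    abort(paste0("contig gene table missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(genes$gene_id)) {
    abort(paste0("duplicate gene_id on contig table: ",
                 genes$gene_id[duplicated(genes$gene_id)][1]))
  }
  key <- paste(genes$contig_id, genes$order_index)
  if (anyDuplicated(key)) {
    abort(paste0("duplicate (contig_id, order_index): ",
                 key[duplicated(key)][1]))
  }
  if (any(genes$intron_count < 0)) abort("intron_count must be >= 0")
  ok <- c("metazoa", "bacteria", "virus", "none")
  if (!all(genes$best_hit_taxon %in% ok)) {
    abort(paste0("best_hit_taxon must be one of: ", paste(ok, collapse = ", ")))
  }
  as_tibble(genes)
}

#' Read a contig gene table
#'
#' TSV columns: `gene_id`, `contig_id`, `order_index`, `best_hit_taxon`
#' (`metazoa`/`bacteria`/`virus`/`none`), `intron_count`, `is_candidate`
#' (1/0), optional `family_id`.
#'
#' @param path TSV path.
#' @return validated tibble.
#' @export
read_contig_table <- function(path) {
  genes <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  genes$is_candidate <- as.logical(as.integer(genes$is_candidate))
  genes$order_index <- as.integer(genes$order_index)
  genes$intron_count <- as.integer(genes$intron_count)
  validate_contig_genes(genes)
}

#' Neighbors of a gene on its contig
#'
#' @param gene_id id of the gene of interest (must be present).
#' @param genes validated contig gene table.
#' @param window maximum distance in gene positions; `Inf` (default) returns
#'   the whole contig.
#' @return tibble of neighbor rows, ordered by position, candidate excluded.
#' @export
neighbors_of <- function(gene_id, genes, window = Inf) {
  genes <- validate_contig_genes(genes)
  row <- genes[genes$gene_id == gene_id, ]
  if (nrow(row) == 0) abort(paste0("gene not in table: ", gene_id))
  genes |>
    filter(.data$contig_id == row$contig_id,
           .data$gene_id != row$gene_id,
           abs(.data$order_index - row$order_index) <= window) |>
    arrange(.data$order_index)
}

#' Classify one HGT candidate from its neighborhood
#'
#' Rule cascade (neighbors with `best_hit_taxon = "none"` are uninformative
#' and ignored):
#' * no (informative) neighbors — `inconclusive`;
#' * any metazoan neighbor — `genuine_insertion` (metazoan context outranks
#'   microbial hits; mixed neighborhoods are flagged in the evidence trail);
#' * all neighbors microbial (`bacteria`/`virus`) and the candidate has no
#'   introns — `contamination_suspect`;
#' * all neighbors microbial but the candidate has introns — `inconclusive`
#'   with `conflicting_evidence = TRUE` (introns are a eukaryotic gene
#'   feature, incoherent with a purely bacterial fragment).
#'
#' @param gene one-row tibble (the candidate).
#' @param neighbors tibble of its neighbors (as from [neighbors_of()]).
#' @return one-row tibble: `verdict`, `conflicting_evidence`, `evidence`
#'   (list-column of tagged statements).
#' @export
classify_hgt_candidate <- function(gene, neighbors) {
  informative <- neighbors[neighbors$best_hit_taxon != "none", ]
  ev <- character(0)
  n_ignored <- nrow(neighbors) - nrow(informative)
  if (n_ignored > 0) {
    ev <- c(ev, paste0("ignored ", n_ignored, " neighbor(s) with no best hit"))
  }
  if (nrow(informative) == 0) {
    ev <- c(ev, if (nrow(neighbors) == 0) "no neighbors on contig"
            else "no informative neighbors on contig")
    return(tibble(verdict = "inconclusive", conflicting_evidence = FALSE,
                  evidence = list(ev)))
  }
  taxa <- informative$best_hit_taxon
  ev <- c(ev, paste0("neighbor ", informative$gene_id, ": best hit ", taxa))
  ev <- c(ev, paste0("candidate intron count: ", gene$intron_count))
  if (any(taxa == "metazoa")) {
    if (any(taxa %in% c("bacteria", "virus"))) {
      ev <- c(ev, "mixed neighborhood: metazoan context given precedence")
    }
    return(tibble(verdict = "genuine_insertion",
                  conflicting_evidence = FALSE, evidence = list(ev)))
  }
  # all informative neighbors are microbial
  if (gene$intron_count == 0) {
    tibble(verdict = "contamination_suspect", conflicting_evidence = FALSE,
           evidence = list(ev))
  } else {
    ev <- c(ev, "introns conflict with the all-microbial neighborhood")
    tibble(verdict = "inconclusive", conflicting_evidence = TRUE,
           evidence = list(ev))
  }
}

#' Screen every candidate gene in a contig table
#'
#' @param genes contig gene table (see [read_contig_table()]).
#' @param window neighborhood size passed to [neighbors_of()].
#' @return tibble of class `pep_hgt`: one row per candidate with `gene_id`,
#'   `family_id` (if present), `verdict`, `conflicting_evidence`, `evidence`.
#'   Per-verdict counts are attached as attribute `summary`.
#' @export
screen_contigs <- function(genes, window = Inf) {
  genes <- validate_contig_genes(genes)
  cands <- genes[genes$is_candidate, ]
  rows <- map(seq_len(nrow(cands)), function(i) {
    g <- cands[i, ]
    v <- classify_hgt_candidate(g, neighbors_of(g$gene_id, genes, window))
    v$gene_id <- g$gene_id
    if ("family_id" %in% names(g)) v$family_id <- g$family_id
    v
  })
  out <- if (length(rows) == 0) {
    tibble(gene_id = character(0), verdict = character(0),
           conflicting_evidence = logical(0), evidence = list())
  } else {
    bind_rows(rows) |> select(any_of(c("gene_id", "family_id")),
                              everything())
  }
  counts <- table(factor(out$verdict,
                         levels = c("genuine_insertion",
                                    "contamination_suspect",
                                    "inconclusive")))
  structure(out, summary = as.list(counts),
            class = c("pep_hgt", class(out)))
}

#' @method glance pep_hgt
#' @export
glance.pep_hgt <- function(x, ...) {
  s <- attr(x, "summary")
  tibble(n_candidates = nrow(x),
         genuine_insertion = s$genuine_insertion,
         contamination_suspect = s$contamination_suspect,
         inconclusive = s$inconclusive)
}
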