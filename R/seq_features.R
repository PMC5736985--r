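# Alignment-column Shannon entropy, highly-variable position counting, and
# N-glycosylation sequon scanning.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Coerce to a validated alignment
#'
#' Accepts a named character vector of equal-length aligned sequences, a
#' `Biostrings::AAStringSet` / `AAMultipleAlignment`, or a plain character
#' vector. Rows must all have the same length; the alphabet is the 20 amino
#' acids plus `-` (gap) and `X` (unknown).
#'
#' @param x sequences in any of the accepted forms.
#' @return named character vector, upper-cased.
#' @export
as_alignment <- function(x) {
  if (inherits(x, "AAMultipleAlignment")) {
    x <- as.character(Biostrings::unmasked(x))
  } else if (inherits(x, "XStringSet")) {
    x <- as.character(x)
  }
  if (!is.character(x) || length(x) == 0) {
    abort("alignment must have at least one sequence")
  }
  x <- toupper(x)
  if (length(unique(nchar(x))) != 1) {
    abort("aligned sequences must all have the same length")
  }
  if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
  if (anyDuplicated(names(x))) abort("duplicate sequence ids in alignment")
  bad <- grepl(paste0("[^", paste(AA20, collapse = ""), "X.-]"), x)
  if (any(bad)) {
    abort(paste0("sequence ", names(x)[bad][1],
                 " contains characters outside the amino-acid alphabet"))
  }
  gsub(".", "-", x, fixed = TRUE)
}

#' Read a protein multiple alignment
#'
#' @param path file path.
#' @param format `"fasta"` (aligned FASTA, default) or `"clustal"`.
#' @return named character vector of aligned sequences.
#' @export
read_alignment <- function(path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  x <- if (format == "fasta") {
    Biostrings::readAAStringSet(path)
  } else {
    Biostrings::readAAMultipleAlignment(path, format = "clustal")
  }
  as_alignment(x)
}

#' Shannon entropy of one alignment column
#'
#' `H = -sum(p_i * log2(p_i))` over the residues observed in the column.
#' With `gap_mode = "exclude"` (default) gaps are dropped before computing
#' the frequencies; with `gap_mode = "symbol"` the gap counts as a 21st
#' symbol. A column of only gaps has `H = 0` and raises a warning.
#'
#' @param column character vector of single residues (one alignment column).
#' @param gap_mode `"exclude"` or `"symbol"`.
#' @return entropy in bits, in `[0, log2(20)]` (`log2(21)` in symbol mode).
#' @export
#' @examples
#' column_entropy(c("A", "A", "C"))   # about 0.918 bits
column_entropy <- function(column, gap_mode = c("exclude", "symbol")) {
  gap_mode <- match.arg(gap_mode)
  if (length(column) == 0) abort("column must be non-empty")
  column <- toupper(as.character(column))
  if (gap_mode == "exclude") column <- column[column != "-"]
  if (length(column) == 0) {
    warn("all-gap column: entropy defined as 0")
    return(0)
  }
  p <- table(column) / length(column)
  -sum(p * log2(p))
}

#' Per-position entropies and the count of highly variable positions
#'
#' Computes [column_entropy()] at every alignment position and counts those
#' strictly above `threshold` (the conventional "Shannon index above 2" cut
#' for highly variable positions).
#'
#' @param aln alignment (see [as_alignment()]).
#' @param threshold entropy cut in bits, default 2.
#' @param gap_mode passed to [column_entropy()].
#' @return object of class `pep_varscan`: list with `count`, `threshold`, and
#'   `entropies`, a tibble of `position`, `entropy`, `n_gap`, `all_gap`.
#' @export
count_highly_variable <- function(aln, threshold = 2,
                                  gap_mode = c("exclude", "symbol")) {
  gap_mode <- match.arg(gap_mode)
  aln <- as_alignment(aln)
  mat <- do.call(rbind, strsplit(aln, ""))
  ent <- numeric(ncol(mat)); gaps <- integer(ncol(mat))
  for (j in seq_len(ncol(mat))) {
    gaps[j] <- sum(mat[, j] == "-")
    ent[j] <- suppressWarnings(column_entropy(mat[, j], gap_mode))
  }
  entropies <- tibble(position = seq_len(ncol(mat)), entropy = ent,
                      n_gap = gaps, all_gap = gaps == nrow(mat))
  structure(
    list(count = sum(ent > threshold), threshold = threshold,
         entropies = entropies),
    class = "pep_varscan"
  )
}

#' @export
print.pep_varscan <- function(x, ...) {
  cat("Alignment variability scan: ", nrow(x$entropies), " positions, ",
      x$count, " with entropy > ", x$threshold, " bits\n", sep = "")
  invisible(x)
}

#' @method tidy pep_varscan
#' @export
tidy.pep_varscan <- function(x, ...) x$entropies

#' @method glance pep_varscan
#' @export
glance.pep_varscan <- function(x, ...) {
  tibble(n_positions = nrow(x$entropies), n_highly_variable = x$count,
         threshold = x$threshold,
         mean_entropy = mean(x$entropies$entropy))
}

#' Scan an ungapped protein sequence for N-glycosylation sequons
#'
#' Reports every 1-based position `i` with `seq[i] == "N"`,
#' `seq[i+1] != "P"` and `seq[i+2]` in `{S, T}` — the canonical N-X-S/T
#' sequon with the proline exclusion. Overlapping sequons are all reported.
#'
#' @param seq a single protein string (gaps are removed first).
#' @return increasing integer vector of sequon positions.
#' @export
#' @examples
#' scan_sequons("NAS")   # 1
#' scan_sequons("NPS")   # integer(0)
#' scan_sequons("NNSS")  # 1 and 2
scan_sequons <- function(seq) {
  if (!is.character(seq) || length(seq) != 1) {
    abort("scan_sequons expects a single string")
  }
  s <- strsplit(gsub("-", "", toupper(seq)), "")[[1]]
  n <- length(s)
  if (n < 3) return(integer(0))
  i <- seq_len(n - 2)
  which(s[i] == "N" & s[i + 1] != "P" & (s[i + 2] == "S" | s[i + 2] == "T"))
}
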