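# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an expansion screen: focal counts against percentile thresholds
#'
#' One point per family (focal count vs the family's percentile-90
#' threshold); families above the identity line are percentile-flagged, and
#' color encodes how many criteria flagged each family.
#'
#' @param object a `pep_screen` from [run_screen()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot pep_screen
#' @export
autoplot.pep_screen <- function(object, ...) {
  d <- tidy(object)
  ggplot(d, aes(x = .data$p90_threshold, y = .data$focal_count,
                color = factor(.data$criterion_count))) +
    geom_abline(slope = 1, intercept = 0, linetype = 2, color = "grey50") +
    geom_point(size = 2, alpha = 0.8) +
    labs(x = "family percentile-90 threshold (genes)",
         y = "focal species gene count",
         color = "criteria met",
         title = paste0("Expansion screen, focal = ", attr(object, "focal"))) +
    theme_minimal()
}

#' Plot per-position alignment entropy
#'
#' @param object a `pep_varscan` from [count_highly_variable()].
#' @param ... unused.
#' @return a ggplot with the variability threshold drawn as a dashed line.
#' @method autoplot pep_varscan
#' @export
autoplot.pep_varscan <- function(object, ...) {
  ggplot(object$entropies, aes(x = .data$position, y = .data$entropy)) +
    geom_line(color = "grey40") +
    geom_point(aes(color = .data$entropy > object$threshold), size = 1.2) +
    geom_hline(yintercept = object$threshold, linetype = 2) +
    scale_color_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
                       labels = c("conserved", "highly variable"),
                       name = NULL) +
    labs(x = "alignment position", y = "Shannon entropy (bits)") +
    theme_minimal()
}

#' Plot per-residue relative exposure of a structure
#'
#' @param object a `pep_sasa` from [shrake_rupley_sasa()].
#' @param rel_threshold exposure cut to mark (default 0.25).
#' @param ... unused.
#' @return a ggplot; basic residues (Lys/Arg) are highlighted.
#' @method autoplot pep_sasa
#' @export
autoplot.pep_sasa <- function(object, rel_threshold = 0.25, ...) {
  if (is.null(object$residues)) abort("no per-residue summary to plot")
  d <- object$residues |>
    mutate(basic = .data$residue_name %in% c("LYS", "ARG"))
  ggplot(d, aes(x = .data$residue_number, y = .data$rel_exposure,
                fill = .data$basic)) +
    geom_col() +
    geom_hline(yintercept = rel_threshold, linetype = 2) +
    scale_fill_manual(values = c(`FALSE` = "grey70", `TRUE` = "goldenrod"),
                      labels = c("other", "Lys/Arg"), name = NULL) +
    labs(x = "residue number", y = "relative exposure") +
    theme_minimal()
}

#' Box plots of family gene counts by feeding habit
#'
#' The classic screen view: per-family count distributions split into
#' hematophagous vs non-hematophagous species.
#'
#' @param tbl long count table.
#' @param families families to show (default: all).
#' @return a ggplot.
#' @export
plot_family_counts <- function(tbl, families = NULL) {
  if (!is.null(families)) {
    tbl <- tbl[as.character(tbl$family) %in% families, ]
  }
  ggplot(tbl, aes(x = .data$hematophagous, y = .data$count,
                  fill = .data$hematophagous)) +
    geom_boxplot(outlier.shape = 1, show.legend = FALSE) +
    facet_wrap(~family, scales = "free_y") +
    scale_x_discrete(labels = c(`FALSE` = "other", `TRUE` = "blood feeders")) +
    labs(x = NULL, y = "gene count") +
    theme_minimal()
}
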