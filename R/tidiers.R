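#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' Tidy the per-gene decisions of an HGT pipeline run
#'
#' @param x An `hgt_result` ([run_hgt_pipeline()]).
#' @param ... Unused.
#' @return The per-gene decision tibble.
#' @export
tidy.hgt_result <- function(x, ...) x$decisions

#' One-row stage-count summary of an HGT pipeline run
#'
#' @inheritParams tidy.hgt_result
#' @return The one-row report tibble.
#' @export
glance.hgt_result <- function(x, ...) x$report

#' Plot an HGT pipeline result
#'
#' `type = "stages"` shows the per-stage gene counts; `type = "origin"` the
#' donor-group percentages of the confirmed set.
#'
#' @param object An `hgt_result`.
#' @param type `"stages"` or `"origin"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hgt_result <- function(object, type = c("stages", "origin"), ...) {
  type <- match.arg(type)
  if (type == "stages") {
    counts <- object$decisions |>
      dplyr::count(.data$stage) |>
      filter(.data$stage != "not_candidate")
    ggplot2::ggplot(counts, ggplot2::aes(
      x = stats::reorder(.data$stage, -.data$n), y = .data$n)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.4) +
      ggplot2::labs(x = NULL, y = "genes", title = "HGT pipeline stages") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$origin, ggplot2::aes(
      x = stats::reorder(.data$taxon_group, -.data$percent),
      y = .data$percent)) +
      ggplot2::geom_col(fill = "darkorange") +
      ggplot2::labs(x = NULL, y = "% of confirmed HGT genes",
                    title = "Origin of confirmed HGT genes") +
      ggplot2::theme_minimal()
  }
}

#' Plot gene-family z-scores of the focal species
#'
#' Focal-species gene count against z, with the +/-2 expansion/contraction
#' thresholds.
#'
#' @param object A `family_zscores` tibble ([family_zscores()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.family_zscores <- function(object, ...) {
  focal <- attr(object, "focal_species")
  df <- as_tibble(object) |>
    filter(.data$species_id == focal, !is.na(.data$z))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$count, y = .data$z,
                                   colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = c(-2, 2), linetype = "dashed") +
    ggplot2::labs(x = paste0(focal, " gene count"), y = "z-score",
                  colour = NULL,
                  title = "Gene-family expansion/contraction z-scores") +
    ggplot2::theme_minimal()
}

#' Cumulative scaffold-length (Nx) curve
#'
#' Cumulative assembly fraction against scaffold rank in descending length
#' order; the N50 scaffold is where the curve crosses 50%.
#'
#' @param scaffolds Scaffold tibble ([read_fasta()]).
#' @return A ggplot.
#' @export
plot_scaffold_lengths <- function(scaffolds) {
  lens <- sort(scaffolds$length, decreasing = TRUE)
  df <- tibble(rank = seq_along(lens), length = lens,
               cum_frac = cumsum(as.numeric(lens)) / sum(as.numeric(lens)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = 100 * .data$cum_frac)) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(yintercept = 50, linetype = "dashed") +
    ggplot2::labs(x = "scaffold rank (longest first)",
                  y = "cumulative assembly (%)",
                  title = "Scaffold length distribution") +
    ggplot2::theme_minimal()
}
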