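# ggplot2 displays for the result objects.

#' Plot a cohort summary
#'
#' Bar chart of individuals with findings per disease category, split by
#' reporting bucket (dominant/X-linked reportable vs recessive carrier),
#' mirroring the usual secondary-findings summary figure.
#'
#' @param object An `sf_cohort_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sf_cohort_summary
#' @export
autoplot.sf_cohort_summary <- function(object, ...) {
  tbl <- object$findings |>
    mutate(bucket = ifelse(.data$status %in% c("recessive_carrier", "xl_carrier"),
                           "carrier", "reportable")) |>
    distinct(.data$sample_id, .data$category, .data$bucket) |>
    count(.data$category, .data$bucket, name = "n_individuals")
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$category, y = .data$n_individuals,
                                    fill = .data$bucket)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "disease category", y = "individuals",
                  fill = NULL,
                  title = "Secondary findings by disease category") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.sf_cohort_summary
#' @method autoplot sf_run
#' @export
autoplot.sf_run <- function(object, ...) {
  autoplot(object$summary, ...)
}

#' Plot cascade stage survivor counts
#'
#' Step plot of variants and carrier genotypes surviving each cascade
#' stage; both tallies are non-increasing by construction.
#'
#' @param findings An `sf_findings` object (or an `sf_run`).
#' @return A ggplot object.
#' @export
plot_stage_counts <- function(findings) {
  sc <- if (inherits(findings, "sf_run")) findings$stage_counts else stage_counts(findings)
  long <- tidyr::pivot_longer(sc, c("n_variants", "n_genotypes"),
                              names_to = "tally", values_to = "n")
  long$stage <- factor(long$stage, levels = sc$stage)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$stage, y = .data$n,
                                     group = .data$tally,
                                     colour = .data$tally)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "cascade stage", y = "survivors", colour = NULL,
                  title = "Filter cascade survivor counts") +
    ggplot2::theme_minimal()
}
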