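# broom-style tidiers for the package's result objects.

#' Tidy a cohort summary into per-gene rows
#'
#' @param x An `sf_cohort_summary`.
#' @param ... Unused.
#' @return Tibble with one row per mutated gene (`gene`, `inheritance`,
#'   `category`, `disease`, `n_individuals`).
#' @method tidy sf_cohort_summary
#' @export
tidy.sf_cohort_summary <- function(x, ...) {
  x$per_gene
}

#' One-row headline summary of a cohort
#'
#' @param x An `sf_cohort_summary`.
#' @param ... Unused.
#' @return One-row tibble of the headline counts and proportions.
#' @method glance sf_cohort_summary
#' @export
glance.sf_cohort_summary <- function(x, ...) {
  x$headline
}

#' @rdname tidy.sf_cohort_summary
#' @method tidy sf_run
#' @export
tidy.sf_run <- function(x, ...) {
  tidy(x$summary)
}

#' @rdname glance.sf_cohort_summary
#' @method glance sf_run
#' @export
glance.sf_run <- function(x, ...) {
  glance(x$summary)
}

#' Tidy a concordance report
#'
#' @param x An `sf_concordance` from [verify_table()].
#' @param ... Unused.
#' @return The per-row tibble (gene, evidence, recorded assertion, engine
#'   verdict, concordance flag).
#' @method tidy sf_concordance
#' @export
tidy.sf_concordance <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "sf_concordance")
  attr(out, "n_concordant") <- NULL
  attr(out, "n_discordant") <- NULL
  out
}

#' @rdname tidy.sf_concordance
#' @method glance sf_concordance
#' @export
glance.sf_concordance <- function(x, ...) {
  tibble(n_rows = nrow(x),
         n_concordant = attr(x, "n_concordant"),
         n_discordant = attr(x, "n_discordant"))
}
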