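# Internal helpers shared across modules.

abort_format <- function(msg, ...) {
  abort(msg, class = "secfindr_format_error", ...)
}

abort_validation <- function(msg, ...) {
  abort(msg, class = "secfindr_validation_error", ...)
}

#' Path to a file shipped with secfindr
#'
#' Convenience wrapper around [system.file()] for the packaged resources
#' (the 59-gene actionable panel and the reference spike table).
#'
#' @param file File name under `inst/extdata`.
#' @return Absolute path to the packaged file.
#' @examples
#' secfindr_extdata("acmg_sf_panel.tsv")
#' @export
secfindr_extdata <- function(file) {
  path <- system.file("extdata", file, package = "secfindr")
  if (!nzchar(path)) {
    abort_validation(sprintf("no packaged file '%s'", file))
  }
  path
}

# Display rounding for cohort percentages: 2 significant figures,
# trailing zeros trimmed ("2.5", "25", "1.1").
format_pct <- function(x) {
  out <- as.character(signif(x, 2))
  out[is.na(x)] <- NA_character_
  out
}

# Deterministic seed scoping without touching the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
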