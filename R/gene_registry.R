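# The actionable-gene registry: the 59-gene ACMG secondary-findings panel
# with per-gene inheritance mode, disease label and disease category.

INHERITANCE_MODES <- c("AD", "AR", "XLD", "XLR")
GENE_CATEGORIES <- c("cardiogenetic", "oncogenetic", "connective_tissue", "other")
ONSET_LEVELS <- c("child", "adult", "child_or_adult", "unknown")

#' Load an actionable-gene panel from a TSV file
#'
#' Reads a tab-separated gene panel (one row per gene) into a registry
#' tibble. The packaged default panel holds the 59 medically actionable
#' genes with their inheritance mode (AD/AR/XLD/XLR), RefSeq transcript,
#' disease label and disease category (cardiogenetic, oncogenetic,
#' connective_tissue, other). Extra columns are preserved untouched.
#'
#' @param path Path to a TSV with header columns at least `symbol`,
#'   `transcript`, `inheritance`, `category`. Defaults to the packaged
#'   59-gene panel.
#' @param build_tag Reference-genome label attached to the registry.
#' @return A tibble of class `gene_registry` with one row per gene and a
#'   `build_tag` attribute.
#' @examples
#' panel <- load_gene_table()
#' nrow(panel) # 59
#' @export
load_gene_table <- function(path = secfindr_extdata("acmg_sf_panel.tsv"),
                            build_tag = "hg19") {
  if (!file.exists(path)) {
    abort_validation(sprintf("gene panel file does not exist: %s", path))
  }
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- c("symbol", "transcript", "inheritance", "category")
  missing <- setdiff(required, names(tbl))
  if (length(missing)) {
    abort_format(sprintf("gene panel is missing required column(s): %s",
                         paste(missing, collapse = ", ")))
  }
  new_gene_registry(tbl, build_tag = build_tag)
}

new_gene_registry <- function(tbl, build_tag = "hg19") {
  tbl <- as_tibble(tbl)
  dup <- tbl$symbol[duplicated(tbl$symbol)]
  if (length(dup)) {
    abort_validation(sprintf("duplicate gene symbol(s) in panel: %s",
                             paste(unique(dup), collapse = ", ")))
  }
  bad_inh <- setdiff(unique(tbl$inheritance), INHERITANCE_MODES)
  if (length(bad_inh)) {
    abort_validation(sprintf("unrecognized inheritance token(s): %s",
                             paste(bad_inh, collapse = ", ")))
  }
  bad_cat <- setdiff(unique(tbl$category), GENE_CATEGORIES)
  if (length(bad_cat)) {
    abort_validation(sprintf("unrecognized category token(s): %s",
                             paste(bad_cat, collapse = ", ")))
  }
  if ("onset" %in% names(tbl)) {
    tbl$onset[is.na(tbl$onset) | tbl$onset == ""] <- "unknown"
    bad_on <- setdiff(unique(tbl$onset), ONSET_LEVELS)
    if (length(bad_on)) {
      abort_validation(sprintf("unrecognized onset token(s): %s",
                               paste(bad_on, collapse = ", ")))
    }
  }
  structure(tbl, build_tag = build_tag,
            class = c("gene_registry", class(tbl)))
}

#' Look up a gene in a registry
#'
#' Case-sensitive lookup on the canonical symbol. Absence is a value, not an
#' error: an unknown symbol returns a zero-row tibble.
#'
#' @param registry A `gene_registry` from [load_gene_table()].
#' @param symbol Gene symbol.
#' @return One-row tibble (or zero rows when absent).
#' @examples
#' lookup_gene(load_gene_table(), "LMNA")
#' @export
lookup_gene <- function(registry, symbol) {
  stopifnot(inherits(registry, "gene_registry"))
  registry_tbl(registry)[registry$symbol == symbol, , drop = FALSE]
}

# plain-tibble view (drops the subclass so dplyr verbs behave normally)
registry_tbl <- function(registry) {
  out <- registry
  class(out) <- setdiff(class(out), "gene_registry")
  attr(out, "build_tag") <- NULL
  out
}

#' Genes of a registry with a given inheritance mode
#'
#' @inheritParams lookup_gene
#' @param mode One of `"AD"`, `"AR"`, `"XLD"`, `"XLR"`.
#' @return Tibble of the matching gene records.
#' @examples
#' genes_by_inheritance(load_gene_table(), "AR")$symbol # MUTYH, ATP7B
#' @export
genes_by_inheritance <- function(registry, mode) {
  stopifnot(inherits(registry, "gene_registry"))
  if (!is.character(mode) || length(mode) != 1L || !mode %in% INHERITANCE_MODES) {
    abort_validation(sprintf("inheritance mode must be one of %s",
                             paste(INHERITANCE_MODES, collapse = "/")))
  }
  registry_tbl(registry)[registry$inheritance == mode, , drop = FALSE]
}

#' Write a gene registry back to the panel TSV format
#'
#' Round-trips with [load_gene_table()].
#'
#' @inheritParams lookup_gene
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(registry, path) {
  stopifnot(inherits(registry, "gene_registry"))
  readr::write_tsv(registry_tbl(registry), path, na = "", progress = FALSE)
  invisible(path)
}

#' @export
print.gene_registry <- function(x, ...) {
  cat(sprintf("<gene_registry> %d genes (%s)\n", nrow(x), attr(x, "build_tag")))
  modes <- table(factor(x$inheritance, INHERITANCE_MODES))
  cat("  inheritance:", paste(names(modes), modes, sep = "=", collapse = " "), "\n")
  NextMethod()
}
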