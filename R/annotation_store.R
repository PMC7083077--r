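# Variant-keyed assertion (ClinVar-style) and allele-frequency stores,
# consumed as versioned flat tables rather than live database queries.

ASSERTION_TOKENS <- c("pathogenic", "likely_pathogenic", "vus",
                      "likely_benign", "benign", "conflicting", "absent")

CONSEQUENCE_TOKENS <- c("stop_gained", "stop_lost", "start_lost", "frameshift",
                        "canonical_splice", "near_splice_within_10bp",
                        "inframe_indel", "missense", "synonymous",
                        "intronic_other", "utr", "intergenic", "other_noncoding")

# Consequence classes retained by the protein-altering filter: truncating
# (stop gain/loss, start loss, frameshift), canonical splice sites, variants
# within 10 bases of an exon boundary, inframe indels, and missense.
PROTEIN_ALTERING <- c("stop_gained", "stop_lost", "start_lost", "frameshift",
                      "canonical_splice", "near_splice_within_10bp",
                      "inframe_indel", "missense")

#' Load a variant assertion table
#'
#' Reads a TSV of clinical-significance assertions keyed by normalized
#' variant (chrom, pos, ref, alt), with the annotated gene symbol,
#' consequence class, ACMG-AMP evidence codes and HGVS display strings.
#' This flat table stands in for a frozen ClinVar extract.
#'
#' @param path TSV with header columns `chrom`, `pos`, `ref`, `alt`, `gene`,
#'   `consequence`, `assertion`, `evidence_codes` (comma-joined), `hgvs_c`,
#'   `hgvs_p`.
#' @return A tibble of class `assertion_store`, one row per variant key.
#' @export
load_assertion_table <- function(path) {
  if (!file.exists(path)) {
    abort_validation(sprintf("assertion table does not exist: %s", path))
  }
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- c("chrom", "pos", "ref", "alt", "gene", "consequence", "assertion")
  missing <- setdiff(required, names(tbl))
  if (length(missing)) {
    abort_format(sprintf("assertion table missing column(s): %s",
                         paste(missing, collapse = ", ")))
  }
  pos_num <- suppressWarnings(as.integer(tbl$pos))
  if (nrow(tbl) && any(is.na(pos_num))) {
    abort_format(sprintf("malformed position at line %d of %s",
                         which(is.na(pos_num))[1] + 1L, basename(path)))
  }
  keys <- if (nrow(tbl)) {
    variant_key(tbl$chrom, pos_num, tbl$ref, tbl$alt)
  } else {
    tibble(chrom = character(), pos = integer(), ref = character(), alt = character())
  }
  bad_assert <- setdiff(unique(tbl$assertion), ASSERTION_TOKENS)
  if (length(bad_assert)) {
    abort_validation(sprintf("unrecognized assertion token(s): %s",
                             paste(bad_assert, collapse = ", ")))
  }
  bad_csq <- setdiff(unique(tbl$consequence), CONSEQUENCE_TOKENS)
  if (length(bad_csq)) {
    abort_validation(sprintf("unrecognized consequence token(s): %s",
                             paste(bad_csq, collapse = ", ")))
  }
  out <- bind_cols(keys, tbl[setdiff(names(tbl), c("chrom", "pos", "ref", "alt"))])
  if (!"evidence_codes" %in% names(out)) out$evidence_codes <- NA_character_
  if (!"hgvs_c" %in% names(out)) out$hgvs_c <- NA_character_
  if (!"hgvs_p" %in% names(out)) out$hgvs_p <- NA_character_
  ids <- key_id(out)
  if (anyDuplicated(ids)) {
    abort_validation(sprintf("duplicate variant key in assertion table: %s",
                             ids[duplicated(ids)][1]))
  }
  # evidence strings are validated eagerly so bad codes fail at load time
  purrr::walk(out$evidence_codes, parse_evidence)
  structure(out, class = c("assertion_store", class(out)))
}

#' Load a variant allele-frequency table
#'
#' Reads a TSV keyed by normalized variant with one column per frequency
#' source (for example `dbsnp`, `gnomad`, `inhouse`). Source labels are
#' open-ended: whatever columns follow the key are treated as sources, and
#' the frequency filter applies its threshold to every source present.
#'
#' @param path TSV with header columns `chrom`, `pos`, `ref`, `alt`, then one
#'   numeric column per source; blank cells mean "no record in this source".
#' @return A tibble of class `frequency_store` with a `sources` attribute.
#' @export
load_frequency_table <- function(path) {
  if (!file.exists(path)) {
    abort_validation(sprintf("frequency table does not exist: %s", path))
  }
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), pos = readr::col_integer(),
    ref = readr::col_character(), alt = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  required <- c("chrom", "pos", "ref", "alt")
  missing <- setdiff(required, names(tbl))
  if (length(missing)) {
    abort_format(sprintf("frequency table missing column(s): %s",
                         paste(missing, collapse = ", ")))
  }
  sources <- setdiff(names(tbl), required)
  for (s in sources) {
    bad <- !is.na(tbl[[s]]) & (tbl[[s]] < 0 | tbl[[s]] > 1)
    if (any(bad)) {
      abort_validation(sprintf("frequency outside [0,1] in source '%s' at row %d",
                               s, which(bad)[1]))
    }
  }
  keys <- if (nrow(tbl)) {
    variant_key(tbl$chrom, tbl$pos, tbl$ref, tbl$alt)
  } else {
    tibble(chrom = character(), pos = integer(), ref = character(), alt = character())
  }
  out <- bind_cols(keys, tbl[sources])
  ids <- key_id(out)
  if (anyDuplicated(ids)) {
    abort_validation(sprintf("duplicate variant key in frequency table: %s",
                             ids[duplicated(ids)][1]))
  }
  structure(out, sources = sources, class = c("frequency_store", class(out)))
}

#' Annotate variant keys against the loaded stores
#'
#' Pure left-join lookup: each input key receives its gene symbol,
#' consequence, assertion and evidence codes from the assertion store and
#' its per-source allele frequencies from the frequency store. Keys absent
#' from the assertion store get `assertion = "absent"`; keys absent from
#' the frequency store get `NA` in every source column (no record anywhere,
#' which the frequency filter treats as rare).
#'
#' @param keys Tibble with columns `chrom`, `pos`, `ref`, `alt` (extra
#'   columns are carried through).
#' @param assertions An `assertion_store` from [load_assertion_table()].
#' @param frequencies A `frequency_store` from [load_frequency_table()], or
#'   `NULL` for no frequency data.
#' @return `keys` with added columns `gene`, `consequence`, `assertion`,
#'   `evidence_codes`, `hgvs_c`, `hgvs_p`, one `af_<source>` column per
#'   frequency source, and `max_af` (maximum over sources present, `NA` when
#'   no source has a record).
#' @export
annotate_variants <- function(keys, assertions, frequencies = NULL) {
  stopifnot(inherits(assertions, "assertion_store"))
  keycols <- c("chrom", "pos", "ref", "alt")
  ann <- as_tibble(assertions)[, c(keycols, "gene", "consequence", "assertion",
                                   "evidence_codes", "hgvs_c", "hgvs_p")]
  out <- left_join(as_tibble(keys), ann, by = keycols)
  out$assertion[is.na(out$assertion)] <- "absent"
  out$consequence[is.na(out$consequence)] <- "other_noncoding"
  if (!is.null(frequencies)) {
    stopifnot(inherits(frequencies, "frequency_store"))
    sources <- attr(frequencies, "sources")
    freq <- as_tibble(frequencies)
    names(freq)[match(sources, names(freq))] <- paste0("af_", sources)
    out <- left_join(out, freq, by = keycols)
    afcols <- paste0("af_", sources)
    if (length(afcols)) {
      m <- as.matrix(out[afcols])
      max_af <- suppressWarnings(apply(m, 1L, max, na.rm = TRUE))
      max_af[!is.finite(max_af)] <- NA_real_
      out$max_af <- max_af
    } else {
      out$max_af <- NA_real_
    }
  } else {
    out$max_af <- NA_real_
  }
  out
}
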