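# Normalized variant keys: (chrom, pos, ref, alt) with 1-based hg19-style
# coordinates, "chr"-prefix stripped, uppercase alleles, minimal representation.

#' Build a tibble of normalized variant keys
#'
#' A variant key is the quadruple (chrom, pos, ref, alt): chromosome label
#' without a `chr` prefix, 1-based position, and uppercase reference/alternate
#' allele strings over A/C/G/T. Keys are normalized to their minimal
#' left-aligned representation (shared suffix then shared prefix trimmed) so
#' that lookups against the annotation stores are representation-invariant.
#'
#' @param chrom Chromosome labels (with or without `chr` prefix).
#' @param pos 1-based positions.
#' @param ref,alt Allele strings.
#' @return A tibble with columns `chrom`, `pos`, `ref`, `alt`.
#' @examples
#' variant_key("chr17", 41246531, "A", "AA")
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  tbl <- tibble(
    chrom = sub("^chr", "", as.character(chrom), ignore.case = TRUE),
    pos = as.integer(pos),
    ref = toupper(as.character(ref)),
    alt = toupper(as.character(alt))
  )
  norm <- pmap(tbl, normalize_one_key)
  out <- bind_rows(norm)
  validate_keys(out)
  out
}

# Trim shared suffix, then shared prefix (advancing pos), keeping >=1 base
# on each side. This is left-alignment against the allele strings themselves;
# reference-sequence-aware re-alignment is out of scope.
normalize_one_key <- function(chrom, pos, ref, alt) {
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substring(ref, nchar(ref)) == substring(alt, nchar(alt))) {
    ref <- substring(ref, 1L, nchar(ref) - 1L)
    alt <- substring(alt, 1L, nchar(alt) - 1L)
  }
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substring(ref, 1L, 1L) == substring(alt, 1L, 1L)) {
    ref <- substring(ref, 2L)
    alt <- substring(alt, 2L)
    pos <- pos + 1L
  }
  tibble(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt)
}

validate_keys <- function(keys) {
  if (any(is.na(keys$pos)) || any(keys$pos < 1L)) {
    abort_format("variant position must be a positive 1-based integer")
  }
  bad <- !grepl("^[ACGT]+$", keys$ref) | !grepl("^[ACGT]+$", keys$alt)
  if (any(bad)) {
    abort_format(sprintf(
      "alleles must be non-empty strings over A/C/G/T (offending row %d)",
      which(bad)[1]
    ))
  }
  if (any(keys$ref == keys$alt)) {
    abort_format("ref and alt alleles must differ")
  }
  invisible(keys)
}

key_id <- function(tbl) {
  paste(tbl$chrom, tbl$pos, tbl$ref, tbl$alt, sep = ":")
}
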