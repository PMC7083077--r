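# Multi-sample VCF ingestion: vcfR parses the file; genotypes are then
# normalized into long-format per-(variant, sample) calls with the QC
# metrics (DP, GQ, allele depths) the filter cascade needs. Multi-allelic
# records are decomposed into biallelic keys so catalogue lookups work.

ZYGOSITY_TOKENS <- c("hom_ref", "het", "hom_alt", "hemizygous", "missing")

#' Read a multi-sample cohort VCF
#'
#' Parses a VCF 4.x file (plain or bgzip/gzip compressed) into cohort
#' metadata and a long tibble of carrier genotype calls. Multi-allelic
#' records are decomposed per alternate allele; keys are normalized
#' (`chr` prefix stripped, minimal allele representation). Reference-only
#' and fully missing genotypes are not emitted; every het, hom-alt or
#' hemizygous call is, with its DP, GQ and AD-derived ref/alt depths.
#'
#' @param path Path to the VCF.
#' @return A list of class `sf_cohort` with elements `meta` (list:
#'   `n_samples`, `sample_ids`, `build_tag`) and `calls` (tibble with
#'   columns `chrom`, `pos`, `ref`, `alt`, `sample_id`, `zygosity`,
#'   `depth`, `gq`, `ref_depth`, `alt_depth`).
#' @export
read_cohort_vcf <- function(path) {
  if (!file.exists(path)) {
    abort_validation(sprintf("VCF does not exist: %s", path))
  }
  sample_ids <- vcf_header_samples(path)
  vcf <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- vcf@fix
  meta <- list(n_samples = length(sample_ids), sample_ids = sample_ids,
               build_tag = "hg19")
  if (is.null(fix) || nrow(fix) == 0L) {
    return(structure(list(meta = meta, calls = empty_calls()),
                     class = "sf_cohort"))
  }
  gt <- vcf@gt
  if (is.null(gt) || !"FORMAT" %in% colnames(gt)) {
    abort_format("VCF has no FORMAT/genotype columns")
  }
  if (ncol(gt) - 1L != length(sample_ids)) {
    abort_format(sprintf("sample count mismatch: header names %d samples, body has %d",
                         length(sample_ids), ncol(gt) - 1L))
  }
  raw <- tibble(
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"], alt = fix[, "ALT"],
    format = gt[, "FORMAT"]
  )
  raw$sample_fields <- lapply(seq_len(nrow(gt)), function(i) unname(gt[i, -1L]))
  calls <- decompose_multiallelic(raw, sample_ids)
  structure(list(meta = meta, calls = calls), class = "sf_cohort")
}

vcf_header_samples <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line)) abort_format("VCF has no #CHROM header line")
    if (startsWith(line, "#CHROM")) {
      fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
      if (length(fields) < 9L || fields[9] != "FORMAT") {
        abort_format("VCF #CHROM line lacks FORMAT/sample columns")
      }
      ids <- fields[-(1:9)]
      if (anyDuplicated(ids)) abort_format("duplicate sample IDs in VCF header")
      return(ids)
    }
    if (!startsWith(line, "#")) abort_format("VCF has no #CHROM header line")
  }
}

empty_calls <- function() {
  tibble(chrom = character(), pos = integer(), ref = character(),
         alt = character(), sample_id = character(), zygosity = character(),
         depth = integer(), gq = integer(), ref_depth = integer(),
         alt_depth = integer())
}

#' Decompose raw VCF rows into biallelic per-sample calls
#'
#' A record with k alternate alleles yields up to k biallelic outputs. For
#' each alternate, a sample's zygosity is recomputed from the count of that
#' allele in its genotype: 2 copies give `hom_alt`, 1 gives `het` (a 1/2
#' genotype is het for both alternates), 0 copies count toward neither this
#' alt nor its carriers; a haploid call of the allele is `hemizygous`; a
#' genotype containing `.` is `missing`. The alt depth is the AD entry for
#' the corresponding allele; missing DP/GQ/AD fields become `NA` (which the
#' genotype QC filter treats as failure).
#'
#' @param raw Tibble with columns `chrom`, `pos`, `ref`, `alt`
#'   (comma-separated alternates), `format` (colon-joined FORMAT string
#'   containing at least `GT`), and list-column `sample_fields` (per-row
#'   character vector of sample entries in cohort order).
#' @param sample_ids Cohort sample IDs, in VCF column order.
#' @return Long tibble of carrier calls as in [read_cohort_vcf()].
#' @export
decompose_multiallelic <- function(raw, sample_ids) {
  out <- vector("list", nrow(raw))
  for (i in seq_len(nrow(raw))) {
    out[[i]] <- decompose_row(raw$chrom[i], raw$pos[i], raw$ref[i], raw$alt[i],
                              raw$format[i], raw$sample_fields[[i]], sample_ids)
  }
  calls <- bind_rows(out)
  if (nrow(calls) == 0L) return(empty_calls())
  calls
}

decompose_row <- function(chrom, pos, ref, alt_csv, format, fields, sample_ids) {
  alts <- strsplit(alt_csv, ",", fixed = TRUE)[[1]]
  alts <- alts[!alts %in% c(".", "*", "<NON_REF>")]
  if (!length(alts)) return(NULL)
  keys <- strsplit(format, ":", fixed = TRUE)[[1]]
  gt_idx <- match("GT", keys)
  if (is.na(gt_idx)) abort_format("VCF record lacks a GT field")
  dp_idx <- match("DP", keys)
  gq_idx <- match("GQ", keys)
  ad_idx <- match("AD", keys)

  parts <- strsplit(fields, ":", fixed = TRUE)
  gt_str <- map_chr(parts, function(p) {
    if (length(p) >= gt_idx && !is.na(p[gt_idx])) p[gt_idx] else "."
  })
  dp <- field_int(parts, dp_idx)
  gq <- field_int(parts, gq_idx)
  ad <- if (!is.na(ad_idx)) {
    lapply(parts, function(p) {
      v <- if (length(p) >= ad_idx) p[ad_idx] else NA_character_
      if (is.na(v) || v == ".") return(NULL)
      vals <- suppressWarnings(as.integer(strsplit(v, ",", fixed = TRUE)[[1]]))
      if (length(vals) != length(alts) + 1L) {
        abort_format(sprintf("AD arity %d inconsistent with %d allele(s) at %s:%d",
                             length(vals), length(alts) + 1L, chrom, pos))
      }
      vals
    })
  } else {
    rep(list(NULL), length(parts))
  }

  alleles <- strsplit(gt_str, "[/|]")
  res <- vector("list", length(alts))
  for (a in seq_along(alts)) {
    zyg <- map_chr(alleles, zygosity_for_alt, alt_index = a)
    carrier <- zyg %in% c("het", "hom_alt", "hemizygous")
    if (!any(carrier)) next
    idx <- which(carrier)
    key <- variant_key(chrom, pos, ref, alts[a])
    res[[a]] <- tibble(
      chrom = key$chrom, pos = key$pos, ref = key$ref, alt = key$alt,
      sample_id = sample_ids[idx],
      zygosity = zyg[idx],
      depth = dp[idx],
      gq = gq[idx],
      ref_depth = map_int(ad[idx], ~ if (is.null(.x)) NA_integer_ else .x[1]),
      alt_depth = map_int(ad[idx], ~ if (is.null(.x)) NA_integer_ else .x[a + 1L])
    )
  }
  bind_rows(res)
}

field_int <- function(parts, idx) {
  if (is.na(idx)) return(rep(NA_integer_, length(parts)))
  map_int(parts, function(p) {
    v <- if (length(p) >= idx) p[idx] else NA_character_
    if (is.na(v) || v == ".") NA_integer_ else suppressWarnings(as.integer(v))
  })
}

# Zygosity of one genotype relative to alternate allele number `alt_index`
# (1-based among the alternates, i.e. VCF allele code alt_index).
zygosity_for_alt <- function(allele_tokens, alt_index) {
  if (any(allele_tokens == ".")) return("missing")
  codes <- suppressWarnings(as.integer(allele_tokens))
  if (any(is.na(codes))) return("missing")
  n_alt <- sum(codes == alt_index)
  if (length(codes) == 1L) {
    return(if (n_alt == 1L) "hemizygous" else "hom_ref")
  }
  if (n_alt >= 2L) "hom_alt" else if (n_alt == 1L) "het" else "hom_ref"
}

#' Add the alternate-allele ratio to genotype calls
#'
#' The alt ratio is `alt_depth / (ref_depth + alt_depth)` — the fraction of
#' allele-informative reads supporting the alternate. The denominator is
#' AD-based rather than DP, since DP may include uninformative reads. A zero
#' or missing denominator yields `NA` (undefined).
#'
#' @param calls Tibble with `ref_depth` and `alt_depth` columns.
#' @return `calls` with an added `alt_ratio` column.
#' @examples
#' compute_alt_ratio(tibble::tibble(ref_depth = 41, alt_depth = 41))$alt_ratio
#' @export
compute_alt_ratio <- function(calls) {
  denom <- calls$ref_depth + calls$alt_depth
  ratio <- ifelse(!is.na(denom) & denom > 0, calls$alt_depth / denom, NA_real_)
  calls$alt_ratio <- ratio
  calls
}

#' @export
print.sf_cohort <- function(x, ...) {
  cat(sprintf("<sf_cohort> %d samples, %d carrier calls at %d variant keys\n",
              x$meta$n_samples, nrow(x$calls),
              length(unique(key_id(x$calls)))))
  invisible(x)
}
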