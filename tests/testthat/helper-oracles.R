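# Independent oracles and tiny fixture builders shared across tests.

# Straight-line transcription of the five-tier combining criteria, written
# as an if-chain over per-class counts, independent of the engine's rule
# table. Returns the verdict only.
oracle_classify <- function(codes) {
  codes <- unique(toupper(codes))
  n_pvs <- sum(codes == "PVS1")
  n_ps <- sum(grepl("^PS[0-9]$", codes))
  n_pm <- sum(grepl("^PM[0-9]$", codes))
  n_pp <- sum(grepl("^PP[0-9]$", codes))
  n_ba <- sum(codes == "BA1")
  n_bs <- sum(grepl("^BS[0-9]$", codes))
  n_bp <- sum(grepl("^BP[0-9]$", codes))

  pathogenic <-
    (n_pvs >= 1 && (n_ps >= 1 || n_pm >= 2 || (n_pm == 1 && n_pp >= 1) || n_pp >= 2)) ||
    n_ps >= 2 ||
    (n_ps == 1 && (n_pm >= 3 || (n_pm == 2 && n_pp >= 2) || (n_pm == 1 && n_pp >= 4)))
  likely_pathogenic <-
    (n_pvs >= 1 && n_pm == 1) ||
    (n_ps == 1 && n_pm >= 1 && n_pm <= 2) ||
    (n_ps == 1 && n_pp >= 2) ||
    n_pm >= 3 ||
    (n_pm == 2 && n_pp >= 2) ||
    (n_pm == 1 && n_pp >= 4)
  benign <- n_ba >= 1 || n_bs >= 2
  likely_benign <- (n_bs == 1 && n_bp >= 1) || n_bp >= 2

  path_side <- pathogenic || likely_pathogenic
  benign_side <- benign || likely_benign
  if (path_side && benign_side) return("vus")
  if (pathogenic) return("pathogenic")
  if (likely_pathogenic) return("likely_pathogenic")
  if (benign) return("benign")
  if (likely_benign) return("likely_benign")
  "vus"
}

# Brute-force cascade oracle: tests every (variant, sample) pair
# independently against the conjunction of the five predicates, with no
# shared machinery beyond the annotation lookup tables themselves.
oracle_cascade <- function(calls, assertion_tbl, frequency_tbl, panel_symbols,
                           cfg = filter_config()) {
  protein_altering <- c("stop_gained", "stop_lost", "start_lost", "frameshift",
                        "canonical_splice", "near_splice_within_10bp",
                        "inframe_indel", "missense")
  keep <- logical(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    row <- calls[i, ]
    if (!row$zygosity %in% c("het", "hom_alt", "hemizygous")) next
    a <- assertion_tbl[assertion_tbl$chrom == row$chrom &
                         assertion_tbl$pos == row$pos &
                         assertion_tbl$ref == row$ref &
                         assertion_tbl$alt == row$alt, ]
    gene <- if (nrow(a)) a$gene[1] else NA_character_
    consequence <- if (nrow(a)) a$consequence[1] else "other_noncoding"
    assertion <- if (nrow(a)) a$assertion[1] else "absent"
    if (is.na(gene) || !gene %in% panel_symbols) next
    if (!consequence %in% protein_altering) next
    f <- frequency_tbl[frequency_tbl$chrom == row$chrom &
                         frequency_tbl$pos == row$pos &
                         frequency_tbl$ref == row$ref &
                         frequency_tbl$alt == row$alt, ]
    if (nrow(f)) {
      vals <- unlist(f[setdiff(names(f), c("chrom", "pos", "ref", "alt"))])
      vals <- vals[!is.na(vals)]
      if (length(vals) && any(vals >= cfg$frequency_threshold)) next
    }
    if (!assertion %in% cfg$accepted_assertions) next
    if (is.na(row$depth) || row$depth < cfg$min_depth) next
    if (is.na(row$gq) || row$gq < cfg$min_gq) next
    denom <- row$ref_depth + row$alt_depth
    if (is.na(denom) || denom == 0) next
    ratio <- row$alt_depth / denom
    ok <- if (row$zygosity == "het") {
      ratio >= cfg$het_ratio_low && ratio <= cfg$het_ratio_high
    } else {
      ratio > cfg$hom_ratio_min
    }
    keep[i] <- ok
  }
  keep
}

# Minimal in-memory registry for unit tests.
tiny_registry <- function() {
  secfindr:::new_gene_registry(tibble::tibble(
    symbol = c("LMNA", "ATP7B", "MUTYH", "GLA", "OTC", "BRCA1"),
    transcript = paste0("NM_", 1:6, ".1"),
    inheritance = c("AD", "AR", "AR", "XLD", "XLR", "AD"),
    category = c("cardiogenetic", "other", "oncogenetic", "other", "other",
                 "oncogenetic"),
    disease = letters[1:6]
  ))
}

# One genotype call row with passing QC defaults.
call_row <- function(chrom = "1", pos = 100L, ref = "A", alt = "G",
                     sample_id = "S001", zygosity = "het", depth = 50L,
                     gq = 90L, ref_depth = 25L, alt_depth = 25L) {
  tibble::tibble(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
                 sample_id = sample_id, zygosity = zygosity,
                 depth = as.integer(depth), gq = as.integer(gq),
                 ref_depth = as.integer(ref_depth),
                 alt_depth = as.integer(alt_depth))
}

write_tsv_tmp <- function(tbl, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- tempfile(tmpdir = dir, fileext = ".tsv")
  readr::write_tsv(tbl, path, na = "", progress = FALSE)
  path
}

# Annotated variant row shaped like annotate_variants() output.
ann_row <- function(gene = "LMNA", consequence = "missense",
                    assertion = "pathogenic", max_af = NA_real_) {
  tibble::tibble(chrom = "1", pos = 1L, ref = "A", alt = "G", gene = gene,
                 consequence = consequence, assertion = assertion,
                 evidence_codes = NA_character_, hgvs_c = NA_character_,
                 hgvs_p = NA_character_, max_af = max_af)
}

# Shared small reference fixture (n = 60) reused across test files; built
# once per test run.
reference_fixture_small <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- build_reference_fixture(n_samples = 60, seed = 42)
    }
    cache
  }
})
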