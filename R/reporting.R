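# Inheritance-aware reporting: turn surviving findings into per-individual
# reportable results and cohort-level summary statistics.

REPORTING_STATUS <- c("dominant_reportable", "xl_reportable",
                      "recessive_biallelic_reportable", "recessive_carrier",
                      "xl_carrier")

#' Assign inheritance-aware reporting status to findings
#'
#' Applies the reporting rules per (sample, gene) group:
#'
#' * AD gene, het or hom-alt: `dominant_reportable`.
#' * XLD gene, any carrier zygosity (hemizygous, hom-alt, or het):
#'   `xl_reportable`.
#' * XLR gene, hemizygous or hom-alt: `xl_reportable`; heterozygous:
#'   `xl_carrier` (excluded from headline dominant counts).
#' * AR gene, hom-alt, or two or more distinct heterozygous variants in the
#'   same gene and sample (presumed in trans, phase unknown):
#'   `recessive_biallelic_reportable`.
#' * AR gene, single het: `recessive_carrier` — tallied in the cohort
#'   summary but excluded from the default clinical report, per the
#'   guideline recommendation to return only biallelic variants in
#'   recessive genes.
#'
#' @param findings An `sf_findings` tibble (or any tibble with `sample_id`,
#'   `gene`, `zygosity`, `assertion` columns). Every finding must carry an
#'   accepted (pathogenic / likely-pathogenic) assertion.
#' @param registry A `gene_registry` resolving every finding's gene.
#' @param accepted Assertion tokens allowed on incoming findings; anything
#'   else is a contract violation. Defaults to pathogenic /
#'   likely-pathogenic, matching the default cascade config.
#' @return `findings` with added columns `inheritance`, `category`, and
#'   `status`; biallelic-by-compound-het rows also get
#'   `phase = "phase_unknown"` (`NA` otherwise).
#' @export
assign_reporting_status <- function(findings, registry,
                                    accepted = c("pathogenic",
                                                 "likely_pathogenic")) {
  stopifnot(inherits(registry, "gene_registry"))
  tbl <- as_tibble(findings)
  if (nrow(tbl) == 0L) {
    tbl$inheritance <- character()
    tbl$category <- character()
    tbl$status <- character()
    tbl$phase <- character()
    return(tbl)
  }
  if (!all(tbl$assertion %in% accepted)) {
    abort_validation("findings outside the accepted assertion set cannot be status-assigned")
  }
  unresolved <- setdiff(unique(tbl$gene), registry$symbol)
  if (length(unresolved)) {
    abort_validation(sprintf("finding gene(s) absent from registry: %s",
                             paste(unresolved, collapse = ", ")))
  }
  gene_info <- registry_tbl(registry)[, c("symbol", "inheritance", "category")]
  tbl <- left_join(tbl, gene_info, by = c(gene = "symbol"))

  tbl <- tbl |>
    group_by(.data$sample_id, .data$gene) |>
    mutate(n_distinct_het = sum(.data$zygosity == "het")) |>
    ungroup() |>
    mutate(
      status = case_when(
        .data$inheritance == "AD" ~ "dominant_reportable",
        .data$inheritance == "XLD" ~ "xl_reportable",
        .data$inheritance == "XLR" &
          .data$zygosity %in% c("hemizygous", "hom_alt") ~ "xl_reportable",
        .data$inheritance == "XLR" ~ "xl_carrier",
        .data$inheritance == "AR" & .data$zygosity == "hom_alt" ~
          "recessive_biallelic_reportable",
        .data$inheritance == "AR" & .data$n_distinct_het >= 2 ~
          "recessive_biallelic_reportable",
        .default = "recessive_carrier"
      ),
      phase = ifelse(.data$status == "recessive_biallelic_reportable" &
                       .data$zygosity == "het", "phase_unknown", NA_character_)
    ) |>
    select(-"n_distinct_het")
  tbl
}

#' Summarize secondary findings over a cohort
#'
#' Rolls status-assigned findings up to the cohort level: headline
#' individual counts by reporting bucket, distinct-variant and mutated-gene
#' counts (with the AD/AR split), per-disease-category and per-gene
#' individual counts, and the corresponding proportions of the cohort and
#' of individuals with findings. Exact fractions are carried alongside
#' display strings rounded to two significant figures.
#'
#' @param findings Output of [assign_reporting_status()].
#' @param n_cohort Cohort size (denominator for cohort proportions).
#' @param registry A `gene_registry`.
#' @return An object of class `sf_cohort_summary` (a list with elements
#'   `headline`, `per_category`, `per_gene`, `findings`).
#' @export
summarize_cohort <- function(findings, n_cohort, registry) {
  stopifnot(inherits(registry, "gene_registry"), n_cohort > 0)
  tbl <- as_tibble(findings)
  if (!"status" %in% names(tbl)) {
    abort_validation("findings must be status-assigned first (assign_reporting_status)")
  }
  tbl <- distinct(tbl, .data$chrom, .data$pos, .data$ref, .data$alt,
                  .data$sample_id, .keep_all = TRUE)

  n_with <- length(unique(tbl$sample_id))
  n_var <- if (nrow(tbl)) length(unique(key_id(tbl))) else 0L
  samples_of <- function(statuses) {
    unique(tbl$sample_id[tbl$status %in% statuses])
  }
  n_dom <- length(samples_of(c("dominant_reportable", "xl_reportable")))
  n_carrier <- length(samples_of("recessive_carrier"))
  n_biallelic <- length(samples_of("recessive_biallelic_reportable"))

  genes <- unique(tbl$gene)
  gene_modes <- registry$inheritance[match(genes, registry$symbol)]

  headline <- tibble(
    n_cohort = as.integer(n_cohort),
    n_individuals_with_finding = n_with,
    n_variants_distinct = n_var,
    n_dominant_individuals = n_dom,
    n_recessive_carrier_individuals = n_carrier,
    n_biallelic_individuals = n_biallelic,
    n_genes = length(genes),
    n_genes_ad = sum(gene_modes == "AD"),
    n_genes_ar = sum(gene_modes == "AR"),
    pct_with_finding = 100 * n_with / n_cohort,
    pct_dominant = 100 * n_dom / n_cohort,
    pct_recessive_carrier = 100 * n_carrier / n_cohort
  ) |>
    mutate(
      pct_dominant_display = format_pct(.data$pct_dominant),
      pct_recessive_carrier_display = format_pct(.data$pct_recessive_carrier)
    )

  per_category <- tbl |>
    group_by(category = factor(.data$category, GENE_CATEGORIES)) |>
    summarise(n_individuals = n_distinct(.data$sample_id), .groups = "drop") |>
    tidyr::complete(category, fill = list(n_individuals = 0L)) |>
    mutate(
      category = as.character(.data$category),
      n_individuals = as.integer(.data$n_individuals),
      pct_of_findings = if (n_with > 0) 100 * .data$n_individuals / n_with else 0,
      pct_of_cohort = 100 * .data$n_individuals / n_cohort,
      pct_of_findings_display = format_pct(.data$pct_of_findings),
      pct_of_cohort_display = format_pct(.data$pct_of_cohort)
    )

  per_gene <- tbl |>
    group_by(gene = .data$gene) |>
    summarise(n_individuals = n_distinct(.data$sample_id), .groups = "drop") |>
    mutate(
      inheritance = registry$inheritance[match(.data$gene, registry$symbol)],
      category = registry$category[match(.data$gene, registry$symbol)],
      disease = if ("disease" %in% names(registry)) {
        registry$disease[match(.data$gene, registry$symbol)]
      } else {
        NA_character_
      }
    ) |>
    arrange(desc(.data$n_individuals), .data$gene)

  structure(
    list(headline = headline, per_category = per_category,
         per_gene = per_gene, findings = tbl),
    class = "sf_cohort_summary"
  )
}

#' Express a carrier count as a 1-in-k prevalence ratio
#'
#' @param count Number of individuals carrying the finding.
#' @param denominator Cohort size.
#' @return One-row tibble with `count`, `denominator`, `k`
#'   (`round(denominator / count)`), and `ratio_text` (`"1:k"`, or `"0"`
#'   when the count is zero).
#' @examples
#' prevalence_ratio(4, 280)$ratio_text # "1:70"
#' @export
prevalence_ratio <- function(count, denominator) {
  if (count < 0 || denominator <= 0) {
    abort_validation("count must be >= 0 and denominator > 0")
  }
  if (count == 0) {
    return(tibble(count = 0L, denominator = as.integer(denominator),
                  k = NA_integer_, ratio_text = "0"))
  }
  k <- as.integer(round(denominator / count))
  tibble(count = as.integer(count), denominator = as.integer(denominator),
         k = k, ratio_text = paste0("1:", k))
}

#' Fold increase of a cohort prevalence over a reference prevalence
#'
#' @param cohort_prev Cohort prevalence (fraction).
#' @param reference_prev Reference-population prevalence (fraction, > 0).
#' @param display_digits Rounding used for the display value (default 0,
#'   i.e. nearest integer).
#' @return One-row tibble with the exact `fold` ratio and a rounded
#'   `fold_display`.
#' @examples
#' fold_increase(1 / 70, 1 / 2500)$fold # 35.714...
#' @export
fold_increase <- function(cohort_prev, reference_prev, display_digits = 0) {
  if (reference_prev <= 0) abort_validation("reference prevalence must be > 0")
  if (cohort_prev < 0) abort_validation("cohort prevalence must be >= 0")
  fold <- cohort_prev / reference_prev
  tibble(fold = fold, fold_display = round(fold, display_digits))
}

#' Write pipeline reports to a directory
#'
#' Emits, with deterministic ordering and formatting:
#' * `findings.tsv` — one row per reportable (sample, variant) pair
#'   (sample, gene, key, HGVS, assertion, status), sorted by sample then
#'   chrom/pos. Recessive-carrier and X-linked-carrier rows are excluded
#'   unless `report_carriers = TRUE`; they always remain in the summary.
#' * `summary.json` — the cohort summary (headline, per-category, per-gene).
#' * `category_table.tsv` — the disease-category table (category, disease,
#'   gene, individuals).
#' * `stage_counts.json` — per-stage cascade survivor counts, when the
#'   findings carry them.
#'
#' @param summary An `sf_cohort_summary`.
#' @param out_dir Output directory (created if needed).
#' @param report_carriers Include carrier-status rows in `findings.tsv`.
#' @param stage_counts Optional stage-count tibble ([stage_counts()]).
#' @return Named character vector of the files written, invisibly.
#' @export
write_reports <- function(summary, out_dir, report_carriers = FALSE,
                          stage_counts = NULL) {
  stopifnot(inherits(summary, "sf_cohort_summary"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  tbl <- summary$findings
  reportable <- if (report_carriers) {
    tbl
  } else {
    tbl[!tbl$status %in% c("recessive_carrier", "xl_carrier"), , drop = FALSE]
  }
  cols <- intersect(c("sample_id", "gene", "chrom", "pos", "ref", "alt",
                      "hgvs_c", "hgvs_p", "assertion", "zygosity", "status",
                      "phase"), names(reportable))
  findings_path <- file.path(out_dir, "findings.tsv")
  reportable |>
    select(all_of(cols)) |>
    arrange(.data$sample_id, .data$chrom, .data$pos, .data$alt) |>
    readr::write_tsv(findings_path, na = "", progress = FALSE)

  summary_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(
    list(headline = summary$headline, per_category = summary$per_category,
         per_gene = summary$per_gene),
    summary_path, auto_unbox = FALSE, digits = NA, pretty = TRUE
  )

  category_path <- file.path(out_dir, "category_table.tsv")
  summary$per_gene |>
    select(category = "category", disease = "disease", gene = "gene",
           individuals = "n_individuals") |>
    arrange(factor(.data$category, GENE_CATEGORIES), desc(.data$individuals),
            .data$gene) |>
    readr::write_tsv(category_path, na = "", progress = FALSE)

  written <- c(findings = findings_path, summary = summary_path,
               category_table = category_path)
  if (!is.null(stage_counts)) {
    sc_path <- file.path(out_dir, "stage_counts.json")
    jsonlite::write_json(stage_counts, sc_path, auto_unbox = FALSE,
                         digits = NA, pretty = TRUE)
    written["stage_counts"] <- sc_path
  }
  invisible(written)
}

#' @export
print.sf_cohort_summary <- function(x, ...) {
  h <- x$headline
  cat(sprintf("<sf_cohort_summary> cohort n=%d\n", h$n_cohort))
  cat(sprintf("  %d individuals with findings, %d distinct variants in %d genes (%d AD, %d AR)\n",
              h$n_individuals_with_finding, h$n_variants_distinct,
              h$n_genes, h$n_genes_ad, h$n_genes_ar))
  cat(sprintf("  dominant/X-linked reportable: %d (%s%%); recessive carriers: %d (%s%%)\n",
              h$n_dominant_individuals, h$pct_dominant_display,
              h$n_recessive_carrier_individuals, h$pct_recessive_carrier_display))
  invisible(x)
}
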