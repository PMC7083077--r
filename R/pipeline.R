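# End-to-end pipeline entry point: ingest -> cascade -> status -> summary
# -> reports, with a run manifest for provenance.

#' Run the full secondary-findings pipeline
#'
#' Wires the stages end to end: reads the cohort VCF, loads the gene panel
#' and the assertion/frequency tables, runs the filter cascade, assigns
#' inheritance-aware reporting status, summarizes the cohort, and (when
#' `out_dir` is given) writes the report files plus a run manifest holding
#' the input checksums, the exact config used and the stage counts. The
#' analysis path is fully deterministic — identical inputs and config give
#' byte-identical findings and summary outputs.
#'
#' @param vcf Path to the multi-sample cohort VCF.
#' @param assertions Path to the assertion TSV ([load_assertion_table()]).
#' @param frequencies Path to the frequency TSV ([load_frequency_table()]),
#'   or `NULL`.
#' @param genes Path to the gene-panel TSV (default: packaged 59-gene
#'   actionable panel).
#' @param config A [filter_config()].
#' @param out_dir Optional output directory for reports.
#' @param report_carriers Include carrier rows in the findings report.
#' @return List of class `sf_run` with elements `findings` (status-assigned
#'   `sf_findings`), `summary` (`sf_cohort_summary`), `stage_counts`,
#'   `meta`, and `manifest`.
#' @export
run_pipeline <- function(vcf, assertions, frequencies = NULL,
                         genes = secfindr_extdata("acmg_sf_panel.tsv"),
                         config = filter_config(), out_dir = NULL,
                         report_carriers = FALSE) {
  registry <- load_gene_table(genes)
  assertion_store <- load_assertion_table(assertions)
  frequency_store <- if (is.null(frequencies)) NULL else load_frequency_table(frequencies)
  cohort <- read_cohort_vcf(vcf)

  findings <- run_cascade(cohort, assertion_store, frequency_store, registry,
                          config)
  sc <- stage_counts(findings)
  findings <- assign_reporting_status(findings, registry,
                                      accepted = config$accepted_assertions)
  summary <- summarize_cohort(findings, cohort$meta$n_samples, registry)

  manifest <- list(
    tool = "secfindr",
    version = as.character(utils::packageVersion("secfindr")),
    inputs = list(
      vcf = unname(tools::md5sum(vcf)),
      assertions = unname(tools::md5sum(assertions)),
      frequencies = if (is.null(frequencies)) NULL else unname(tools::md5sum(frequencies)),
      genes = unname(tools::md5sum(genes))
    ),
    config = unclass(config),
    config_hash = rlang::hash(unclass(config)),
    stage_counts = sc,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )

  if (!is.null(out_dir)) {
    written <- write_reports(summary, out_dir, report_carriers = report_carriers,
                             stage_counts = sc)
    manifest_path <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
    manifest$written <- c(written, manifest = manifest_path)
  }

  structure(
    list(findings = findings, summary = summary, stage_counts = sc,
         meta = cohort$meta, manifest = manifest),
    class = "sf_run"
  )
}

#' @export
print.sf_run <- function(x, ...) {
  cat("<sf_run>\n")
  print(x$summary)
  cat("  stage counts:\n")
  sc <- x$stage_counts
  for (i in seq_len(nrow(sc))) {
    cat(sprintf("    %-12s %5d variants %6d genotypes\n",
                sc$stage[i], sc$n_variants[i], sc$n_genotypes[i]))
  }
  invisible(x)
}
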