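# The ordered filter cascade: panel membership -> protein-altering
# consequence -> population frequency -> clinical assertion -> per-genotype
# QC, with per-stage survivor logging.

#' Filter-cascade configuration
#'
#' Bundles the cascade thresholds with their defaults: variants must be
#' rarer than 1% in every frequency source with a record, asserted
#' pathogenic or likely pathogenic, and carried by at least one genotype
#' with depth >= 15, genotype quality >= 20, and an alt ratio inside
#' [0.3, 0.7] for hets or strictly above 0.85 for hom-alt (and hemizygous)
#' calls. Values can be overridden from a YAML/JSON config file and/or
#' named arguments; precedence is defaults < file < arguments.
#'
#' @param ... Named overrides of any config field (`frequency_threshold`,
#'   `min_depth`, `min_gq`, `het_ratio_low`, `het_ratio_high`,
#'   `hom_ratio_min`, `accepted_assertions`).
#' @param file Optional path to a YAML (or JSON) file of overrides.
#' @return A named list of class `filter_config`.
#' @examples
#' filter_config(min_depth = 20)
#' @export
filter_config <- function(..., file = NULL) {
  cfg <- list(
    frequency_threshold = 0.01,
    min_depth = 15,
    min_gq = 20,
    het_ratio_low = 0.3,
    het_ratio_high = 0.7,
    hom_ratio_min = 0.85,
    accepted_assertions = c("pathogenic", "likely_pathogenic")
  )
  if (!is.null(file)) {
    if (!file.exists(file)) abort_validation(sprintf("config file not found: %s", file))
    over <- yaml::read_yaml(file)
    cfg <- utils::modifyList(cfg, over[intersect(names(over), names(cfg))])
  }
  args <- list(...)
  unknown <- setdiff(names(args), names(cfg))
  if (length(unknown)) {
    abort_validation(sprintf("unknown config field(s): %s",
                             paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(cfg, args)
  validate_filter_config(cfg)
  structure(cfg, class = "filter_config")
}

validate_filter_config <- function(cfg) {
  with(cfg, {
    if (!(frequency_threshold > 0 && frequency_threshold <= 1)) {
      abort_validation("frequency_threshold must be in (0, 1]")
    }
    if (!(het_ratio_low >= 0 && het_ratio_low <= het_ratio_high &&
          het_ratio_high <= 1)) {
      abort_validation("need 0 <= het_ratio_low <= het_ratio_high <= 1")
    }
    if (!(hom_ratio_min >= 0 && hom_ratio_min <= 1)) {
      abort_validation("hom_ratio_min must be in [0, 1]")
    }
    bad <- setdiff(accepted_assertions, ASSERTION_TOKENS)
    if (length(bad)) {
      abort_validation(sprintf("unknown assertion token(s) in accepted_assertions: %s",
                               paste(bad, collapse = ", ")))
    }
  })
  invisible(cfg)
}

#' Variant-level filter predicates
#'
#' Each predicate is pure and order-independent; `run_cascade()` applies
#' them in the fixed documented order for reproducible stage logs.
#'
#' * `panel_filter()`: keep iff the annotated gene symbol resolves in the
#'   actionable-gene registry.
#' * `consequence_filter()`: keep iff the consequence class is
#'   protein-altering (truncating, canonical or near splice, inframe indel,
#'   missense).
#' * `frequency_filter()`: keep iff every frequency source with a record is
#'   strictly below the threshold; variants with no frequency record
#'   anywhere are kept (novel variants are rare until shown otherwise).
#' * `assertion_filter()`: keep iff the assertion is among the accepted
#'   tokens (default: pathogenic, likely_pathogenic); VUS, conflicting and
#'   absent all fail.
#'
#' @param annotations Annotated variant tibble from [annotate_variants()].
#' @param registry A `gene_registry`.
#' @param config A `filter_config`.
#' @return Logical keep vector, one element per annotation row.
#' @name variant_filters
NULL

#' @rdname variant_filters
#' @export
panel_filter <- function(annotations, registry) {
  stopifnot(inherits(registry, "gene_registry"))
  !is.na(annotations$gene) & annotations$gene %in% registry$symbol
}

#' @rdname variant_filters
#' @export
consequence_filter <- function(annotations) {
  annotations$consequence %in% PROTEIN_ALTERING
}

#' @rdname variant_filters
#' @export
frequency_filter <- function(annotations, config = filter_config()) {
  is.na(annotations$max_af) | annotations$max_af < config$frequency_threshold
}

#' @rdname variant_filters
#' @export
assertion_filter <- function(annotations, config = filter_config()) {
  annotations$assertion %in% config$accepted_assertions
}

#' Per-genotype QC filter
#'
#' A carrier genotype passes iff depth and genotype quality meet their
#' minima (`DP >= 15`, `GQ >= 20` by default; a value exactly at the
#' minimum passes), and its alt ratio sits in the zygosity-appropriate
#' window: inclusive `[het_ratio_low, het_ratio_high]` for hets, strictly
#' above `hom_ratio_min` for hom-alt; hemizygous calls are held to the
#' hom-alt window. Any missing required metric (DP, GQ, or AD-derived
#' ratio) fails: an unknowable metric cannot certify a call.
#'
#' @param calls Genotype-call tibble with `zygosity`, `depth`, `gq`,
#'   `ref_depth`, `alt_depth` columns.
#' @param config A `filter_config`.
#' @return Logical keep vector.
#' @export
genotype_qc_filter <- function(calls, config = filter_config()) {
  calls <- compute_alt_ratio(calls)
  ok_metrics <- !is.na(calls$depth) & !is.na(calls$gq) & !is.na(calls$alt_ratio) &
    calls$depth >= config$min_depth & calls$gq >= config$min_gq
  het_ok <- calls$alt_ratio >= config$het_ratio_low &
    calls$alt_ratio <= config$het_ratio_high
  hom_ok <- calls$alt_ratio > config$hom_ratio_min
  window_ok <- case_when(
    calls$zygosity == "het" ~ het_ok,
    calls$zygosity %in% c("hom_alt", "hemizygous") ~ hom_ok,
    .default = FALSE
  )
  ok <- ok_metrics & window_ok
  ok[is.na(ok)] <- FALSE
  ok
}

#' Run the full filter cascade over a cohort
#'
#' Applies panel -> consequence -> frequency -> assertion at the variant
#' level, then genotype QC at the carrier level; a variant survives iff it
#' passes every variant-level filter and retains at least one carrier after
#' QC. Stage survivor counts (distinct variants and carrier genotypes) are
#' logged after every stage and are non-increasing by construction.
#'
#' @param cohort An `sf_cohort` from [read_cohort_vcf()], or a plain calls
#'   tibble (`chrom`, `pos`, `ref`, `alt`, `sample_id`, `zygosity`,
#'   `depth`, `gq`, `ref_depth`, `alt_depth`).
#' @param assertions An `assertion_store`.
#' @param frequencies A `frequency_store` (or `NULL`).
#' @param registry A `gene_registry`.
#' @param config A `filter_config`.
#' @return A tibble of class `sf_findings`: one row per surviving
#'   (variant, carrier) pair, annotation columns included, sorted by
#'   (chrom, pos, alt, sample_id); attribute `stage_counts` holds the
#'   per-stage tally tibble (`stage`, `n_variants`, `n_genotypes`).
#' @export
run_cascade <- function(cohort, assertions, frequencies, registry,
                        config = filter_config()) {
  calls <- if (inherits(cohort, "sf_cohort")) cohort$calls else as_tibble(cohort)
  calls <- calls[calls$zygosity %in% c("het", "hom_alt", "hemizygous"), ,
                 drop = FALSE]

  keys <- distinct(calls, .data$chrom, .data$pos, .data$ref, .data$alt)
  ann <- annotate_variants(keys, assertions, frequencies)

  stages <- list()
  tally <- function(ann_keep, calls_now) {
    ids <- key_id(ann_keep)
    calls_now <- calls_now[key_id(calls_now) %in% ids, , drop = FALSE]
    list(n_variants = nrow(ann_keep), n_genotypes = nrow(calls_now),
         calls = calls_now)
  }

  t0 <- tally(ann, calls)
  stages[["input"]] <- t0

  ann <- ann[panel_filter(ann, registry), , drop = FALSE]
  stages[["panel"]] <- tally(ann, calls)

  ann <- ann[consequence_filter(ann), , drop = FALSE]
  stages[["consequence"]] <- tally(ann, calls)

  ann <- ann[frequency_filter(ann, config), , drop = FALSE]
  stages[["frequency"]] <- tally(ann, calls)

  ann <- ann[assertion_filter(ann, config), , drop = FALSE]
  stages[["assertion"]] <- tally(ann, calls)

  surviving_calls <- stages[["assertion"]]$calls
  qc_keep <- genotype_qc_filter(surviving_calls, config)
  surviving_calls <- surviving_calls[qc_keep, , drop = FALSE]
  ann <- ann[key_id(ann) %in% key_id(surviving_calls), , drop = FALSE]
  stages[["genotype_qc"]] <- list(n_variants = nrow(ann),
                                  n_genotypes = nrow(surviving_calls))

  stage_counts <- tibble(
    stage = names(stages),
    n_variants = map_int(stages, ~ as.integer(.x$n_variants)),
    n_genotypes = map_int(stages, ~ as.integer(.x$n_genotypes))
  )

  findings <- surviving_calls |>
    compute_alt_ratio() |>
    left_join(ann, by = c("chrom", "pos", "ref", "alt")) |>
    arrange(.data$chrom, .data$pos, .data$alt, .data$sample_id)

  structure(findings, stage_counts = stage_counts, config = config,
            class = c("sf_findings", class(findings)))
}

#' Per-stage survivor counts of a cascade run
#'
#' @param findings An `sf_findings` object from [run_cascade()].
#' @return Tibble with columns `stage`, `n_variants`, `n_genotypes`.
#' @export
stage_counts <- function(findings) {
  sc <- attr(findings, "stage_counts")
  if (is.null(sc)) abort_validation("object carries no stage_counts attribute")
  sc
}

#' @export
print.sf_findings <- function(x, ...) {
  cat(sprintf("<sf_findings> %d surviving (variant, carrier) pairs: %d variants in %d individuals\n",
              nrow(x), length(unique(key_id(x))), length(unique(x$sample_id))))
  NextMethod()
}
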