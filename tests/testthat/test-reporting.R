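finding_row <- function(gene, sample_id = "S001", zygosity = "het",
                        pos = 100L, alt = "G",
                        assertion = "pathogenic") {
  call_row(pos = pos, alt = alt, sample_id = sample_id,
           zygosity = zygosity) |>
    dplyr::mutate(gene = gene, assertion = assertion,
                  consequence = "missense",
                  hgvs_c = NA_character_, hgvs_p = NA_character_)
}

test_that("reporting status follows the inheritance-aware rules", {
  reg <- tiny_registry()
  tbl <- dplyr::bind_rows(
    finding_row("LMNA", "S001"),                                    # AD het
    finding_row("BRCA1", "S002", zygosity = "hom_alt"),             # AD hom
    finding_row("ATP7B", "S003"),                                   # AR single het
    finding_row("ATP7B", "S004", pos = 200L),                       # AR compound het
    finding_row("ATP7B", "S004", pos = 300L),
    finding_row("MUTYH", "S005", zygosity = "hom_alt"),             # AR hom
    finding_row("OTC", "S006", zygosity = "hemizygous"),            # XLR male
    finding_row("OTC", "S007"),                                     # XLR het female
    finding_row("GLA", "S008")                                      # XLD het
  )
  out <- assign_reporting_status(tbl, reg)
  status_of <- function(s) unique(out$status[out$sample_id == s])
  expect_equal(status_of("S001"), "dominant_reportable")
  expect_equal(status_of("S002"), "dominant_reportable")
  expect_equal(status_of("S003"), "recessive_carrier")
  expect_equal(status_of("S004"), "recessive_biallelic_reportable")
  expect_equal(unique(out$phase[out$sample_id == "S004"]), "phase_unknown")
  expect_equal(status_of("S005"), "recessive_biallelic_reportable")
  expect_true(is.na(unique(out$phase[out$sample_id == "S005"])))
  expect_equal(status_of("S006"), "xl_reportable")
  expect_equal(status_of("S007"), "xl_carrier")
  expect_equal(status_of("S008"), "xl_reportable")

  # sub-threshold assertions violate the contract
  expect_error(assign_reporting_status(finding_row("LMNA", assertion = "vus"), reg),
               class = "secfindr_validation_error")
  # unknown gene violates the contract
  expect_error(assign_reporting_status(finding_row("TTN"), reg),
               class = "secfindr_validation_error")
})

test_that("cohort summary reproduces the reference headline counts and categories", {
  fx <- reference_fixture_small()
  res <- run_pipeline(fx$vcf, fx$assertions, fx$frequencies)
  h <- glance(res)

  expect_equal(h$n_individuals_with_finding, 24L)
  expect_equal(h$n_variants_distinct, 19L)
  expect_equal(h$n_dominant_individuals, 17L)
  expect_equal(h$n_recessive_carrier_individuals, 7L)
  expect_equal(h$n_genes, 12L)
  expect_equal(h$n_genes_ad, 10L)
  expect_equal(h$n_genes_ar, 2L)

  per_cat <- res$summary$per_category
  expect_equal(per_cat$n_individuals[per_cat$category == "cardiogenetic"], 6L)
  expect_equal(per_cat$n_individuals[per_cat$category == "connective_tissue"], 1L)
  expect_equal(per_cat$pct_of_findings[per_cat$category == "cardiogenetic"],
               100 * 6 / 24)

  per_gene <- tidy(res)
  counts <- setNames(per_gene$n_individuals, per_gene$gene)
  expect_equal(counts[["LDLR"]], 4L)
  expect_equal(counts[["ATP7B"]], 4L)
  expect_equal(counts[["MUTYH"]], 3L)
  expect_equal(counts[["RYR1"]], 3L)
  expect_equal(counts[["KCNQ1"]], 2L)
  expect_equal(counts[["KCNH2"]], 2L)
  for (g in c("BRCA1", "BRCA2", "PMS2", "FBN1", "LMNA", "TMEM43")) {
    expect_equal(counts[[g]], 1L)
  }
  expect_equal(sum(per_gene$n_individuals), 24L)

  # displayed percentages equal their exact fractions within rounding
  expect_equal(h$pct_recessive_carrier, 100 * 7 / h$n_cohort)
  expect_equal(as.numeric(h$pct_recessive_carrier_display),
               signif(h$pct_recessive_carrier, 2))
})

test_that("an empty finding set summarizes to zeros", {
  reg <- tiny_registry()
  empty <- assign_reporting_status(
    dplyr::mutate(secfindr:::empty_calls(), gene = character(),
                  assertion = character(), hgvs_c = character(),
                  hgvs_p = character()), reg)
  s <- summarize_cohort(empty, n_cohort = 100, reg)
  expect_equal(glance(s)$n_individuals_with_finding, 0L)
  expect_equal(glance(s)$pct_dominant, 0)
  expect_true(all(s$per_category$n_individuals == 0L))
  expect_equal(nrow(tidy(s)), 0L)
})

test_that("prevalence ratios render 1-in-k with a rounded k", {
  expect_equal(prevalence_ratio(4, 280)$ratio_text, "1:70")
  expect_equal(prevalence_ratio(7, 280)$ratio_text, "1:40")
  expect_equal(prevalence_ratio(3, 280)$k, 93L) # 280/3 = 93.33 rounds down
  expect_equal(prevalence_ratio(0, 280)$ratio_text, "0")
  expect_error(prevalence_ratio(-1, 280), class = "secfindr_validation_error")
  expect_error(prevalence_ratio(1, 0), class = "secfindr_validation_error")
})

test_that("fold increase is the exact prevalence ratio with configurable display", {
  f <- fold_increase(1 / 70, 1 / 2500)
  expect_equal(f$fold, 2500 / 70)
  expect_equal(f$fold_display, 36) # exact 35.71 rounds to 36
  expect_equal(fold_increase(1 / 70, 1 / 2500, display_digits = 2)$fold_display,
               35.71)
  expect_equal(fold_increase(0.01, 0.01)$fold, 1)
  expect_equal(fold_increase(1 / 90, 1 / 100)$fold, 100 / 90, tolerance = 1e-12)
  expect_error(fold_increase(0.1, 0), class = "secfindr_validation_error")
})

test_that("report files are deterministic, complete and carrier-aware", {
  fx <- reference_fixture_small()
  out1 <- tempfile(); out2 <- tempfile()
  res <- run_pipeline(fx$vcf, fx$assertions, fx$frequencies, out_dir = out1)
  run_pipeline(fx$vcf, fx$assertions, fx$frequencies, out_dir = out2)

  # default report excludes the 7 recessive carriers
  findings <- readr::read_tsv(file.path(out1, "findings.tsv"),
                              show_col_types = FALSE)
  expect_equal(nrow(findings), 17L)
  expect_false(any(findings$status == "recessive_carrier"))

  out3 <- tempfile()
  run_pipeline(fx$vcf, fx$assertions, fx$frequencies, out_dir = out3,
               report_carriers = TRUE)
  with_carriers <- readr::read_tsv(file.path(out3, "findings.tsv"),
                                   show_col_types = FALSE)
  expect_equal(nrow(with_carriers), 24L)

  # identical inputs and config give byte-identical findings and summary
  for (f in c("findings.tsv", "summary.json", "category_table.tsv",
              "stage_counts.json")) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)), label = f)
  }

  cat_tbl <- readr::read_tsv(file.path(out1, "category_table.tsv"),
                             show_col_types = FALSE)
  expect_equal(cat_tbl$individuals[cat_tbl$gene == "LDLR"], 4L)
  expect_equal(cat_tbl$category[cat_tbl$gene == "LDLR"], "other")

  manifest <- jsonlite::read_json(file.path(out1, "manifest.json"))
  expect_equal(manifest$tool, "secfindr")
  expect_true(nzchar(manifest$config_hash))
  expect_equal(length(manifest$inputs), 4L)
})
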