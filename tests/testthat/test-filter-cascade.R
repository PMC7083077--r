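test_that("genotype QC boundary semantics follow the documented bounds", {
  cfg <- filter_config()
  qc <- function(zygosity, depth, gq, ratio, dp_for_ad = 100L) {
    alt <- as.integer(round(dp_for_ad * ratio))
    genotype_qc_filter(call_row(zygosity = zygosity, depth = depth, gq = gq,
                                ref_depth = dp_for_ad - alt, alt_depth = alt),
                       cfg)
  }
  # depth: strictly-below-15 drops, 15 itself passes
  expect_false(qc("het", 14L, 99L, 0.5))
  expect_true(qc("het", 15L, 99L, 0.5))
  # genotype quality: strictly-below-20 drops, 20 itself passes
  expect_false(qc("het", 30L, 19L, 0.5))
  expect_true(qc("het", 30L, 20L, 0.5))
  # het window inclusive at both ends
  expect_false(qc("het", 30L, 99L, 0.29))
  expect_true(qc("het", 30L, 99L, 0.30))
  expect_true(qc("het", 30L, 99L, 0.70))
  expect_false(qc("het", 30L, 99L, 0.71))
  # hom-alt bound strict at 0.85
  expect_false(qc("hom_alt", 30L, 99L, 0.85))
  expect_true(qc("hom_alt", 30L, 99L, 0.86))
  # hemizygous held to the hom-alt window
  expect_true(qc("hemizygous", 30L, 99L, 0.90))
  expect_false(qc("hemizygous", 30L, 99L, 0.50))
})

test_that("missing QC metrics fail conservatively", {
  cfg <- filter_config()
  expect_false(genotype_qc_filter(call_row(depth = NA_integer_), cfg))
  expect_false(genotype_qc_filter(call_row(gq = NA_integer_), cfg))
  expect_false(genotype_qc_filter(call_row(ref_depth = NA_integer_,
                                           alt_depth = NA_integer_), cfg))
  expect_false(genotype_qc_filter(call_row(ref_depth = 0L, alt_depth = 0L), cfg))
})

test_that("variant-level predicates implement the documented keep/drop semantics", {
  reg <- tiny_registry()
  cfg <- filter_config()

  expect_true(panel_filter(ann_row(gene = "LMNA"), reg))
  expect_false(panel_filter(ann_row(gene = "TTN"), reg))
  expect_false(panel_filter(ann_row(gene = NA_character_), reg))

  expect_true(consequence_filter(ann_row(consequence = "missense")))
  expect_true(consequence_filter(ann_row(consequence = "near_splice_within_10bp")))
  expect_true(consequence_filter(ann_row(consequence = "inframe_indel")))
  expect_false(consequence_filter(ann_row(consequence = "synonymous")))
  expect_false(consequence_filter(ann_row(consequence = "utr")))

  # any source at or above 1% drops; all-below keeps; absent keeps
  expect_false(frequency_filter(ann_row(max_af = 0.02), cfg))
  expect_false(frequency_filter(ann_row(max_af = 0.01), cfg))
  expect_true(frequency_filter(ann_row(max_af = 0.009), cfg))
  expect_true(frequency_filter(ann_row(max_af = NA_real_), cfg))

  expect_true(assertion_filter(ann_row(assertion = "pathogenic"), cfg))
  expect_true(assertion_filter(ann_row(assertion = "likely_pathogenic"), cfg))
  expect_false(assertion_filter(ann_row(assertion = "vus"), cfg))
  expect_false(assertion_filter(ann_row(assertion = "conflicting"), cfg))
  expect_false(assertion_filter(ann_row(assertion = "absent"), cfg))
})

test_that("variant-level filters are order-insensitive pure predicates", {
  fx <- reference_fixture_small()
  store <- load_assertion_table(fx$assertions)
  freq <- load_frequency_table(fx$frequencies)
  reg <- load_gene_table()
  cohort <- read_cohort_vcf(fx$vcf)
  keys <- dplyr::distinct(cohort$calls, chrom, pos, ref, alt)
  ann <- annotate_variants(keys, store, freq)
  cfg <- filter_config()

  preds <- list(
    function(a) panel_filter(a, reg),
    function(a) consequence_filter(a),
    function(a) frequency_filter(a, cfg),
    function(a) assertion_filter(a, cfg)
  )
  reference_keep <- Reduce(`&`, lapply(preds, function(p) p(ann)))
  for (perm in list(c(4, 3, 2, 1), c(2, 4, 1, 3), c(3, 1, 4, 2))) {
    surviving <- ann
    for (j in perm) surviving <- surviving[preds[[j]](surviving), ]
    expect_setequal(secfindr:::key_id(surviving),
                    secfindr:::key_id(ann[reference_keep, ]))
  }
})

test_that("stage counts are non-increasing and findings match the truth table", {
  fx <- reference_fixture_small()
  res <- run_pipeline(fx$vcf, fx$assertions, fx$frequencies)
  sc <- res$stage_counts
  expect_equal(sc$stage, c("input", "panel", "consequence", "frequency",
                           "assertion", "genotype_qc"))
  expect_true(all(diff(sc$n_variants) <= 0))
  expect_true(all(diff(sc$n_genotypes) <= 0))

  truth <- fx$truth[fx$truth$expected == "survives", ]
  expect_setequal(
    paste(res$findings$chrom, res$findings$pos, res$findings$alt,
          res$findings$sample_id),
    paste(truth$chrom, truth$pos, truth$alt, truth$sample_id))
})

test_that("raising one spiked variant's population frequency removes exactly that finding", {
  fx <- reference_fixture_small()
  freq <- readr::read_tsv(fx$frequencies, show_col_types = FALSE)
  hit <- freq$pos == 32968825 & freq$chrom == "13"
  expect_true(any(hit))
  freq$gnomad[hit] <- 0.05
  edited <- tempfile(fileext = ".tsv")
  readr::write_tsv(freq, edited, na = "", progress = FALSE)

  res <- run_pipeline(fx$vcf, fx$assertions, edited)
  expect_equal(glance(res)$n_variants_distinct, 18L)
  expect_false("BRCA2" %in% res$findings$gene)
})

test_that("cascade output equals the brute-force per-pair oracle on small random cohorts", {
  reg <- tiny_registry()
  genes <- reg$symbol
  consequences <- c("missense", "frameshift", "synonymous", "stop_gained", "utr")
  assertions_pool <- c("pathogenic", "likely_pathogenic", "vus", "benign",
                       "conflicting")

  withr::with_seed(2024, {
    for (rep_i in 1:8) {
      n_var <- sample(5:50, 1)
      n_samp <- sample(2:5, 1)
      samples <- paste0("P", seq_len(n_samp))
      pos <- sample(1e6, n_var)
      ann_tbl <- tibble::tibble(
        chrom = sample(c("1", "2", "X"), n_var, replace = TRUE),
        pos = as.integer(pos), ref = "A",
        alt = sample(c("C", "G", "T"), n_var, replace = TRUE),
        gene = sample(c(genes, "TTN", NA), n_var, replace = TRUE),
        consequence = sample(consequences, n_var, replace = TRUE),
        assertion = sample(assertions_pool, n_var, replace = TRUE),
        evidence_codes = NA_character_,
        hgvs_c = NA_character_, hgvs_p = NA_character_
      )
      freq_tbl <- ann_tbl[sample(n_var, ceiling(n_var / 2)),
                          c("chrom", "pos", "ref", "alt")]
      freq_tbl$gnomad <- runif(nrow(freq_tbl), 0, 0.05)
      freq_tbl$inhouse <- ifelse(runif(nrow(freq_tbl)) < 0.5,
                                 runif(nrow(freq_tbl), 0, 0.02), NA_real_)

      # every sample gets a shot at every variant with random QC metrics
      calls <- tidyr::crossing(ann_tbl[, c("chrom", "pos", "ref", "alt")],
                               sample_id = samples) |>
        dplyr::mutate(
          zygosity = sample(c("het", "hom_alt", "hemizygous", "hom_ref"),
                            dplyr::n(), replace = TRUE),
          depth = sample(5:60, dplyr::n(), replace = TRUE),
          gq = sample(5:99, dplyr::n(), replace = TRUE),
          alt_depth = as.integer(round(depth * runif(dplyr::n(), 0, 1))),
          ref_depth = depth - alt_depth
        )
      calls <- calls[sample(nrow(calls), ceiling(nrow(calls) * 0.7)), ]

      store <- load_assertion_table(write_tsv_tmp(ann_tbl))
      freqs <- load_frequency_table(write_tsv_tmp(freq_tbl))
      findings <- run_cascade(calls, store, freqs, reg)

      want <- oracle_cascade(calls, ann_tbl, freq_tbl, genes)
      expect_setequal(
        paste(findings$chrom, findings$pos, findings$alt, findings$sample_id),
        paste(calls$chrom, calls$pos, calls$alt, calls$sample_id)[want])
    }
  })
})

test_that("an empty cohort yields empty findings and all-zero stage counts", {
  fx <- reference_fixture_small()
  store <- load_assertion_table(fx$assertions)
  freq <- load_frequency_table(fx$frequencies)
  findings <- run_cascade(secfindr:::empty_calls(), store, freq,
                          load_gene_table())
  expect_equal(nrow(findings), 0L)
  sc <- stage_counts(findings)
  expect_true(all(sc$n_variants == 0L))
  expect_true(all(sc$n_genotypes == 0L))
})

test_that("filter configuration validates fields and applies file/argument precedence", {
  cfg_file <- tempfile(fileext = ".yaml")
  writeLines(c("min_depth: 25", "min_gq: 30"), cfg_file)
  cfg <- filter_config(min_gq = 40, file = cfg_file)
  expect_equal(cfg$min_depth, 25)
  expect_equal(cfg$min_gq, 40) # argument beats file
  expect_equal(cfg$frequency_threshold, 0.01) # default survives

  expect_error(filter_config(frequency_threshold = 0),
               class = "secfindr_validation_error")
  expect_error(filter_config(het_ratio_low = 0.8, het_ratio_high = 0.4),
               class = "secfindr_validation_error")
  expect_error(filter_config(nonsense = 1),
               class = "secfindr_validation_error")
  expect_error(filter_config(accepted_assertions = "maybe"),
               class = "secfindr_validation_error")
})
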