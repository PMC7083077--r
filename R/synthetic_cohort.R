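# Deterministic synthetic-cohort simulator: spikes the packaged catalogue of
# pathogenic/likely-pathogenic variants into a cohort at their catalogued
# carrier counts, adds adversarial background variation engineered to fail
# exactly one cascade stage each, and writes the VCF + annotation tables +
# a truth table that serves as the pipeline oracle.

#' Background-variation specification
#'
#' Controls the adversarial background added around the spiked variants.
#' Every background record is constructed to fail exactly one cascade
#' stage, which the truth table records:
#'
#' * `n_common_pathogenic_annotated` — on-panel, protein-altering,
#'   asserted pathogenic, but common (>= 1% in at least one source):
#'   fails the frequency filter.
#' * `n_rare_benign` — on-panel, protein-altering, rare, asserted benign /
#'   likely benign / conflicting: fails the assertion filter. The first two
#'   records share a site as a multi-allelic pair so decomposition is
#'   exercised on every fixture.
#' * `n_vus` — as above but asserted VUS: fails the assertion filter.
#' * `n_low_qc` — on-panel, rare, asserted pathogenic, but every carrier
#'   genotype violates depth, genotype quality, or allele-balance QC:
#'   fails genotype QC.
#' * `n_off_panel` — asserted pathogenic but in a gene outside the
#'   actionable panel: fails the panel filter.
#'
#' @param n_common_pathogenic_annotated,n_rare_benign,n_vus,n_low_qc,n_off_panel
#'   Record counts (all >= 0).
#' @return A named list of class `background_spec`.
#' @export
background_spec <- function(n_common_pathogenic_annotated = 6,
                            n_rare_benign = 8,
                            n_vus = 8,
                            n_low_qc = 6,
                            n_off_panel = 12) {
  spec <- list(
    n_common_pathogenic_annotated = n_common_pathogenic_annotated,
    n_rare_benign = n_rare_benign,
    n_vus = n_vus,
    n_low_qc = n_low_qc,
    n_off_panel = n_off_panel
  )
  if (any(unlist(spec) < 0)) abort_validation("background counts must be >= 0")
  structure(spec, class = "background_spec")
}

#' Load a spike specification table
#'
#' The spike table lists the variants to embed: normalized key, gene,
#' consequence, assertion, evidence codes, HGVS strings, the number of
#' distinct carrier samples, and the spiked zygosity. The packaged default
#' is the reference catalogue of 19 pathogenic/likely-pathogenic variants
#' across 12 actionable genes, with carrier counts summing to 24.
#'
#' @param path TSV path; defaults to the packaged reference spike table.
#' @return Tibble of spike entries.
#' @export
load_spike_spec <- function(path = secfindr_extdata("reference_spike_spec.tsv")) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    pos = readr::col_integer(), n_carriers = readr::col_integer(),
    .default = readr::col_character()
  ), progress = FALSE)
  required <- c("chrom", "pos", "ref", "alt", "gene", "consequence",
                "assertion", "evidence_codes", "n_carriers", "zygosity")
  missing <- setdiff(required, names(tbl))
  if (length(missing)) {
    abort_format(sprintf("spike spec missing column(s): %s",
                         paste(missing, collapse = ", ")))
  }
  tbl
}

#' Simulate adversarial background variation
#'
#' Generates the background records described by a [background_spec()]:
#' site definitions, carrier genotypes, assertion/frequency annotation rows,
#' and truth-table rows naming the single cascade stage each record fails.
#' On-panel background sites are placed on the chromosomes of the spiked
#' genes at offsets near the spiked positions; off-panel sites go to a
#' non-panel gene. Generation is a pure function of (arguments, RNG state):
#' callers seed the RNG (see [build_reference_fixture()]).
#'
#' @param n_samples Cohort size.
#' @param spec A `background_spec`.
#' @param spike Spike table ([load_spike_spec()]) supplying panel loci.
#' @param sample_ids Cohort sample IDs.
#' @return List with tibbles `variants` (key + gene + consequence +
#'   assertion + evidence), `carriers` (per-(variant, sample) genotype
#'   metrics), `frequencies` (key + per-source columns), and `truth`
#'   (key + class + expected stage label).
#' @export
simulate_background <- function(n_samples, spec = background_spec(),
                                spike = load_spike_spec(),
                                sample_ids = sprintf("S%03d", seq_len(n_samples))) {
  stopifnot(inherits(spec, "background_spec"))
  loci <- spike |>
    group_by(gene = .data$gene) |>
    summarise(chrom = .data$chrom[1], anchor = min(.data$pos), .groups = "drop")

  used <- key_id(spike)
  used_pos <- paste(spike$chrom, spike$pos)
  bases <- c("A", "C", "G", "T")

  new_site <- function(on_panel) {
    repeat {
      if (on_panel) {
        g <- loci[sample.int(nrow(loci), 1L), ]
        chrom <- g$chrom
        gene <- g$gene
        pos <- g$anchor + sample(500:50000, 1L)
      } else {
        chrom <- "2"
        gene <- "TTN"
        pos <- sample.int(150000000L, 1L) + 1000000L
      }
      if (!paste(chrom, pos) %in% used_pos) {
        used_pos <<- c(used_pos, paste(chrom, pos))
        ref <- sample(bases, 1L)
        alt <- sample(setdiff(bases, ref), 1L)
        return(tibble(chrom = chrom, pos = as.integer(pos), ref = ref,
                      alt = alt, gene = gene))
      }
    }
  }

  classes <- c(
    rep("common_pathogenic", spec$n_common_pathogenic_annotated),
    rep("rare_benign", spec$n_rare_benign),
    rep("vus", spec$n_vus),
    rep("low_qc", spec$n_low_qc),
    rep("off_panel", spec$n_off_panel)
  )
  if (!length(classes)) {
    empty <- tibble(chrom = character(), pos = integer(), ref = character(),
                    alt = character(), gene = character())
    return(list(
      variants = mutate(empty, consequence = character(), assertion = character(),
                        evidence_codes = character(), hgvs_c = character(),
                        hgvs_p = character()),
      carriers = empty_calls(),
      frequencies = mutate(empty[0, 1:4],
                           dbsnp = double(), gnomad = double(), inhouse = double()),
      truth = mutate(empty, class = character(), expected = character())
    ))
  }

  sites <- bind_rows(map(classes != "off_panel", new_site))
  sites$class <- classes

  # force one multi-allelic pair: the second rare_benign site reuses the
  # first one's position and ref with the remaining alt base
  rb <- which(classes == "rare_benign")
  if (length(rb) >= 2L) {
    i <- rb[1]; j <- rb[2]
    sites$chrom[j] <- sites$chrom[i]
    sites$pos[j] <- sites$pos[i]
    sites$ref[j] <- sites$ref[i]
    sites$alt[j] <- sample(setdiff(bases, c(sites$ref[i], sites$alt[i])), 1L)
    sites$gene[j] <- sites$gene[i]
  }

  sites <- sites |>
    mutate(
      consequence = "missense",
      assertion = case_when(
        .data$class %in% c("common_pathogenic", "low_qc", "off_panel") ~ "pathogenic",
        .data$class == "vus" ~ "vus",
        .default = NA_character_
      ),
      evidence_codes = case_when(
        .data$class %in% c("common_pathogenic", "low_qc", "off_panel") ~ "PS3,PM2,PP3,PP5",
        .data$class == "vus" ~ "PM2,PP3",
        .default = NA_character_
      ),
      hgvs_c = NA_character_, hgvs_p = NA_character_
    )
  benign_labels <- c("benign", "likely_benign", "conflicting")
  is_rb <- sites$class == "rare_benign"
  sites$assertion[is_rb] <- sample(benign_labels, sum(is_rb), replace = TRUE)
  sites$evidence_codes[is_rb] <- ifelse(sites$assertion[is_rb] == "benign",
                                        "BA1,BP4", "BS1,BP4")

  carriers <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    cls <- sites$class[i]
    n_car <- switch(cls,
                    common_pathogenic = sample(5:25, 1L),
                    sample(1:3, 1L))
    # samples already carrying another allele of the same site are excluded
    # so a genotype never spans two background records
    prior <- bind_rows(carriers[seq_len(i - 1L)])
    taken <- if (nrow(prior)) {
      prior$sample_id[prior$chrom == sites$chrom[i] & prior$pos == sites$pos[i]]
    } else {
      character()
    }
    pool <- setdiff(sample_ids, taken)
    who <- sample(pool, min(n_car, length(pool)))
    g <- if (cls == "low_qc") {
      bad_genotypes(length(who))
    } else {
      good_genotypes(length(who))
    }
    carriers[[i]] <- bind_cols(
      sites[rep(i, length(who)), c("chrom", "pos", "ref", "alt")],
      tibble(sample_id = who, zygosity = "het"), g
    )
  }
  carriers <- bind_rows(carriers)

  freq <- sites[, c("chrom", "pos", "ref", "alt", "class")] |>
    mutate(
      dbsnp = ifelse(.data$class == "common_pathogenic",
                     runif(n(), 0.02, 0.25),
                     ifelse(runif(n()) < 0.5, runif(n(), 0, 0.005), NA_real_)),
      gnomad = ifelse(.data$class == "common_pathogenic",
                      runif(n(), 0.02, 0.25), runif(n(), 0, 0.005)),
      inhouse = ifelse(runif(n()) < 0.5, runif(n(), 0, 0.008), NA_real_)
    ) |>
    select(-"class")

  truth <- sites |>
    mutate(expected = recode(.data$class,
                             common_pathogenic = "fails:frequency",
                             rare_benign = "fails:assertion",
                             vus = "fails:assertion",
                             low_qc = "fails:genotype_qc",
                             off_panel = "fails:panel")) |>
    select("chrom", "pos", "ref", "alt", "gene", "class", "expected")

  list(variants = select(sites, -"class"), carriers = carriers,
       frequencies = freq, truth = truth)
}

good_genotypes <- function(n) {
  dp <- sample(20:120, n, replace = TRUE)
  ratio <- runif(n, 0.35, 0.65)
  alt_depth <- as.integer(round(dp * ratio))
  tibble(depth = as.integer(dp), gq = sample(60:99, n, replace = TRUE),
         ref_depth = as.integer(dp - alt_depth), alt_depth = alt_depth)
}

# each bad genotype violates exactly one QC criterion
bad_genotypes <- function(n) {
  mode <- sample(c("low_dp", "low_gq", "bad_ratio"), n, replace = TRUE)
  dp <- ifelse(mode == "low_dp", sample(5:14, n, replace = TRUE),
               sample(30:80, n, replace = TRUE))
  gq <- ifelse(mode == "low_gq", sample(2:19, n, replace = TRUE),
               sample(60:99, n, replace = TRUE))
  ratio <- ifelse(mode == "bad_ratio",
                  sample(c(0.1, 0.9), n, replace = TRUE),
                  runif(n, 0.4, 0.6))
  alt_depth <- as.integer(round(dp * ratio))
  tibble(depth = as.integer(dp), gq = as.integer(gq),
         ref_depth = as.integer(dp - alt_depth), alt_depth = alt_depth)
}

#' Build the reference synthetic fixture
#'
#' Generates a complete, deterministic pipeline input set: a multi-sample
#' VCF spiking each catalogued variant heterozygous into its catalogued
#' number of distinct carrier samples (no sample receives two spiked
#' variants; spiked genotypes always pass QC), plus adversarial background,
#' the matching assertion and frequency TSVs, and the truth table. With the
#' packaged defaults this reproduces the reference study design: 19
#' variants in 24 distinct carriers within a 280-sample cohort.
#'
#' Identical `(spec, seed)` give byte-identical output files; a different
#' seed permutes sample assignments and background but never the spiked
#' (variant, carrier-count) multiset.
#'
#' @param n_samples Cohort size (>= total spiked carriers).
#' @param seed Integer seed driving all randomness.
#' @param out_dir Directory for the fixture files.
#' @param spike Spike table ([load_spike_spec()]).
#' @param background A [background_spec()].
#' @return List with paths `vcf`, `assertions`, `frequencies`, `truth_path`,
#'   plus tibbles `truth` and `sample_ids`.
#' @export
build_reference_fixture <- function(n_samples = 280, seed = 1,
                                    out_dir = tempfile("sf_fixture_"),
                                    spike = load_spike_spec(),
                                    background = background_spec()) {
  total_spiked <- sum(spike$n_carriers)
  if (n_samples < total_spiked) {
    abort_validation(sprintf(
      "n_samples (%d) is smaller than the %d spiked carriers", n_samples,
      total_spiked))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sample_ids <- sprintf("S%03d", seq_len(n_samples))

  with_seed(seed, {
    # one finding per individual: carriers drawn without replacement
    chosen <- sample(sample_ids, total_spiked)
    idx <- rep(seq_len(nrow(spike)), spike$n_carriers)
    spike_carriers <- bind_cols(
      spike[idx, c("chrom", "pos", "ref", "alt")],
      tibble(sample_id = chosen, zygosity = spike$zygosity[idx]),
      good_genotypes(total_spiked)
    )

    bg <- simulate_background(n_samples, background, spike, sample_ids)

    variants <- bind_rows(
      spike |> select("chrom", "pos", "ref", "alt", "gene", "consequence",
                      "assertion", "evidence_codes", "hgvs_c", "hgvs_p"),
      bg$variants
    )
    carriers <- bind_rows(spike_carriers, bg$carriers)

    spike_freq <- spike[, c("chrom", "pos", "ref", "alt")] |>
      mutate(
        dbsnp = ifelse(runif(n()) < 0.4, runif(n(), 0, 0.004), NA_real_),
        gnomad = ifelse(runif(n()) < 0.7, runif(n(), 0, 0.005), NA_real_),
        inhouse = ifelse(runif(n()) < 0.6, runif(n(), 0, 0.008), NA_real_)
      )
    frequencies <- bind_rows(spike_freq, bg$frequencies)

    truth <- bind_rows(
      spike_carriers |>
        mutate(gene = spike$gene[idx], class = "spike", expected = "survives") |>
        select("chrom", "pos", "ref", "alt", "gene", "sample_id", "class",
               "expected"),
      bg$truth |> mutate(sample_id = NA_character_) |>
        select("chrom", "pos", "ref", "alt", "gene", "sample_id", "class",
               "expected")
    )

    vcf_path <- file.path(out_dir, "cohort.vcf")
    write_fixture_vcf(variants, carriers, sample_ids, vcf_path)

    assertion_path <- file.path(out_dir, "assertions.tsv")
    variants |>
      filter(!is.na(.data$assertion)) |>
      arrange(chrom_rank(.data$chrom), .data$pos, .data$alt) |>
      readr::write_tsv(assertion_path, na = "", progress = FALSE)

    frequency_path <- file.path(out_dir, "frequencies.tsv")
    frequencies |>
      arrange(chrom_rank(.data$chrom), .data$pos, .data$alt) |>
      readr::write_tsv(frequency_path, na = "", progress = FALSE)

    truth_path <- file.path(out_dir, "truth.tsv")
    readr::write_tsv(truth, truth_path, na = "", progress = FALSE)

    list(vcf = vcf_path, assertions = assertion_path,
         frequencies = frequency_path, truth_path = truth_path,
         truth = truth, sample_ids = sample_ids)
  })
}

chrom_rank <- function(chrom) {
  suppressWarnings(num <- as.integer(chrom))
  num[chrom == "X"] <- 23L
  num[chrom == "Y"] <- 24L
  num[is.na(num)] <- 25L
  num * 1e9 + as.integer(factor(chrom))
}

#' Write a fixture VCF
#'
#' Serializes site records and carrier genotypes into a valid VCF 4.2 file
#' with `GT:DP:GQ:AD` genotype fields. Records sharing (chrom, pos, ref)
#' are emitted as one multi-allelic line with per-allele AD entries.
#' Non-carrier samples get a constant well-formed hom-ref genotype. The
#' file round-trips through [read_cohort_vcf()] at the data-model level.
#'
#' @param variants Tibble of biallelic records: `chrom`, `pos`, `ref`, `alt`.
#' @param carriers Tibble of carrier genotypes: key columns plus
#'   `sample_id`, `zygosity`, `depth`, `gq`, `ref_depth`, `alt_depth`.
#' @param sample_ids Cohort sample IDs (VCF column order).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fixture_vcf <- function(variants, carriers, sample_ids, path) {
  variants <- as_tibble(variants)
  ord <- order(chrom_rank(variants$chrom), variants$pos, variants$alt)
  if (!identical(ord, seq_len(nrow(variants)))) {
    variants <- variants[ord, , drop = FALSE]
  }
  sites <- variants |>
    group_by(.data$chrom, .data$pos, .data$ref) |>
    summarise(alts = list(unique(.data$alt)), .groups = "drop") |>
    arrange(chrom_rank(.data$chrom), .data$pos)

  header <- c(
    "##fileformat=VCFv4.2",
    "##source=secfindr_synthetic_cohort",
    paste0("##contig=<ID=", unique(sites$chrom), ">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t")
  )

  carrier_key <- paste(carriers$chrom, carriers$pos, carriers$ref,
                       carriers$alt, carriers$sample_id)
  lines <- character(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    alts <- s$alts[[1]]
    n_alt <- length(alts)
    gts <- rep(paste0("0/0:40:99:", paste(c(40L, rep(0L, n_alt)), collapse = ",")),
               length(sample_ids))
    for (a in seq_len(n_alt)) {
      hit <- carriers[carriers$chrom == s$chrom & carriers$pos == s$pos &
                        carriers$ref == s$ref & carriers$alt == alts[a], ,
                      drop = FALSE]
      if (!nrow(hit)) next
      si <- match(hit$sample_id, sample_ids)
      if (any(is.na(si))) abort_validation("carrier sample not in sample_ids")
      gt_code <- ifelse(hit$zygosity == "hom_alt", paste0(a, "/", a),
                        ifelse(hit$zygosity == "hemizygous", as.character(a),
                               paste0("0/", a)))
      ad <- vapply(seq_len(nrow(hit)), function(k) {
        v <- rep(0L, n_alt + 1L)
        v[1] <- hit$ref_depth[k]
        v[a + 1L] <- hit$alt_depth[k]
        paste(v, collapse = ",")
      }, character(1))
      gts[si] <- paste(gt_code, hit$depth, hit$gq, ad, sep = ":")
    }
    lines[i] <- paste(c(s$chrom, s$pos, ".", s$ref, paste(alts, collapse = ","),
                        "50", "PASS", ".", "GT:DP:GQ:AD", gts), collapse = "\t")
  }
  writeLines(c(header, lines), path)
  invisible(path)
}
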