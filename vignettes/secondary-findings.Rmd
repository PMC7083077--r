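---
title: "Triage of actionable secondary findings: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triage of actionable secondary findings: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(secfindr)
```

## The problem

When a cohort is exome-sequenced for diagnostic purposes, the data inevitably
contain findings unrelated to the indication for testing. A subset of these —
pathogenic variants in genes whose associated conditions respond to medical
intervention — are deliberately sought and reported as *secondary findings*.
The accepted scope for this search is the ACMG list of 59 medically
actionable genes covering hereditary cancer syndromes, cardiomyopathies and
arrhythmias, aortopathies/connective-tissue disease, familial
hypercholesterolemia, malignant hyperthermia, Wilson disease and a few
others. secfindr implements the complete downstream workflow for such a
screen — from a jointly-called multi-sample VCF to per-individual reportable
findings and cohort prevalence statistics — as small, composable,
tibble-in/tibble-out functions.

Variant calling itself (alignment, deduplication, recalibration, joint
genotyping) is out of scope: the pipeline starts at a called VCF, the way a
clinical bioinformatician receives one.

## The filter cascade

`run_cascade()` applies five filters in a fixed order and logs survivor
counts (distinct variants, and carrier genotypes) after each stage:

1. **Panel membership** — the variant's annotated gene symbol must resolve
   in the 59-gene registry (`load_gene_table()`).
2. **Consequence** — only protein-altering classes are kept: stop
   gain/loss, start loss, frameshift, canonical splice site, positions
   within ten bases of an exon boundary, inframe indels, and missense.
3. **Frequency** — the variant must be *strictly below* 1% in every
   frequency source that has a record for it (the threshold applies to all
   sources present, however many there are). A variant with no record in
   any source is kept: novel variants have no frequency, and dropping them
   would defeat the rare-variant intent of the screen.
4. **Assertion** — only variants asserted pathogenic or likely pathogenic
   in the (frozen, table-based) clinical archive are kept. VUS,
   conflicting, benign-side and absent assertions all fail. The archive is
   consumed as a versioned flat TSV rather than a live query, so results
   are reproducible offline.
5. **Genotype QC** — each carrier genotype must have depth ≥ 15 and
   genotype quality ≥ 20, and an allele balance (alt reads over
   allele-informative reads, AD-based rather than DP-based) inside
   [0.30, 0.70] for heterozygotes or strictly above 0.85 for
   homozygous-alternate and hemizygous calls. A variant survives only if at
   least one carrier passes.

The four variant-level filters are pure predicates, so the surviving set is
order-invariant; the fixed order exists only to make the stage log
reproducible and comparable across runs.

Boundary semantics are deliberate: "lower than 15/20" reads as a strict
drop below the cutoff, so DP = 15 and GQ = 20 pass; the het window
"between 0.3 and 0.7" is taken inclusive at both ends (the inclusive choice
is ours — the wording does not settle it); "above 0.85" is strict. A
carrier genotype missing DP, GQ or AD fails QC outright: the purpose of the
stage is artifact removal, and an unknowable metric cannot certify a call.

## The evidence-combining engine

`classify_evidence()` implements the 2015 ACMG-AMP combining criteria over
the 28 evidence codes (PVS1; PS1–PS4; PM1–PM6; PP1–PP5; BA1; BS1–BS4;
BP1–BP7), producing the five-tier verdict and the label of the rule that
fired, for auditability. Codes are taken at printed strength; strength
modification (e.g. a PM used at supporting level) is not supported because
the packaged catalogue never uses it.

Contradictory evidence is handled at the *combination* level: a verdict is
uncertain (`vus`) only when complete combinations fire on both the
pathogenic and the benign side. Lone benign-side codes that complete no
benign combination do not force a conflict — the packaged catalogue
contains pathogenic conclusions for rows carrying a stray BS2 or BP4, which
is consistent only with this reading. A `strict` mode flags any mixed-side
evidence in the fired-rule label (without changing the verdict) for
sensitivity analysis.

One catalogued row is internally inconsistent with the combining rules:
the ATP7B p.P1273L record carries PS3 PM1 PM2 PP3 PP5 with a recorded
conclusion of likely pathogenic, yet one strong + two moderate + ≥ two
supporting combines to pathogenic — and the catalogue's MUTYH p.P295L row,
with the same multiset shape (PS3 PM2 PM3 PP3 PP5), is recorded pathogenic.
The engine follows the combining rules, so `verify_table()` over the
19-row catalogue reports 18/19 concordant and names that row. We chose not
to special-case it: a classification engine that silently reproduces an
inconsistent label would be worse than one that flags it. The cohort
statistics are unaffected, because the filter cascade keys on the archive's
assertion labels, not on engine verdicts.

## Inheritance-aware reporting

`assign_reporting_status()` maps each surviving finding, per sample and
gene, to a reporting status using the registry's inheritance mode:

* autosomal-dominant gene, het or hom-alt → `dominant_reportable`;
* X-linked dominant, any carrier zygosity → `xl_reportable`;
* X-linked recessive, hemizygous or hom-alt → `xl_reportable`; het →
  `xl_carrier`;
* autosomal-recessive, hom-alt **or** two or more distinct het variants in
  the same gene and sample → `recessive_biallelic_reportable`; a compound
  het inferred this way is flagged `phase_unknown`, since exome data
  without trios cannot establish phase;
* autosomal-recessive, single het → `recessive_carrier`.

Following the guideline recommendation to return only biallelic variants
in the recessive panel genes (MUTYH, ATP7B), `write_reports()` excludes
carrier-status rows from the clinical findings file by default while
keeping them in the cohort summary; `report_carriers = TRUE` includes them,
which is the defensible choice in populations with high consanguinity where
carrier information has direct family value.

`summarize_cohort()` carries every proportion as an exact fraction plus a
display string rounded to two significant figures with trailing zeros
trimmed (so 17/280 displays as "6.1", 6/280 as "2.1", 7/280 as "2.5").
`prevalence_ratio(count, n)` renders the conventional 1:k form with
k = round(n/count), and `fold_increase()` reports the exact prevalence
ratio alongside a configurable display rounding — e.g. a 1:70 cohort
prevalence against a 1:2500 reference is exactly 35.71-fold, displayed as
36 at the default integer rounding (nearest-integer; sources that floor
would print 35).

## The synthetic cohort generator

No real cohort ships with the package. `build_reference_fixture()`
regenerates the study design the package targets: each of the 19 catalogued
pathogenic/likely-pathogenic variants (across 12 panel genes) is spiked
heterozygous into its catalogued number of distinct carrier samples — 24
carriers in all, at most one spiked variant per individual — inside a
280-sample cohort by default. Spiked genotypes are drawn to sit safely
inside the QC windows (DP uniform on 20–120, covering the ~80× depths
typical of exome calls; allele balance uniform on 0.35–0.65; GQ 60–99):
the fixture exercises the cascade's logic, while boundary behaviour is
pinned by unit tests.

Around the spikes, `simulate_background()` adds adversarial records each
engineered to fail exactly one cascade stage — common-but-asserted-
pathogenic (frequency), rare benign/conflicting (assertion), VUS
(assertion), pathogenic with only QC-failing carriers (genotype QC), and
off-panel (panel) — with defaults of 6/8/8/6/12 records, enough to hit
every stage while keeping full-cohort generation and analysis in seconds.
Two background records always share a site as a multi-allelic pair, so
decomposition is exercised on every fixture. A truth table listing every
spiked (sample, variant) and every background record's expected failure
stage ships with each fixture and is the oracle the test suite compares
pipeline output against.

Everything is a pure function of (specification, seed): identical seeds
give byte-identical files; different seeds permute sample assignments and
background but never the spiked (variant, carrier-count) multiset, which is
why the headline counts (24/19/17/7…) are seed- and cohort-size-invariant
while cohort-denominator proportions scale.

What the generator does *not* emulate: linkage structure, relatedness,
site-level FILTER annotations, sequencing error profiles, CNVs, or real
exon coordinates (background positions are offsets near the catalogued
ones; consequence classes are assigned in the annotation table, not derived
from transcript models — allele strings for the catalogued indels are
likewise encoded from the cDNA description, not from genome sequence).
Passing tests therefore demonstrate the correctness of the triage logic on
well-formed calls, not robustness to upstream calling artifacts beyond the
QC metrics modelled.

## Worked example

```{r example, eval = FALSE}
fx <- build_reference_fixture(n_samples = 280, seed = 1)
res <- run_pipeline(fx$vcf, fx$assertions, fx$frequencies,
                    out_dir = "reports")
glance(res)       # headline counts and proportions
tidy(res)         # per-gene individual counts
autoplot(res)     # findings by disease category
plot_stage_counts(res)
```

## Problem sizes and numerical choices

The test suite runs the full pipeline at cohort sizes 280 (reference
design), 60 (shared small fixture) and 40/30 (property sweeps); the
evidence engine is checked exhaustively against an independent oracle over
all evidence multisets with up to three codes per strength class (4096
cases), and the cascade against a brute-force per-(variant, sample) oracle
on random cohorts of up to 5 samples × 50 variants. These sizes were chosen
so the whole suite completes in well under a minute per component while
still covering every code path; the statistics computed are count-exact, so
larger simulations would add nothing.

Ties and degenerate inputs: an allele-informative read count of zero makes
the alt ratio undefined (and the genotype fails QC); an empty VCF yields a
valid empty result with all-zero stage counts; absence — of a gene in the
registry, an assertion, a frequency record — is everywhere a value, never
an error.

## Known limitations

* Consequence classes are trusted from the annotation input; there is no
  transcript-model re-annotation.
* HGVS strings are opaque display text, not parsed or validated.
* Sex is not modelled; haploid genotypes mark hemizygosity directly.
* CNVs and structural variants are out of scope, as is any live database
  access.
* The 59-gene panel is packaged as printed in its source catalogue,
  including transcript versions that differ from current RefSeq.
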