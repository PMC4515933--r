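---
title: "Methods: variant prioritisation, internal-database filtering and coverage QC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variant prioritisation, internal-database filtering and coverage QC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelTriage)
```

## Scope and model

`panelTriage` implements the analysis layer that sits between an upstream
variant-calling/annotation pipeline and the clinical curator. It consumes
the pipeline's products — an annotated VCF per sample, per-base coverage
over the capture target, per-sample QC metrics — and produces what a
curator needs: a ranked, filtered variant list, an LOVD3-compatible
export, three-level coverage reports, automated sample gates and a
provenance manifest. Alignment, variant calling and annotation themselves
are out of scope by design: the package assumes those are handled by
standard tooling and treats their outputs as the contract.

### Variant Priority Index (VPI)

Variants are placed into four tiers from the combination of predicted
impact, population rarity and conservation:

* **VPI 1 ("rare")** — missense or in-frame indel with allele frequency
  below 0.01 in *every* population database annotated (EVS, 1000
  Genomes, ExAC). Because the condition must hold in all databases, the
  implementation compares the **maximum** of the available frequencies
  against the threshold.
* **VPI 2 ("very rare or novel")** — as VPI 1 but with maximum frequency
  below 0.0005. A variant absent from all three databases is treated as
  novel and counts as below every threshold. This is deliberate: an
  absent annotation is *lack of evidence of commonness*, and zero-filling
  it would silently demote genuinely novel variants.
* **VPI 3 ("very rare and conserved")** — VPI 2 plus Condel score
  strictly above 0.07. An absent Condel score never reaches tier 3
  (conservation unproven) but remains eligible for tier 2. The 0.07
  cut-off is unusually low for Condel; it is the documented default and
  is configurable per profile (`condel_threshold`).
* **VPI 4** — frameshift, truncating or splice-site variants, including
  intronic variants within the profile's splice window. Tier 4 ignores
  population frequency by default: the tier definition is purely
  consequence-based. Whether the frequency cut should also apply to
  tier 4 is genuinely open; we chose not to apply it (a common
  "frameshift" is more often an annotation artefact worth seeing than a
  benign variant worth hiding) and expose `apply_af_to_vpi4 = true` for
  sites that disagree.

Tiers 1–3 are nested by construction and all inequalities are strict
(`< 0.01`, `< 0.0005`, `> 0.07`), exactly as documented — a variant at
frequency exactly 0.01 is not rare, a Condel of exactly 0.07 is not
conserved. Variants below VPI 1 are hidden from the result set (with a
machine-readable reason, never silently).

### Gene Priority Index (GPI)

Genes carry an a-priori category per profile: 1 for any gene in the
analysis target, 2 for genes known causal for the patient group, 3 for
in-silico prioritised genes, 4 for clinician-nominated genes. Exclusion
dominates everything; among inclusions the **maximum** category wins.
The maximum is the curator-favourable choice: when lists disagree, the
variant sorts higher rather than lower. Symbols are compared
case-insensitively after trimming; no alias resolution is attempted
(HGNC synonym handling belongs upstream). Category 2–4 lists are clamped
to the target universe with a warning, since the categories are
progressive refinements of "in the analysis".

### Report ordering

Retained variants sort by VPI descending, then GPI descending, then
chromosome in karyotype order (1–22, X, Y, MT, others last), position,
and alternate allele. The sort is stable and permutation-invariant, which
the reproducibility contract depends on.

## Analysis profiles

A profile is a flat `key=value` text file — deliberately the simplest
format a laboratory can audit and version. Gene lists may be inline or
one-symbol-per-line sidecar files (LF or CRLF). Unknown keys are
*collected, not rejected*: sites add custom settings without forking the
parser. Defaults: rare 0.01, very rare 0.0005, Condel 0.07, coverage QC
threshold 15×, splice window 2 bp (the canonical splice donor/acceptor
dinucleotides; sites wanting broader near-splice capture typically raise
it to 5–10 bp). Sample-gate limits (median coverage, fragment-size
range, duplicate rate, FASTQC metrics) have **no** defaults: an
unconfigured gate reports `SKIPPED` rather than inventing a limit.

## Internal variant-observation database

Every analysed sample's variants are recorded (presence only, no
genotypes) in a single-file SQLite store keyed by canonicalised
`(chrom, pos, ref, alt)`. Recurrence across samples from *different*
disease cohorts marks private population variants and pipeline
artefacts — a variant truly causal for one phenotype should not recur
across unrelated phenotypes. The exclusion policy has two arms:

* cohort arm — exclude when seen in at least `db_min_other_cohort_samples`
  samples from other cohorts (default 3; there is no published value, so
  the default was chosen once as the smallest count that cannot be
  produced by a single recurrent family plus one coincidence);
* frequency arm — exclude when the internal observation frequency
  exceeds `db_max_internal_frequency` (disabled by default; whether
  internal frequency should count per-cohort or overall is not settled,
  so the overall-frequency arm ships off).

The policy never fires with fewer than two registered samples, and a
sample's own previous observations are excluded from its query — without
that rule every variant would filter itself at its second analysis.
Re-registering a sample replaces its prior contribution, so re-analysis
is idempotent. The store is the *only* quantity that legitimately drifts
between re-analyses; archiving a snapshot (byte copy plus JSON manifest
with an MD5 digest) before each analysis pins it, and the package
guarantees byte-identical reports from a restored snapshot in
no-timestamp mode.

## Allele canonicalisation

VCF representations of the same indel differ by padding. Keys are
canonicalised by trimming shared leading context first (advancing the
position), then shared trailing context, always keeping at least one
base per allele: `pos 100 CTT>CT` becomes `pos 101 TT>T`. Any two padded
representations of the same allele reduce to the same key, which is the
property the observation store requires and the property the tests
enforce. Full left-alignment across repeat tracts would need the
reference genome, which the VCF-only contract does not provide; variants
emitted by a single upstream caller are internally consistent, so
context trimming suffices for key identity. Symbolic alleles (`<DEL>`,
breakends) pass through untouched with consequence `OTHER` and a flag.

Coordinates follow one rule everywhere: VCF and in-memory positions are
1-based, BED and report gap coordinates are 0-based half-open, and all
conversions happen at the file boundaries only.

## Coverage QC

Three reports at increasing resolution, all driven by one configurable
depth threshold (default 15×):

* **Gap report** — maximal runs of bases with depth strictly below the
  threshold (`depth == threshold` is covered), with length, minimum and
  median depth, annotated with overlapping gene/exon.
* **Exon report** — per exon, the fraction of bases below threshold and
  a status: `FULL` (none below), `NONE` (all below), else `PARTIAL`.
  Bases in the exon model but absent from the coverage file count as
  depth 0 — sequencing dropout is a finding, not a parse error (one
  warning is raised).
* **Gene report** — traffic-light colours: `GREEN` requires at least
  95 % of targeted bases covered *and* no entirely-uncovered exon (a
  `NONE` exon vetoes green even at high overall coverage — a missed exon
  is exactly what a curator must not overlook); `AMBER` at ≥ 80 %;
  `RED` below. The 0.95/0.80 defaults are our choice — no published
  definition of "potentially unsatisfactory" exists — and both are
  profile-configurable.

Medians use the lower-median convention (even-length input takes the
lower middle value), so a reported median is always an observed depth.
Within each exon the summed overlapping gap lengths equal the
below-threshold base count as an exact integer identity; the test suite
asserts this on randomised fixtures.

## Sample checks

Five automated gates: FASTQC summary metrics (fails iff any
profile-listed metric reports FAIL), median coverage (strictly below the
limit fails), median fragment size (inclusive range: a value exactly at
either bound passes), duplicate rate (strictly above the maximum fails),
and sex consistency. No method for the sex check is prescribed anywhere,
so the package infers sex from capture coverage: with
`rx = mean X depth / mean autosomal depth` and `ry` likewise for Y,
`MALE` requires `ry ≥ 0.2` and `rx ≤ 0.8`; `FEMALE` requires
`ry < 0.05` and `rx ≥ 0.8`; anything else is `UNKNOWN`. The wide dead
zone is deliberate for a clinical gate: a borderline ratio should
withhold the call (→ `SKIPPED` comparison), never force a wrong one.
With ±10 % noise on ideal male (0.5/0.5) and female (1.0/~0) ratios the
call is always correct; ratios placed inside the dead zone always return
`UNKNOWN`. The overall sample verdict fails iff any individual check
fails; skipped checks never fail a sample.

## Outputs and provenance

The curation "spreadsheet" is realised as CSV with a fixed column order;
the LOVD3-compatible CSV carries identical information under LOVD-style
column names, row for row. Absent annotations are empty cells, never 0.
Frequencies print with 6 fixed decimals so output is byte-stable across
platforms. The provenance manifest records path, byte size and MD5
digest of every input and output plus the full effective profile; in
no-timestamp mode two runs on identical inputs produce byte-identical
manifests. Batch directories follow a fixed layout in which design files
are copied once at first run and never modified after, and all computed
results stay under `analysis/`.

## The synthetic-data generator

`generateBatch()` emulates the *outputs* of an upstream pipeline, not
the pipeline itself: annotated VCFs with synthesised INFO fields,
piecewise-constant per-base coverage with planted dropouts, metrics with
coverage-derived sex ratios. Defaults describe a small production batch:
12 samples across four cohorts, a 10-gene panel (8 exons × 150 bp),
~2,000 common background variants per sample, planted variants covering
every tier and filter reason, three planted coverage dropouts and one
declared-sex mismatch. Reference bases are a deterministic function of
position so the same site yields the same variant key in every sample.
Background noise on coverage is clamped at the QC threshold (guard
band), keeping planted gap coordinates exact. The expected VPI/GPI in
`truth.json` are computed by a separate literal restatement of the tier
rules inside the generator, not by calling the package's assignment
functions.

What the generator does **not** emulate — and therefore what passing
tests do not show about real data: read-level error models, mapping
artefacts, multi-transcript consequence disagreement (the package keeps
the most severe class when an annotation carries several terms, a choice
flagged in the ingest documentation), population structure in the allele
frequencies, and relatedness between samples. The package targets
single, unrelated samples; family-aware analysis is out of scope.

## Numerical and degenerate-input choices

* Strict inequalities on all tier thresholds; inclusive fragment-size
  bounds; duplicate rate fails only strictly above its maximum.
* Empty exon set → splice classification is `FALSE` with a warning;
  zero splice window classifies nothing.
* Empty record sets produce valid header-only CSVs ("no reportable
  variants" is a result, not an error).
* Missing depth/quality on a variant is treated as unknown and does not
  trip the depth/quality gates; missing population AF is novel.
* Coverage parsing is strict where silence would corrupt results:
  non-contiguous per-base offsets and negative depths are errors with
  line numbers.
* Test and example problem sizes (500 random tracks for the gap oracle,
  100-case simulations, a 12-sample batch) were chosen as the smallest
  sizes that still exercise every boundary; all randomised tests run
  under fixed seeds.
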