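# panelTriage

Clinical variant prioritisation, cohort-aware artefact filtering,
coverage QC and curation-ready reporting for targeted gene panels and
diagnostic exomes.

A diagnostic laboratory's bioinformatic pipeline ends with a person: a
curator who must decide, per patient, which of tens of thousands of
called variants deserve clinical consideration. `panelTriage`
implements the layer that makes that job tractable. It consumes the
standard outputs of an upstream pipeline — annotated VCFs (population
allele frequencies, Condel scores, transcript consequences), per-base
coverage over the capture target, and per-sample QC metrics — and
produces a ranked, filtered, reproducible variant report together with
coverage and sample-quality evidence.

## The core method

**Variant Priority Index (VPI).** Each variant lands in one of four
tiers (0 = hidden):

| tier | definition |
|------|------------|
| VPI 1 | "rare": missense / in-frame indel with AF < 0.01 in every population database (EVS, 1000G, ExAC) |
| VPI 2 | "very rare or novel": AF < 0.0005, or absent from all databases |
| VPI 3 | VPI 2 and "highly conserved": Condel > 0.07 |
| VPI 4 | frameshift, truncating or splice-site variants (including intronic variants within the profile's splice window) |

Tiers 1–3 are nested; all inequalities are strict; the AF condition must
hold in *all* databases, so the maximum annotated frequency is compared.

**Gene Priority Index (GPI).** Genes carry an a-priori category from the
per-sample analysis profile: 1 = in the target region, 2 = known causal
for the patient group, 3 = in-silico prioritised, 4 =
clinician-nominated; excluded genes are 0. Reports sort by
(VPI desc, GPI desc, karyotype position), putting the most promising
variants at the top.

**Internal observation database.** Every analysed sample's variants
accumulate in a single-file SQLite store. Variants recurring across
samples from *different disease cohorts* are private population variants
or pipeline artefacts, not plausible causal candidates, and are filtered
(default policy: seen in ≥ 3 samples from other cohorts). Snapshots of
the store make any past analysis exactly reproducible.

**Coverage QC.** Three reports per sample from per-base depth: a
base-pair-resolution gap report (maximal runs below a configurable
threshold, default 15×), an exon report (`FULL`/`PARTIAL`/`NONE`), and
a colour-coded gene report (`GREEN`/`AMBER`/`RED`).

**Sample gates.** FASTQC metric flags, median coverage, fragment-size
range, duplicate rate, and an X/Y-to-autosome depth-ratio sex check
against the declared sex. Any failing gate fails the sample.

## Worked example

The package ships a seeded generator that fabricates a complete batch
(annotated VCFs, coverage, BEDs, metrics, profile) with known truth:

```r
library(panelTriage)

batch <- file.path(tempdir(), "demo-batch")
spec  <- simulationSpec(seed = 11, nSamples = 4, backgroundVariantRate = 200)
generateBatch(spec, batch)

store <- createObservationStore(file.path(tempdir(), "site-observations.db"))
res <- runBatch(batch, file.path(batch, "profile.txt"),
                store = store, timestamp = FALSE)

head(res$retained[, c("sample_id", "gene", "vpi", "gpi", "chrom", "pos",
                      "ref", "alt", "consequence")], 5)
#>   sample_id   gene vpi gpi chrom    pos ref alt consequence
#> 1      S001 GENE05   4   4  chr2 181022  GT   G  FRAMESHIFT
#> 2      S002 GENE04   4   3  chr1 166151   T   C       OTHER
#> 3      S001 GENE03   4   3  chr3 145026   G   A  TRUNCATING
#> 4      S002 GENE02   3   2  chr2 122023   T   C    MISSENSE
#> 5      S003 GENE01   2   1  chr1 103024   A   G    MISSENSE
```

Row 1 is the planted frameshift in the clinician-nominated gene
(VPI 4 / GPI 4 — the most promising variant in the batch); row 2 is an
intronic variant caught by the 2 bp splice window (consequence `OTHER`,
promoted to VPI 4). All ~800 planted common background variants were
hidden:

```r
table(sub(",.*", "", res$removed$filter_reasons))
#>     GENE_EXCLUDED   GENE_OFF_TARGET HIDDEN_BELOW_VPI1
#>                 1                 1               807

res$checkVerdicts
#>   S001   S002   S003   S004
#> "PASS" "PASS" "PASS" "PASS"
```

Coverage QC on sample S001 finds exactly the two planted dropouts, and
the gene report flags the gene with an entirely uncovered exon:

```r
p     <- parseProfile(file.path(batch, "profile.txt"))
track <- readPerBaseCoverage(file.path(batch, "data", "S001.cov.tsv"), "S001")
exons <- readExonBed(file.path(batch, "data", "exons.bed"))
findGaps(track, coverageQcThreshold(p), exons)
#>   chrom  start    end length min_depth median_depth   gene exon_rank
#> 1  chr1 101050 101090     40         3            3 GENE01         2
#> 2  chr2 123000 123150    150         0            0 GENE02         4

gr <- geneReport(exonReport(track, exons, 15), track)
gr[gr$colour != "GREEN", ]
#>     gene median_depth fraction_targeted_bases_ok n_exons n_exons_partial_or_none colour
#> 5 GENE02           60                      0.875       8                       1  AMBER
```

`runBatch()` also wrote `variant_report.csv`, the LOVD3-compatible
`variants_lovd.csv`, a removed-variant audit file, per-sample QC TSVs
and a provenance manifest under `analysis/results/`. A command-line
wrapper is installed at `inst/scripts/panel-triage`
(`panel-triage run|qc|db|simulate ...`).

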