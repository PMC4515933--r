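#' @import methods
#' @importFrom S4Vectors mcols mcols<-
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom IRanges IntegerList
NULL

#' AnalysisProfile: per-sample analysis settings
#'
#' An `AnalysisProfile` bundles every setting that customises an analysis
#' for one patient group: the gene lists that drive the Gene Priority Index
#' (GPI), the allele-frequency and conservation thresholds that drive the
#' Variant Priority Index (VPI), the splice-site window, variant quality
#' gates, coverage-report thresholds and the internal-database filtering
#' policy. Profiles are predefined and validated once per patient group, so
#' that each diagnostic test configuration can be accredited independently.
#'
#' Gene symbols are stored upper-cased and trimmed; all membership tests are
#' case-insensitive. Thresholds use strict inequalities downstream
#' (frequency `< 0.01`, `< 0.0005`; Condel `> 0.07`).
#'
#' @slot name profile identifier (required).
#' @slot targetGenes genes in the capture/analysis target (GPI 1 universe).
#' @slot knownCausalGenes genes commonly known to be causal for the
#'   disease or patient group (GPI 2).
#' @slot insilicoGenes genes prioritised by in-silico tools (GPI 3).
#' @slot clinicianGenes genes nominated by the treating clinician (GPI 4).
#' @slot excludedGenes genes removed from the analysis regardless of any
#'   other membership.
#' @slot spliceWindowBp width (bp) of the window beyond exon boundaries in
#'   which an intronic variant is treated as a potential splice-site variant.
#' @slot minVariantCoverage minimum read depth for a reported variant.
#' @slot minVariantQual minimum variant quality for a reported variant.
#' @slot rareAfThreshold population AF below which a missense/in-frame
#'   variant is "rare" (VPI 1); default 0.01.
#' @slot veryRareAfThreshold AF below which it is "very rare" (VPI 2);
#'   default 0.0005.
#' @slot condelThreshold Condel score above which a very-rare variant is
#'   "highly conserved" (VPI 3); default 0.07.
#' @slot applyAfToVpi4 logical; if `TRUE` the rare-AF cut is also applied to
#'   frameshift/truncating/splice (tier 4) variants. Default `FALSE`.
#' @slot coverageQcThreshold depth threshold for the coverage gap/exon/gene
#'   reports; default 15.
#' @slot medianCoverageMin sample-level QC: minimum median coverage
#'   (`NA` = check skipped).
#' @slot fragmentSizeRange sample-level QC: inclusive `[low, high]` bounds on
#'   median fragment size (`NA` = skipped).
#' @slot maxDuplicateRate sample-level QC: maximum PCR duplicate rate
#'   (`NA` = skipped).
#' @slot fastqcChecks names of FASTQC summary metrics that must not be FAIL
#'   (empty = check skipped).
#' @slot greenMinOk,amberMinOk gene-report colour thresholds on the fraction
#'   of targeted bases at/above `coverageQcThreshold`.
#' @slot dbMinOtherCohortSamples internal-database policy: exclude a variant
#'   seen in at least this many samples from other disease cohorts.
#' @slot dbMaxInternalFrequency internal-database policy: exclude a variant
#'   whose internal observation frequency exceeds this (`NA` = arm disabled).
#' @slot extraSettings open key/value list for custom settings.
#' @export
setClass("AnalysisProfile",
    representation(
        name = "character",
        targetGenes = "character",
        knownCausalGenes = "character",
        insilicoGenes = "character",
        clinicianGenes = "character",
        excludedGenes = "character",
        spliceWindowBp = "integer",
        minVariantCoverage = "integer",
        minVariantQual = "numeric",
        rareAfThreshold = "numeric",
        veryRareAfThreshold = "numeric",
        condelThreshold = "numeric",
        applyAfToVpi4 = "logical",
        coverageQcThreshold = "integer",
        medianCoverageMin = "numeric",
        fragmentSizeRange = "numeric",
        maxDuplicateRate = "numeric",
        fastqcChecks = "character",
        greenMinOk = "numeric",
        amberMinOk = "numeric",
        dbMinOtherCohortSamples = "integer",
        dbMaxInternalFrequency = "numeric",
        extraSettings = "list"
    ),
    prototype(
        name = NA_character_,
        targetGenes = character(),
        knownCausalGenes = character(),
        insilicoGenes = character(),
        clinicianGenes = character(),
        excludedGenes = character(),
        spliceWindowBp = 2L,
        minVariantCoverage = 0L,
        minVariantQual = 0,
        rareAfThreshold = 0.01,
        veryRareAfThreshold = 0.0005,
        condelThreshold = 0.07,
        applyAfToVpi4 = FALSE,
        coverageQcThreshold = 15L,
        medianCoverageMin = NA_real_,
        fragmentSizeRange = c(NA_real_, NA_real_),
        maxDuplicateRate = NA_real_,
        fastqcChecks = character(),
        greenMinOk = 0.95,
        amberMinOk = 0.80,
        dbMinOtherCohortSamples = 3L,
        dbMaxInternalFrequency = NA_real_,
        extraSettings = list()
    )
)

setValidity("AnalysisProfile", function(object) {
    msg <- character()
    if (length(object@name) != 1L || is.na(object@name) || !nzchar(object@name))
        msg <- c(msg, "profile must have a non-empty 'name'")
    chkFrac <- function(x, what, lo = 0) {
        if (!is.na(x) && (x <= lo || x > 1))
            sprintf("%s must lie in (%g, 1]", what, lo) else character()
    }
    msg <- c(msg,
        chkFrac(object@rareAfThreshold, "rare_af_threshold"),
        chkFrac(object@veryRareAfThreshold, "very_rare_af_threshold"),
        chkFrac(object@dbMaxInternalFrequency, "db_max_internal_frequency"))
    if (object@veryRareAfThreshold > object@rareAfThreshold)
        msg <- c(msg, "very_rare_af_threshold must be <= rare_af_threshold")
    if (object@spliceWindowBp < 0L)
        msg <- c(msg, "splice_window_bp must be >= 0")
    if (object@minVariantCoverage < 0L)
        msg <- c(msg, "min_variant_coverage must be >= 0")
    if (object@minVariantQual < 0)
        msg <- c(msg, "min_variant_qual must be >= 0")
    if (object@coverageQcThreshold <= 0L)
        msg <- c(msg, "coverage_qc_threshold must be > 0")
    fr <- object@fragmentSizeRange
    if (length(fr) != 2L)
        msg <- c(msg, "fragment_size_range must have exactly two values")
    else if (!any(is.na(fr)) && fr[1] >= fr[2])
        msg <- c(msg, "fragment_size_range low bound must be < high bound")
    if (!is.na(object@maxDuplicateRate) &&
        (object@maxDuplicateRate < 0 || object@maxDuplicateRate > 1))
        msg <- c(msg, "max_duplicate_rate must lie in [0, 1]")
    if (object@dbMinOtherCohortSamples < 1L)
        msg <- c(msg, "db_min_other_cohort_samples must be >= 1")
    if (!is.na(object@greenMinOk) && !is.na(object@amberMinOk) &&
        object@amberMinOk >= object@greenMinOk)
        msg <- c(msg, "amber_min_ok must be < green_min_ok")
    bad <- intersect(object@excludedGenes, object@clinicianGenes)
    if (length(bad))
        msg <- c(msg, paste0("genes cannot be both excluded and ",
            "clinician-nominated: ", paste(bad, collapse = ", ")))
    extra <- setdiff(object@clinicianGenes, object@targetGenes)
    if (length(extra))
        msg <- c(msg, paste0("clinician_genes outside the target region: ",
            paste(extra, collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' ObservationStore: site-local database of observed variants
#'
#' A single-file SQLite database recording, for every sample ever analysed
#' at a site, the normalised variants observed in that sample together with
#' the sample's disease cohort. The observation frequency in this store is
#' used — alongside public population frequencies — to filter out recurrent
#' private population variants and sequencing/bioinformatic artefacts:
#' variants observed in multiple samples belonging to different disease
#' cohorts are unlikely to be causal for any one of them.
#'
#' The object holds only the file path; every operation opens a short-lived
#' connection so that snapshots (plain file copies) are always consistent.
#'
#' @slot path path to the SQLite store file.
#' @export
setClass("ObservationStore", representation(path = "character"))

setValidity("ObservationStore", function(object) {
    if (length(object@path) != 1L || !nzchar(object@path))
        return("store path must be a single non-empty string")
    TRUE
})

#' CoverageTrack: per-base sequencing depth over target intervals
#'
#' Holds the per-base read depth for one sample over a set of target
#' intervals, as produced by a per-base coverage tool (one depth value per
#' base of each interval). Intervals are stored as a `GRanges` (1-based,
#' inclusive) with a parallel `IntegerList` of depths; input files use
#' 0-based half-open BED-style coordinates and are converted on read.
#'
#' @slot sampleId sample identifier.
#' @slot intervals `GRanges` of target intervals, sorted, non-overlapping
#'   within each chromosome.
#' @slot depths `IntegerList`, one vector per interval, length equal to the
#'   interval width, all values >= 0.
#' @export
setClass("CoverageTrack",
    representation(
        sampleId = "character",
        intervals = "GRanges",
        depths = "IntegerList"
    )
)

setValidity("CoverageTrack", function(object) {
    msg <- character()
    iv <- object@intervals
    if (length(iv) != length(object@depths))
        msg <- c(msg, "one depth vector per interval required")
    else if (length(iv)) {
        if (!all(GenomicRanges::width(iv) ==
                 lengths(object@depths)))
            msg <- c(msg, "depth vector lengths must equal interval widths")
        if (any(unlist(object@depths, use.names = FALSE) < 0))
            msg <- c(msg, "depths must be >= 0")
        byChrom <- split(iv, as.character(GenomicRanges::seqnames(iv)))
        for (g in byChrom) {
            if (length(g) > 1L) {
                o <- order(GenomicRanges::start(g))
                if (any(GenomicRanges::start(g)[o][-1] <=
                        GenomicRanges::end(g)[o][-length(g)]))
                    msg <- c(msg, "intervals overlap within a chromosome")
            }
        }
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "AnalysisProfile", function(object) {
    cat("AnalysisProfile '", object@name, "'\n", sep = "")
    cat("  genes: target=", length(object@targetGenes),
        " known=", length(object@knownCausalGenes),
        " insilico=", length(object@insilicoGenes),
        " clinician=", length(object@clinicianGenes),
        " excluded=", length(object@excludedGenes), "\n", sep = "")
    cat(sprintf("  AF tiers: rare < %g, very rare < %g; Condel > %g\n",
        object@rareAfThreshold, object@veryRareAfThreshold,
        object@condelThreshold))
    cat(sprintf("  splice window: %d bp; variant gates: depth >= %d, qual >= %g\n",
        object@spliceWindowBp, object@minVariantCoverage,
        object@minVariantQual))
    cat(sprintf("  coverage QC threshold: %dx\n", object@coverageQcThreshold))
})

setMethod("show", "ObservationStore", function(object) {
    n <- tryCatch(totalSamples(object), error = function(e) NA_integer_)
    cat("ObservationStore at ", object@path, " (", n, " samples)\n", sep = "")
})

setMethod("show", "CoverageTrack", function(object) {
    cat("CoverageTrack for sample '", object@sampleId, "': ",
        length(object@intervals), " intervals, ",
        sum(lengths(object@depths)), " bases\n", sep = "")
})
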