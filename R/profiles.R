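## Analysis profiles: flat key=value text files, '#' comments, gene lists
## either inline (comma-separated) or as sidecar one-symbol-per-line files.

.GENE_LIST_KEYS <- c(
    target_genes = "targetGenes",
    known_causal_genes = "knownCausalGenes",
    insilico_genes = "insilicoGenes",
    clinician_genes = "clinicianGenes",
    excluded_genes = "excludedGenes"
)

.NUMERIC_KEYS <- c(
    splice_window_bp = "spliceWindowBp",
    min_variant_coverage = "minVariantCoverage",
    min_variant_qual = "minVariantQual",
    rare_af_threshold = "rareAfThreshold",
    very_rare_af_threshold = "veryRareAfThreshold",
    condel_threshold = "condelThreshold",
    coverage_qc_threshold = "coverageQcThreshold",
    median_coverage_min = "medianCoverageMin",
    max_duplicate_rate = "maxDuplicateRate",
    green_min_ok = "greenMinOk",
    amber_min_ok = "amberMinOk",
    db_min_other_cohort_samples = "dbMinOtherCohortSamples",
    db_max_internal_frequency = "dbMaxInternalFrequency"
)

.INTEGER_SLOTS <- c("spliceWindowBp", "minVariantCoverage",
    "coverageQcThreshold", "dbMinOtherCohortSamples")

.normGenes <- function(x) {
    x <- toupper(trimws(x))
    unique(x[nzchar(x)])
}

.parseBool <- function(value, key, line = NA_integer_) {
    v <- tolower(trimws(value))
    if (v %in% c("true", "yes", "1")) return(TRUE)
    if (v %in% c("false", "no", "0")) return(FALSE)
    stop(sprintf("profile configuration error: key '%s'%s: '%s' is not a logical",
        key, if (is.na(line)) "" else sprintf(" (line %d)", line), value),
        call. = FALSE)
}

.parseNum <- function(value, key, line = NA_integer_) {
    v <- suppressWarnings(as.numeric(trimws(value)))
    if (is.na(v) && !tolower(trimws(value)) %in% c("na", ""))
        stop(sprintf(
            "profile configuration error: key '%s'%s: '%s' is not numeric",
            key, if (is.na(line)) "" else sprintf(" (line %d)", line), value),
            call. = FALSE)
    v
}

#' Construct an analysis profile
#'
#' Builds a validated [AnalysisProfile-class] from explicit settings.
#' Unspecified settings take the documented defaults. Gene symbols are
#' upper-cased and trimmed. Known-causal, in-silico and clinician gene
#' lists are clamped to the target gene set (with a warning) since the
#' gene categories narrow progressively from the target universe.
#'
#' @param name profile identifier (required).
#' @param targetGenes,knownCausalGenes,insilicoGenes,clinicianGenes,excludedGenes
#'   character vectors of gene symbols.
#' @param ... further settings named after the slots of
#'   [AnalysisProfile-class] (e.g. `rareAfThreshold`, `spliceWindowBp`,
#'   `fragmentSizeRange`).
#' @param extraSettings named list of custom settings.
#' @return an `AnalysisProfile`.
#' @examples
#' p <- analysisProfile("EPIL", targetGenes = c("SCN1A", "KCNQ2"),
#'                      knownCausalGenes = "SCN1A")
#' geneCategory(p, "SCN1A")
#' @export
analysisProfile <- function(name, targetGenes = character(),
                            knownCausalGenes = character(),
                            insilicoGenes = character(),
                            clinicianGenes = character(),
                            excludedGenes = character(),
                            ..., extraSettings = list()) {
    args <- list(...)
    p <- new("AnalysisProfile", name = as.character(name))
    p@targetGenes <- .normGenes(targetGenes)
    p@knownCausalGenes <- .normGenes(knownCausalGenes)
    p@insilicoGenes <- .normGenes(insilicoGenes)
    p@clinicianGenes <- .normGenes(clinicianGenes)
    p@excludedGenes <- .normGenes(excludedGenes)
    for (slotName in names(args)) {
        if (!slotName %in% slotNames("AnalysisProfile"))
            stop("unknown AnalysisProfile setting: ", slotName, call. = FALSE)
        value <- args[[slotName]]
        if (slotName %in% .INTEGER_SLOTS) value <- as.integer(value)
        slot(p, slotName) <- value
    }
    p@extraSettings <- extraSettings
    ## Categories 2-4 narrow from the target universe; clamp and warn.
    for (s in c("knownCausalGenes", "insilicoGenes", "clinicianGenes")) {
        outside <- setdiff(slot(p, s), p@targetGenes)
        if (length(outside)) {
            warning(sprintf("%s not in target region dropped from %s: %s",
                "gene(s)", s, paste(outside, collapse = ", ")),
                call. = FALSE)
            slot(p, s) <- setdiff(slot(p, s), outside)
        }
    }
    validObject(p)
    p
}

#' Parse an analysis-profile configuration file
#'
#' Reads a flat `key=value` text file (one setting per line, `#` starts a
#' comment, blank lines ignored). Gene-list keys (`target_genes`,
#' `known_causal_genes`, `insilico_genes`, `clinician_genes`,
#' `excluded_genes`) accept either an inline comma-separated list of
#' symbols or a path (relative to the profile file) to a sidecar file with
#' one symbol per line (LF or CRLF). Numeric keys must parse as numbers;
#' `fragment_size_range` takes `low,high`. Keys the package does not know
#' are collected into `extraSettings`, never rejected, so sites can define
#' custom settings.
#'
#' @param path path to the profile configuration file.
#' @return an [AnalysisProfile-class].
#' @seealso [writeProfile()] for the inverse operation.
#' @export
parseProfile <- function(path) {
    if (!file.exists(path))
        stop("profile file not found: ", path, call. = FALSE)
    lines <- readLines(path, warn = FALSE)
    lines <- sub("\r$", "", lines)
    dir <- dirname(path)

    fields <- list()
    extras <- list()
    for (i in seq_along(lines)) {
        ln <- sub("#.*$", "", lines[i])
        ln <- trimws(ln)
        if (!nzchar(ln)) next
        eq <- regexpr("=", ln, fixed = TRUE)
        if (eq < 0)
            stop(sprintf(
                "profile configuration error: line %d is not key=value: '%s'",
                i, lines[i]), call. = FALSE)
        key <- trimws(substr(ln, 1L, eq - 1L))
        value <- trimws(substr(ln, eq + 1L, nchar(ln)))
        if (key == "name") {
            fields$name <- value
        } else if (key %in% names(.GENE_LIST_KEYS)) {
            sidecar <- file.path(dir, value)
            symbols <- if (nzchar(value) && file.exists(sidecar) &&
                           !dir.exists(sidecar)) {
                readLines(sidecar, warn = FALSE)
            } else {
                strsplit(value, ",", fixed = TRUE)[[1]]
            }
            fields[[.GENE_LIST_KEYS[[key]]]] <- .normGenes(symbols)
        } else if (key %in% names(.NUMERIC_KEYS)) {
            fields[[.NUMERIC_KEYS[[key]]]] <- .parseNum(value, key, i)
        } else if (key == "fragment_size_range") {
            if (toupper(value) %in% c("", "NA")) next
            parts <- strsplit(value, ",", fixed = TRUE)[[1]]
            if (length(parts) != 2L)
                stop(sprintf(
                    "profile configuration error: key 'fragment_size_range' (line %d): expected 'low,high'",
                    i), call. = FALSE)
            fields$fragmentSizeRange <- c(.parseNum(parts[1], key, i),
                                          .parseNum(parts[2], key, i))
        } else if (key == "fastqc_checks") {
            checks <- trimws(strsplit(value, ",", fixed = TRUE)[[1]])
            fields$fastqcChecks <- checks[nzchar(checks)]
        } else if (key == "apply_af_to_vpi4") {
            fields$applyAfToVpi4 <- .parseBool(value, key, i)
        } else {
            extras[[key]] <- value
        }
    }
    if (is.null(fields$name))
        stop("profile configuration error: required key 'name' is missing",
            call. = FALSE)
    geneArgs <- fields[names(fields) %in% c("name", unname(.GENE_LIST_KEYS))]
    otherArgs <- fields[!names(fields) %in% names(geneArgs)]
    do.call(analysisProfile,
            c(geneArgs, otherArgs, list(extraSettings = extras)))
}

#' Write an analysis profile back to its text form
#'
#' Serialises an [AnalysisProfile-class] to the same flat `key=value`
#' format read by [parseProfile()]; gene lists are written inline
#' (comma-separated). `parseProfile(writeProfile(p, f))` reproduces `p` on
#' every field.
#'
#' @param profile an `AnalysisProfile`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeProfile <- function(profile, path) {
    fmtNum <- function(x) {
        if (all(is.na(x))) "NA" else paste(format(x, digits = 15,
            scientific = FALSE, trim = TRUE), collapse = ",")
    }
    out <- c(paste0("name=", profile@name))
    for (key in names(.GENE_LIST_KEYS)) {
        genes <- slot(profile, .GENE_LIST_KEYS[[key]])
        out <- c(out, paste0(key, "=", paste(genes, collapse = ",")))
    }
    for (key in names(.NUMERIC_KEYS))
        out <- c(out, paste0(key, "=", fmtNum(slot(profile, .NUMERIC_KEYS[[key]]))))
    out <- c(out,
        paste0("fragment_size_range=", fmtNum(profile@fragmentSizeRange)),
        paste0("fastqc_checks=", paste(profile@fastqcChecks, collapse = ",")),
        paste0("apply_af_to_vpi4=", tolower(as.character(profile@applyAfToVpi4))))
    for (key in names(profile@extraSettings))
        out <- c(out, paste0(key, "=", profile@extraSettings[[key]]))
    writeLines(out, path)
    invisible(path)
}

#' Gene Priority Index category of a gene within a profile
#'
#' Returns the a-priori gene category used by the Gene Priority Index
#' (GPI): 0 for genes outside the analysis (off target, or explicitly
#' excluded — exclusion dominates every other membership), otherwise the
#' highest category among the lists containing the gene: 1 target region,
#' 2 known causal for the patient group, 3 in-silico prioritised, 4
#' clinician-nominated. Comparison is case-insensitive; the function is
#' total (unknown or `NA` symbols give 0) and vectorised.
#'
#' @param profile an [AnalysisProfile-class].
#' @param gene character vector of gene symbols.
#' @return integer vector of categories in 0..4.
#' @export
geneCategory <- function(profile, gene) {
    g <- toupper(trimws(as.character(gene)))
    cat <- integer(length(g))
    inTarget <- g %in% profile@targetGenes
    cat[inTarget] <- 1L
    cat[g %in% profile@knownCausalGenes & inTarget] <- 2L
    sel <- g %in% profile@insilicoGenes & inTarget
    cat[sel] <- pmax(cat[sel], 3L)
    sel <- g %in% profile@clinicianGenes & inTarget
    cat[sel] <- pmax(cat[sel], 4L)
    cat[g %in% profile@excludedGenes | is.na(g)] <- 0L
    cat
}

#' Internal-database filtering policy of a profile
#'
#' @param profile an [AnalysisProfile-class].
#' @return list with `minOtherCohortSamples` and `maxInternalFrequency`
#'   (`NA` when the frequency arm is disabled).
#' @export
internalFilterPolicy <- function(profile) {
    list(minOtherCohortSamples = profile@dbMinOtherCohortSamples,
         maxInternalFrequency = profile@dbMaxInternalFrequency)
}

#' @rdname accessors
#' @name accessors
#' @title Accessors for AnalysisProfile settings
#' @description Read individual settings without touching slots directly.
#' @param profile an [AnalysisProfile-class].
#' @param name for `profileSetting`, the key of an extra (custom) setting.
#' @param default value returned when an extra setting is absent.
#' @return the requested setting.
#' @export
profileName <- function(profile) profile@name

#' @rdname accessors
#' @export
targetGenes <- function(profile) profile@targetGenes

#' @rdname accessors
#' @export
spliceWindow <- function(profile) profile@spliceWindowBp

#' @rdname accessors
#' @export
coverageQcThreshold <- function(profile) profile@coverageQcThreshold

#' @rdname accessors
#' @export
profileSetting <- function(profile, name, default = NULL) {
    if (name %in% names(profile@extraSettings))
        profile@extraSettings[[name]]
    else default
}
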