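## Automated per-sample QC gates: FASTQC summary metrics, median
## coverage, fragment-size range, duplicate rate, and a sex consistency
## check based on X/Y-to-autosome depth ratios.

.checkRow <- function(name, status, observed, limit, message = "") {
    if (status == "FAIL" && !nzchar(message))
        message <- sprintf("%s: observed %s, limit %s", name, observed, limit)
    data.frame(check_name = name, status = status,
               observed = as.character(observed),
               limit = as.character(limit),
               message = message, stringsAsFactors = FALSE)
}

#' Read a sample metrics table
#'
#' Reads the per-sample QC metrics TSV with columns `sample_id`,
#' `median_coverage`, `median_fragment_size`, `duplicate_rate`,
#' `mean_depth_x`, `mean_depth_y`, `mean_depth_autosome`, `declared_sex`
#' (`MALE`/`FEMALE`/`UNKNOWN`) and `fastqc_flags`
#' (`metric:STATUS` pairs separated by `;`, e.g.
#' `per_base_quality:PASS;adapter_content:FAIL`).
#'
#' @param path path to the metrics TSV.
#' @return data.frame, one row per sample.
#' @export
readSampleMetrics <- function(path) {
    if (!file.exists(path))
        stop("metrics file not found: ", path, call. = FALSE)
    utils::read.delim(path, stringsAsFactors = FALSE)
}

.parseFastqcFlags <- function(flags) {
    if (is.null(flags) || is.na(flags) || !nzchar(flags))
        return(stats::setNames(character(0), character(0)))
    parts <- strsplit(flags, ";", fixed = TRUE)[[1]]
    kv <- strsplit(parts, ":", fixed = TRUE)
    stats::setNames(vapply(kv, `[`, character(1), 2L),
                    vapply(kv, `[`, character(1), 1L))
}

#' Run the configurable threshold checks for one sample
#'
#' Evaluates the automated gates against the profile limits:
#'
#' 1. `fastqc` — FAIL iff any profile-listed FASTQC metric reports FAIL;
#' 2. `median_coverage` — FAIL iff the overall median coverage falls
#'    below the configured threshold;
#' 3. `fragment_size` — FAIL iff the median fragment size falls outside
#'    the configured range (bounds inclusive: a fragment size exactly at
#'    either bound passes);
#' 4. `duplicate_rate` — FAIL iff the PCR duplicate rate is greater than
#'    the configured maximum (at the limit passes).
#'
#' A check whose limit is not configured in the profile is reported as
#' `SKIPPED`, never silently dropped. Checks are pure functions of
#' (metrics, profile).
#'
#' @param metrics one row of [readSampleMetrics()] (data.frame or list).
#' @param profile an [AnalysisProfile-class].
#' @return data.frame of check results (`check_name`, `status`,
#'   `observed`, `limit`, `message`).
#' @export
runThresholdChecks <- function(metrics, profile) {
    rows <- list()

    flags <- .parseFastqcFlags(metrics$fastqc_flags)
    if (length(profile@fastqcChecks) == 0L) {
        rows$fastqc <- .checkRow("fastqc", "SKIPPED", NA, NA,
            "no FASTQC metrics configured")
    } else {
        watched <- flags[names(flags) %in% profile@fastqcChecks]
        failing <- names(watched)[watched == "FAIL"]
        rows$fastqc <- if (length(failing))
            .checkRow("fastqc", "FAIL", paste(failing, collapse = ","),
                      "no FAIL", sprintf("FASTQC metric(s) failed: %s",
                                         paste(failing, collapse = ", ")))
        else .checkRow("fastqc", "PASS", "all PASS/WARN", "no FAIL")
    }

    mc <- metrics$median_coverage
    rows$median_coverage <- if (is.na(profile@medianCoverageMin))
        .checkRow("median_coverage", "SKIPPED", mc, NA, "no threshold configured")
    else if (mc < profile@medianCoverageMin)
        .checkRow("median_coverage", "FAIL", mc,
                  paste0(">=", profile@medianCoverageMin),
                  sprintf("median coverage %s below threshold %s",
                          mc, profile@medianCoverageMin))
    else .checkRow("median_coverage", "PASS", mc,
                   paste0(">=", profile@medianCoverageMin))

    fr <- profile@fragmentSizeRange
    fs <- metrics$median_fragment_size
    rows$fragment_size <- if (any(is.na(fr)))
        .checkRow("fragment_size", "SKIPPED", fs, NA, "no range configured")
    else if (fs < fr[1] || fs > fr[2])
        .checkRow("fragment_size", "FAIL", fs,
                  sprintf("[%g, %g]", fr[1], fr[2]),
                  sprintf("median fragment size %s outside [%g, %g]",
                          fs, fr[1], fr[2]))
    else .checkRow("fragment_size", "PASS", fs,
                   sprintf("[%g, %g]", fr[1], fr[2]))

    dr <- metrics$duplicate_rate
    rows$duplicate_rate <- if (is.na(profile@maxDuplicateRate))
        .checkRow("duplicate_rate", "SKIPPED", dr, NA, "no maximum configured")
    else if (dr > profile@maxDuplicateRate)
        .checkRow("duplicate_rate", "FAIL", dr,
                  paste0("<=", profile@maxDuplicateRate),
                  sprintf("duplicate rate %s above maximum %s",
                          dr, profile@maxDuplicateRate))
    else .checkRow("duplicate_rate", "PASS", dr,
                   paste0("<=", profile@maxDuplicateRate))

    out <- do.call(rbind, unname(rows))
    rownames(out) <- NULL
    out
}

#' Infer sample sex from X/Y-to-autosome depth ratios
#'
#' Computes `rx = mean_depth_x / mean_depth_autosome` and
#' `ry = mean_depth_y / mean_depth_autosome` and calls:
#'
#' * `MALE` when `ry >= 0.2` and `rx <= 0.8` (one X, one Y);
#' * `FEMALE` when `ry < 0.05` and `rx >= 0.8` (two X, no Y);
#' * `UNKNOWN` otherwise (dead zone), or when the autosomal depth is 0.
#'
#' The dead zone is deliberate: on capture data a borderline ratio should
#' withhold the call rather than force a possibly wrong one, since the sex
#' check gates a clinical analysis.
#'
#' @param meanDepthX,meanDepthY,meanDepthAutosome mean read depths over X,
#'   Y and the autosomes; or pass a metrics row as the first argument.
#' @return `"MALE"`, `"FEMALE"` or `"UNKNOWN"`.
#' @export
inferSex <- function(meanDepthX, meanDepthY = NULL, meanDepthAutosome = NULL) {
    if (is.data.frame(meanDepthX) || is.list(meanDepthX)) {
        m <- meanDepthX
        meanDepthX <- m$mean_depth_x
        meanDepthY <- m$mean_depth_y
        meanDepthAutosome <- m$mean_depth_autosome
    }
    if (is.na(meanDepthAutosome) || meanDepthAutosome <= 0)
        return("UNKNOWN")
    rx <- meanDepthX / meanDepthAutosome
    ry <- meanDepthY / meanDepthAutosome
    if (ry >= 0.2 && rx <= 0.8) "MALE"
    else if (ry < 0.05 && rx >= 0.8) "FEMALE"
    else "UNKNOWN"
}

#' Check consistency of inferred and declared sex
#'
#' FAIL only when both sexes are known and differ; if either side is
#' `UNKNOWN` the check is `SKIPPED` with an explanatory message rather
#' than silently passed.
#'
#' @param inferred sex inferred from coverage, see [inferSex()].
#' @param declared sex declared in the sample metadata.
#' @return one-row check result data.frame.
#' @export
checkSex <- function(inferred, declared) {
    declared <- toupper(as.character(declared))
    if (is.na(declared) || !declared %in% c("MALE", "FEMALE"))
        declared <- "UNKNOWN"
    if (inferred == "UNKNOWN" || declared == "UNKNOWN")
        .checkRow("sex", "SKIPPED", inferred, declared,
                  sprintf("sex not comparable (inferred %s, declared %s)",
                          inferred, declared))
    else if (inferred != declared)
        .checkRow("sex", "FAIL", inferred, declared,
                  sprintf("inferred sex %s inconsistent with declared %s",
                          inferred, declared))
    else .checkRow("sex", "PASS", inferred, declared)
}

#' Run all automated checks for one sample
#'
#' Runs the threshold checks plus the sex consistency check and attaches
#' the overall verdict: the sample fails iff any individual check fails
#' (`SKIPPED` checks do not fail a sample).
#'
#' @param metrics one row of [readSampleMetrics()].
#' @param profile an [AnalysisProfile-class].
#' @return data.frame of check results with attribute `verdict`
#'   (`"PASS"` or `"FAIL"`).
#' @export
runSampleChecks <- function(metrics, profile) {
    out <- rbind(runThresholdChecks(metrics, profile),
                 checkSex(inferSex(metrics), metrics$declared_sex))
    attr(out, "verdict") <- if (any(out$status == "FAIL")) "FAIL" else "PASS"
    out
}
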