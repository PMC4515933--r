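## Curation outputs: ranked variant report CSV, LOVD3-compatible CSV,
## provenance manifest, batch directory layout and the batch driver.

## fixed precision keeps report bytes stable across platforms
.fmtFrac <- function(x) ifelse(is.na(x), "", sprintf("%.6f", x))
.fmtNum <- function(x) ifelse(is.na(x), "", sprintf("%g", x))
.fmtInt <- function(x) ifelse(is.na(x), "", sprintf("%d", as.integer(x)))

.REPORT_COLUMNS <- c("sample", "gene", "gpi", "vpi", "chrom", "pos", "ref",
    "alt", "consequence", "af_evs", "af_1000g", "af_exac", "condel",
    "obs_count", "obs_frequency", "depth", "qual")

.LOVD_COLUMNS <- c("chromosome", "position_g_start", "reference",
    "alternate", "gene_symbol", "effect", "frequency_evs",
    "frequency_1000g", "frequency_exac", "frequency_internal",
    "conservation_condel", "vpi", "gpi", "sample_id", "read_depth",
    "variant_quality")

.reportCells <- function(records) {
    data.frame(
        sample = records$sample_id,
        gene = ifelse(is.na(records$gene), "", records$gene),
        gpi = .fmtInt(records$gpi),
        vpi = .fmtInt(records$vpi),
        chrom = records$chrom,
        pos = .fmtInt(records$pos),
        ref = records$ref,
        alt = records$alt,
        consequence = records$consequence,
        af_evs = .fmtFrac(records$af_evs),
        af_1000g = .fmtFrac(records$af_1000g),
        af_exac = .fmtFrac(records$af_exac),
        condel = .fmtFrac(records$condel),
        obs_count = .fmtInt(records$obs_count),
        obs_frequency = .fmtFrac(records$obs_frequency),
        depth = .fmtInt(records$depth),
        qual = .fmtNum(records$qual),
        stringsAsFactors = FALSE, check.names = FALSE)
}

.writeCsv <- function(cells, path) {
    con <- tryCatch(file(path, open = "wt"),
        error = function(e) stop("cannot write report to: ", path,
                                 call. = FALSE))
    on.exit(close(con))
    utils::write.csv(cells, con, row.names = FALSE, quote = TRUE)
    invisible(path)
}

#' Write the ranked variant report
#'
#' Writes the curation spreadsheet as CSV with a stable, documented
#' column order: sample, gene, GPI, VPI, chrom, pos, ref, alt,
#' consequence, the three population frequencies, Condel, internal
#' observation count and frequency, depth, qual. Row order is the input
#' order (records are expected pre-sorted by [sortForReport()] so the
#' most promising variants sit at the top). Absent values are written as
#' empty cells — never `0`, since a missing population frequency means
#' "not observed", not "frequency zero". Frequencies use 6 fixed
#' decimals for byte-stable output. An empty record set yields a valid
#' header-only file ("no reportable variants").
#'
#' @param records sorted retained variant records.
#' @param outPath output CSV path.
#' @return `outPath`, invisibly.
#' @export
writeVariantReport <- function(records, outPath) {
    cells <- if (nrow(records)) .reportCells(records)
        else stats::setNames(
            as.data.frame(matrix(character(0), 0, length(.REPORT_COLUMNS)),
                          stringsAsFactors = FALSE), .REPORT_COLUMNS)
    .writeCsv(cells, outPath)
}

#' Write the LOVD3-compatible variant CSV
#'
#' Writes the same retained variants re-mapped to columns suitable for
#' import into an LOVD3-compatible curation database. The file carries
#' identical information to the main report — same rows, same values —
#' under LOVD-style names (`chromosome`, `position_g_start`, `reference`,
#' `alternate`, `gene_symbol`, `effect`, frequency fields, ...).
#'
#' @param records sorted retained variant records.
#' @param outPath output CSV path.
#' @return `outPath`, invisibly.
#' @export
writeLovdCsv <- function(records, outPath) {
    cells <- if (nrow(records)) {
        main <- .reportCells(records)
        stats::setNames(main[, c("chrom", "pos", "ref", "alt", "gene",
            "consequence", "af_evs", "af_1000g", "af_exac",
            "obs_frequency", "condel", "vpi", "gpi", "sample", "depth",
            "qual")], .LOVD_COLUMNS)
    } else stats::setNames(
        as.data.frame(matrix(character(0), 0, length(.LOVD_COLUMNS)),
                      stringsAsFactors = FALSE), .LOVD_COLUMNS)
    .writeCsv(cells, outPath)
}

#' Write the removed-variant audit file
#'
#' Companion CSV listing every variant removed by filtering together with
#' its machine-readable reason codes, so every hidden variant remains
#' auditable.
#'
#' @param removed removed records from [applyFilters()] (with
#'   `filter_reasons`).
#' @param outPath output CSV path.
#' @return `outPath`, invisibly.
#' @export
writeRemovedReport <- function(removed, outPath) {
    cells <- if (nrow(removed)) {
        cbind(.reportCells(removed),
              data.frame(filter_reasons = removed$filter_reasons,
                         stringsAsFactors = FALSE))
    } else stats::setNames(
        as.data.frame(matrix(character(0), 0,
                             length(.REPORT_COLUMNS) + 1L),
                      stringsAsFactors = FALSE),
        c(.REPORT_COLUMNS, "filter_reasons"))
    .writeCsv(cells, outPath)
}

#' Write a provenance manifest
#'
#' Records exactly what an analysis consumed and produced: for every
#' input and output file its path, byte size and MD5 content digest; the
#' full effective profile settings; the package version; and (unless
#' `timestamp = FALSE`) the run time. With `timestamp = FALSE` the
#' manifest is byte-identical across reruns on identical files, which is
#' the file-level reproducibility contract.
#'
#' @param inputs character vector of input file paths (must exist).
#' @param profile the effective [AnalysisProfile-class].
#' @param outputs character vector of output file paths (must exist).
#' @param outPath manifest destination (JSON).
#' @param timestamp include the run time.
#' @return `outPath`, invisibly.
#' @export
writeProvenance <- function(inputs, profile, outputs, outPath,
                            timestamp = TRUE) {
    describe <- function(paths) {
        lapply(paths, function(p) {
            if (!file.exists(p))
                stop("provenance: file does not exist: ", p, call. = FALSE)
            list(path = p, bytes = unname(file.size(p)),
                 md5 = unname(tools::md5sum(p)))
        })
    }
    settings <- lapply(slotNames("AnalysisProfile"), function(s) slot(profile, s))
    names(settings) <- slotNames("AnalysisProfile")
    manifest <- list(
        tool = paste0("panelTriage ",
                      as.character(utils::packageVersion("panelTriage"))),
        inputs = describe(inputs),
        settings = settings,
        outputs = describe(outputs)
    )
    if (timestamp)
        manifest$run_at <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    jsonlite::write_json(manifest, outPath, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA, null = "null")
    invisible(outPath)
}

#' Create (or verify) the standard batch directory layout
#'
#' Each analysis batch is isolated in one directory: raw inputs stay
#' quarantined under `data/`, the profile and gene lists are copied once
#' to `design/` (so re-running the analysis later uses the design as it
#' was at first run, even if the site profile has since changed), all
#' computed results live under `analysis/` with stage subdirectories
#' (`fastqc`, `align`, `variants`, `qc`) and final outputs under
#' `analysis/results/`.
#'
#' @param batchDir batch root directory.
#' @return named list of the layout paths, invisibly.
#' @export
createBatchLayout <- function(batchDir) {
    layout <- list(
        root = batchDir,
        data = file.path(batchDir, "data"),
        design = file.path(batchDir, "design"),
        analysis = file.path(batchDir, "analysis"),
        fastqc = file.path(batchDir, "analysis", "fastqc"),
        align = file.path(batchDir, "analysis", "align"),
        variants = file.path(batchDir, "analysis", "variants"),
        qc = file.path(batchDir, "analysis", "qc"),
        results = file.path(batchDir, "analysis", "results")
    )
    for (d in unlist(layout))
        dir.create(d, recursive = TRUE, showWarnings = FALSE)
    invisible(layout)
}

## copy profile + sidecar gene lists into design/ at first run only
.ensureDesign <- function(layout, profilePath) {
    designProfile <- file.path(layout$design, basename(profilePath))
    if (!file.exists(designProfile)) {
        file.copy(profilePath, designProfile)
        srcDir <- dirname(profilePath)
        for (f in list.files(srcDir, pattern = "\\.(genes|txt|list)$",
                             full.names = TRUE)) {
            dest <- file.path(layout$design, basename(f))
            if (!file.exists(dest) && !identical(f, profilePath))
                file.copy(f, dest)
        }
    }
    designProfile
}

#' Run a full batch analysis
#'
#' Batch driver tying the modules together for a directory prepared in
#' the standard layout (see [createBatchLayout()]): for every sample
#' listed in `data/samples.tsv` (columns `sample_id`, `sex`, `cohort`,
#' `profile`) it reads the annotated VCF (`data/<sample>.vcf`), runs
#' sample QC checks from `data/metrics.tsv`, prioritises and filters
#' variants (consulting the observation store when given, after archiving
#' a snapshot of it), produces the three coverage reports from
#' `data/<sample>.cov.tsv` and the exon model `data/exons.bed`, writes
#' the ranked variant report, the LOVD3-compatible CSV, the
#' removed-variant audit file, the per-sample QC reports and a provenance
#' manifest under `analysis/results/`, and finally registers each
#' sample's variants in the store.
#'
#' @param batchDir batch root directory containing `data/`.
#' @param profilePath path to the analysis-profile file (copied to
#'   `design/` at first run and read from there thereafter).
#' @param store optional [ObservationStore-class] consulted for internal
#'   filtering and updated with the batch's samples.
#' @param timestamp `FALSE` gives byte-identical outputs across reruns.
#' @param registerInStore register analysed samples in the store after
#'   reporting (default `TRUE`).
#' @return named list: `retained`, `removed`, `checks`, `files` (paths of
#'   all written outputs), `checkVerdicts`.
#' @export
runBatch <- function(batchDir, profilePath, store = NULL, timestamp = TRUE,
                     registerInStore = TRUE) {
    layout <- createBatchLayout(batchDir)
    designProfile <- .ensureDesign(layout, profilePath)
    profile <- parseProfile(designProfile)

    samplesFile <- file.path(layout$data, "samples.tsv")
    if (!file.exists(samplesFile))
        stop("batch has no data/samples.tsv", call. = FALSE)
    samples <- utils::read.delim(samplesFile, stringsAsFactors = FALSE)
    metricsFile <- file.path(layout$data, "metrics.tsv")
    metrics <- if (file.exists(metricsFile)) readSampleMetrics(metricsFile)
               else NULL
    exonsFile <- file.path(layout$data, "exons.bed")
    exons <- if (file.exists(exonsFile)) readExonBed(exonsFile) else NULL

    snapshotPath <- NULL
    if (!is.null(store)) {
        snapshotPath <- file.path(layout$qc, "observation_store_snapshot.db")
        snapshotStore(store, snapshotPath, timestamp = timestamp)
    }

    allRetained <- list(); allRemoved <- list(); allChecks <- list()
    allRecords <- list()
    verdicts <- character(0)
    inputs <- c(designProfile, samplesFile)
    threshold <- profile@coverageQcThreshold

    for (i in seq_len(nrow(samples))) {
        sid <- samples$sample_id[i]
        vcfPath <- file.path(layout$data, paste0(sid, ".vcf"))
        if (!file.exists(vcfPath))
            stop("missing VCF for sample ", sid, ": ", vcfPath,
                 call. = FALSE)
        inputs <- c(inputs, vcfPath)
        records <- readAnnotatedVcf(vcfPath, sampleId = sid)
        allRecords[[sid]] <- records
        res <- prioritiseVariants(records, profile, exons, store)
        allRetained[[sid]] <- res$retained
        allRemoved[[sid]] <- res$removed

        if (!is.null(metrics)) {
            m <- metrics[metrics$sample_id == sid, , drop = FALSE]
            if (nrow(m) == 1L) {
                if (!is.null(samples$sex))
                    m$declared_sex <- samples$sex[i]
                chk <- runSampleChecks(m, profile)
                verdicts[sid] <- attr(chk, "verdict")
                allChecks[[sid]] <- cbind(data.frame(sample = sid,
                    stringsAsFactors = FALSE), chk)
            }
        }

        covPath <- file.path(layout$data, paste0(sid, ".cov.tsv"))
        if (file.exists(covPath) && !is.null(exons)) {
            inputs <- c(inputs, covPath)
            track <- readPerBaseCoverage(covPath, sampleId = sid)
            gaps <- findGaps(track, threshold, exons)
            exRows <- suppressWarnings(exonReport(track, exons, threshold))
            gRows <- geneReport(exRows, track,
                                greenMinOk = profile@greenMinOk,
                                amberMinOk = profile@amberMinOk)
            utils::write.table(gaps,
                file.path(layout$qc, paste0(sid, ".gaps.tsv")),
                sep = "\t", row.names = FALSE, quote = FALSE)
            utils::write.table(exRows,
                file.path(layout$qc, paste0(sid, ".exons.tsv")),
                sep = "\t", row.names = FALSE, quote = FALSE)
            utils::write.table(gRows,
                file.path(layout$qc, paste0(sid, ".genes.tsv")),
                sep = "\t", row.names = FALSE, quote = FALSE)
        }
    }

    retained <- sortForReport(do.call(rbind, c(allRetained,
        list(make.row.names = FALSE))))
    removed <- do.call(rbind, c(allRemoved, list(make.row.names = FALSE)))
    checks <- if (length(allChecks))
        do.call(rbind, c(allChecks, list(make.row.names = FALSE)))
    else NULL

    files <- list(
        report = file.path(layout$results, "variant_report.csv"),
        lovd = file.path(layout$results, "variants_lovd.csv"),
        removed = file.path(layout$results, "variants_removed.csv"),
        provenance = file.path(layout$results, "provenance.json")
    )
    writeVariantReport(retained, files$report)
    writeLovdCsv(retained, files$lovd)
    writeRemovedReport(removed, files$removed)
    if (!is.null(checks)) {
        files$checks <- file.path(layout$results, "sample_checks.tsv")
        utils::write.table(checks, files$checks, sep = "\t",
                           row.names = FALSE, quote = FALSE)
        files$checksJson <- file.path(layout$results, "sample_checks.json")
        jsonlite::write_json(list(verdicts = as.list(verdicts),
                                  checks = checks),
                             files$checksJson, auto_unbox = TRUE,
                             pretty = TRUE, digits = NA)
    }
    writeProvenance(unique(inputs), profile,
                    unlist(files[names(files) != "provenance"],
                           use.names = FALSE),
                    files$provenance, timestamp = timestamp)

    if (!is.null(store) && registerInStore) {
        for (i in seq_len(nrow(samples))) {
            sid <- samples$sample_id[i]
            cohort <- if (!is.null(samples$cohort)) samples$cohort[i]
                      else NA_character_
            registerSample(store, sid, cohort, allRecords[[sid]])
        }
    }

    list(retained = retained, removed = removed, checks = checks,
         files = files, checkVerdicts = verdicts)
}
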