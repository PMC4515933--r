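## Internal variant-observation database: a single-file SQLite store of
## every variant observed in every sample analysed at a site. Presence
## only — no genotypes. Connections are opened per operation with a busy
## timeout, so concurrent writers see a retryable locked error rather than
## corruption, and a snapshot is always a consistent file copy.

.storeConnect <- function(store, create = FALSE) {
    if (!create && !file.exists(store@path))
        stop("observation store not found: ", store@path, call. = FALSE)
    con <- DBI::dbConnect(RSQLite::SQLite(), store@path)
    DBI::dbExecute(con, "PRAGMA busy_timeout = 5000")
    con
}

.storeInit <- function(con) {
    DBI::dbExecute(con, paste(
        "CREATE TABLE IF NOT EXISTS samples (",
        " sample_id TEXT PRIMARY KEY, cohort TEXT NOT NULL)"))
    DBI::dbExecute(con, paste(
        "CREATE TABLE IF NOT EXISTS observations (",
        " chrom TEXT NOT NULL, pos INTEGER NOT NULL,",
        " ref TEXT NOT NULL, alt TEXT NOT NULL, sample_id TEXT NOT NULL,",
        " UNIQUE(chrom, pos, ref, alt, sample_id))"))
    DBI::dbExecute(con,
        "CREATE INDEX IF NOT EXISTS idx_obs_key ON observations(chrom, pos, ref, alt)")
}

#' Create a new observation store
#'
#' Initialises an empty single-file SQLite observation database with
#' tables `samples(sample_id, cohort)` and
#' `observations(chrom, pos, ref, alt, sample_id)`.
#'
#' @param path file path for the new store; must not already exist unless
#'   `overwrite = TRUE`.
#' @param overwrite replace an existing file.
#' @return an [ObservationStore-class].
#' @export
createObservationStore <- function(path, overwrite = FALSE) {
    if (file.exists(path)) {
        if (!overwrite)
            stop("store already exists: ", path, call. = FALSE)
        unlink(path)
    }
    store <- new("ObservationStore", path = path)
    con <- .storeConnect(store, create = TRUE)
    on.exit(DBI::dbDisconnect(con))
    .storeInit(con)
    store
}

#' Open an existing observation store
#'
#' @param path path to a store file created by [createObservationStore()]
#'   or restored from a snapshot.
#' @return an [ObservationStore-class].
#' @export
openObservationStore <- function(path) {
    store <- new("ObservationStore", path = path)
    con <- .storeConnect(store)
    on.exit(DBI::dbDisconnect(con))
    tabs <- DBI::dbListTables(con)
    if (!all(c("samples", "observations") %in% tabs))
        stop("not an observation store (missing tables): ", path,
             call. = FALSE)
    store
}

#' Record one sample's observed variants
#'
#' Registers a sample (with its disease cohort) and the canonical keys of
#' all variants observed in it. The store accumulates samples over time as
#' analyses are run. Re-registering a sample replaces its previous
#' contribution entirely, so repeating a registration is idempotent.
#' Variant keys are canonicalised with [normalizeAlleles()] so that two
#' representations of the same allele collide on one key; duplicate keys
#' within a sample count once.
#'
#' @param store an [ObservationStore-class].
#' @param sampleId sample identifier.
#' @param cohort disease-cohort label for the sample.
#' @param variants data.frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @return the store, invisibly.
#' @export
registerSample <- function(store, sampleId, cohort, variants) {
    con <- .storeConnect(store)
    on.exit(DBI::dbDisconnect(con))
    norm <- normalizeAlleles(variants$pos, variants$ref, variants$alt)
    keys <- unique(data.frame(chrom = as.character(variants$chrom),
                              pos = norm$pos, ref = norm$ref, alt = norm$alt,
                              stringsAsFactors = FALSE))
    keys$sample_id <- rep(sampleId, nrow(keys))
    DBI::dbWithTransaction(con, {
        DBI::dbExecute(con, "DELETE FROM observations WHERE sample_id = ?",
                       params = list(sampleId))
        DBI::dbExecute(con, "DELETE FROM samples WHERE sample_id = ?",
                       params = list(sampleId))
        DBI::dbExecute(con,
            "INSERT INTO samples (sample_id, cohort) VALUES (?, ?)",
            params = list(sampleId, as.character(cohort)))
        if (nrow(keys))
            DBI::dbAppendTable(con, "observations", keys)
    })
    invisible(store)
}

#' @rdname storeAccessors
#' @name storeAccessors
#' @title Low-level store accessors
#' @description `totalSamples` returns the number of registered samples;
#'   `storeSamples` the sample/cohort table; `.storeObservations` (internal)
#'   the raw observation rows.
#' @param store an [ObservationStore-class].
#' @return see description.
#' @export
totalSamples <- function(store) {
    con <- .storeConnect(store)
    on.exit(DBI::dbDisconnect(con))
    as.integer(DBI::dbGetQuery(con, "SELECT COUNT(*) AS n FROM samples")$n)
}

#' @rdname storeAccessors
#' @export
storeSamples <- function(store) {
    con <- .storeConnect(store)
    on.exit(DBI::dbDisconnect(con))
    DBI::dbGetQuery(con, "SELECT sample_id, cohort FROM samples ORDER BY sample_id")
}

.storeObservations <- function(store) {
    con <- .storeConnect(store)
    on.exit(DBI::dbDisconnect(con))
    DBI::dbGetQuery(con,
        "SELECT chrom, pos, ref, alt, sample_id FROM observations")
}

.storeSampleCohorts <- function(store) {
    s <- storeSamples(store)
    stats::setNames(s$cohort, s$sample_id)
}

.observationStatsFrom <- function(hits, cohorts, nTotal, queryingCohort) {
    carriers <- unique(hits$sample_id)
    countTotal <- length(carriers)
    carrierCohorts <- cohorts[match(carriers, names(cohorts))]
    countOther <- if (is.na(queryingCohort) || is.null(queryingCohort))
        countTotal
    else sum(carrierCohorts != queryingCohort, na.rm = TRUE) +
        sum(is.na(carrierCohorts))
    list(count_total = countTotal,
         count_other_cohorts = as.integer(countOther),
         total_samples = nTotal,
         internal_frequency = if (nTotal > 0L) countTotal / nTotal else 0)
}

#' Observation statistics for one variant key
#'
#' Returns how often a variant has been seen in the store: the number of
#' distinct samples carrying it, how many of those belong to a different
#' disease cohort than the querying sample, the total number of registered
#' samples, and the internal observation frequency
#' (`count_total / total_samples`, 0 for an empty store).
#'
#' @param store an [ObservationStore-class].
#' @param chrom,pos,ref,alt the variant key (canonicalised internally).
#' @param queryingCohort cohort of the sample being analysed (`NA` counts
#'   every carrier as "other cohort").
#' @param excludeSample optional sample id whose own observations are
#'   ignored — used so a sample cannot filter itself at re-analysis.
#' @return list with `count_total`, `count_other_cohorts`,
#'   `total_samples`, `internal_frequency`.
#' @export
observationStats <- function(store, chrom, pos, ref, alt,
                             queryingCohort = NA_character_,
                             excludeSample = NULL) {
    norm <- normalizeAlleles(pos, ref, alt)
    con <- .storeConnect(store)
    on.exit(DBI::dbDisconnect(con))
    nTotal <- as.integer(
        DBI::dbGetQuery(con, "SELECT COUNT(*) AS n FROM samples")$n)
    hits <- DBI::dbGetQuery(con, paste(
        "SELECT o.sample_id, s.cohort FROM observations o",
        "JOIN samples s ON s.sample_id = o.sample_id",
        "WHERE o.chrom = ? AND o.pos = ? AND o.ref = ? AND o.alt = ?"),
        params = list(as.character(chrom), norm$pos, norm$ref, norm$alt))
    if (!is.null(excludeSample))
        hits <- hits[!hits$sample_id %in% excludeSample, , drop = FALSE]
    cohorts <- stats::setNames(hits$cohort, hits$sample_id)
    .observationStatsFrom(hits, cohorts, nTotal, queryingCohort)
}

#' Internal-database exclusion decision
#'
#' A variant is excluded when it has been observed in at least
#' `minOtherCohortSamples` samples belonging to other disease cohorts —
#' such recurrence across unrelated phenotypes marks private population
#' variants and sequencing artefacts — or when its internal observation
#' frequency exceeds `maxInternalFrequency` (arm disabled when `NA`). The
#' policy never fires while the store holds fewer than two samples.
#'
#' @param stats result of [observationStats()].
#' @param policy list with `minOtherCohortSamples` and
#'   `maxInternalFrequency`, see [internalFilterPolicy()].
#' @return logical: exclude the variant?
#' @export
internalFilterDecision <- function(stats, policy) {
    if (stats$total_samples < 2L) return(FALSE)
    byCohort <- stats$count_other_cohorts >= policy$minOtherCohortSamples
    byFreq <- !is.na(policy$maxInternalFrequency) &&
        stats$internal_frequency > policy$maxInternalFrequency
    isTRUE(byCohort || byFreq)
}

#' Snapshot the observation store
#'
#' Copies the store file byte-for-byte and writes a JSON manifest sidecar
#' (`<snapshot>.manifest.json`) recording the sample count, an MD5 content
#' digest and (unless `timestamp = FALSE`) the time of capture. Archiving
#' a snapshot before each analysis pins the only quantity that legitimately
#' drifts between re-analyses — the internal observation frequency — so a
#' restored snapshot reproduces identical filtering decisions.
#'
#' @param store an [ObservationStore-class].
#' @param outPath destination file path for the snapshot copy.
#' @param timestamp include the capture time in the manifest (`FALSE`
#'   yields byte-identical manifests across reruns).
#' @return an [ObservationStore-class] opened on the snapshot file.
#' @export
snapshotStore <- function(store, outPath, timestamp = TRUE) {
    if (!file.exists(store@path))
        stop("observation store not found: ", store@path, call. = FALSE)
    dir.create(dirname(outPath), recursive = TRUE, showWarnings = FALSE)
    ok <- file.copy(store@path, outPath, overwrite = TRUE)
    if (!ok)
        stop("cannot write snapshot to: ", outPath, call. = FALSE)
    snap <- openObservationStore(outPath)
    manifest <- list(
        source = store@path,
        samples = totalSamples(snap),
        md5 = unname(tools::md5sum(outPath))
    )
    if (timestamp)
        manifest$created <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    jsonlite::write_json(manifest, paste0(outPath, ".manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    snap
}
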