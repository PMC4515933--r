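## Three-level coverage QC: base-pair gap report, exon report, gene report,
## from per-base depth tracks (BEDTools `coverage -d`-style TSV).

#' Lower median
#'
#' Median convention used throughout the coverage reports: for
#' even-length input the lower of the two middle values is taken, so the
#' result is always an observed depth.
#'
#' @param x numeric vector.
#' @return the lower median, `NA` for empty input.
#' @export
lowerMedian <- function(x) {
    if (length(x) == 0L) return(NA_real_)
    s <- sort(x)
    as.numeric(s[ceiling(length(s) / 2)])
}

#' Read a per-base coverage file
#'
#' Reads the TSV produced by per-base coverage tools (`coverage -d`
#' style): columns chrom, start, end, optional name, offset (1-based
#' position within the interval) and depth. Offsets must be contiguous
#' `1..(end-start)` within each interval; a missing or non-monotone offset
#' or a negative depth is a parse error reported with its line number.
#' Intervals are returned sorted in karyotype order.
#'
#' @param path path to the coverage TSV.
#' @param sampleId sample identifier for the track; defaults to the file
#'   base name.
#' @return a [CoverageTrack-class].
#' @export
readPerBaseCoverage <- function(path, sampleId = NULL) {
    if (!file.exists(path))
        stop("coverage file not found: ", path, call. = FALSE)
    if (is.null(sampleId))
        sampleId <- sub("\\..*$", "", basename(path))
    raw <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
    nc <- ncol(raw)
    if (!nc %in% c(5L, 6L))
        stop("coverage file must have 5 or 6 columns, found ", nc,
             call. = FALSE)
    names(raw) <- if (nc == 6L)
        c("chrom", "start", "end", "name", "offset", "depth")
    else c("chrom", "start", "end", "offset", "depth")
    if (any(raw$depth < 0))
        stop("negative depth at line ", which(raw$depth < 0)[1],
             call. = FALSE)

    id <- paste(raw$chrom, raw$start, raw$end, sep = ":")
    groups <- split(seq_len(nrow(raw)), factor(id, levels = unique(id)))
    chrom <- character(0); start <- integer(0); end <- integer(0)
    depths <- list()
    for (g in groups) {
        len <- raw$end[g[1]] - raw$start[g[1]]
        off <- raw$offset[g]
        if (!identical(as.integer(off), seq_len(len))) {
            bad <- which(as.integer(off) != seq_along(off))[1]
            stop("offsets for interval ", id[g[1]],
                 " are not contiguous 1..", len, " (line ",
                 g[if (is.na(bad)) length(g) else bad], ")", call. = FALSE)
        }
        chrom <- c(chrom, raw$chrom[g[1]])
        start <- c(start, raw$start[g[1]])
        end <- c(end, raw$end[g[1]])
        depths <- c(depths, list(as.integer(raw$depth[g])))
    }
    o <- order(.chromRank(chrom), start)
    gr <- GenomicRanges::GRanges(chrom[o],
        IRanges::IRanges(start = start[o] + 1L, end = end[o]))
    new("CoverageTrack", sampleId = sampleId, intervals = gr,
        depths = IRanges::IntegerList(depths[o]))
}

#' Construct a coverage track in memory
#'
#' @param sampleId sample identifier.
#' @param chrom,start,end interval coordinates (0-based half-open, one
#'   entry per interval).
#' @param depths list of integer vectors, one per interval, length
#'   `end - start`.
#' @return a [CoverageTrack-class].
#' @export
coverageTrack <- function(sampleId, chrom, start, end, depths) {
    o <- order(.chromRank(chrom), start)
    gr <- GenomicRanges::GRanges(chrom[o],
        IRanges::IRanges(start = as.integer(start[o]) + 1L,
                         end = as.integer(end[o])))
    new("CoverageTrack", sampleId = sampleId, intervals = gr,
        depths = IRanges::IntegerList(lapply(depths[o], as.integer)))
}

#' Base-pair gap report: regions below the coverage threshold
#'
#' Finds every maximal run of consecutive target bases whose depth is
#' strictly below `threshold` ("below" is strict: a base exactly at the
#' threshold is covered). Gaps are reported at base-pair resolution with
#' their length, minimum and (lower) median depth, and annotated with the
#' overlapping gene and exon rank when an exon model is supplied.
#'
#' @param track a [CoverageTrack-class].
#' @param threshold depth threshold (>= 1).
#' @param exons optional exon `GRanges` from [readExonBed()].
#' @return data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `length`, `min_depth`, `median_depth`, `gene`,
#'   `exon_rank`, sorted by (chrom, start).
#' @export
findGaps <- function(track, threshold, exons = NULL) {
    stopifnot(threshold >= 1)
    out <- list()
    iv <- track@intervals
    for (i in seq_along(iv)) {
        d <- track@depths[[i]]
        below <- d < threshold
        if (!any(below)) next
        r <- rle(below)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        sel <- which(r$values)
        iv0 <- GenomicRanges::start(iv)[i] - 1L   # back to 0-based
        for (j in sel) {
            seg <- d[starts[j]:ends[j]]
            out[[length(out) + 1L]] <- data.frame(
                chrom = as.character(GenomicRanges::seqnames(iv)[i]),
                start = iv0 + starts[j] - 1L,
                end = iv0 + ends[j],
                length = r$lengths[j],
                min_depth = min(seg),
                median_depth = lowerMedian(seg),
                stringsAsFactors = FALSE)
        }
    }
    if (!length(out)) {
        return(data.frame(chrom = character(0), start = integer(0),
            end = integer(0), length = integer(0), min_depth = integer(0),
            median_depth = numeric(0), gene = character(0),
            exon_rank = integer(0), stringsAsFactors = FALSE))
    }
    gaps <- do.call(rbind, out)
    gaps <- gaps[order(.chromRank(gaps$chrom), gaps$start), , drop = FALSE]
    rownames(gaps) <- NULL
    gaps$gene <- NA_character_
    gaps$exon_rank <- NA_integer_
    if (!is.null(exons) && length(exons)) {
        gapGr <- GenomicRanges::GRanges(gaps$chrom,
            IRanges::IRanges(start = gaps$start + 1L, end = gaps$end))
        hit <- GenomicRanges::findOverlaps(gapGr, exons, select = "first")
        ok <- !is.na(hit)
        gaps$gene[ok] <- mcols(exons)$gene[hit[ok]]
        gaps$exon_rank[ok] <- mcols(exons)$exon_rank[hit[ok]]
    }
    gaps
}

## per-base depths of a track over an arbitrary interval; bases in the
## target model but absent from the track count as depth 0 (dropout).
.trackDepthsOver <- function(track, chrom, start1, end1) {
    d <- rep(0L, end1 - start1 + 1L)
    iv <- track@intervals
    sel <- which(as.character(GenomicRanges::seqnames(iv)) == chrom &
                 GenomicRanges::start(iv) <= end1 &
                 GenomicRanges::end(iv) >= start1)
    covered <- 0L
    for (i in sel) {
        s <- max(GenomicRanges::start(iv)[i], start1)
        e <- min(GenomicRanges::end(iv)[i], end1)
        off <- s - GenomicRanges::start(iv)[i] + 1L
        d[(s - start1 + 1L):(e - start1 + 1L)] <-
            track@depths[[i]][off:(off + e - s)]
        covered <- covered + (e - s + 1L)
    }
    attr(d, "uncovered") <- length(d) - covered
    d
}

#' Exon-level coverage report
#'
#' One row per exon of the exon model: the fraction of its bases whose
#' depth is strictly below the threshold, the (lower) median depth, and a
#' status — `FULL` when no base is below, `NONE` when every base is below,
#' `PARTIAL` otherwise. Exon bases outside the coverage track count as
#' depth 0 (sequencing dropout) and trigger a single warning.
#'
#' @param track a [CoverageTrack-class].
#' @param exons exon `GRanges` from [readExonBed()].
#' @param threshold depth threshold (>= 1).
#' @return data.frame with columns `gene`, `exon_rank`, `chrom`, `start`,
#'   `end` (0-based half-open), `length`, `bases_below`,
#'   `fraction_below_threshold`, `median_depth`, `status`.
#' @export
exonReport <- function(track, exons, threshold) {
    stopifnot(threshold >= 1)
    n <- length(exons)
    rows <- vector("list", n)
    anyUncovered <- FALSE
    for (i in seq_len(n)) {
        chrom <- as.character(GenomicRanges::seqnames(exons)[i])
        s1 <- GenomicRanges::start(exons)[i]
        e1 <- GenomicRanges::end(exons)[i]
        d <- .trackDepthsOver(track, chrom, s1, e1)
        if (attr(d, "uncovered") > 0L) anyUncovered <- TRUE
        below <- sum(d < threshold)
        len <- length(d)
        status <- if (below == 0L) "FULL"
                  else if (below == len) "NONE"
                  else "PARTIAL"
        rows[[i]] <- data.frame(
            gene = mcols(exons)$gene[i],
            exon_rank = mcols(exons)$exon_rank[i],
            chrom = chrom, start = s1 - 1L, end = e1, length = len,
            bases_below = below,
            fraction_below_threshold = below / len,
            median_depth = lowerMedian(d),
            status = status, stringsAsFactors = FALSE)
    }
    if (anyUncovered)
        warning("some exon bases are absent from the coverage track; ",
                "counted as depth 0", call. = FALSE)
    out <- do.call(rbind, rows)
    if (is.null(out))
        out <- data.frame(gene = character(0), exon_rank = integer(0),
            chrom = character(0), start = integer(0), end = integer(0),
            length = integer(0), bases_below = integer(0),
            fraction_below_threshold = numeric(0),
            median_depth = numeric(0), status = character(0),
            stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}

#' Gene-level coverage report with traffic-light colours
#'
#' Aggregates the exon report per gene so a curator can assess at a glance
#' whether coverage is adequate over the genes of interest: the fraction
#' of targeted bases at/above the threshold, the (lower) median depth over
#' all targeted bases, exon counts, and a colour — `GREEN` when the ok
#' fraction is at least `greenMinOk` **and** no exon is entirely uncovered
#' (a `NONE` exon vetoes green even at high overall coverage), `AMBER`
#' when the ok fraction is at least `amberMinOk`, `RED` otherwise.
#'
#' @param exonRows output of [exonReport()].
#' @param track the same [CoverageTrack-class] (for per-gene median depth).
#' @param greenMinOk,amberMinOk colour thresholds on the ok fraction;
#'   `amberMinOk` must be `< greenMinOk`. Defaults 0.95 / 0.80.
#' @return data.frame with columns `gene`, `median_depth`,
#'   `fraction_targeted_bases_ok`, `n_exons`, `n_exons_partial_or_none`,
#'   `colour`.
#' @export
geneReport <- function(exonRows, track, greenMinOk = 0.95,
                       amberMinOk = 0.80) {
    stopifnot(amberMinOk < greenMinOk)
    genes <- unique(exonRows$gene)
    rows <- lapply(genes, function(g) {
        er <- exonRows[exonRows$gene == g, , drop = FALSE]
        totalLen <- sum(er$length)
        below <- sum(er$bases_below)
        okFrac <- if (totalLen > 0L) 1 - below / totalLen else NA_real_
        d <- unlist(lapply(seq_len(nrow(er)), function(i)
            as.integer(.trackDepthsOver(track, er$chrom[i],
                                        er$start[i] + 1L, er$end[i]))))
        colour <- if (!is.na(okFrac) && okFrac >= greenMinOk &&
                      !any(er$status == "NONE")) "GREEN"
                  else if (!is.na(okFrac) && okFrac >= amberMinOk) "AMBER"
                  else "RED"
        data.frame(gene = g, median_depth = lowerMedian(d),
            fraction_targeted_bases_ok = okFrac,
            n_exons = nrow(er),
            n_exons_partial_or_none = sum(er$status != "FULL"),
            colour = colour, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        out <- data.frame(gene = character(0), median_depth = numeric(0),
            fraction_targeted_bases_ok = numeric(0), n_exons = integer(0),
            n_exons_partial_or_none = integer(0), colour = character(0),
            stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}
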