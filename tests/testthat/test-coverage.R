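test_that("per-base coverage files parse into tracks, with line-accurate errors", {
    f <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c(
        "chr1\t100\t106\tG1_exon1\t1\t10",
        "chr1\t100\t106\tG1_exon1\t2\t10",
        "chr1\t100\t106\tG1_exon1\t3\t3",
        "chr1\t100\t106\tG1_exon1\t4\t4",
        "chr1\t100\t106\tG1_exon1\t5\t10",
        "chr1\t100\t106\tG1_exon1\t6\t2",
        "chr2\t500\t503\tG2_exon1\t1\t30",
        "chr2\t500\t503\tG2_exon1\t2\t30",
        "chr2\t500\t503\tG2_exon1\t3\t30"), f)
    track <- readPerBaseCoverage(f, "S1")
    expect_s4_class(track, "CoverageTrack")
    expect_equal(length(track@intervals), 2L)
    expect_equal(as.integer(track@depths[[1]]), c(10L, 10L, 3L, 4L, 10L, 2L))

    # a missing offset is a parse error naming the line
    bad <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c(
        "chr1\t100\t106\tG1\t1\t10",
        "chr1\t100\t106\tG1\t2\t10",
        "chr1\t100\t106\tG1\t3\t3",
        "chr1\t100\t106\tG1\t5\t10",
        "chr1\t100\t106\tG1\t6\t2"), bad)
    expect_error(readPerBaseCoverage(bad), "contiguous")

    neg <- withr::local_tempfile(fileext = ".tsv")
    writeLines("chr1\t0\t1\tG1\t1\t-3", neg)
    expect_error(readPerBaseCoverage(neg), "negative depth")
})

test_that("gap finding reproduces the worked example with maximality", {
    track <- coverageTrack("S1", "chr1", 100L, 106L,
                           list(c(10L, 10L, 3L, 4L, 10L, 2L)))
    gaps <- findGaps(track, 5)
    expect_equal(nrow(gaps), 2L)
    expect_equal(gaps$start, c(102L, 105L))
    expect_equal(gaps$end, c(104L, 106L))
    expect_equal(gaps$length, c(2L, 1L))
    expect_equal(gaps$min_depth, c(3L, 2L))
    # all depths at/above threshold: no gaps
    ok <- coverageTrack("S1", "chr1", 0L, 4L, list(rep(5L, 4L)))
    expect_equal(nrow(findGaps(ok, 5)), 0L)
    # all below: one gap spanning the interval
    low <- coverageTrack("S1", "chr1", 10L, 14L, list(rep(1L, 4L)))
    g <- findGaps(low, 5)
    expect_equal(nrow(g), 1L)
    expect_equal(c(g$start, g$end), c(10L, 14L))
})

test_that("gap finding equals a brute-force per-base scan on random tracks", {
    set.seed(2024)
    for (rep in 1:100) {
        len <- sample(20:400, 1)
        threshold <- sample(2:30, 1)
        # mixture concentrating depths near the threshold to hit the edge
        depths <- as.integer(sample(c(threshold - 1L, threshold,
                                      threshold + 1L, 0L,
                                      sample(0:60, 5)), len,
                                    replace = TRUE))
        start0 <- sample(1000L, 1)
        track <- coverageTrack("S", "chr1", start0, start0 + len,
                               list(depths))
        got <- findGaps(track, threshold)
        exp <- bruteForceGaps("chr1", start0, depths, threshold)
        expect_equal(nrow(got), nrow(exp))
        expect_equal(got$start, exp$start)
        expect_equal(got$end, exp$end)
        expect_equal(got$min_depth, exp$min_depth)
        # depth == threshold is covered, never inside a gap
        for (k in seq_len(nrow(got))) {
            seg <- depths[(got$start[k] - start0 + 1L):(got$end[k] - start0)]
            expect_true(all(seg < threshold))
        }
    }
})

test_that("raising the threshold never shrinks or removes a gap", {
    set.seed(5)
    for (rep in 1:20) {
        depths <- as.integer(sample(0:40, 200, replace = TRUE))
        track <- coverageTrack("S", "chr1", 0L, 200L, list(depths))
        lo <- findGaps(track, 10)
        hi <- findGaps(track, 25)
        # every low-threshold gap lies within some high-threshold gap
        for (k in seq_len(nrow(lo))) {
            expect_true(any(hi$start <= lo$start[k] & hi$end >= lo$end[k]))
        }
        expect_gte(sum(hi$length), sum(lo$length))
    }
})

test_that("exon report fractions, statuses and dropout handling", {
    ex <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(start = c(101, 301, 601), width = 10))
    S4Vectors::mcols(ex)$gene <- c("G1", "G1", "G2")
    S4Vectors::mcols(ex)$exon_rank <- c(1L, 2L, 1L)
    track <- coverageTrack("S1", c("chr1", "chr1"), c(100L, 300L),
        c(110L, 310L),
        list(rep(50L, 10L), c(rep(50L, 5L), rep(2L, 5L))))
    expect_warning(rows <- exonReport(track, ex, 15), "depth 0")
    expect_equal(rows$status, c("FULL", "PARTIAL", "NONE"))
    expect_equal(rows$fraction_below_threshold, c(0, 0.5, 1))
    # status invariant: FULL <=> fraction 0, NONE <=> fraction 1
    expect_true(all((rows$status == "FULL") ==
                    (rows$fraction_below_threshold == 0)))
    expect_true(all((rows$status == "NONE") ==
                    (rows$fraction_below_threshold == 1)))
})

test_that("per-exon gap lengths and below-threshold counts agree exactly", {
    set.seed(77)
    for (rep in 1:30) {
        len <- 120L
        depths <- as.integer(sample(c(0:20, 40), len, replace = TRUE))
        start0 <- 1000L
        track <- coverageTrack("S", "chr1", start0, start0 + len,
                               list(depths))
        # three exons tiling the interval
        ex <- GenomicRanges::GRanges("chr1",
            IRanges::IRanges(start = start0 + c(1L, 41L, 81L), width = 40))
        S4Vectors::mcols(ex)$gene <- "G1"
        S4Vectors::mcols(ex)$exon_rank <- 1:3
        threshold <- 15
        gaps <- findGaps(track, threshold)
        rows <- exonReport(track, ex, threshold)
        for (k in 1:3) {
            exStart0 <- start0 + (k - 1L) * 40L
            exEnd0 <- exStart0 + 40L
            overlap <- pmax(0L, pmin(gaps$end, exEnd0) -
                                pmax(gaps$start, exStart0))
            expect_identical(sum(overlap), rows$bases_below[k])
            expect_identical(rows$bases_below[k] ==
                round(rows$fraction_below_threshold[k] * rows$length[k]),
                TRUE)
        }
    }
})

test_that("gene report colours follow the documented decision table", {
    mkRows <- function(fracs, statuses, lens = rep(100L, length(fracs))) {
        data.frame(gene = "G", exon_rank = seq_along(fracs),
            chrom = "chr1",
            start = seq_along(fracs) * 1000L,
            end = seq_along(fracs) * 1000L + lens,
            length = lens, bases_below = as.integer(round(fracs * lens)),
            fraction_below_threshold = fracs,
            median_depth = 50, status = statuses,
            stringsAsFactors = FALSE)
    }
    emptyTrack <- coverageTrack("S", character(0), integer(0), integer(0),
                                list())
    # all exons full -> GREEN
    g <- geneReport(mkRows(c(0, 0), c("FULL", "FULL")), emptyTrack)
    expect_equal(g$colour, "GREEN")
    # one NONE exon vetoes GREEN even at 97% ok overall
    g <- geneReport(mkRows(c(0, 0, 1), c("FULL", "FULL", "NONE"),
                           lens = c(1000L, 1000L, 67L)), emptyTrack)
    expect_gte(g$fraction_targeted_bases_ok, 0.95)
    expect_equal(g$colour, "AMBER")
    # middling coverage -> AMBER; poor -> RED
    g <- geneReport(mkRows(c(0.15), "PARTIAL"), emptyTrack)
    expect_equal(g$colour, "AMBER")
    g <- geneReport(mkRows(c(0.5), "PARTIAL"), emptyTrack)
    expect_equal(g$colour, "RED")
    expect_error(geneReport(mkRows(0, "FULL"), emptyTrack,
                            greenMinOk = 0.8, amberMinOk = 0.9))
})

test_that("lower-median convention on even-length input", {
    expect_equal(lowerMedian(c(4L, 1L, 3L, 2L)), 2)   # not 2.5
    expect_equal(lowerMedian(c(5L, 1L, 9L)), 5)
    expect_true(is.na(lowerMedian(integer(0))))
    # gap median uses the same convention
    track <- coverageTrack("S", "chr1", 0L, 4L, list(c(1L, 2L, 3L, 4L)))
    g <- findGaps(track, 10)
    expect_equal(g$median_depth, 2)
})
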