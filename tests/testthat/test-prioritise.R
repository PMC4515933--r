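test_that("VPI matches the printed tier rules on the full decision table", {
    profile <- analysisProfile("T")
    classes <- c("TRUNCATING", "FRAMESHIFT", "SPLICE", "MISSENSE",
                 "INFRAME_INDEL", "SYNONYMOUS", "OTHER")
    afBands <- c("absent", "lt_very_rare", "mid", "common")
    condelBands <- c("absent", "below", "above")
    grid <- expand.grid(class = classes, af = afBands, condel = condelBands,
                        stringsAsFactors = FALSE)
    for (i in seq_len(nrow(grid))) {
        g <- grid[i, ]
        got <- assignVpi(g$class, afBandValue(g$af),
                         condelBandValue(g$condel), FALSE, profile)
        expect_identical(got,
            expectedVpiFromBands(g$class, g$af, g$condel),
            info = paste(g$class, g$af, g$condel))
    }
})

test_that("VPI worked examples behave as documented", {
    p <- analysisProfile("T")
    # rare but not very rare missense
    expect_identical(assignVpi("MISSENSE", max(c(0.005, 0.004, 0.008)),
                               0.9, FALSE, p), 1L)
    # novel + conserved missense
    expect_identical(assignVpi("MISSENSE", NA, 0.9, FALSE, p), 3L)
    # very rare but unconserved
    expect_identical(assignVpi("MISSENSE", 0.0001, 0.05, FALSE, p), 2L)
    # frameshift ignores frequency by default
    expect_identical(assignVpi("FRAMESHIFT", 0.3, NA, FALSE, p), 4L)
    # ...unless the profile switch applies the AF cut to tier 4
    p2 <- analysisProfile("T", applyAfToVpi4 = TRUE)
    expect_identical(assignVpi("FRAMESHIFT", 0.3, NA, FALSE, p2), 0L)
    expect_identical(assignVpi("FRAMESHIFT", 0.005, NA, FALSE, p2), 4L)
    # synonymous never reaches a tier
    expect_identical(assignVpi("SYNONYMOUS", NA, NA, FALSE, p), 0L)
    # an intronic variant inside the splice window is tier 4
    expect_identical(assignVpi("OTHER", NA, NA, TRUE, p), 4L)
    # Condel exactly at the threshold is not conserved (strict >)
    expect_identical(assignVpi("MISSENSE", NA, 0.07, FALSE, p), 2L)
    # AF exactly at a threshold is not below it (strict <)
    expect_identical(assignVpi("MISSENSE", 0.01, NA, FALSE, p), 0L)
    expect_identical(assignVpi("MISSENSE", 0.0005, NA, FALSE, p), 1L)
})

test_that("tiers one to three are nested and thresholds act monotonically", {
    p <- analysisProfile("T")
    set.seed(11)
    afs <- c(NA, runif(200, 0, 0.02))
    condels <- sample(c(NA, runif(10)), 201, replace = TRUE)
    vpi <- assignVpi(rep("MISSENSE", 201), afs, condels, FALSE, p)
    # the tier-k predicate implies the tier-(k-1) predicate
    belowRare <- is.na(afs) | afs < p@rareAfThreshold
    belowVeryRare <- is.na(afs) | afs < p@veryRareAfThreshold
    expect_true(all(vpi[vpi >= 2] <= 3))
    expect_true(all(belowVeryRare[vpi >= 2]))
    expect_true(all(belowRare[vpi >= 1]))
    # tightening very-rare never raises any VPI
    pTight <- analysisProfile("T", veryRareAfThreshold = 0.0001)
    vpiTight <- assignVpi(rep("MISSENSE", 201), afs, condels, FALSE, pTight)
    expect_true(all(vpiTight <= vpi))
})

test_that("GPI equals the gene category and handles missing genes", {
    p <- testProfile()
    expect_identical(assignGpi("GENE02", p), 2L)   # known causal
    expect_identical(assignGpi(NA_character_, p), 0L)
    expect_identical(assignGpi("GENE03", p), 3L)   # known + insilico: max
    expect_identical(assignGpi("GENE05", p), 4L)
    expect_identical(assignGpi(recordRows(1, gene = "OFFPANEL"), p), 0L)
})

test_that("filters partition the input and give the documented reasons", {
    p <- testProfile(minVariantCoverage = 20L, minVariantQual = 100)
    rec <- rbind(
        recordRows(1, vpi = 2L, gpi = 1L),                       # retained
        recordRows(1, vpi = 0L, gpi = 1L, pos = 200L),           # hidden
        recordRows(1, vpi = 4L, gpi = 0L, gene = "GENE10",
                   pos = 300L),                                  # excluded
        recordRows(1, vpi = 4L, gpi = 0L, gene = "OFFPANEL",
                   pos = 400L),                                  # off target
        recordRows(1, vpi = 3L, gpi = 2L, depth = 5L,
                   pos = 500L),                                  # low depth
        recordRows(1, vpi = 3L, gpi = 2L, qual = 10, pos = 600L))# low qual
    res <- applyFilters(rec, p)
    expect_equal(nrow(res$retained) + nrow(res$removed), nrow(rec))
    expect_equal(nrow(res$retained), 1L)
    reasons <- res$removed$filter_reasons
    expect_match(reasons[res$removed$pos == 200], "HIDDEN_BELOW_VPI1")
    expect_match(reasons[res$removed$pos == 300], "GENE_EXCLUDED")
    expect_false(grepl("GENE_OFF_TARGET",
                       reasons[res$removed$pos == 300]))
    expect_match(reasons[res$removed$pos == 400], "GENE_OFF_TARGET")
    expect_match(reasons[res$removed$pos == 500], "LOW_DEPTH")
    expect_match(reasons[res$removed$pos == 600], "LOW_QUAL")
    # retained records carry no reasons and gained store columns
    expect_true(all(c("obs_count", "obs_frequency") %in%
                    names(res$retained)))
    expect_equal(res$retained$obs_count, 0L)
})

test_that("internal-database policy removes recurrent cross-cohort variants", {
    p <- testProfile(dbMinOtherCohortSamples = 3L)
    store <- createObservationStore(withr::local_tempfile(fileext = ".db"))
    # variant seen in 5 prior samples across 3 other cohorts
    for (i in 1:5) {
        registerSample(store, sprintf("P%d", i),
                       c("EPIL", "RENAL", "NEURO")[(i %% 3) + 1],
                       data.frame(chrom = "chr1", pos = 100L,
                                  ref = "A", alt = "G"))
    }
    rec <- rbind(recordRows(1, pos = 100L, vpi = 4L, gpi = 1L),
                 recordRows(1, pos = 900L, vpi = 2L, gpi = 1L))
    rec$sample_id <- "S_NEW"
    res <- applyFilters(rec, p, store)
    expect_equal(nrow(res$removed), 1L)
    expect_match(res$removed$filter_reasons, "INTERNAL_DB_COMMON")
    expect_equal(res$removed$pos, 100L)
    expect_equal(res$removed$obs_count, 5L)
    # the unseen variant is untouched
    expect_equal(res$retained$pos, 900L)
})

test_that("a sample's own prior observations never filter it", {
    p <- testProfile(dbMinOtherCohortSamples = 1L)
    store <- createObservationStore(withr::local_tempfile(fileext = ".db"))
    registerSample(store, "S1", "CARDIO",
                   data.frame(chrom = "chr1", pos = 100L, ref = "A",
                              alt = "G"))
    registerSample(store, "S2", "EPIL",
                   data.frame(chrom = "chr1", pos = 500L, ref = "C",
                              alt = "T"))
    rec <- recordRows(1, pos = 100L)   # sample_id S1, same variant again
    res <- applyFilters(rec, p, store)
    expect_equal(nrow(res$retained), 1L)
})

test_that("report ordering is stable, karyotypic and permutation-invariant", {
    rec <- rbind(
        recordRows(1, vpi = 4L, gpi = 4L, chrom = "chr2", pos = 50L),
        recordRows(1, vpi = 4L, gpi = 1L, chrom = "chr1", pos = 10L),
        recordRows(1, vpi = 1L, gpi = 4L, chrom = "chr1", pos = 5L),
        recordRows(1, vpi = 2L, gpi = 2L, chrom = "chrX", pos = 7L),
        recordRows(1, vpi = 2L, gpi = 2L, chrom = "chr10", pos = 7L),
        recordRows(1, vpi = 2L, gpi = 2L, chrom = "chr2", pos = 7L,
                   alt = "T"),
        recordRows(1, vpi = 2L, gpi = 2L, chrom = "chr2", pos = 7L,
                   alt = "A"))
    sorted <- sortForReport(rec)
    expect_equal(sorted$vpi[1:2], c(4L, 4L))
    expect_equal(sorted$gpi[1:2], c(4L, 1L))          # VPI before GPI
    expect_equal(sorted$vpi[nrow(sorted)], 1L)
    # karyotype order: chr2 before chr10 before chrX
    sub <- sorted[sorted$vpi == 2L, ]
    expect_equal(sub$chrom, c("chr2", "chr2", "chr10", "chrX"))
    # tie on everything but alt: A before T
    expect_equal(sub$alt[1:2], c("A", "T"))
    # permutation invariance
    set.seed(3)
    for (i in 1:20) {
        perm <- rec[sample(nrow(rec)), , drop = FALSE]
        expect_equal(sortForReport(perm), sorted)
    }
    # degenerate inputs
    expect_equal(nrow(sortForReport(rec[0, ])), 0L)
    expect_equal(sortForReport(rec[1, ]), {
        x <- rec[1, ]; rownames(x) <- NULL; x })
})
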