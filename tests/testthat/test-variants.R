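test_that("allele canonicalisation trims shared context deterministically", {
    # frozen expected form for the padded deletion
    n <- normalizeAlleles(100L, "CTT", "CT")
    expect_equal(n$pos, 101L)
    expect_equal(n$ref, "TT")
    expect_equal(n$alt, "T")

    # oracle by construction: pad a known minimal variant with context on
    # either side; canonicalisation must recover one fixed form for all
    # paddings of the same allele
    minimal <- list(
        list(pos = 200L, ref = "A", alt = "G"),        # SNV
        list(pos = 200L, ref = "AT", alt = "A"),       # 1 bp deletion
        list(pos = 200L, ref = "A", alt = "ACG"),      # insertion
        list(pos = 200L, ref = "ACGT", alt = "A"),     # 3 bp deletion
        list(pos = 200L, ref = "AC", alt = "GT"))      # MNV
    pads <- c("", "G", "GA", "GAT", "TTAC")
    for (m in minimal) {
        forms <- lapply(pads, function(p) {
            normalizeAlleles(m$pos - nchar(p),
                             paste0(p, m$ref, "GG"),
                             paste0(p, m$alt, "GG"))
        })
        canon <- forms[[1]]
        for (f in forms[-1]) expect_equal(f, canon,
            info = paste(m$ref, ">", m$alt))
        # canonical form has no trimmable shared context left
        r <- strsplit(canon$ref, "")[[1]]; a <- strsplit(canon$alt, "")[[1]]
        expect_false(length(r) > 1 && length(a) > 1 && r[1] == a[1])
        expect_false(length(r) > 1 && length(a) > 1 &&
                     r[length(r)] == a[length(a)])
    }

    # symbolic alleles pass through untouched
    s <- normalizeAlleles(500L, "A", "<DEL>")
    expect_equal(s$alt, "<DEL>")
    expect_equal(s$pos, 500L)
})

test_that("consequence normalisation is total, deterministic and both-vocabulary", {
    expect_equal(normalizeConsequence("stopgain"), "TRUNCATING")
    expect_equal(normalizeConsequence("stop_gained"), "TRUNCATING")
    expect_equal(normalizeConsequence("synonymous_variant"), "SYNONYMOUS")
    expect_equal(normalizeConsequence("upstream_gene_variant"), "OTHER")
    expect_equal(normalizeConsequence("nonsynonymous SNV"), "MISSENSE")
    expect_equal(normalizeConsequence("frameshift deletion"), "FRAMESHIFT")
    expect_equal(normalizeConsequence("splice_acceptor_variant"), "SPLICE")
    expect_equal(normalizeConsequence("inframe_deletion"), "INFRAME_INDEL")
    # most severe wins on multi-term annotations
    expect_equal(normalizeConsequence("synonymous_variant&stop_gained"),
                 "TRUNCATING")
    expect_equal(normalizeConsequence("missense_variant,splice_region_variant"),
                 "SPLICE")
    # never raises, covers the whole class set over the shipped vocabulary
    vocab <- utils::read.delim(system.file("extdata",
        "consequence_map.tsv", package = "panelTriage"))
    got <- normalizeConsequence(c(vocab$term, NA, "", "garbage#1"))
    expect_true(all(got %in% c("TRUNCATING", "FRAMESHIFT", "SPLICE",
        "MISSENSE", "INFRAME_INDEL", "SYNONYMOUS", "OTHER")))
    expect_setequal(unique(got), c("TRUNCATING", "FRAMESHIFT", "SPLICE",
        "MISSENSE", "INFRAME_INDEL", "SYNONYMOUS", "OTHER"))
})

test_that("splice-region classification matches the positional definition", {
    ex <- IRanges::IRanges(101, 200)   # exon covering 1-based 101..200
    # enumerate every position around the exon against the brute oracle
    for (p in 95:210) {
        expect_identical(classifySpliceRegion(p, ex, 2),
                         bruteForceSplice(p, 101, 200, 2),
                         info = paste("pos", p))
    }
    expect_true(classifySpliceRegion(201, ex, 2))
    expect_false(classifySpliceRegion(150, ex, 2))   # exonic, not splice
    expect_false(classifySpliceRegion(201, ex, 0))   # zero window
    expect_warning(res <- classifySpliceRegion(201, IRanges::IRanges(), 2),
                   "empty exon")
    expect_false(res)
})

test_that("splice-region agrees with brute force on random exon models", {
    set.seed(42)
    for (rep in 1:200) {
        nEx <- sample(1:4, 1)
        starts <- sort(sample(seq(100, 2000, by = 50), nEx))
        ends <- starts + sample(20:40, nEx, replace = TRUE)
        window <- sample(0:10, 1)
        ex <- IRanges::IRanges(starts, ends)
        positions <- sample(1:2100, 5)
        for (p in positions) {
            expect_identical(
                classifySpliceRegion(p, ex, window),
                bruteForceSplice(p, starts, ends, window),
                info = sprintf("rep %d pos %d window %d", rep, p, window))
        }
    }
})

test_that("maximum population AF handles missing databases", {
    expect_equal(maxPopulationAf(0.005, NA, 0.008), 0.008)
    expect_true(is.na(maxPopulationAf(NA, NA, NA)))
    expect_equal(maxPopulationAf(0.0001, 0.0002, 0.0004), 0.0004)
    # cross-check on enumerated triples against elementwise comparison
    vals <- c(NA, 0, 1e-4, 5e-4, 1e-2, 0.5)
    grid <- expand.grid(a = vals, b = vals, c = vals)
    got <- maxPopulationAf(grid$a, grid$b, grid$c)
    for (i in seq_len(nrow(grid))) {
        trio <- c(grid$a[i], grid$b[i], grid$c[i])
        exp <- if (all(is.na(trio))) NA_real_ else max(trio, na.rm = TRUE)
        expect_equal(got[i], exp)
    }
})

test_that("annotated VCF ingest splits multi-allelics and keeps missingness", {
    f <- withr::local_tempfile(fileext = ".vcf")
    writeTestVcf(f, c(
        "chr1\t100\t.\tC\tA,T\t500\tPASS\tGENE=GENE01;CSQT=missense_variant;AF_EVS=0.005;DP=80",
        "chr1\t300\t.\tG\tC\t900\tPASS\tGENE=GENE02;CSQT=stop_gained;DP=60",
        "chr2\t150\t.\tCTT\tCT\t700\tPASS\tGENE=GENE03;CSQT=frameshift_variant;DP=70"))
    rec <- readAnnotatedVcf(f, sampleId = "S1")
    expect_equal(nrow(rec), 4L)   # multi-allelic split into two records
    first2 <- rec[rec$pos == 100, ]
    expect_equal(first2$alt, c("A", "T"))
    expect_equal(first2$ref, c("C", "C"))
    # record with no AF keys: all three AF fields absent, never zero
    noAf <- rec[rec$gene == "GENE02", ]
    expect_true(is.na(noAf$af_evs) && is.na(noAf$af_1000g) &&
                is.na(noAf$af_exac))
    expect_equal(noAf$consequence, "TRUNCATING")
    # indel canonicalised on ingest
    indel <- rec[rec$gene == "GENE03", ]
    expect_equal(indel$pos, 151L)
    expect_equal(indel$ref, "TT")
    expect_equal(indel$alt, "T")
    # splitting preserves the multiset of sites
    expect_setequal(paste(rec$chrom, rec$pos, rec$ref, rec$alt),
        c("chr1 100 C A", "chr1 100 C T", "chr1 300 G C", "chr2 151 TT T"))

    expect_error(readAnnotatedVcf(tempfile()), "not found")
})

test_that("exon BED reading assigns genes and ranks", {
    f <- withr::local_tempfile(fileext = ".bed")
    writeLines(c("chr1\t100\t250\tGENE01_exon1",
                 "chr1\t500\t650\tGENE01_exon2",
                 "chr2\t100\t200\tGENE02"), f)
    ex <- readExonBed(f)
    expect_equal(length(ex), 3L)
    expect_equal(S4Vectors::mcols(ex)$gene, c("GENE01", "GENE01", "GENE02"))
    expect_equal(S4Vectors::mcols(ex)$exon_rank, c(1L, 2L, 1L))
    # BED is 0-based half-open; GRanges 1-based inclusive
    expect_equal(GenomicRanges::start(ex)[1], 101L)
    expect_equal(GenomicRanges::end(ex)[1], 250L)
})
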