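# Independent oracles and small fixture builders shared across tests.
# Each oracle is a direct, brute-force restatement of the documented rule,
# kept deliberately separate from the package's implementation path.

# brute-force gap scan: for every base, is depth < threshold; then collect
# maximal runs by walking the boolean vector one base at a time
bruteForceGaps <- function(chrom, start0, depths, threshold) {
    below <- depths < threshold
    out <- list()
    i <- 1L
    while (i <= length(below)) {
        if (below[i]) {
            j <- i
            while (j < length(below) && below[j + 1L]) j <- j + 1L
            out[[length(out) + 1L]] <- data.frame(
                chrom = chrom, start = start0 + i - 1L, end = start0 + j,
                length = j - i + 1L,
                min_depth = min(depths[i:j]),
                stringsAsFactors = FALSE)
            i <- j + 1L
        } else i <- i + 1L
    }
    if (!length(out))
        return(data.frame(chrom = character(0), start = integer(0),
                          end = integer(0), length = integer(0),
                          min_depth = integer(0)))
    do.call(rbind, out)
}

# brute-force splice-region decision for a single position: scan the
# documented definition literally (strictly outside every exon, within
# window of some boundary)
bruteForceSplice <- function(pos, starts, ends, window) {
    if (window == 0) return(FALSE)
    for (k in seq_along(starts))
        if (pos >= starts[k] && pos <= ends[k]) return(FALSE)
    for (k in seq_along(starts)) {
        for (w in 1:window) {
            if (pos == starts[k] - w || pos == ends[k] + w) return(TRUE)
        }
    }
    FALSE
}

# printed tier rules restated as a literal decision table over bands
expectedVpiFromBands <- function(class, afBand, condelBand,
                                 rare = 0.01, veryRare = 0.0005) {
    if (class %in% c("FRAMESHIFT", "TRUNCATING", "SPLICE")) return(4L)
    if (!class %in% c("MISSENSE", "INFRAME_INDEL")) return(0L)
    belowVeryRare <- afBand %in% c("absent", "lt_very_rare")
    belowRare <- belowVeryRare || afBand == "mid"
    if (belowVeryRare && condelBand == "above") return(3L)
    if (belowVeryRare) return(2L)
    if (belowRare) return(1L)
    0L
}

# representative numeric value for each band
afBandValue <- function(band) switch(band,
    absent = NA_real_, lt_very_rare = 0.0001, mid = 0.004, common = 0.05)
condelBandValue <- function(band) switch(band,
    absent = NA_real_, below = 0.05, above = 0.9)

# write a minimal annotated VCF for ingest tests
writeTestVcf <- function(path, lines,
                         contigs = c("chr1", "chr2")) {
    header <- c("##fileformat=VCFv4.2",
        sprintf("##contig=<ID=%s>", contigs),
        "##INFO=<ID=GENE,Number=1,Type=String,Description=\"g\">",
        "##INFO=<ID=CSQT,Number=1,Type=String,Description=\"c\">",
        "##INFO=<ID=AF_EVS,Number=1,Type=Float,Description=\"f\">",
        "##INFO=<ID=AF_1000G,Number=1,Type=Float,Description=\"f\">",
        "##INFO=<ID=AF_EXAC,Number=1,Type=Float,Description=\"f\">",
        "##INFO=<ID=CONDEL,Number=1,Type=Float,Description=\"f\">",
        "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
        "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
    writeLines(c(header, lines), path)
    path
}

# variant record rows for filter tests, with sane defaults
recordRows <- function(n = 1, ...) {
    base <- data.frame(
        sample_id = "S1", chrom = "chr1", pos = seq_len(n) * 100L,
        ref = "A", alt = "G", gene = "GENE01",
        consequence = "MISSENSE", af_evs = NA_real_,
        af_1000g = NA_real_, af_exac = NA_real_, condel = NA_real_,
        depth = 100L, qual = 900, symbolic = FALSE,
        vpi = 2L, gpi = 1L, stringsAsFactors = FALSE)
    base <- base[rep(1L, n), , drop = FALSE]
    base$pos <- seq_len(n) * 100L
    over <- list(...)
    for (nm in names(over)) base[[nm]] <- over[[nm]]
    rownames(base) <- NULL
    base
}

testProfile <- function(...) {
    args <- utils::modifyList(list(name = "TEST",
        targetGenes = sprintf("GENE%02d", 1:10),
        knownCausalGenes = c("GENE02", "GENE03"),
        insilicoGenes = c("GENE03", "GENE04"),
        clinicianGenes = "GENE05",
        excludedGenes = "GENE10"), list(...))
    do.call(analysisProfile, args)
}
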