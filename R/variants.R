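## Variant ingest: annotated VCF -> normalised per-alternate variant
## records with harmonised consequence classes and population frequencies.

.CONSEQUENCE_CLASSES <- c("TRUNCATING", "FRAMESHIFT", "SPLICE", "MISSENSE",
    "INFRAME_INDEL", "SYNONYMOUS", "OTHER")

## severity: index 1 most severe; used to pick one class per record when a
## transcript annotation carries several terms.
.SEVERITY_ORDER <- .CONSEQUENCE_CLASSES

.consequenceMapEnv <- new.env(parent = emptyenv())

.consequenceMap <- function(path = NULL) {
    if (is.null(path)) {
        if (is.null(.consequenceMapEnv$map)) {
            f <- system.file("extdata", "consequence_map.tsv",
                             package = "panelTriage", mustWork = TRUE)
            tbl <- utils::read.delim(f, stringsAsFactors = FALSE)
            .consequenceMapEnv$map <- stats::setNames(tbl$class, tbl$term)
        }
        .consequenceMapEnv$map
    } else {
        tbl <- utils::read.delim(path, stringsAsFactors = FALSE)
        stats::setNames(tbl$class, tbl$term)
    }
}

#' Normalise a raw consequence annotation to a consequence class
#'
#' Maps annotation-tool vocabulary (both classic annotator terms such as
#' `"stopgain"`/`"nonsynonymous SNV"` and Sequence Ontology terms such as
#' `"stop_gained"`/`"missense_variant"`) onto the seven classes used by the
#' prioritisation rules: `TRUNCATING`, `FRAMESHIFT`, `SPLICE`, `MISSENSE`,
#' `INFRAME_INDEL`, `SYNONYMOUS`, `OTHER`. The mapping is total — any term
#' not in the table maps to `OTHER` and no input raises an error. When a
#' record carries several terms (separated by `&`, `,` or `;`) the most
#' severe class is kept, in the order
#' TRUNCATING > FRAMESHIFT > SPLICE > MISSENSE > INFRAME_INDEL >
#' SYNONYMOUS > OTHER.
#'
#' The vocabulary ships as an editable two-column table
#' (`extdata/consequence_map.tsv`); pass `mapFile` to use a site-local one.
#'
#' @param raw character vector of raw annotation strings.
#' @param mapFile optional path to an alternative term-to-class table.
#' @return character vector of consequence classes, same length as `raw`.
#' @examples
#' normalizeConsequence(c("stopgain", "synonymous_variant", "weird_term"))
#' @export
normalizeConsequence <- function(raw, mapFile = NULL) {
    map <- .consequenceMap(mapFile)
    vapply(as.character(raw), function(s) {
        if (is.na(s) || !nzchar(trimws(s))) return("OTHER")
        terms <- tolower(trimws(strsplit(s, "[&,;]")[[1]]))
        classes <- ifelse(terms %in% names(map), map[terms], "OTHER")
        classes <- factor(classes, levels = .SEVERITY_ORDER)
        as.character(sort(classes)[1])
    }, character(1), USE.NAMES = FALSE)
}

#' Canonicalise variant alleles by trimming shared context
#'
#' Reduces each (pos, ref, alt) to a canonical minimal representation:
#' shared leading context is trimmed first (advancing the position), then
#' shared trailing context, always leaving at least one base in each
#' allele. Alleles are upper-cased. Two padded representations of the same
#' allele therefore yield identical canonical forms, which is what the
#' observation-store key relies on. Symbolic alleles (`<DEL>`, breakends,
#' `*`) are passed through untouched.
#'
#' @param pos integer vector of 1-based positions.
#' @param ref,alt character vectors of alleles.
#' @return data.frame with columns `pos`, `ref`, `alt`.
#' @examples
#' normalizeAlleles(100, "CTT", "CT")   # -> pos 101, TT > T
#' @export
normalizeAlleles <- function(pos, ref, alt) {
    ref <- toupper(as.character(ref))
    alt <- toupper(as.character(alt))
    pos <- as.integer(pos)
    symbolic <- grepl("[<>\\[\\]*]", ref) | grepl("[<>\\[\\]*]", alt) |
        is.na(ref) | is.na(alt)
    for (i in which(!symbolic)) {
        r <- strsplit(ref[i], "")[[1]]
        a <- strsplit(alt[i], "")[[1]]
        p <- pos[i]
        while (length(r) > 1L && length(a) > 1L && r[1] == a[1]) {
            r <- r[-1]; a <- a[-1]; p <- p + 1L
        }
        while (length(r) > 1L && length(a) > 1L &&
               r[length(r)] == a[length(a)]) {
            r <- r[-length(r)]; a <- a[-length(a)]
        }
        pos[i] <- p
        ref[i] <- paste(r, collapse = "")
        alt[i] <- paste(a, collapse = "")
    }
    data.frame(pos = pos, ref = ref, alt = alt, stringsAsFactors = FALSE)
}

#' Read an annotated VCF into normalised variant records
#'
#' Reads a VCF 4.x file (plain or bgzip) whose INFO fields carry the
#' annotations produced upstream (population allele frequencies, Condel
#' score, gene symbol, transcript consequence) and returns one row per
#' alternate allele. Multi-allelic sites are split; alleles are
#' canonicalised with [normalizeAlleles()]; missing annotations stay `NA`
#' and are never zero-filled (an absent frequency means "not observed in
#' that database", i.e. potentially novel — not frequency 0 evidence).
#' Records with symbolic alternate alleles (structural events) are kept
#' with consequence `OTHER` and flagged in the `symbolic` column.
#'
#' @param path path to the VCF file.
#' @param schema named list mapping logical fields to INFO keys; recognised
#'   names: `af_evs`, `af_1000g`, `af_exac`, `condel`, `gene`,
#'   `consequence`, `depth`. Defaults cover a conventional annotation
#'   layout (`AF_EVS`, `AF_1000G`, `AF_EXAC`, `CONDEL`, `GENE`, `CSQT`,
#'   `DP`).
#' @param sampleId sample identifier attached to every record; defaults to
#'   the first sample named in the VCF header, else the file base name.
#' @param mapFile optional consequence vocabulary table, see
#'   [normalizeConsequence()].
#' @return data.frame with columns `sample_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `gene`, `consequence`, `af_evs`, `af_1000g`, `af_exac`,
#'   `condel`, `depth`, `qual`, `symbolic` (one row per alternate allele),
#'   plus empty `vpi`/`gpi` columns filled later by the prioritisation
#'   step.
#' @export
readAnnotatedVcf <- function(path, schema = list(), sampleId = NULL,
                             mapFile = NULL) {
    if (!file.exists(path))
        stop("VCF file not found: ", path, call. = FALSE)
    defaults <- list(af_evs = "AF_EVS", af_1000g = "AF_1000G",
                     af_exac = "AF_EXAC", condel = "CONDEL", gene = "GENE",
                     consequence = "CSQT", depth = "DP")
    schema <- utils::modifyList(defaults, schema)

    vcf <- VariantAnnotation::readVcf(path)
    vcf <- VariantAnnotation::expand(vcf)   # one row per alternate allele
    n <- length(vcf)
    rr <- SummarizedExperiment::rowRanges(vcf)
    info <- VariantAnnotation::info(vcf)

    getInfo <- function(key, as = "numeric") {
        if (is.null(key) || !key %in% colnames(info))
            return(rep(if (as == "numeric") NA_real_ else NA_character_, n))
        v <- info[[key]]
        if (is(v, "List")) {
            v <- vapply(v, function(x)
                if (length(x)) as.character(x[1]) else NA_character_,
                character(1))
        }
        if (as == "numeric") suppressWarnings(as.numeric(v))
        else as.character(v)
    }

    if (is.null(sampleId)) {
        hdrSamples <- VariantAnnotation::samples(VariantAnnotation::header(vcf))
        sampleId <- if (length(hdrSamples)) hdrSamples[1]
                    else sub("\\.vcf(\\.gz|\\.bgz)?$", "", basename(path))
    }

    ref <- as.character(rr$REF)
    alt <- as.character(rr$ALT)
    norm <- normalizeAlleles(GenomicRanges::start(rr), ref, alt)
    symbolic <- grepl("[<>\\[\\]*]", ref) | grepl("[<>\\[\\]*]", alt)

    consequenceRaw <- getInfo(schema$consequence, "character")
    consequence <- normalizeConsequence(consequenceRaw, mapFile)
    consequence[symbolic] <- "OTHER"

    rec <- data.frame(
        sample_id = rep(sampleId, n),
        chrom = as.character(GenomicRanges::seqnames(rr)),
        pos = norm$pos,
        ref = norm$ref,
        alt = norm$alt,
        gene = toupper(getInfo(schema$gene, "character")),
        consequence = consequence,
        af_evs = getInfo(schema$af_evs),
        af_1000g = getInfo(schema$af_1000g),
        af_exac = getInfo(schema$af_exac),
        condel = getInfo(schema$condel),
        depth = suppressWarnings(as.integer(getInfo(schema$depth))),
        qual = as.numeric(rr$QUAL),
        symbolic = symbolic,
        vpi = NA_integer_,
        gpi = NA_integer_,
        stringsAsFactors = FALSE
    )
    rownames(rec) <- NULL
    rec
}

#' Is a variant in the splice window of an exon?
#'
#' A position is classified as a potential splice-site variant when it lies
#' strictly outside every exon of the gene but within `windowBp` bases of
#' some exon boundary. With `windowBp = 0` nothing is classified as splice.
#'
#' @param pos integer vector of 1-based variant positions.
#' @param exons exon intervals for the relevant gene as a [IRanges::IRanges]
#'   or [GenomicRanges::GRanges] (1-based, inclusive; BED input is converted
#'   on read by [readExonBed()]). An empty set returns `FALSE` with a
#'   warning.
#' @param windowBp splice window width in bases, >= 0.
#' @return logical vector, same length as `pos`.
#' @examples
#' library(IRanges)
#' classifySpliceRegion(c(201, 150, 99), IRanges(101, 200), windowBp = 2)
#' @export
classifySpliceRegion <- function(pos, exons, windowBp) {
    stopifnot(windowBp >= 0)
    if (is(exons, "GRanges")) exons <- IRanges::ranges(exons)
    if (length(exons) == 0L) {
        warning("empty exon set: no positions classified as splice region",
                call. = FALSE)
        return(rep(FALSE, length(pos)))
    }
    if (windowBp == 0) return(rep(FALSE, length(pos)))
    starts <- IRanges::start(exons)
    ends <- IRanges::end(exons)
    vapply(as.integer(pos), function(p) {
        if (any(p >= starts & p <= ends)) return(FALSE)
        dist <- min(ifelse(p < starts, starts - p, p - ends))
        dist <= windowBp
    }, logical(1))
}

#' Maximum population allele frequency over the annotated databases
#'
#' The rarity tiers require the frequency condition to hold in all
#' population databases (EVS, 1000 Genomes, ExAC), so the comparison uses
#' the maximum over the frequencies that are present. When all three are
#' absent the variant is "novel" and the result is `NA`, which downstream
#' counts as below every threshold.
#'
#' @param afEvs,af1000g,afExac numeric vectors (may contain `NA`), or
#'   `afEvs` may be a variant record data.frame with columns `af_evs`,
#'   `af_1000g`, `af_exac`.
#' @return numeric vector of maxima, `NA` where all inputs are absent.
#' @export
maxPopulationAf <- function(afEvs, af1000g = NULL, afExac = NULL) {
    if (is.data.frame(afEvs)) {
        df <- afEvs
        afEvs <- df$af_evs; af1000g <- df$af_1000g; afExac <- df$af_exac
    }
    m <- cbind(afEvs, af1000g, afExac)
    res <- apply(m, 1L, function(r)
        if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE))
    as.numeric(res)
}

#' Read an exon BED file
#'
#' Reads a BED file of exon intervals (0-based half-open) with the gene
#' symbol carried in the name column, either bare (`SCN1A`) or with an
#' explicit exon rank (`SCN1A_exon3`). Returns 1-based inclusive
#' `GRanges` with metadata columns `gene` and `exon_rank`; when ranks are
#' not given they are assigned per gene in positional order along the
#' chromosome.
#'
#' @param path path to the BED file (3+ columns, tab-separated).
#' @return a `GRanges` with `gene` and `exon_rank` metadata columns.
#' @export
readExonBed <- function(path) {
    if (!file.exists(path))
        stop("BED file not found: ", path, call. = FALSE)
    bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                             col.names = c("chrom", "start", "end", "name",
                                           "score", "strand")[1:min(6,
                                 max(utils::count.fields(path, sep = "\t")))],
                             fill = TRUE)
    if (is.null(bed$name)) bed$name <- ""
    name <- as.character(bed$name)
    hasRank <- grepl("_exon[0-9]+$", name)
    gene <- toupper(ifelse(hasRank, sub("_exon[0-9]+$", "", name), name))
    rank <- rep(NA_integer_, length(name))
    rank[hasRank] <- as.integer(sub("^.*_exon([0-9]+)$", "\\1",
                                    name[hasRank]))
    gr <- GenomicRanges::GRanges(bed$chrom,
        IRanges::IRanges(start = bed$start + 1L, end = bed$end))
    mcols(gr)$gene <- gene
    mcols(gr)$exon_rank <- as.integer(rank)
    gr <- gr[order(.chromRank(as.character(GenomicRanges::seqnames(gr))),
                   GenomicRanges::start(gr))]
    ## positional rank per gene where the BED gave none
    for (g in unique(mcols(gr)$gene)) {
        sel <- which(mcols(gr)$gene == g)
        if (all(is.na(mcols(gr)$exon_rank[sel])))
            mcols(gr)$exon_rank[sel] <- seq_along(sel)
    }
    gr
}

## karyotype order: 1..22, X, Y, MT/M, then others lexicographically
.chromRank <- function(chrom) {
    base <- sub("^chr", "", chrom, ignore.case = TRUE)
    known <- c(as.character(1:22), "X", "Y", "MT", "M")
    r <- match(toupper(base), known)
    r[toupper(base) == "M"] <- 25L
    unknown <- is.na(r)
    if (any(unknown)) {
        extra <- sort(unique(base[unknown]))
        r[unknown] <- 100L + match(base[unknown], extra)
    }
    r
}
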