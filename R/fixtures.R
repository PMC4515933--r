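## Seeded synthetic-data generator: complete analysis batches (annotated
## VCF, per-base coverage, exon BEDs, metrics, metadata, profile) with a
## machine-readable truth manifest, so every module and the end-to-end
## pipeline can be exercised without external data. Variants are written
## directly as annotated VCF (annotations synthesised); read-level
## simulation is deliberately out of scope.

#' SimulationSpec: parameters of a synthetic batch
#'
#' Describes one synthetic diagnostic batch. The defaults produced by
#' [simulationSpec()] emulate a small production batch: 12 samples from
#' four disease cohorts, a 10-gene panel of 8 exons x 150 bp each, about
#' 2,000 common background variants per sample, a set of planted variants
#' covering every priority tier and filter reason, planted coverage
#' dropouts, and one declared-sex mismatch.
#'
#' @slot seed integer RNG seed; the same seed and spec give byte-identical
#'   outputs.
#' @slot nSamples number of samples.
#' @slot cohorts cohort labels, assigned round-robin.
#' @slot genes data.frame with columns `gene`, `chrom`, `n_exons`,
#'   `exon_length`.
#' @slot knownCausalGenes,insilicoGenes,clinicianGenes,excludedGenes
#'   profile gene lists (subsets of `genes$gene`).
#' @slot plantedVariants data.frame of planted variants, see
#'   [plantedVariantDefaults()].
#' @slot backgroundVariantRate expected number of common background
#'   variants per sample.
#' @slot coverageMean baseline per-base depth.
#' @slot coverageNoise uniform integer noise amplitude on the baseline
#'   (never crosses the QC threshold: a guard clamp keeps non-dropout
#'   bases at or above it).
#' @slot coverageDropouts data.frame of planted low-coverage regions:
#'   `sample`, `gene`, `exon`, `offset`, `length`, `depth` (depth below
#'   the QC threshold; `offset` is 0-based within the exon).
#' @slot sexes true sex per sample (recycled).
#' @slot sexMismatch indices of samples whose declared sex is flipped
#'   relative to the coverage-derived truth.
#' @slot duplicateRate,fragmentSize per-sample metrics (recycled).
#' @export
setClass("SimulationSpec",
    representation(
        seed = "integer", nSamples = "integer", cohorts = "character",
        genes = "data.frame",
        knownCausalGenes = "character", insilicoGenes = "character",
        clinicianGenes = "character", excludedGenes = "character",
        plantedVariants = "data.frame",
        backgroundVariantRate = "numeric",
        coverageMean = "integer", coverageNoise = "integer",
        coverageDropouts = "data.frame",
        sexes = "character", sexMismatch = "integer",
        duplicateRate = "numeric", fragmentSize = "numeric"
    )
)

setValidity("SimulationSpec", function(object) {
    msg <- character()
    if (object@nSamples < 1L) msg <- c(msg, "nSamples must be >= 1")
    if (!all(c("gene", "chrom", "n_exons", "exon_length") %in%
             colnames(object@genes)))
        msg <- c(msg, "genes needs columns gene, chrom, n_exons, exon_length")
    if (length(msg)) msg else TRUE
})

#' Default planted-variant table
#'
#' One row per planted variant: `sample` (index), `gene`, `class`
#' (consequence class to realise), `af_evs`/`af_1000g`/`af_exac` (`NA` =
#' absent from that database), `condel` (`NA` = unscored), `splice_site`
#' (`TRUE` plants an intronic variant one base past an exon boundary).
#' The default set covers all four priority tiers, the splice window, an
#' excluded gene, an off-target gene and a hidden common variant.
#'
#' @return data.frame of planted variants.
#' @export
plantedVariantDefaults <- function() {
    data.frame(
        sample = c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L, 9L, 10L),
        gene = c("GENE05", "GENE02", "GENE01", "GENE01", "GENE03",
                 "GENE04", "GENE10", "GENE01", "GENEX", "GENE06"),
        class = c("FRAMESHIFT", "MISSENSE", "MISSENSE", "MISSENSE",
                  "TRUNCATING", "SPLICE_WINDOW", "MISSENSE", "SYNONYMOUS",
                  "MISSENSE", "INFRAME_INDEL"),
        af_evs = c(NA, NA, 1e-4, 5e-3, NA, NA, NA, 0.30, NA, NA),
        af_1000g = c(NA, NA, 2e-4, 4e-3, NA, NA, NA, 0.28, NA, NA),
        af_exac = c(NA, NA, 4e-4, 8e-3, NA, NA, NA, 0.31, NA, NA),
        condel = c(NA, 0.9, 0.05, 0.9, NA, NA, 0.9, NA, 0.9, NA),
        splice_site = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE,
                        FALSE, FALSE, FALSE),
        stringsAsFactors = FALSE)
}

#' Construct a simulation spec
#'
#' All arguments default to the standard synthetic batch conditions; see
#' [SimulationSpec-class].
#'
#' @param seed RNG seed.
#' @param nSamples number of samples (default 12).
#' @param cohorts cohort labels.
#' @param genes panel definition data.frame.
#' @param knownCausalGenes,insilicoGenes,clinicianGenes,excludedGenes
#'   profile gene lists.
#' @param plantedVariants planted variant table.
#' @param backgroundVariantRate background variants per sample.
#' @param coverageMean,coverageNoise coverage model.
#' @param coverageDropouts planted low-coverage regions.
#' @param sexes,sexMismatch,duplicateRate,fragmentSize sample metrics.
#' @return a [SimulationSpec-class].
#' @export
simulationSpec <- function(seed = 1L, nSamples = 12L,
        cohorts = c("CARDIO", "EPIL", "RENAL", "NEURO"),
        genes = data.frame(
            gene = sprintf("GENE%02d", 1:10),
            chrom = rep(c("chr1", "chr2", "chr3"), length.out = 10),
            n_exons = 8L, exon_length = 150L, stringsAsFactors = FALSE),
        knownCausalGenes = c("GENE02", "GENE03"),
        insilicoGenes = c("GENE03", "GENE04"),
        clinicianGenes = "GENE05",
        excludedGenes = "GENE10",
        plantedVariants = plantedVariantDefaults(),
        backgroundVariantRate = 2000,
        coverageMean = 60L, coverageNoise = 5L,
        coverageDropouts = data.frame(
            sample = c(1L, 1L, 2L),
            gene = c("GENE01", "GENE02", "GENE07"),
            exon = c(2L, 4L, 1L),
            offset = c(50L, 0L, 100L),
            length = c(40L, 150L, 25L),
            depth = c(3L, 0L, 10L), stringsAsFactors = FALSE),
        sexes = c("MALE", "FEMALE"),
        sexMismatch = 12L,
        duplicateRate = 0.08, fragmentSize = 330) {
    new("SimulationSpec", seed = as.integer(seed),
        nSamples = as.integer(nSamples), cohorts = cohorts, genes = genes,
        knownCausalGenes = knownCausalGenes, insilicoGenes = insilicoGenes,
        clinicianGenes = clinicianGenes, excludedGenes = excludedGenes,
        plantedVariants = plantedVariants,
        backgroundVariantRate = backgroundVariantRate,
        coverageMean = as.integer(coverageMean),
        coverageNoise = as.integer(coverageNoise),
        coverageDropouts = coverageDropouts,
        sexes = sexes, sexMismatch = as.integer(sexMismatch),
        duplicateRate = duplicateRate, fragmentSize = fragmentSize)
}

## deterministic reference base at a position (same in every sample, so
## the same site yields the same variant key across samples)
.baseAt <- function(pos) c("A", "C", "G", "T")[(pos %% 4L) + 1L]
.altOf <- function(ref1) c(A = "G", C = "T", G = "A", T = "C")[ref1]

## exon model for a spec: gene i occupies a 10 kb block on its chromosome,
## exons spaced 1 kb apart. Returns 1-based inclusive coordinates.
.specExons <- function(spec) {
    g <- spec@genes
    rows <- list()
    for (i in seq_len(nrow(g))) {
        block <- 100000L + (i - 1L) * 20000L
        for (e in seq_len(g$n_exons[i])) {
            s <- block + (e - 1L) * 1000L + 1L
            rows[[length(rows) + 1L]] <- data.frame(
                gene = g$gene[i], chrom = g$chrom[i], exon = e,
                start1 = s, end1 = s + g$exon_length[i] - 1L,
                stringsAsFactors = FALSE)
        }
    }
    do.call(rbind, rows)
}

## expected VPI under the default thresholds; written independently of
## assignVpi so the truth manifest does not merely restate the code path.
.expectedVpi <- function(class, afs, condel, spliceSite) {
    if (spliceSite || class %in% c("FRAMESHIFT", "TRUNCATING", "SPLICE"))
        return(4L)
    if (!class %in% c("MISSENSE", "INFRAME_INDEL")) return(0L)
    maxAf <- if (all(is.na(afs))) NA_real_ else max(afs, na.rm = TRUE)
    if (is.na(maxAf) || maxAf < 0.0005) {
        if (!is.na(condel) && condel > 0.07) 3L else 2L
    } else if (maxAf < 0.01) 1L else 0L
}

.expectedGpi <- function(gene, spec) {
    inTarget <- gene %in% spec@genes$gene
    if (!inTarget || gene %in% spec@excludedGenes) return(0L)
    if (gene %in% spec@clinicianGenes) return(4L)
    if (gene %in% spec@insilicoGenes) return(3L)
    if (gene %in% spec@knownCausalGenes) return(2L)
    1L
}

.vcfConsequenceTerm <- function(class) {
    switch(class,
        FRAMESHIFT = "frameshift_variant",
        TRUNCATING = "stop_gained",
        SPLICE = "splice_donor_variant",
        MISSENSE = "missense_variant",
        INFRAME_INDEL = "inframe_deletion",
        SYNONYMOUS = "synonymous_variant",
        SPLICE_WINDOW = "intron_variant",
        "intergenic_variant")
}

## realise one planted variant as VCF fields at a reproducible position
.plantVariant <- function(row, idx, exons, spec) {
    if (row$gene %in% exons$gene) {
        ex <- exons[exons$gene == row$gene, , drop = FALSE]
        e <- ex[(idx %% nrow(ex)) + 1L, ]
        pos <- if (isTRUE(row$splice_site)) e$end1 + 1L
               else e$start1 + 20L + idx
        chrom <- e$chrom
    } else {
        chrom <- "chr9"       # off-target gene lives outside the panel
        pos <- 500000L + idx * 100L
    }
    refBase <- .baseAt(pos)
    cls <- row$class
    if (cls == "FRAMESHIFT") {
        ref <- paste0(refBase, .baseAt(pos + 1L)); alt <- refBase
    } else if (cls == "INFRAME_INDEL") {
        ref <- paste0(refBase, .baseAt(pos + 1L), .baseAt(pos + 2L),
                      .baseAt(pos + 3L))
        alt <- refBase
    } else {
        ref <- refBase; alt <- unname(.altOf(refBase))
    }
    list(chrom = chrom, pos = pos, ref = ref, alt = alt,
         term = .vcfConsequenceTerm(cls))
}

.vcfHeader <- function(contigs) {
    c("##fileformat=VCFv4.2",
      sprintf("##contig=<ID=%s>", contigs),
      "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
      "##INFO=<ID=CSQT,Number=1,Type=String,Description=\"Transcript consequence\">",
      "##INFO=<ID=AF_EVS,Number=1,Type=Float,Description=\"EVS allele frequency\">",
      "##INFO=<ID=AF_1000G,Number=1,Type=Float,Description=\"1000 Genomes allele frequency\">",
      "##INFO=<ID=AF_EXAC,Number=1,Type=Float,Description=\"ExAC allele frequency\">",
      "##INFO=<ID=CONDEL,Number=1,Type=Float,Description=\"Condel consensus deleteriousness score\">",
      "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
      "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
}

.vcfLine <- function(chrom, pos, ref, alt, qual, info) {
    paste(chrom, pos, ".", ref, alt, sprintf("%.1f", qual), "PASS", info,
          sep = "\t")
}

.infoString <- function(gene, term, afEvs, af1000g, afExac, condel, dp) {
    parts <- c(sprintf("GENE=%s", gene), sprintf("CSQT=%s", term))
    if (!is.na(afEvs)) parts <- c(parts, sprintf("AF_EVS=%.6f", afEvs))
    if (!is.na(af1000g)) parts <- c(parts, sprintf("AF_1000G=%.6f", af1000g))
    if (!is.na(afExac)) parts <- c(parts, sprintf("AF_EXAC=%.6f", afExac))
    if (!is.na(condel)) parts <- c(parts, sprintf("CONDEL=%.3f", condel))
    c(paste(c(parts, sprintf("DP=%d", dp)), collapse = ";"))
}

#' Generate a complete synthetic analysis batch
#'
#' Writes, under `outDir` (which must be empty or absent — the generator
#' never clobbers): the batch `data/` directory with one annotated VCF and
#' one per-base coverage TSV per sample, the exon and target BED files,
#' `samples.tsv` metadata and `metrics.tsv` QC metrics, an analysis
#' profile `profile.txt`, and `truth.json` recording every planted
#' variant with its expected VPI/GPI/retention and reasons, every planted
#' coverage gap with exact coordinates, and the planted sex mismatches.
#' Identical spec + seed give a byte-identical directory tree.
#'
#' Background variants are all common (population AF at or above the rare
#' threshold) and non-truncating, so none of them should survive
#' filtering — any background variant in a report is a defect.
#'
#' @param spec a [SimulationSpec-class].
#' @param outDir output directory.
#' @return path to `truth.json`, invisibly; the truth list itself as the
#'   attribute `"truth"`.
#' @export
generateBatch <- function(spec, outDir) {
    if (dir.exists(outDir) && length(list.files(outDir, all.files = TRUE,
                                                no.. = TRUE)))
        stop("output directory is not empty: ", outDir, call. = FALSE)
    dataDir <- file.path(outDir, "data")
    dir.create(dataDir, recursive = TRUE, showWarnings = FALSE)
    set.seed(spec@seed)

    exons <- .specExons(spec)
    sampleIds <- sprintf("S%03d", seq_len(spec@nSamples))
    cohorts <- rep_len(spec@cohorts, spec@nSamples)
    trueSex <- rep_len(spec@sexes, spec@nSamples)
    declaredSex <- trueSex
    mism <- spec@sexMismatch[spec@sexMismatch <= spec@nSamples]
    declaredSex[mism] <- ifelse(trueSex[mism] == "MALE", "FEMALE", "MALE")

    ## exon BED (0-based half-open) and target BED
    bed <- data.frame(chrom = exons$chrom, start = exons$start1 - 1L,
                      end = exons$end1,
                      name = sprintf("%s_exon%d", exons$gene, exons$exon))
    utils::write.table(bed, file.path(dataDir, "exons.bed"), sep = "\t",
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
    targetBed <- data.frame(chrom = exons$chrom[!duplicated(exons$gene)],
        start = tapply(exons$start1 - 1L, exons$gene, min)[
            unique(exons$gene)],
        end = tapply(exons$end1, exons$gene, max)[unique(exons$gene)],
        name = unique(exons$gene))
    utils::write.table(targetBed, file.path(dataDir, "target.bed"),
                       sep = "\t", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)

    ## profile (inline gene lists)
    profile <- analysisProfile(name = "SYNTH",
        targetGenes = spec@genes$gene,
        knownCausalGenes = spec@knownCausalGenes,
        insilicoGenes = spec@insilicoGenes,
        clinicianGenes = spec@clinicianGenes,
        excludedGenes = spec@excludedGenes,
        minVariantCoverage = 15L, minVariantQual = 50,
        medianCoverageMin = 20, fragmentSizeRange = c(150, 500),
        maxDuplicateRate = 0.25,
        fastqcChecks = c("per_base_quality", "adapter_content"))
    writeProfile(profile, file.path(outDir, "profile.txt"))

    ## planted variants -> truth rows and per-sample VCF lines
    planted <- spec@plantedVariants
    truthVariants <- list()
    vcfLines <- stats::setNames(vector("list", spec@nSamples), sampleIds)
    plantedPos <- character(0)
    for (i in seq_len(nrow(planted))) {
        row <- planted[i, ]
        s <- ((row$sample - 1L) %% spec@nSamples) + 1L
        v <- .plantVariant(row, i, exons, spec)
        afs <- c(row$af_evs, row$af_1000g, row$af_exac)
        cls <- if (row$class == "SPLICE_WINDOW") "OTHER" else row$class
        vpi <- .expectedVpi(row$class,
                            afs, row$condel,
                            isTRUE(row$splice_site))
        gpi <- .expectedGpi(row$gene, spec)
        reasons <- character(0)
        if (vpi == 0L) reasons <- c(reasons, "HIDDEN_BELOW_VPI1")
        if (gpi == 0L)
            reasons <- c(reasons, if (row$gene %in% spec@excludedGenes)
                "GENE_EXCLUDED" else "GENE_OFF_TARGET")
        dp <- 80L + (i * 7L) %% 40L
        qual <- 500 + (i * 97) %% 1000
        vcfLines[[s]] <- c(vcfLines[[s]], .vcfLine(v$chrom, v$pos, v$ref,
            v$alt, qual, .infoString(row$gene, v$term, row$af_evs,
                row$af_1000g, row$af_exac, row$condel, dp)))
        plantedPos <- c(plantedPos, paste(v$chrom, v$pos))
        truthVariants[[i]] <- list(sample = sampleIds[s], gene = row$gene,
            chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
            consequence_class = cls,
            splice_window = isTRUE(row$splice_site),
            expected_vpi = vpi, expected_gpi = gpi,
            expected_retained = (length(reasons) == 0L),
            expected_reasons = as.list(reasons))
    }

    ## background: common, non-truncating, never reportable
    exonPositions <- unlist(lapply(seq_len(nrow(exons)), function(i)
        exons$start1[i]:exons$end1[i]))
    exonChroms <- rep(exons$chrom, exons$end1 - exons$start1 + 1L)
    exonGenes <- rep(exons$gene, exons$end1 - exons$start1 + 1L)
    keyAll <- paste(exonChroms, exonPositions)
    usable <- !keyAll %in% plantedPos
    bgClasses <- c("synonymous_variant", "missense_variant",
                   "upstream_gene_variant", "intron_variant")
    for (s in seq_len(spec@nSamples)) {
        nBg <- min(stats::rpois(1, spec@backgroundVariantRate), sum(usable))
        sel <- sample(which(usable), nBg)
        pos <- exonPositions[sel]
        ref <- .baseAt(pos)
        alt <- unname(.altOf(ref))
        af <- round(stats::runif(nBg, 0.01, 0.5), 6)
        term <- sample(bgClasses, nBg, replace = TRUE)
        dp <- 60L + as.integer(stats::runif(nBg, 0, 80))
        qual <- round(stats::runif(nBg, 200, 1500), 1)
        lines <- vapply(seq_len(nBg), function(j)
            .vcfLine(exonChroms[sel[j]], pos[j], ref[j], alt[j], qual[j],
                .infoString(exonGenes[sel[j]], term[j], af[j], af[j],
                            af[j], NA, dp[j])),
            character(1))
        vcfLines[[s]] <- c(vcfLines[[s]], lines)
    }

    contigs <- unique(c(exons$chrom, "chr9"))
    for (s in seq_len(spec@nSamples)) {
        lines <- vcfLines[[s]]
        if (length(lines)) {
            fields <- strsplit(lines, "\t", fixed = TRUE)
            chrom <- vapply(fields, `[`, character(1), 1L)
            pos <- as.integer(vapply(fields, `[`, character(1), 2L))
            lines <- lines[order(.chromRank(chrom), pos)]
        }
        writeLines(c(.vcfHeader(contigs), lines),
                   file.path(dataDir, paste0(sampleIds[s], ".vcf")))
    }

    ## coverage tracks: per-base depth over each exon, with planted dropouts
    qcThreshold <- profile@coverageQcThreshold
    truthGaps <- list()
    for (s in seq_len(spec@nSamples)) {
        lines <- character(0)
        drops <- spec@coverageDropouts[spec@coverageDropouts$sample == s, ,
                                       drop = FALSE]
        for (i in seq_len(nrow(exons))) {
            len <- exons$end1[i] - exons$start1[i] + 1L
            depth <- spec@coverageMean +
                as.integer(stats::runif(len, -spec@coverageNoise,
                                        spec@coverageNoise))
            ## guard: background bases never dip below the QC threshold,
            ## so planted gap coordinates stay exact
            depth <- pmax(depth, qcThreshold)
            d <- drops[drops$gene == exons$gene[i] &
                       drops$exon == exons$exon[i], , drop = FALSE]
            for (k in seq_len(nrow(d))) {
                from <- d$offset[k] + 1L
                to <- min(len, d$offset[k] + d$length[k])
                depth[from:to] <- d$depth[k]
                truthGaps[[length(truthGaps) + 1L]] <- list(
                    sample = sampleIds[s], chrom = exons$chrom[i],
                    start = exons$start1[i] - 1L + d$offset[k],
                    end = exons$start1[i] - 1L + d$offset[k] + (to - from + 1L),
                    gene = exons$gene[i])
            }
            lines <- c(lines, paste(exons$chrom[i], exons$start1[i] - 1L,
                exons$end1[i],
                sprintf("%s_exon%d", exons$gene[i], exons$exon[i]),
                seq_len(len), depth, sep = "\t"))
        }
        writeLines(lines, file.path(dataDir,
                                    paste0(sampleIds[s], ".cov.tsv")))
    }

    ## sample metadata and QC metrics
    samples <- data.frame(sample_id = sampleIds, sex = declaredSex,
                          cohort = cohorts, profile = "SYNTH",
                          stringsAsFactors = FALSE)
    utils::write.table(samples, file.path(dataDir, "samples.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    auto <- spec@coverageMean
    metrics <- data.frame(
        sample_id = sampleIds,
        median_coverage = auto,
        median_fragment_size = rep_len(spec@fragmentSize, spec@nSamples),
        duplicate_rate = rep_len(spec@duplicateRate, spec@nSamples),
        mean_depth_x = ifelse(trueSex == "MALE", round(0.50 * auto, 1),
                              round(0.98 * auto, 1)),
        mean_depth_y = ifelse(trueSex == "MALE", round(0.45 * auto, 1),
                              round(0.005 * auto, 2)),
        mean_depth_autosome = auto,
        declared_sex = declaredSex,
        fastqc_flags = "per_base_quality:PASS;adapter_content:PASS",
        stringsAsFactors = FALSE)
    utils::write.table(metrics, file.path(dataDir, "metrics.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)

    truth <- list(
        seed = spec@seed, n_samples = spec@nSamples, profile = "SYNTH",
        planted_variants = truthVariants,
        planted_gaps = truthGaps,
        sex_checks = lapply(seq_len(spec@nSamples), function(s) list(
            sample = sampleIds[s], declared = declaredSex[s],
            truth = trueSex[s], expect_fail = s %in% mism))
    )
    truthPath <- file.path(outDir, "truth.json")
    jsonlite::write_json(truth, truthPath, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    out <- truthPath
    attr(out, "truth") <- truth
    invisible(out)
}

#' Generate a populated observation store with planted artefacts
#'
#' Builds a store of `nSamples` registered samples spread round-robin over
#' `cohorts`, plants each artefact variant into its first `n_carriers`
#' samples, and gives every sample a handful of private variants. Returns
#' the store plus a truth table of per-artefact carrier and cohort counts
#' computed by direct construction.
#'
#' @param outPath store file path (must not exist).
#' @param nSamples number of registered samples (default 20).
#' @param cohorts cohort labels (default 4 cohorts).
#' @param artefacts data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `n_carriers`; defaults to three recurrent artefacts carried by 5, 8
#'   and 12 of the samples.
#' @param privatePerSample private (singleton) variants per sample.
#' @param seed RNG seed.
#' @return list with `store` ([ObservationStore-class]) and `truth`
#'   (data.frame: artefact key, carriers, carriers per cohort).
#' @export
generatePopulationStore <- function(outPath, nSamples = 20L,
        cohorts = c("CARDIO", "EPIL", "RENAL", "NEURO"),
        artefacts = data.frame(
            chrom = c("chr1", "chr2", "chr3"),
            pos = c(100021L, 140021L, 180021L),
            ref = c("C", "A", "C"), alt = c("T", "G", "T"),
            n_carriers = c(5L, 8L, 12L), stringsAsFactors = FALSE),
        privatePerSample = 5L, seed = 1L) {
    set.seed(seed)
    store <- createObservationStore(outPath)
    sampleIds <- sprintf("P%03d", seq_len(nSamples))
    cohort <- rep_len(cohorts, nSamples)
    for (s in seq_len(nSamples)) {
        own <- artefacts[s <= artefacts$n_carriers, c("chrom", "pos",
                                                      "ref", "alt")]
        pos <- 900000L + s * 1000L + seq_len(privatePerSample) * 4L
        priv <- data.frame(chrom = "chr1", pos = pos,
                           ref = .baseAt(pos),
                           alt = unname(.altOf(.baseAt(pos))),
                           stringsAsFactors = FALSE)
        registerSample(store, sampleIds[s], cohort[s], rbind(own, priv))
    }
    truth <- do.call(rbind, lapply(seq_len(nrow(artefacts)), function(i) {
        carriers <- sampleIds[seq_len(artefacts$n_carriers[i])]
        carrierCohorts <- cohort[seq_len(artefacts$n_carriers[i])]
        counts <- table(factor(carrierCohorts, levels = cohorts))
        cbind(data.frame(chrom = artefacts$chrom[i],
                         pos = artefacts$pos[i], ref = artefacts$ref[i],
                         alt = artefacts$alt[i],
                         carriers = length(carriers),
                         frequency = length(carriers) / nSamples,
                         stringsAsFactors = FALSE),
              as.data.frame.matrix(t(as.matrix(counts))))
    }))
    list(store = store, truth = truth,
         samples = data.frame(sample_id = sampleIds, cohort = cohort,
                              stringsAsFactors = FALSE))
}
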