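## Variant Priority Index / Gene Priority Index assignment, profile and
## internal-database filtering, and report ordering.

.FILTER_REASONS <- c("HIDDEN_BELOW_VPI1", "GENE_EXCLUDED", "GENE_OFF_TARGET",
    "LOW_DEPTH", "LOW_QUAL", "INTERNAL_DB_COMMON")

#' Assign the Variant Priority Index (VPI)
#'
#' Places each variant into one of four priority tiers (0 = below every
#' tier, hidden from the result set):
#'
#' * **VPI 4** — frameshift, truncating or splice-site variants (including
#'   intronic variants falling inside the profile's splice window),
#'   irrespective of population frequency (unless the profile's
#'   `applyAfToVpi4` switch is on, in which case the rare-frequency cut is
#'   applied to tier 4 as well).
#' * **VPI 3** — "very rare or novel" missense/in-frame variants that are
#'   also "highly conserved": maximum population AF `<` the very-rare
#'   threshold (default 0.0005) and Condel `>` the Condel threshold
#'   (default 0.07). An absent Condel score never reaches tier 3.
#' * **VPI 2** — "very rare or novel": maximum population AF `<` the
#'   very-rare threshold.
#' * **VPI 1** — "rare": missense or in-frame indel with maximum population
#'   AF `<` the rare threshold (default 0.01) in every database.
#'
#' Tiers 1-3 are nested subsets. All inequalities are strict. A variant
#' absent from every population database ("novel") counts as below every
#' frequency threshold. Consequence classes other than
#' missense/in-frame/frameshift/truncating/splice give 0.
#'
#' @param consequence character vector of consequence classes
#'   (see [normalizeConsequence()]).
#' @param maxAf numeric vector of maximum population allele frequencies
#'   (`NA` = novel), see [maxPopulationAf()].
#' @param condel numeric vector of Condel scores (`NA` = not scored).
#' @param isSplice logical vector: variant inside the profile's splice
#'   window (see [classifySpliceRegion()]). Default `FALSE`.
#' @param profile an [AnalysisProfile-class] providing the thresholds.
#' @return integer vector of tiers in 0..4.
#' @export
assignVpi <- function(consequence, maxAf, condel, isSplice = FALSE,
                      profile = analysisProfile("default")) {
    n <- length(consequence)
    maxAf <- rep_len(as.numeric(maxAf), n)
    condel <- rep_len(as.numeric(condel), n)
    isSplice <- rep_len(as.logical(isSplice), n)
    rare <- profile@rareAfThreshold
    veryRare <- profile@veryRareAfThreshold
    condelMin <- profile@condelThreshold

    belowRare <- is.na(maxAf) | maxAf < rare
    belowVeryRare <- is.na(maxAf) | maxAf < veryRare
    conserved <- !is.na(condel) & condel > condelMin

    vpi <- integer(n)
    tier4 <- consequence %in% c("FRAMESHIFT", "TRUNCATING", "SPLICE") |
        (isSplice %in% TRUE)
    if (profile@applyAfToVpi4) tier4 <- tier4 & belowRare
    eligible <- consequence %in% c("MISSENSE", "INFRAME_INDEL") & !tier4
    vpi[eligible & belowRare] <- 1L
    vpi[eligible & belowVeryRare] <- 2L
    vpi[eligible & belowVeryRare & conserved] <- 3L
    vpi[tier4] <- 4L
    vpi
}

#' Assign the Gene Priority Index (GPI)
#'
#' The GPI is the a-priori gene category of the variant's gene under the
#' profile, see [geneCategory()]: 1 for any gene in the analysis target
#' region, narrowing to 2 (known causal for the patient group), 3
#' (in-silico prioritised) and 4 (clinician-nominated). Variants with no
#' resolved gene, off-target genes, or excluded genes get 0.
#'
#' @param records variant record data.frame with a `gene` column, or a
#'   character vector of gene symbols.
#' @param profile an [AnalysisProfile-class].
#' @return integer vector of categories in 0..4.
#' @export
assignGpi <- function(records, profile) {
    gene <- if (is.data.frame(records)) records$gene else records
    geneCategory(profile, gene)
}

#' Apply the profile and internal-database filters
#'
#' Partitions prioritised variant records into the retained set (reported
#' for curation) and the removed set, recording for every removed variant
#' the machine-readable reasons: `HIDDEN_BELOW_VPI1` (did not meet at
#' least VPI 1), `GENE_EXCLUDED` / `GENE_OFF_TARGET` (GPI 0, split by
#' cause for auditability), `LOW_DEPTH`, `LOW_QUAL` (profile quality
#' gates), `INTERNAL_DB_COMMON` (excluded by the internal
#' observation-database policy). Every input row appears in exactly one of
#' the two outputs; retained rows gain `obs_count` and `obs_frequency`
#' columns from the store (0 when no store is supplied).
#'
#' A sample's own previous observations never count against it: the store
#' query excludes each record's `sample_id`, so a variant cannot filter
#' itself at re-analysis.
#'
#' @param records data.frame of variant records with `vpi` and `gpi`
#'   assigned (see [assignVpi()], [assignGpi()]).
#' @param profile an [AnalysisProfile-class].
#' @param store optional [ObservationStore-class]; `NULL` disables the
#'   internal-database filter.
#' @return list with elements `retained` (data.frame) and `removed`
#'   (data.frame with a `filter_reasons` column, comma-separated reason
#'   codes).
#' @export
applyFilters <- function(records, profile, store = NULL) {
    n <- nrow(records)
    reasons <- vector("list", n)
    addReason <- function(sel, code) {
        for (i in which(sel)) reasons[[i]] <<- c(reasons[[i]], code)
    }

    addReason(records$vpi == 0L, "HIDDEN_BELOW_VPI1")
    gene <- toupper(as.character(records$gene))
    excluded <- !is.na(gene) & gene %in% profile@excludedGenes
    addReason(records$gpi == 0L & excluded, "GENE_EXCLUDED")
    addReason(records$gpi == 0L & !excluded, "GENE_OFF_TARGET")
    if (!is.null(records$depth))
        addReason(!is.na(records$depth) &
                  records$depth < profile@minVariantCoverage, "LOW_DEPTH")
    if (!is.null(records$qual))
        addReason(!is.na(records$qual) &
                  records$qual < profile@minVariantQual, "LOW_QUAL")

    obsCount <- rep(0L, n)
    obsFreq <- rep(0, n)
    if (!is.null(store) && n > 0L) {
        policy <- internalFilterPolicy(profile)
        obs <- .storeObservations(store)
        nTotal <- totalSamples(store)
        cohorts <- .storeSampleCohorts(store)
        if (nTotal >= 1L && nrow(obs) > 0L) {
            key <- paste(records$chrom, records$pos, records$ref,
                         records$alt, sep = ":")
            obsKey <- paste(obs$chrom, obs$pos, obs$ref, obs$alt, sep = ":")
            qCohort <- cohorts[match(records$sample_id, names(cohorts))]
            for (i in seq_len(n)) {
                hit <- obs[obsKey == key[i] &
                           obs$sample_id != records$sample_id[i], ,
                           drop = FALSE]
                stats <- .observationStatsFrom(hit, cohorts, nTotal,
                                               qCohort[i])
                obsCount[i] <- stats$count_total
                obsFreq[i] <- stats$internal_frequency
                if (internalFilterDecision(stats, policy))
                    reasons[[i]] <- c(reasons[[i]], "INTERNAL_DB_COMMON")
            }
        }
    }

    records$obs_count <- obsCount
    records$obs_frequency <- obsFreq
    removedSel <- lengths(reasons) > 0L
    removed <- records[removedSel, , drop = FALSE]
    removed$filter_reasons <- vapply(reasons[removedSel],
        paste, character(1), collapse = ",")
    retained <- records[!removedSel, , drop = FALSE]
    rownames(retained) <- rownames(removed) <- NULL
    list(retained = retained, removed = removed)
}

#' Order retained variants for the curation report
#'
#' Sorts so that the most promising variants come first: VPI descending,
#' then GPI descending, then chromosome in karyotype order (1-22, X, Y,
#' MT, others last), position ascending, alternate allele lexicographic.
#' The sort is stable and the output is invariant under permutation of the
#' input.
#'
#' @param records data.frame of retained variant records with `vpi`, `gpi`,
#'   `chrom`, `pos`, `alt` columns.
#' @return the reordered data.frame.
#' @export
sortForReport <- function(records) {
    if (nrow(records) == 0L) return(records)
    o <- order(-records$vpi, -records$gpi, .chromRank(records$chrom),
               records$pos, records$alt, records$ref, records$sample_id,
               method = "radix")
    out <- records[o, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Prioritise a set of variant records under a profile
#'
#' Convenience wrapper running the full prioritisation for one sample:
#' splice-window classification against the exon model, VPI and GPI
#' assignment, profile + internal-database filtering, and report ordering.
#'
#' @param records variant records from [readAnnotatedVcf()].
#' @param profile an [AnalysisProfile-class].
#' @param exons exon `GRanges` from [readExonBed()] (used for the splice
#'   window; `NULL` skips splice classification).
#' @param store optional [ObservationStore-class].
#' @return list with `retained` (sorted), `removed` (with reasons).
#' @export
prioritiseVariants <- function(records, profile, exons = NULL, store = NULL) {
    isSplice <- rep(FALSE, nrow(records))
    if (!is.null(exons) && profile@spliceWindowBp > 0L && nrow(records)) {
        for (g in unique(stats::na.omit(records$gene))) {
            sel <- which(records$gene == g)
            ex <- exons[mcols(exons)$gene == g]
            if (length(ex) == 0L) next
            for (i in sel) {
                exChrom <- ex[as.character(GenomicRanges::seqnames(ex)) ==
                              records$chrom[i]]
                if (length(exChrom))
                    isSplice[i] <- classifySpliceRegion(records$pos[i],
                        exChrom, profile@spliceWindowBp)
            }
        }
    }
    records$vpi <- assignVpi(records$consequence,
                             maxPopulationAf(records),
                             records$condel, isSplice, profile)
    records$gpi <- assignGpi(records, profile)
    res <- applyFilters(records, profile, store)
    res$retained <- sortForReport(res$retained)
    res
}
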