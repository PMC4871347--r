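#' Co-segregating candidate SNPs
#'
#' The exact zygosity screen used to find a recessive causal SNP: keep
#' sites called homozygous-alternate in ALL affected samples and not
#' homozygous-alternate in ANY unaffected sample. Missing calls are
#' tolerated in at most `maxMissing` samples per site (default 0); a
#' tolerated missing call never counts for or against. An optional region
#' filter restricts the scan.
#'
#' @param vt a [VariantTable].
#' @param affected,unaffected disjoint non-empty sample name vectors.
#' @param region optional [GenomicRanges::GRanges] restriction.
#' @param maxMissing tolerated missing calls per site (default 0).
#' @return data.frame `chrom`, `pos`, `ref`, `alt`, `pattern` (per-sample
#'   calls `affected|unaffected`, `.` for missing).
#' @export
cosegregatingSnps <- function(vt, affected, unaffected, region = NULL,
                              maxMissing = 0L) {
    if (!length(affected) || !length(unaffected))
        stop("both groups must be non-empty")
    both <- intersect(affected, unaffected)
    if (length(both))
        stop("sample(s) in both groups: ", paste(both, collapse = ", "))
    .assertSample(vt, c(affected, unaffected))
    gt <- assay(vt, "GT")
    ga <- gt[, affected, drop = FALSE]
    gu <- gt[, unaffected, drop = FALSE]
    nMiss <- rowSums(is.na(ga)) + rowSums(is.na(gu))
    keep <- nMiss <= maxMissing &
        rowSums(ga == 2L, na.rm = TRUE) == rowSums(!is.na(ga)) &
        rowSums(gu == 2L, na.rm = TRUE) == 0L &
        rowSums(!is.na(ga)) > 0L
    if (!is.null(region))
        keep <- keep & overlapsAny(rowRanges(vt), region)
    rr <- rowRanges(vt)[keep]
    calls <- cbind(ga, gu)[keep, , drop = FALSE]
    pat <- apply(calls, 1L, function(x) {
        x <- ifelse(is.na(x), ".", x)
        paste0(paste(x[seq_along(affected)], collapse = ""), "|",
               paste(x[-seq_along(affected)], collapse = ""))
    })
    data.frame(chrom = as.character(seqnames(rr)), pos = start(rr),
               ref = mcols(rr)$ref, alt = mcols(rr)$alt,
               pattern = if (length(pat)) pat else character(),
               stringsAsFactors = FALSE)
}

# CDS pieces of a gene model, genomic order
.cdsRanges <- function(model) {
    IRanges::restrict(model@exons, model@cdsStart, model@cdsEnd)
}

# spliced CDS sequence (coding strand) from the chromosome sequence
.cdsSequence <- function(model, chromSeq) {
    cds <- .cdsRanges(model)
    pieces <- lapply(seq_along(cds), function(i)
        Biostrings::subseq(chromSeq, IRanges::start(cds)[i],
                           IRanges::end(cds)[i]))
    s <- do.call(Biostrings::xscat, pieces)
    if (model@strand == "-") s <- Biostrings::reverseComplement(s)
    s
}

# genomic position -> 1-based coordinate within the spliced CDS (coding
# strand), or NA when not coding
.cdsCoord <- function(model, pos) {
    cds <- .cdsRanges(model)
    st <- IRanges::start(cds); en <- IRanges::end(cds)
    hit <- which(pos >= st & pos <= en)
    if (!length(hit)) return(NA_integer_)
    if (model@strand == "+") {
        before <- if (hit > 1L) sum(en[seq_len(hit - 1L)] -
                                        st[seq_len(hit - 1L)] + 1L) else 0L
        before + (pos - st[hit]) + 1L
    } else {
        after <- if (hit < length(cds))
            sum(en[(hit + 1L):length(cds)] - st[(hit + 1L):length(cds)] + 1L)
        else 0L
        after + (en[hit] - pos) + 1L
    }
}

#' Classify the coding effect of a variant
#'
#' Minimal re-implementation of the effect categories reported for the
#' introgressed regions: within the CDS a single-base change is translated
#' strand-aware through the standard genetic code and classified as
#' `synonymous`, `nonsynonymous` or `stop_gained`; a variant within 2 bp of
#' an exon-intron boundary on the intron side (the canonical GT/AG
#' dinucleotides) is a `splice_site`; a length-changing variant inside the
#' CDS whose length difference is not a multiple of 3 is a `frameshift`
#' (in-frame length changes are reported as `nonsynonymous`); everything
#' else, including variants outside any gene model, is `noncoding`.
#'
#' @param chrom,pos,ref,alt the variant (1-based; `ref`/`alt` allele
#'   strings on the plus strand).
#' @param geneModels named list of [GeneModel]s (see [readGeneModels()]).
#' @param refSeqs a [Biostrings::DNAStringSet] of chromosome sequences
#'   named by chromosome; the reference codon context.
#' @return list with `effect` and `geneId` (`NA` when noncoding/intergenic).
#' @export
classifyEffect <- function(chrom, pos, ref, alt, geneModels, refSeqs) {
    if (!chrom %in% names(refSeqs))
        stop("no reference sequence for chromosome ", chrom)
    chromSeq <- refSeqs[[chrom]]
    if (pos < 1L || pos + nchar(ref) - 1L > length(chromSeq))
        stop("position outside chromosome ", chrom)
    seqRef <- as.character(Biostrings::subseq(chromSeq, pos,
                                              pos + nchar(ref) - 1L))
    if (seqRef != ref)
        stop(sprintf("ref mismatch at %s:%d: variant says %s, sequence %s",
                     chrom, pos, ref, seqRef))
    for (gid in names(geneModels)) {
        model <- geneModels[[gid]]
        if (model@chrom != chrom) next
        ex <- model@exons
        span <- range(c(IRanges::start(ex), IRanges::end(ex)))
        if (pos < span[1L] || pos > span[2L]) next
        # splice site: within 2 intronic bp of an exon boundary
        inExon <- any(pos >= IRanges::start(ex) & pos <= IRanges::end(ex))
        if (!inExon) {
            nearDonor <- any((pos - IRanges::end(ex)) %in% 1:2)
            nearAcceptor <- any((IRanges::start(ex) - pos) %in% 1:2)
            if (nearDonor || nearAcceptor)
                return(list(effect = "splice_site", geneId = gid))
            next   # intron interior
        }
        cc <- .cdsCoord(model, pos)
        if (is.na(cc)) next   # UTR exon
        if (nchar(ref) != nchar(alt)) {
            shift <- abs(nchar(alt) - nchar(ref)) %% 3L
            return(list(effect = if (shift != 0L) "frameshift"
                        else "nonsynonymous", geneId = gid))
        }
        cdsSeq <- .cdsSequence(model, chromSeq)
        codonIdx <- (cc - 1L) %/% 3L
        within <- (cc - 1L) %% 3L + 1L
        codon <- as.character(Biostrings::subseq(cdsSeq, codonIdx * 3L + 1L,
                                                 codonIdx * 3L + 3L))
        base <- if (model@strand == "+") alt else
            as.character(Biostrings::reverseComplement(
                Biostrings::DNAString(alt)))
        altCodon <- codon
        substr(altCodon, within, within) <- base
        aaRef <- Biostrings::GENETIC_CODE[[codon]]
        aaAlt <- Biostrings::GENETIC_CODE[[altCodon]]
        eff <- if (aaAlt == aaRef) "synonymous"
               else if (aaAlt == "*") "stop_gained"
               else "nonsynonymous"
        return(list(effect = eff, geneId = gid))
    }
    list(effect = "noncoding", geneId = NA_character_)
}

.effectSeverity <- c(stop_gained = 1, frameshift = 1, splice_site = 2,
                     nonsynonymous = 3, synonymous = 4, noncoding = 4)

#' Ranked candidate report
#'
#' Annotates co-segregating SNPs with their coding effect (when gene models
#' and reference sequence are supplied) and ranks by effect severity
#' (stop-gained / frameshift first, then splice site, then nonsynonymous),
#' breaking ties by position.
#'
#' @param candidates data.frame from [cosegregatingSnps()].
#' @param geneModels optional named list of [GeneModel]s.
#' @param refSeqs optional [Biostrings::DNAStringSet]; required with
#'   `geneModels`.
#' @return the candidates data.frame with `effect`, `geneId` and `rank`
#'   columns, sorted.
#' @export
candidateReport <- function(candidates, geneModels = NULL, refSeqs = NULL) {
    out <- candidates
    if (!nrow(out)) {
        out$effect <- character(); out$geneId <- character()
        out$rank <- integer()
        return(out)
    }
    if (!is.null(geneModels)) {
        eff <- lapply(seq_len(nrow(out)), function(i)
            classifyEffect(out$chrom[i], out$pos[i], out$ref[i],
                           out$alt[i], geneModels, refSeqs))
        out$effect <- vapply(eff, `[[`, "", "effect")
        out$geneId <- vapply(eff, `[[`, "", "geneId")
    } else {
        out$effect <- "noncoding"
        out$geneId <- NA_character_
    }
    o <- order(.effectSeverity[out$effect], out$chrom, out$pos)
    out <- out[o, , drop = FALSE]
    out$rank <- seq_len(nrow(out))
    rownames(out) <- NULL
    out
}
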