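#' Raw SNP index of a DNA pool
#'
#' The per-marker SNP index is the mutant-allele read count divided by the
#' total read count (the pooled alternate-allele frequency of the
#' MutMap/QTL-seq strategy). Markers with fewer than `minDepth` total reads
#' are set undefined (`NA`).
#'
#' @param counts data.frame with columns `chrom`, `pos`, `mut`, `total`
#'   (mutant-allele and total read counts; see [poolCounts()] or
#'   [simulateBsaExperiment()]).
#' @param minDepth minimum total reads for a defined index (default 5).
#' @return data.frame `chrom`, `pos`, `mut`, `total`, `index` sorted by
#'   position within chromosome.
#' @export
snpIndex <- function(counts, minDepth = 5L) {
    need <- c("chrom", "pos", "mut", "total")
    if (!all(need %in% names(counts)))
        stop("counts needs columns ", paste(need, collapse = ", "))
    if (any(counts$mut < 0 | counts$total < 0, na.rm = TRUE))
        stop("counts must be >= 0")
    out <- counts[order(counts$chrom, counts$pos), need, drop = FALSE]
    out$index <- ifelse(!is.na(out$total) & out$total >= minDepth,
                        out$mut / out$total, NA_real_)
    rownames(out) <- NULL
    out
}

#' Smooth a SNP-index track with a moving marker window
#'
#' Averages the raw index over a moving window of `windowSnps` consecutive
#' *defined* markers, shifting by `stepSnps` markers at a time (defaults:
#' 20 consecutive SNPs, step 1). Each window is anchored at the midpoint of
#' its first and last marker positions; chromosomes with fewer than
#' `windowSnps` defined markers yield no smoothed values. (The anchor
#' choice is recorded in the `anchor` attribute: the source figure legends
#' describe a "midpoint between the first and fifth SNP", which cannot be
#' literal for a 20-SNP window; the first-to-last midpoint is used here.)
#'
#' @param raw a [snpIndex()] data.frame.
#' @param windowSnps markers per window (default 20).
#' @param stepSnps markers to shift per step (default 1).
#' @return data.frame `chrom`, `start`, `end` (first/last marker of the
#'   window), `anchor`, `n`, `value`.
#' @export
smoothTrack <- function(raw, windowSnps = 20L, stepSnps = 1L) {
    .assertScalarNum(windowSnps, "windowSnps", 1)
    .assertScalarNum(stepSnps, "stepSnps", 1)
    res <- lapply(split(raw, raw$chrom), function(d) {
        d <- d[!is.na(d$index), , drop = FALSE]
        d <- d[order(d$pos), , drop = FALSE]
        n <- nrow(d)
        if (n < windowSnps) return(NULL)
        starts <- seq.int(1L, n - windowSnps + 1L, by = as.integer(stepSnps))
        cs <- cumsum(c(0, d$index))
        val <- (cs[starts + windowSnps] - cs[starts]) / windowSnps
        firstPos <- d$pos[starts]
        lastPos <- d$pos[starts + windowSnps - 1L]
        data.frame(chrom = d$chrom[1L], start = firstPos, end = lastPos,
                   anchor = (firstPos + lastPos) / 2, n = windowSnps,
                   value = val, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res)
    if (is.null(out))
        out <- data.frame(chrom = character(), start = integer(),
                          end = integer(), anchor = numeric(),
                          n = integer(), value = numeric())
    rownames(out) <- NULL
    attr(out, "anchor") <- "midpoint of first and last window marker"
    attr(out, "windowSnps") <- as.integer(windowSnps)
    out
}

.sameWindows <- function(a, b) {
    identical(paste(a$chrom, a$start, a$end),
              paste(b$chrom, b$start, b$end))
}

#' Call causal peak regions from two smoothed pool tracks
#'
#' A window is peak-like when the mutant pool's smoothed index reaches
#' `high` while the wild-type pool's stays at or below `controlMax`
#' (mirroring the contrast of a mutant pool approaching 1 against a
#' wild-type pool near its Mendelian 1/3). Maximal runs of at least
#' `minWindows` consecutive peak-like windows become regions spanning the
#' first to last window anchor. Both tracks must be smoothed over the same
#' marker windows (align the defined-marker sets first; see [bsaTracks()]).
#'
#' @param mutant,wildtype smoothed tracks from [smoothTrack()].
#' @param high mutant-pool threshold (default 0.9).
#' @param controlMax wild-type-pool ceiling (default 0.7).
#' @param minWindows minimum run length (default 5).
#' @return a [GenomicRanges::GRanges] of peak regions.
#' @export
callPeakRegions <- function(mutant, wildtype, high = 0.9,
                            controlMax = 0.7, minWindows = 5L) {
    if (!.sameWindows(mutant, wildtype))
        stop("mutant and wildtype tracks are not on the same windows")
    hit <- mutant$value >= high & wildtype$value <= controlMax
    out <- GRanges()
    if (!any(hit)) return(out)
    for (chr in unique(mutant$chrom)) {
        sel <- mutant$chrom == chr
        r <- rle(hit[sel])
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        keep <- r$values & r$lengths >= minWindows
        if (!any(keep)) next
        idx <- which(sel)
        gr <- GRanges(chr, IRanges(
            as.integer(round(mutant$anchor[idx[starts[keep]]])),
            as.integer(round(mutant$anchor[idx[ends[keep]]]))))
        out <- c(out, gr)
    }
    sort(out)
}

#' Per-window difference between two smoothed tracks
#'
#' The delta SNP index (mutant minus wild type), the standard companion
#' statistic for visual pool comparison.
#'
#' @param mutant,wildtype smoothed tracks from [smoothTrack()] on the same
#'   windows.
#' @return the `mutant` data.frame with `value` replaced by the
#'   difference.
#' @export
deltaIndex <- function(mutant, wildtype) {
    if (!.sameWindows(mutant, wildtype))
        stop("tracks are not on the same windows")
    out <- mutant
    out$value <- mutant$value - wildtype$value
    out
}

#' Pooled counts of the mutant-parent allele from a VariantTable
#'
#' Builds the `(chrom, pos, mut, total)` count table for a pool sample,
#' restricted to markers informative for the mapping cross: both parents
#' genotyped homozygous and different. The counted ("mutated SNP") allele
#' is the allele carried by the mutant parent, fixed here at table
#' construction.
#'
#' @param vt a [VariantTable] holding the pool and both parents.
#' @param pool pool sample name.
#' @param mutantParent,otherParent parent sample names.
#' @return data.frame `chrom`, `pos`, `mut`, `total`.
#' @export
poolCounts <- function(vt, pool, mutantParent, otherParent) {
    .assertSample(vt, c(pool, mutantParent, otherParent))
    gt <- assay(vt, "GT")
    mp <- gt[, mutantParent]
    op <- gt[, otherParent]
    inf <- !is.na(mp) & !is.na(op) & mp %in% c(0L, 2L) &
        op %in% c(0L, 2L) & mp != op
    rr <- rowRanges(vt)[inf]
    ref <- assay(vt, "refDepth")[inf, pool]
    alt <- assay(vt, "altDepth")[inf, pool]
    mutIsAlt <- mp[inf] == 2L
    data.frame(chrom = as.character(seqnames(rr)), pos = start(rr),
               mut = as.integer(ifelse(mutIsAlt, alt, ref)),
               total = as.integer(ref + alt), stringsAsFactors = FALSE)
}

#' Compute aligned raw and smoothed SNP-index tracks for two pools
#'
#' Convenience orchestration: raw indices per pool, restriction to markers
#' defined in both pools (so the smoothed tracks share windows), smoothing,
#' and the delta track.
#'
#' @param mutCounts,wtCounts count tables (`chrom`, `pos`, `mut`, `total`)
#'   for the mutant and wild-type pools.
#' @param minDepth per-marker depth floor (default 5).
#' @param windowSnps,stepSnps smoothing geometry (defaults 20 / 1).
#' @return list with `rawMut`, `rawWt`, `smoothMut`, `smoothWt`, `delta`.
#' @export
bsaTracks <- function(mutCounts, wtCounts, minDepth = 5L,
                      windowSnps = 20L, stepSnps = 1L) {
    rawM <- snpIndex(mutCounts, minDepth)
    rawW <- snpIndex(wtCounts, minDepth)
    keyM <- .siteKey(rawM$chrom, rawM$pos)
    keyW <- .siteKey(rawW$chrom, rawW$pos)
    if (!identical(keyM, keyW))
        stop("pools were counted at different marker sets")
    both <- !is.na(rawM$index) & !is.na(rawW$index)
    smoothM <- smoothTrack(rawM[both, ], windowSnps, stepSnps)
    smoothW <- smoothTrack(rawW[both, ], windowSnps, stepSnps)
    list(rawMut = rawM, rawWt = rawW, smoothMut = smoothM,
         smoothWt = smoothW, delta = deltaIndex(smoothM, smoothW))
}
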