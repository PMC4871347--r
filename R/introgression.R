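#' SNP density along the genome in overlapping sliding windows
#'
#' Counts a sample's non-reference calls in windows of width `width`
#' anchored every `step` bp (defaults: 2-Mb windows sliding by 5 kb, the
#' plotting scheme used to flag high-SNP regions). A call at position p is
#' counted in every window containing p. Trailing windows are truncated at
#' the chromosome end and their density rescaled to SNPs per 2 Mb.
#'
#' @param vt a [VariantTable].
#' @param sample sample name.
#' @param width window width in bp (default 2e6).
#' @param step window step in bp (default 5e3).
#' @param include `"all"` counts every non-reference call, `"het_only"`
#'   only heterozygous ones.
#' @return a [GenomicRanges::GRanges] of windows with metadata columns
#'   `snpCount` and `density` (SNPs per 2 Mb).
#' @export
snpDensityTrack <- function(vt, sample, width = 2e6, step = 5e3,
                            include = c("all", "het_only")) {
    include <- match.arg(include)
    .assertSample(vt, sample)
    if (width < step) stop("width must be >= step")
    gt <- assay(vt, "GT")[, sample]
    keep <- if (include == "all") !is.na(gt) & gt > 0L else
        !is.na(gt) & gt == 1L
    rr <- rowRanges(vt)
    lens <- .chromLengths(seqinfo(rr))
    res <- lapply(names(lens), function(chr) {
        L <- lens[[chr]]
        anchors <- seq.int(1L, L, by = as.integer(step))
        ends <- pmin(anchors + as.integer(width) - 1L, L)
        pos <- sort(start(rr)[keep & as.character(seqnames(rr)) == chr])
        cnt <- findInterval(ends, pos) - findInterval(anchors - 1L, pos)
        gr <- GRanges(chr, IRanges(anchors, ends), seqinfo = seqinfo(rr))
        mcols(gr)$snpCount <- cnt
        mcols(gr)$density <- cnt * (2e6 / (ends - anchors + 1))
        gr
    })
    track <- do.call(c, res)
    metadata(track) <- list(sample = sample, width = width, step = step,
                            include = include)
    track
}

#' Call raw high-SNP-density regions against control tracks
#'
#' A window is "high" when the sample's density reaches the absolute floor
#' `minAbs` AND is at least `fold` times the maximum control density at
#' that window (controls floored at 1 SNP/2 Mb so clean windows do not
#' divide by zero). Maximal runs of high windows are merged into regions;
#' runs separated by less than one window width are merged too. These
#' explicit thresholds quantify what the original screen judged by eye.
#'
#' @param sampleTrack track from [snpDensityTrack()] for the focal sample.
#' @param controlTracks list of tracks on the identical window grid for the
#'   control samples (at least one).
#' @param fold fold-change over controls (default 10).
#' @param minAbs absolute density floor in SNPs per 2 Mb (default 20,
#'   chosen so any segment with at least 20 sample-specific SNPs --- the
#'   detection guarantee --- can clear the floor).
#' @return a [GenomicRanges::GRanges] of raw candidate regions.
#' @export
callHighDensityRegions <- function(sampleTrack, controlTracks, fold = 10,
                                   minAbs = 20) {
    if (is(controlTracks, "GRanges")) controlTracks <- list(controlTracks)
    if (!length(controlTracks)) stop("at least one control track required")
    key <- paste(seqnames(sampleTrack), start(sampleTrack))
    for (ct in controlTracks)
        if (!identical(paste(seqnames(ct), start(ct)), key))
            stop("control track not on the same window grid")
    ctrl <- do.call(pmax, lapply(controlTracks,
                                 function(ct) mcols(ct)$density))
    dens <- mcols(sampleTrack)$density
    high <- dens >= minAbs & dens >= fold * pmax(ctrl, 1)
    if (!any(high)) return(GRanges(seqinfo = seqinfo(sampleTrack)))
    width <- metadata(sampleTrack)$width %||%
        max(GenomicRanges::width(sampleTrack))
    reduce(sampleTrack[high], min.gapwidth = width)
}

# sample-specific site: non-ref in the sample, ref or missing in ALL controls
.sampleSpecificSites <- function(vt, sample, controls) {
    gt <- assay(vt, "GT")
    focal <- !is.na(gt[, sample]) & gt[, sample] > 0L
    cg <- gt[, controls, drop = FALSE]
    clean <- rowSums(!is.na(cg) & cg > 0L) == 0L
    focal & clean
}

#' Refine introgression borders by the 10-kb rule
#'
#' The border of a region is placed `pad` bp outside the outermost
#' sample-specific SNP it contains --- a SNP present in the focal sample but
#' reference or missing in every control --- and clipped to the chromosome.
#' Regions with fewer than `minRegionSnps` sample-specific SNPs are dropped
#' with a message.
#'
#' @param rawRegions [GenomicRanges::GRanges] from
#'   [callHighDensityRegions()].
#' @param vt a [VariantTable] containing `sample` and `controls`.
#' @param sample,controls focal and control sample names.
#' @param pad border padding in bp (default 10,000).
#' @param minRegionSnps minimum sample-specific SNPs per region
#'   (default 10).
#' @param maxGap split a raw region into separate introgression events
#'   where consecutive sample-specific SNPs lie further apart than this
#'   (default 1e5 bp; with the desk-scale donor marker spacing of ~500 bp a
#'   100-kb SNP desert is unambiguous recipient material). The wide
#'   sliding windows otherwise bridge distinct events into one raw region.
#' @return refined `GRanges` with metadata column `snpCount` (number of
#'   sample-specific SNPs).
#' @export
refineBorders <- function(rawRegions, vt, sample, controls, pad = 1e4,
                          minRegionSnps = 10L, maxGap = 1e5) {
    .assertSample(vt, c(sample, controls))
    rr <- rowRanges(vt)
    lens <- .chromLengths(seqinfo(rr))
    spec <- .sampleSpecificSites(vt, sample, controls)
    sites <- rr[spec]
    out <- list()
    for (i in seq_along(rawRegions)) {
        reg <- rawRegions[i]
        inReg <- overlapsAny(sites, reg)
        pos <- sort(start(sites)[inReg])
        chr <- as.character(seqnames(reg))
        if (!length(pos)) {
            message(sprintf("region %s:%d-%d dropped (no sample-specific SNPs)",
                            chr, start(reg), end(reg)))
            next
        }
        # one event per run of SNPs separated by <= maxGap
        runId <- cumsum(c(1L, diff(pos) > maxGap))
        for (p in split(pos, runId)) {
            if (length(p) < minRegionSnps) {
                message(sprintf(
                    "event in %s:%d-%d dropped (%d sample-specific SNPs < %d)",
                    chr, start(reg), end(reg), length(p), minRegionSnps))
                next
            }
            gr <- GRanges(chr,
                          IRanges(max(1L, min(p) - as.integer(pad)),
                                  min(lens[[chr]],
                                      max(p) + as.integer(pad))),
                          seqinfo = seqinfo(rr))
            mcols(gr)$snpCount <- length(p)
            out[[length(out) + 1L]] <- gr
        }
    }
    if (!length(out)) return(GRanges(seqinfo = seqinfo(rr)))
    sort(do.call(c, out))
}

#' Classify the zygosity of a region
#'
#' Among the sample's genotyped non-reference calls inside the region:
#' `heterozygous` when the het fraction is at least `hetHi`, `homozygous`
#' when at most `hetLo`, `mixed` otherwise (a candidate internal
#' recombination breakpoint).
#'
#' @param region a single-range [GenomicRanges::GRanges].
#' @param vt a [VariantTable].
#' @param sample sample name.
#' @param hetHi,hetLo classification thresholds (defaults 0.8 / 0.2).
#' @return `"heterozygous"`, `"homozygous"` or `"mixed"`.
#' @export
classifyZygosity <- function(region, vt, sample, hetHi = 0.8, hetLo = 0.2) {
    .assertSample(vt, sample)
    gt <- assay(vt, "GT")[, sample]
    inReg <- overlapsAny(rowRanges(vt), region)
    calls <- gt[inReg & !is.na(gt) & gt > 0L]
    if (!length(calls)) stop("no genotyped non-reference calls in region")
    hf <- mean(calls == 1L)
    if (hf >= hetHi) "heterozygous" else if (hf <= hetLo) "homozygous"
    else "mixed"
}

#' Donor similarity of a region
#'
#' Fraction of the sample's non-reference sites in the region at which the
#' donor sample carries the same alternate allele. Values near 1 support
#' introgressed (donor-derived) material; culture mutations score 0.
#'
#' @inheritParams classifyZygosity
#' @param donorSample donor sample name.
#' @return a fraction in `[0, 1]`.
#' @export
donorSimilarity <- function(region, vt, sample, donorSample) {
    .assertSample(vt, c(sample, donorSample))
    gt <- assay(vt, "GT")
    inReg <- overlapsAny(rowRanges(vt), region)
    sel <- inReg & !is.na(gt[, sample]) & gt[, sample] > 0L
    if (!sum(sel)) stop("sample has no non-reference sites in region")
    dg <- gt[sel, donorSample]
    mean(!is.na(dg) & dg > 0L)
}

#' Heterozygosity profile in fixed bins
#'
#' Counts heterozygous calls per fixed bin (default 100 kb), the profile
#' used to recognize a genome-wide heterozygous regenerant. Bin 1 covers
#' positions 1 to `bin`.
#'
#' @param vt a [VariantTable].
#' @param sample sample name.
#' @param bin bin width in bp (default 1e5).
#' @return a [GenomicRanges::GRanges] tiling of the genome with a
#'   `hetCount` column.
#' @export
hetProfile <- function(vt, sample, bin = 1e5) {
    .assertSample(vt, sample)
    rr <- rowRanges(vt)
    gt <- assay(vt, "GT")[, sample]
    het <- rr[!is.na(gt) & gt == 1L]
    bins <- unlist(tileGenome(seqlengths(seqinfo(rr)),
                              tilewidth = as.integer(bin)))
    mcols(bins)$hetCount <- countOverlaps(bins, het)
    bins
}

#' Classify the global genome state of a sample
#'
#' `genome_wide_heterozygous` when at least `hiFrac` of the bins exceed the
#' het-count floor (the signature of a fresh outcross regenerant); `clean`
#' when no introgression regions were called and at most `cleanFrac` of
#' bins exceed the floor; `segmental_introgression` otherwise.
#'
#' @param profile a [hetProfile()] result.
#' @param regions called introgression regions ([GenomicRanges::GRanges]).
#' @param floorCount het calls per bin above which a bin counts as
#'   heterozygous (default 10).
#' @param hiFrac,cleanFrac bin-fraction thresholds (defaults 0.9 / 0.01).
#' @return one of `"clean"`, `"segmental_introgression"`,
#'   `"genome_wide_heterozygous"`.
#' @export
classifyGenomeState <- function(profile, regions, floorCount = 10L,
                                hiFrac = 0.9, cleanFrac = 0.01) {
    above <- mean(mcols(profile)$hetCount > floorCount)
    if (above >= hiFrac) return("genome_wide_heterozygous")
    if (length(regions) == 0L && above <= cleanFrac) return("clean")
    "segmental_introgression"
}

# recursively split a mixed region at the boundary of its longest
# same-zygosity run of sample-specific SNPs; recursion is on the ordered
# site vectors so halves can never re-absorb each other's sites
.splitSites <- function(chr, pos, z, pad, minRegionSnps, hetHi, hetLo,
                        lens, si) {
    mk <- function(p, zygosity, n) {
        gr <- GRanges(chr, IRanges(max(1L, min(p) - as.integer(pad)),
                                   min(lens[[chr]],
                                       max(p) + as.integer(pad))),
                      seqinfo = si)
        mcols(gr)$snpCount <- n
        mcols(gr)$zygosity <- zygosity
        gr
    }
    classify <- function(hf) {
        if (hf >= hetHi) "heterozygous"
        else if (hf <= hetLo) "homozygous"
        else "mixed"
    }
    hf <- mean(z)
    cls <- classify(hf)
    if (cls != "mixed" || length(pos) < 2 * minRegionSnps)
        return(mk(pos, cls, length(pos)))
    runs <- rle(z)
    if (length(runs$lengths) < 2L) return(mk(pos, cls, length(pos)))
    ends <- cumsum(runs$lengths)
    big <- which.max(runs$lengths)
    cut <- if (big == 1L) ends[1L] else ends[big - 1L]
    if (cut < minRegionSnps || length(pos) - cut < minRegionSnps)
        return(mk(pos, cls, length(pos)))
    c(.splitSites(chr, pos[seq_len(cut)], z[seq_len(cut)], pad,
                  minRegionSnps, hetHi, hetLo, lens, si),
      .splitSites(chr, pos[(cut + 1L):length(pos)],
                  z[(cut + 1L):length(z)], pad, minRegionSnps, hetHi,
                  hetLo, lens, si))
}

.splitRegion <- function(region, vt, sample, spec, pad, minRegionSnps,
                         hetHi, hetLo, lens) {
    rr <- rowRanges(vt)
    gt <- assay(vt, "GT")[, sample]
    inReg <- which(spec & overlapsAny(rr, region) & !is.na(gt) & gt > 0L)
    pos <- start(rr)[inReg]
    z <- gt[inReg] == 1L     # het vs hom among non-ref calls
    o <- order(pos)
    .splitSites(as.character(seqnames(region)), pos[o], z[o], pad,
                minRegionSnps, hetHi, hetLo, lens, seqinfo(rr))
}

#' Detect introgression regions for one sample
#'
#' End-to-end detector: sliding-window SNP density for the sample and the
#' controls, high-density region calls, border refinement by the 10-kb
#' rule, zygosity classification (mixed regions recursively split at their
#' largest het/hom run boundary when both halves retain enough SNPs), and
#' optional donor similarity.
#'
#' @param vt a [VariantTable].
#' @param sample focal sample name.
#' @param controls control sample names (at least one required).
#' @param donorSample optional donor sample for the similarity column.
#' @param width,step sliding-window geometry (see [snpDensityTrack()]).
#' @param fold,minAbs high-density thresholds
#'   (see [callHighDensityRegions()]).
#' @param pad,minRegionSnps,maxGap border rule (see [refineBorders()]).
#' @param hetHi,hetLo zygosity thresholds (see [classifyZygosity()]).
#' @return a [GenomicRanges::GRanges] of introgression regions with
#'   metadata columns `zygosity`, `snpCount` and (when `donorSample` is
#'   given) `donorSimilarity`.
#' @export
detectIntrogression <- function(vt, sample, controls, donorSample = NULL,
                                width = 2e6, step = 5e3, fold = 10,
                                minAbs = 20, pad = 1e4, minRegionSnps = 10L,
                                maxGap = 1e5, hetHi = 0.8, hetLo = 0.2) {
    if (!length(controls)) stop("at least one control sample is required")
    .assertSample(vt, c(sample, controls))
    st <- snpDensityTrack(vt, sample, width, step)
    ct <- lapply(controls, function(s) snpDensityTrack(vt, s, width, step))
    raw <- callHighDensityRegions(st, ct, fold, minAbs)
    regions <- refineBorders(raw, vt, sample, controls, pad, minRegionSnps,
                             maxGap)
    if (!length(regions)) return(regions)
    lens <- .chromLengths(seqinfo(rowRanges(vt)))
    spec <- .sampleSpecificSites(vt, sample, controls)
    pieces <- lapply(seq_along(regions), function(i)
        .splitRegion(granges(regions[i]), vt, sample, spec, pad,
                     minRegionSnps, hetHi, hetLo, lens))
    out <- sort(do.call(c, pieces))
    if (!is.null(donorSample))
        mcols(out)$donorSimilarity <- vapply(seq_along(out), function(i)
            donorSimilarity(out[i], vt, sample, donorSample), 0)
    out
}
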