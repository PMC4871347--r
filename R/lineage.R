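#' Introgressed genome fraction
#'
#' Fraction of the genome covered by introgression regions after interval
#' union, optionally restricted by zygosity (regions lacking a `zygosity`
#' column count only under `mode = "any"`). Overlapping regions of
#' conflicting zygosity are resolved by plain interval arithmetic on the
#' selected subset.
#'
#' @param regions a [GenomicRanges::GRanges], typically from
#'   [detectIntrogression()].
#' @param genome a [GenomeInfoDb::Seqinfo].
#' @param mode `"any"`, `"hom"`, `"het"` or `"mixed"`.
#' @return list with `overall` (single fraction) and `perChromosome`
#'   (named vector over all chromosomes of the genome).
#' @export
introgressionFraction <- function(regions, genome,
                                  mode = c("any", "hom", "het", "mixed")) {
    mode <- match.arg(mode)
    lens <- .chromLengths(genome)
    if (length(regions) && any(end(regions) > lens[as.character(seqnames(regions))]))
        stop("regions exceed chromosome bounds")
    if (mode != "any") {
        z <- mcols(regions)$zygosity
        if (is.null(z)) stop("regions carry no zygosity column")
        want <- c(hom = "homozygous", het = "heterozygous",
                  mixed = "mixed")[[mode]]
        regions <- regions[z == want]
    }
    red <- reduce(regions, ignore.strand = TRUE)
    perChrom <- vapply(names(lens), function(chr)
        sum(GenomicRanges::width(red[seqnames(red) == chr])) / lens[[chr]],
        0)
    list(overall = sum(GenomicRanges::width(red)) / sum(lens),
         perChromosome = perChrom)
}

#' Union introgression fraction over several plants
#'
#' Fraction of the genome covered by the union of all plants' region sets
#' --- the "sum of any possible introgressed region" summary used to argue
#' the generation of the founding outcross.
#'
#' @param regionSets list of [GenomicRanges::GRanges] (one per plant).
#' @param genome a [GenomeInfoDb::Seqinfo].
#' @return a single fraction.
#' @export
unionFraction <- function(regionSets, genome) {
    if (!length(regionSets)) stop("at least one plant required")
    all <- reduce(do.call(c, unname(lapply(regionSets, granges))),
                  ignore.strand = TRUE)
    sum(GenomicRanges::width(all)) / sum(.chromLengths(genome))
}

#' Expected zygosity of initially heterozygous material after selfing
#'
#' After g selfing generations, material heterozygous in the founding F1
#' remains heterozygous with probability (1/2)^g and fixes to either
#' homozygote with probability (1 - (1/2)^g)/2 each.
#'
#' @param g number of selfing generations (>= 0).
#' @return named numeric vector `c(het, homDonor, homRecipient)`, summing
#'   to 1.
#' @examples
#' expectedZygosityAfterSelfing(2)  # het 0.25: the "(1/2)^2" argument
#' @export
expectedZygosityAfterSelfing <- function(g) {
    .assertScalarNum(g, "g", 0)
    het <- 0.5^g
    c(het = het, homDonor = (1 - het) / 2, homRecipient = (1 - het) / 2)
}

#' Infer generations since the outcross from the het fraction
#'
#' Inverts the (1/2)^g decay: the continuous estimate is -log2(fraction)
#' and the integer estimate its rounding. The fraction must be the het
#' share of *initially heterozygous* material --- all loci segregating from
#' the outcross, including those since fixed to the recipient --- because
#' only that denominator decays as (1/2)^g.
#'
#' @param hetFraction observed het fraction in (0, 1].
#' @return list with `gHat` (integer) and `continuous`.
#' @examples
#' inferGenerations(0.25)  # gHat = 2
#' @export
inferGenerations <- function(hetFraction) {
    .assertScalarNum(hetFraction, "hetFraction")
    if (hetFraction <= 0 || hetFraction > 1)
        stop("'hetFraction' must be in (0, 1]")
    cont <- -log2(hetFraction)
    list(gHat = as.integer(round(cont)), continuous = cont)
}

#' Track regions across generations
#'
#' Matches regions between consecutive generations by reciprocal overlap
#' (each region covering at least `minOverlap` of the other) and labels the
#' trajectory of every generation-1 region: `het->het`, `het->hom`,
#' `het->lost`, `hom->hom`, etc. Later-generation regions never matched to
#' an earlier one are returned in the `unmatched` attribute.
#'
#' @param regionSetsByGeneration ordered named list of
#'   [GenomicRanges::GRanges], each with a `zygosity` column.
#' @param minOverlap reciprocal-overlap fraction (default 0.5).
#' @return data.frame with the founding region, its per-generation states
#'   (`NA` once lost) and a `trajectory` label; attribute `unmatched`.
#' @export
trackFixation <- function(regionSetsByGeneration, minOverlap = 0.5) {
    gens <- regionSetsByGeneration
    if (!length(gens)) stop("empty generation list")
    if (is.null(names(gens))) names(gens) <- paste0("gen", seq_along(gens))
    zy <- function(gr) {
        z <- mcols(gr)$zygosity
        if (is.null(z)) rep("any", length(gr)) else as.character(z)
    }
    short <- function(z) c(heterozygous = "het", homozygous = "hom",
                           mixed = "mixed", any = "any")[z]
    matchOne <- function(reg, later) {
        if (!length(later)) return(NA_integer_)
        ov <- findOverlaps(reg, later)
        if (!length(ov)) return(NA_integer_)
        j <- S4Vectors::subjectHits(ov)
        inter <- GenomicRanges::width(pintersect(rep(reg, length(j)),
                                                 later[j]))
        recip <- inter / GenomicRanges::width(reg) >= minOverlap &
            inter / GenomicRanges::width(later[j]) >= minOverlap
        if (!any(recip)) return(NA_integer_)
        j[recip][which.max(inter[recip])]
    }
    first <- gens[[1L]]
    touched <- lapply(gens, function(g) logical(length(g)))
    rows <- lapply(seq_along(first), function(i) {
        states <- character(length(gens))
        states[1L] <- short(zy(first)[i])
        cur <- first[i]
        alive <- TRUE
        for (k in seq_along(gens)[-1L]) {
            if (!alive) { states[k] <- NA_character_; next }
            j <- matchOne(cur, gens[[k]])
            if (is.na(j)) { states[k] <- "lost"; alive <- FALSE; next }
            touched[[k]][j] <<- TRUE
            states[k] <- short(zy(gens[[k]])[j])
            cur <- gens[[k]][j]
        }
        last <- states[!is.na(states)]
        data.frame(chrom = as.character(seqnames(first[i])),
                   start = start(first[i]), end = end(first[i]),
                   t(stats::setNames(states, names(gens))),
                   trajectory = paste(states[1L], last[length(last)],
                                      sep = "->"),
                   stringsAsFactors = FALSE)
    })
    out <- if (length(rows)) do.call(rbind, rows) else
        data.frame(chrom = character(), start = integer(), end = integer(),
                   trajectory = character())
    unmatchedList <- lapply(seq_along(gens)[-1L], function(k) {
        u <- granges(gens[[k]][!touched[[k]]])
        mcols(u)$generation <- rep(names(gens)[k], length(u))
        u
    })
    unmatched <- if (length(unmatchedList)) do.call(c, unmatchedList)
                 else GRanges()
    attr(out, "unmatched") <- unmatched
    out
}

#' Zygosity of a single marker locus in a sample
#'
#' Classification used for the T-DNA presence pseudo-marker: hom-alt maps
#' to `homozygous`, het to `heterozygous`, hom-ref to `azygous` (the
#' transgene is absent), and an uncalled genotype to `missing`.
#'
#' @param vt a [VariantTable].
#' @param sample sample name.
#' @param chrom,pos locus coordinates (must be a site of the table).
#' @return one of `"homozygous"`, `"heterozygous"`, `"azygous"`,
#'   `"missing"`.
#' @export
classifyLocusZygosity <- function(vt, sample, chrom, pos) {
    .assertSample(vt, sample)
    rr <- rowRanges(vt)
    i <- which(as.character(seqnames(rr)) == chrom & start(rr) == pos)
    if (!length(i)) stop(sprintf("locus %s:%d not in table", chrom, pos))
    g <- assay(vt, "GT")[i[1L], sample]
    if (is.na(g)) "missing"
    else c("azygous", "heterozygous", "homozygous")[g + 1L]
}

#' Het fraction of initially heterozygous material in simulated plants
#'
#' Truth-based summary for generation inference: the fraction of
#' donor-diagnostic markers (all heterozygous in the founding F1) that are
#' still heterozygous, averaged over the supplied plants.
#'
#' @param plants a list of [SimPlant]s descended from a single F1.
#' @param panel the marker panel.
#' @return a single fraction.
#' @export
hetFractionOfIntrogressed <- function(plants, panel) {
    if (is(plants, "SimPlant")) plants <- list(plants)
    donorIdx <- mcols(panel)$class == "donor-diagnostic"
    if (!sum(donorIdx)) stop("panel has no donor-diagnostic markers")
    mean(vapply(plants, function(p)
        mean(.plantDosage(p, panel)[donorIdx] == 1L), 0))
}
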