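#' Simulated genome layout
#'
#' Chromosome-length table for the simulator. The default desk-scale genome
#' is 12 chromosomes of 2.5 Mb each, small enough that a full pedigree plus
#' all downstream analyses run in seconds; real chromosome lengths can be
#' supplied instead via `lengths`.
#'
#' @param nChrom number of chromosomes (ignored when `lengths` is given).
#' @param chromLength length in bp of every chromosome (ignored when
#'   `lengths` is given).
#' @param lengths optional named integer vector of chromosome lengths.
#' @return a [GenomeInfoDb::Seqinfo].
#' @examples
#' riceGenome()
#' riceGenome(lengths = c(chr1 = 4e6, chr2 = 3e6))
#' @export
riceGenome <- function(nChrom = 12L, chromLength = 2.5e6, lengths = NULL) {
    if (is.null(lengths)) {
        .assertScalarNum(nChrom, "nChrom", 1)
        .assertScalarNum(chromLength, "chromLength", 1)
        lengths <- stats::setNames(rep(as.integer(chromLength), nChrom),
                                   paste0("chr", seq_len(nChrom)))
    }
    if (is.null(names(lengths)) || anyDuplicated(names(lengths)))
        stop("chromosome names must be present and unique")
    if (any(lengths <= 0)) stop("chromosome lengths must be > 0")
    Seqinfo(seqnames = names(lengths), seqlengths = as.integer(lengths),
            genome = "sim")
}

# new plant whose two haplotypes are single-ancestry across the genome
.foundPlant <- function(id, genome, ancestry) {
    lens <- .chromLengths(genome)
    mosaic <- data.frame(chrom = names(lens), start = 1L,
                         end = as.integer(lens), ancestry = ancestry,
                         stringsAsFactors = FALSE)
    hap <- list(mosaic = mosaic, extras = .emptyExtras())
    new("SimPlant", id = id, genome = genome, haplotypes = list(hap, hap))
}

.emptyExtras <- function() {
    data.frame(chrom = character(), pos = integer(), class = character(),
               stringsAsFactors = FALSE)
}

.markerClasses <- c("donor-diagnostic", "parent2-diagnostic",
                    "culture-mutation", "tdna-proxy")

# assemble a sorted marker panel GRanges from per-class position lists
.panelFromSites <- function(genome, chrom, pos, class, ref = NULL, alt = NULL) {
    n <- length(pos)
    if (is.null(ref)) {
        ref <- sample(.DNA, n, replace = TRUE)
        shift <- sample.int(3L, n, replace = TRUE)   # uniform non-ref base
        alt <- .DNA[(match(ref, .DNA) - 1L + shift) %% 4L + 1L]
    }
    gr <- GRanges(chrom, IRanges(pos, width = 1L), seqinfo = genome)
    mcols(gr)$ref <- unname(ref)
    mcols(gr)$alt <- unname(alt)
    mcols(gr)$class <- class
    sort(gr)
}

#' Create the founder plants and marker panel
#'
#' Lays down the biallelic marker map and the three founder lines of the
#' crossing history: the *japonica* recipient (homozygous reference
#' everywhere), the *indica*-like donor (homozygous alternate at every
#' donor-diagnostic marker) and a second *japonica* mapping parent
#' (homozygous alternate at every parent2-diagnostic marker). Marker counts
#' per chromosome are Poisson with mean `density * length`, positions
#' uniform. Defaults mirror the observed contrast between an
#' indica-vs-japonica comparison (millions of genome-wide SNPs; desk-scaled
#' here to ~2 SNPs/kb) and a japonica-vs-japonica cross (tens of thousands;
#' ~0.17 SNPs/kb).
#'
#' @param genome a [GenomeInfoDb::Seqinfo], see [riceGenome()].
#' @param donorDensity donor-diagnostic markers per bp (default `2e-3`).
#' @param parent2Density parent2-diagnostic markers per bp (default
#'   `1.7e-4`).
#' @param forcedDonorMarkers optional data.frame (`chrom`, `pos`) of
#'   positions guaranteed to carry a donor-diagnostic marker (used to place
#'   causal loci deterministically).
#' @return list with elements `panel` (a sorted [GenomicRanges::GRanges]
#'   with `ref`, `alt`, `class` columns), `recipient`, `donor`, `parent2`
#'   (three [SimPlant] founders).
#' @examples
#' f <- withr::with_seed(1, makeFounders(riceGenome(2, 1e6)))
#' f$panel
#' @export
makeFounders <- function(genome, donorDensity = 2e-3,
                         parent2Density = 1.7e-4,
                         forcedDonorMarkers = NULL) {
    .assertScalarNum(donorDensity, "donorDensity", 0)
    .assertScalarNum(parent2Density, "parent2Density", 0)
    if (donorDensity >= 1 || parent2Density >= 1)
        stop("marker density implies expected spacing below 1 bp")
    if (donorDensity <= 0)
        stop("donorDensity must be > 0")
    lens <- .chromLengths(genome)
    draw <- function(density) {
        res <- lapply(names(lens), function(chr) {
            n <- min(stats::rpois(1L, density * lens[[chr]]),
                     lens[[chr]])
            pos <- sort(unique(as.integer(
                ceiling(stats::runif(n) * lens[[chr]]))))
            data.frame(chrom = rep(chr, length(pos)), pos = pos,
                       stringsAsFactors = FALSE)
        })
        do.call(rbind, res)
    }
    dsites <- draw(donorDensity)
    if (!is.null(forcedDonorMarkers)) {
        dsites <- rbind(dsites, forcedDonorMarkers[, c("chrom", "pos")])
        dsites <- dsites[!duplicated(.siteKey(dsites$chrom, dsites$pos)), ]
    }
    psites <- draw(parent2Density)
    # a site can diagnose only one parent: later classes yield to earlier
    psites <- psites[!.siteKey(psites$chrom, psites$pos) %in%
                         .siteKey(dsites$chrom, dsites$pos), , drop = FALSE]
    chrom <- c(dsites$chrom, psites$chrom)
    pos <- c(dsites$pos, psites$pos)
    class <- rep(c("donor-diagnostic", "parent2-diagnostic"),
                 c(nrow(dsites), nrow(psites)))
    panel <- .panelFromSites(genome, chrom, pos, class)
    list(panel = panel,
         recipient = .foundPlant("recipient", genome, "recipient"),
         donor = .foundPlant("donor", genome, "donor"),
         parent2 = .foundPlant("parent2", genome, "parent2"))
}

#' Haplotype ancestry mosaics of a simulated plant
#'
#' The simulation truth: each haplotype as a [GenomicRanges::GRanges] of
#' ancestry segments (metadata columns `ancestry` and `haplotype`),
#' 1-based closed, tiling every chromosome.
#'
#' @param plant a [SimPlant].
#' @return a `GRanges` with one range per ancestry segment.
#' @export
haplotypeRanges <- function(plant) {
    stopifnot(is(plant, "SimPlant"))
    grs <- lapply(1:2, function(h) {
        m <- plant@haplotypes[[h]]$mosaic
        gr <- GRanges(m$chrom, IRanges(m$start, m$end), seqinfo = plant@genome)
        mcols(gr)$ancestry <- m$ancestry
        mcols(gr)$haplotype <- h
        gr
    })
    sort(c(grs[[1]], grs[[2]]), ignore.strand = TRUE)
}

#' Truth donor segments of a plant
#'
#' Convenience view of the simulation truth used to score the detector:
#' the union of segments whose ancestry matches `ancestry` on either
#' haplotype (mode `"any"`), on both (`"hom"`), or on exactly one (`"het"`).
#'
#' @param plant a [SimPlant].
#' @param ancestry ancestry label to extract (default `"donor"`).
#' @param mode `"any"`, `"hom"` or `"het"`.
#' @return a reduced [GenomicRanges::GRanges].
#' @export
truthSegments <- function(plant, ancestry = "donor",
                          mode = c("any", "hom", "het")) {
    mode <- match.arg(mode)
    hr <- haplotypeRanges(plant)
    h1 <- reduce(hr[hr$ancestry == ancestry & hr$haplotype == 1L])
    h2 <- reduce(hr[hr$ancestry == ancestry & hr$haplotype == 2L])
    switch(mode,
           any = reduce(c(h1, h2)),
           hom = GenomicRanges::intersect(h1, h2),
           het = GenomicRanges::setdiff(reduce(c(h1, h2)),
                                        GenomicRanges::intersect(h1, h2)))
}

#' Donor allele share of a simulated plant
#'
#' Fraction of the diploid genome (by bp, both haplotypes) with the given
#' ancestry, computed from the truth mosaics.
#'
#' @param plant a [SimPlant].
#' @param ancestry ancestry label (default `"donor"`).
#' @return a fraction in `[0, 1]`.
#' @export
ancestryShare <- function(plant, ancestry = "donor") {
    stopifnot(is(plant, "SimPlant"))
    tot <- 2 * sum(.chromLengths(plant@genome))
    bp <- sum(vapply(plant@haplotypes, function(h) {
        m <- h$mosaic
        sum(as.numeric(m$end - m$start + 1L)[m$ancestry == ancestry])
    }, 0))
    bp / tot
}

setMethod("show", "SimPlant", function(object) {
    nseg <- sum(vapply(object@haplotypes,
                       function(h) nrow(h$mosaic), 0L))
    nex <- sum(vapply(object@haplotypes,
                      function(h) nrow(h$extras), 0L))
    cat(sprintf("SimPlant '%s': %d chromosomes, %d ancestry segments, %d extra sites\n",
                object@id, length(seqlevels(object@genome)), nseg, nex))
})
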