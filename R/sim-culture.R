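#' Apply tissue-culture point mutations to a regenerant
#'
#' Somaclonal point mutations arise during callus induction and
#' regeneration. The number of new sites is Poisson with mean
#' `mu * genome size`; each lands at a position not already in the marker
#' panel and on one random haplotype, so every culture mutation is
#' heterozygous in the regenerant. New sites are appended to the panel as
#' `culture-mutation` markers. The default rate sits inside the measured
#' somaclonal range of 8.9--21.0 x 10^-7 per site per diploid genome.
#'
#' @param plant the [SimPlant] entering tissue culture.
#' @param panel the current marker panel ([GenomicRanges::GRanges]).
#' @param mu mutation rate per site per diploid genome (default `1.5e-6`).
#' @param forcedMutations optional data.frame (`chrom`, `pos`) of mutation
#'   sites planted deterministically (in addition to the Poisson draw); used
#'   to place a causal culture SNP.
#' @return list with the mutated `plant` and the augmented `panel`.
#' @export
applyCultureMutations <- function(plant, panel, mu = 1.5e-6,
                                  forcedMutations = NULL) {
    stopifnot(is(plant, "SimPlant"))
    .assertScalarNum(mu, "mu", 0)
    lens <- .chromLengths(plant@genome)
    n <- stats::rpois(1L, mu * sum(lens))
    sites <- NULL
    if (n > 0L) {
        chrom <- sample(names(lens), n, replace = TRUE,
                        prob = lens / sum(lens))
        pos <- as.integer(ceiling(stats::runif(n) * lens[chrom]))
        sites <- data.frame(chrom = chrom, pos = pmax(pos, 1L),
                            stringsAsFactors = FALSE)
    }
    if (!is.null(forcedMutations))
        sites <- rbind(sites, data.frame(chrom = forcedMutations$chrom,
                                         pos = as.integer(forcedMutations$pos),
                                         stringsAsFactors = FALSE))
    if (is.null(sites) || !nrow(sites)) return(list(plant = plant, panel = panel))
    # no collisions with existing markers or each other
    occupied <- .siteKey(as.character(seqnames(panel)), start(panel))
    sites <- sites[!.siteKey(sites$chrom, sites$pos) %in% occupied, , drop = FALSE]
    sites <- sites[!duplicated(.siteKey(sites$chrom, sites$pos)), , drop = FALSE]
    if (!nrow(sites)) return(list(plant = plant, panel = panel))
    hap <- sample.int(2L, nrow(sites), replace = TRUE)
    for (h in 1:2) {
        add <- sites[hap == h, , drop = FALSE]
        if (!nrow(add)) next
        add$class <- "culture-mutation"
        plant@haplotypes[[h]]$extras <-
            rbind(plant@haplotypes[[h]]$extras, add)
    }
    newMarkers <- .panelFromSites(plant@genome, sites$chrom, sites$pos,
                                  "culture-mutation")
    list(plant = plant, panel = sort(c(panel, newMarkers)))
}

#' Insert the T-DNA pseudo-marker
#'
#' The T-DNA is modeled as a biallelic presence marker (`tdna-proxy` class)
#' carried on one haplotype of the regenerant (dosage 1); it then segregates
#' Mendelianly through subsequent meioses. Flanking-sequence mechanics are
#' out of scope.
#'
#' @param plant the regenerant [SimPlant].
#' @param panel the marker panel.
#' @param chrom,pos insertion site (1-based), must lie within the chromosome.
#' @return list with updated `plant` and `panel`.
#' @export
insertTdna <- function(plant, panel, chrom, pos) {
    stopifnot(is(plant, "SimPlant"))
    lens <- .chromLengths(plant@genome)
    if (!chrom %in% names(lens)) stop("unknown chromosome: ", chrom)
    pos <- as.integer(pos)
    if (pos < 1L || pos > lens[[chrom]])
        stop(sprintf("position %d outside %s (length %d)", pos, chrom,
                     lens[[chrom]]))
    if (.siteKey(chrom, pos) %in%
        .siteKey(as.character(seqnames(panel)), start(panel)))
        stop("insertion site collides with an existing marker")
    plant@haplotypes[[1]]$extras <- rbind(
        plant@haplotypes[[1]]$extras,
        data.frame(chrom = chrom, pos = pos, class = "tdna-proxy",
                   stringsAsFactors = FALSE))
    newMarker <- .panelFromSites(plant@genome, chrom, pos, "tdna-proxy")
    list(plant = plant, panel = sort(c(panel, newMarker)))
}

#' T-DNA dosage of a plant
#'
#' @param plant a [SimPlant].
#' @return 0, 1 or 2 copies of the T-DNA pseudo-marker.
#' @export
tdnaDosage <- function(plant) {
    sum(vapply(plant@haplotypes,
               function(h) sum(h$extras$class == "tdna-proxy"), 0L))
}

#' Phenotype labels from causal loci
#'
#' Both causal traits in the modeled line are fully penetrant recessives: a
#' label is asserted iff both haplotypes carry the causal (alternate)
#' allele. One causal locus sits on a donor haplotype (the grain-size
#' locus), the other is a tissue-culture mutation (the tillering-dwarf
#' locus).
#'
#' @param plant a [SimPlant].
#' @param panel the marker panel.
#' @param causalLoci data.frame with columns `chrom`, `pos`, `label`; every
#'   locus must be a marker in the panel.
#' @return character vector of asserted labels (possibly empty).
#' @examples
#' # hom donor at the grain locus and hom culture SNP at the dwarf locus
#' # yields both labels, matching a large-grain tillering-dwarf plant
#' @export
phenotypeOf <- function(plant, panel, causalLoci) {
    stopifnot(is(plant, "SimPlant"))
    if (!nrow(causalLoci)) return(character())
    pchrom <- as.character(seqnames(panel))
    ppos <- start(panel)
    idx <- vapply(seq_len(nrow(causalLoci)), function(k) {
        i <- which(pchrom == causalLoci$chrom[k] &
                       ppos == causalLoci$pos[k])
        if (!length(i)) stop("causal locus not in panel: ",
                             causalLoci$chrom[k], ":", causalLoci$pos[k])
        i[1L]
    }, 0L)
    dos <- .dosageAtSites(plant, causalLoci$chrom, causalLoci$pos,
                          mcols(panel)$class[idx])
    as.character(causalLoci$label[dos == 2L])
}
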