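#' @import methods
#' @importFrom BiocGenerics sort strand
#' @importFrom S4Vectors DataFrame SimpleList mcols mcols<- metadata metadata<-
#' @importFrom GenomicRanges GRanges granges seqnames start end width reduce
#'   findOverlaps countOverlaps pintersect tileGenome
#' @importFrom IRanges IRanges subsetByOverlaps overlapsAny
#' @importFrom GenomeInfoDb Seqinfo seqlengths seqlevels seqinfo seqinfo<-
#' @importFrom SummarizedExperiment SummarizedExperiment rowRanges colData assay
#'   assays assayNames
NULL

#' Multi-sample SNP genotype and allele-depth table
#'
#' `VariantTable` is the pipeline's universal currency: biallelic SNP sites
#' (rows, reference-anchored and sorted by chromosome and position) crossed
#' with samples (columns). It extends
#' [SummarizedExperiment::RangedSummarizedExperiment] with three assays:
#'
#' * `GT` -- integer alternate-allele dosage calls: 0 (hom-ref), 1 (het),
#'   2 (hom-alt), `NA` (missing, including half-calls),
#' * `refDepth`, `altDepth` -- per-allele read counts (`NA` when the source
#'   VCF carried no AD field).
#'
#' Row metadata columns `ref` and `alt` hold the single-base alleles;
#' multiallelic source records are split into one row per alternate allele,
#' so `(chrom, pos, alt)` is a unique key.
#'
#' @seealso [makeVariantTable()], [readVariantTable()], [emitVcf()]
#' @aliases VariantTable
#' @exportClass VariantTable
setClass("VariantTable", contains = "RangedSummarizedExperiment")

setValidity("VariantTable", function(object) {
    msg <- NULL
    need <- c("GT", "refDepth", "altDepth")
    if (!all(need %in% assayNames(object)))
        msg <- c(msg, sprintf("assays must include %s",
                              paste(need, collapse = ", ")))
    rr <- rowRanges(object)
    if (!all(c("ref", "alt") %in% colnames(mcols(rr))))
        msg <- c(msg, "rowRanges must carry 'ref' and 'alt' columns")
    if (length(rr)) {
        o <- order(as.integer(seqnames(rr)), start(rr))
        if (!identical(o, seq_along(rr)))
            msg <- c(msg, "sites must be sorted by (chrom, pos)")
        key <- paste(seqnames(rr), start(rr), mcols(rr)$alt)
        if (anyDuplicated(key))
            msg <- c(msg, "duplicate (chrom, pos, alt) keys")
        for (a in c("refDepth", "altDepth")) {
            v <- assay(object, a)
            if (any(v < 0, na.rm = TRUE))
                msg <- c(msg, sprintf("%s has negative counts", a))
        }
        gt <- assay(object, "GT")
        if (!all(gt %in% c(0L, 1L, 2L, NA)))
            msg <- c(msg, "GT values must be 0, 1, 2 or NA")
    }
    if (is.null(msg)) TRUE else msg
})

#' Simulated plant with known haplotype ancestry
#'
#' A diploid individual from the forward simulator. Each of the two
#' haplotypes is a mosaic of ancestry segments (recipient / donor / parent2)
#' tiling every chromosome, plus a set of "extra" sites physically carried on
#' that haplotype: tissue-culture point mutations and the T-DNA
#' presence pseudo-marker. The mosaics are the simulation truth against
#' which introgression calls are scored.
#'
#' @slot id single character plant identifier.
#' @slot genome a [GenomeInfoDb::Seqinfo] with chromosome lengths.
#' @slot haplotypes list of two haplotypes; each is a list with elements
#'   `mosaic` (data.frame `chrom`, `start`, `end`, `ancestry`; 1-based
#'   closed, tiling each chromosome exactly) and `extras` (data.frame
#'   `chrom`, `pos`, `class`).
#'
#' @seealso [makeFounders()], [selfPlant()], [haplotypeRanges()]
#' @exportClass SimPlant
setClass("SimPlant", representation(
    id = "character",
    genome = "Seqinfo",
    haplotypes = "list"
))

setValidity("SimPlant", function(object) {
    msg <- NULL
    if (length(object@id) != 1L) msg <- c(msg, "id must be a single string")
    if (length(object@haplotypes) != 2L)
        msg <- c(msg, "a plant has exactly two haplotypes")
    lens <- seqlengths(object@genome)
    for (h in object@haplotypes) {
        m <- h$mosaic
        if (!all(c("chrom", "start", "end", "ancestry") %in% names(m))) {
            msg <- c(msg, "mosaic lacks chrom/start/end/ancestry")
            next
        }
        for (chr in names(lens)) {
            seg <- m[m$chrom == chr, , drop = FALSE]
            if (!nrow(seg)) { msg <- c(msg, sprintf("no segments on %s", chr)); next }
            seg <- seg[order(seg$start), , drop = FALSE]
            ok <- seg$start[1] == 1L && seg$end[nrow(seg)] == lens[[chr]] &&
                all(seg$end >= seg$start) &&
                (nrow(seg) == 1L || all(seg$start[-1] == seg$end[-nrow(seg)] + 1L))
            if (!ok) msg <- c(msg, sprintf("segments do not tile %s", chr))
        }
    }
    if (is.null(msg)) TRUE else msg
})

#' Minimal gene model for coding-effect classification
#'
#' Exon structure and CDS extent of one gene, in genomic (1-based closed)
#' coordinates. Exons are stored in genomic order; [exonsInCodingOrder()]
#' returns them 5'->3' on the coding strand.
#'
#' @slot geneId single character identifier.
#' @slot chrom chromosome name.
#' @slot strand `"+"` or `"-"`.
#' @slot exons an [IRanges::IRanges] of non-overlapping exons, genomic order.
#' @slot cdsStart,cdsEnd genomic bounds of the coding sequence; the CDS is
#'   the intersection of the exons with `[cdsStart, cdsEnd]` and its total
#'   length must be divisible by 3.
#'
#' @seealso [readGeneModels()], [classifyEffect()]
#' @exportClass GeneModel
setClass("GeneModel", representation(
    geneId = "character",
    chrom = "character",
    strand = "character",
    exons = "IRanges",
    cdsStart = "integer",
    cdsEnd = "integer"
))

setValidity("GeneModel", function(object) {
    msg <- NULL
    if (!object@strand %in% c("+", "-"))
        msg <- c(msg, "strand must be '+' or '-'")
    ex <- object@exons
    if (length(ex)) {
        if (is.unsorted(IRanges::start(ex)))
            msg <- c(msg, "exons must be in genomic order")
        if (length(ex) > 1L &&
            any(IRanges::start(ex)[-1] <= IRanges::end(ex)[-length(ex)]))
            msg <- c(msg, "exons overlap")
    }
    cdsLen <- sum(IRanges::width(IRanges::restrict(ex, object@cdsStart,
                                                   object@cdsEnd)))
    if (cdsLen %% 3L != 0L)
        msg <- c(msg, sprintf("gene %s: CDS length %d not divisible by 3",
                              object@geneId, cdsLen))
    if (is.null(msg)) TRUE else msg
})
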