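#' Read a VCF into a VariantTable
#'
#' Parses a VCF 4.x file (via `VariantAnnotation::readVcf`) into the
#' pipeline's [VariantTable]. Multiallelic records are split into one
#' biallelic row per alternate allele, with the genotype re-expressed as
#' the dosage of that allele; half-calls (e.g. `./1`) become missing;
#' records without an AD field get `NA` depths. Indels (non single-base
#' REF/ALT) are excluded with a message, since all downstream SNP-density
#' and SNP-index statistics are SNP-based.
#'
#' @param path VCF file path.
#' @param samples optional character vector restricting the sample columns.
#' @param keepIndels keep length-changing records instead of dropping them
#'   (they are flagged in a `isIndel` row column); default `FALSE`.
#' @return a [VariantTable].
#' @export
readVariantTable <- function(path, samples = NULL, keepIndels = FALSE) {
    if (!file.exists(path)) stop("no such file: ", path)
    vcf <- VariantAnnotation::readVcf(path)
    if (!"GT" %in% rownames(VariantAnnotation::geno(
            VariantAnnotation::header(vcf))))
        stop("VCF has no GT FORMAT field")
    if (!is.null(samples)) {
        bad <- setdiff(samples, colnames(vcf))
        if (length(bad)) stop("samples not in VCF: ",
                              paste(bad, collapse = ", "))
        vcf <- vcf[, samples]
    }
    rr <- SummarizedExperiment::rowRanges(vcf)
    ref <- as.character(VariantAnnotation::ref(vcf))
    altList <- VariantAnnotation::alt(vcf)
    nAlt <- lengths(altList)
    gtStr <- VariantAnnotation::geno(vcf)$GT
    adRaw <- if ("AD" %in% names(VariantAnnotation::geno(vcf)))
        VariantAnnotation::geno(vcf)$AD else NULL
    nS <- ncol(vcf)
    # expand to one row per (record, alt allele)
    recIdx <- rep(seq_along(rr), nAlt)
    altIdx <- unlist(lapply(nAlt, seq_len), use.names = FALSE)
    alt <- as.character(unlist(altList, use.names = FALSE))
    nOut <- length(recIdx)
    gt <- matrix(NA_integer_, nOut, nS)
    rd <- matrix(NA_integer_, nOut, nS)
    ad <- matrix(NA_integer_, nOut, nS)
    if (nS) colnames(gt) <- colnames(rd) <- colnames(ad) <- colnames(vcf)
    if (nOut && nS) {
        # dosage of allele k from the GT string of the source record
        alleles1 <- sub("[/|].*", "", gtStr)
        alleles2 <- sub(".*[/|]", "", gtStr)
        half <- matrix(alleles1 == "." | alleles2 == "." | gtStr == ".",
                       nrow(gtStr))
        a1 <- suppressWarnings(matrix(as.integer(alleles1), nrow(gtStr)))
        a2 <- suppressWarnings(matrix(as.integer(alleles2), nrow(gtStr)))
        for (j in seq_len(nS)) {
            k <- altIdx
            i <- recIdx
            d <- (a1[i, j] == k) + (a2[i, j] == k)
            d[half[i, j]] <- NA_integer_
            gt[, j] <- as.integer(d)
        }
        if (!is.null(adRaw)) {
            asInt <- function(x) suppressWarnings(as.integer(x))
            for (j in seq_len(nS)) {
                if (length(dim(adRaw)) == 3L) {
                    rd[, j] <- asInt(adRaw[recIdx, j, 1L])
                    ad[, j] <- asInt(adRaw[cbind(recIdx, j, altIdx + 1L)])
                } else {
                    adj <- adRaw[, j]   # list column: ragged alt counts
                    rd[, j] <- vapply(recIdx, function(i)
                        asInt(adj[[i]][1L]), 0L)
                    ad[, j] <- vapply(seq_len(nOut), function(r)
                        asInt(adj[[recIdx[r]]][altIdx[r] + 1L]), 0L)
                }
            }
        }
    }
    out <- GRanges(seqnames(rr)[recIdx],
                   IRanges(start(rr)[recIdx], width = nchar(ref)[recIdx]),
                   seqinfo = seqinfo(vcf))
    mcols(out)$ref <- ref[recIdx]
    mcols(out)$alt <- alt
    isIndel <- nchar(mcols(out)$ref) != 1L | nchar(mcols(out)$alt) != 1L
    if (any(isIndel) && !keepIndels) {
        message(sum(isIndel), " indel record(s) excluded")
        keep <- !isIndel
        out <- out[keep]
        gt <- gt[keep, , drop = FALSE]
        rd <- rd[keep, , drop = FALSE]
        ad <- ad[keep, , drop = FALSE]
        isIndel <- isIndel[keep]
    }
    if (keepIndels) mcols(out)$isIndel <- isIndel
    o <- order(as.integer(seqnames(out)), start(out))
    makeVariantTable(out[o], gt[o, , drop = FALSE], rd[o, , drop = FALSE],
                     ad[o, , drop = FALSE])
}

#' BED export / import of region sets
#'
#' Regions are 1-based closed inside the package (the VCF convention used
#' for every coordinate in the analyses) and 0-based half-open on disk (BED
#' convention); `rtracklayer` performs the lossless conversion at the file
#' boundary. A metadata column `name` (or the column named by `label`)
#' becomes the BED name field.
#'
#' @param regions a [GenomicRanges::GRanges].
#' @param path file path.
#' @param label optional metadata column to store in the BED name field.
#' @return `writeBed`: `path`, invisibly. `readBed`: a `GRanges` with a
#'   `name` column when present.
#' @export
writeBed <- function(regions, path, label = "name") {
    stopifnot(is(regions, "GRanges"))
    if (length(regions) && any(start(regions) < 1L))
        stop("regions with coordinates below 1")
    gr <- granges(regions)
    if (label %in% colnames(mcols(regions)))
        mcols(gr)$name <- as.character(mcols(regions)[[label]])
    rtracklayer::export.bed(gr, path)
    invisible(path)
}

#' @rdname writeBed
#' @export
readBed <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    if (file.size(path) == 0L) return(GRanges())
    rtracklayer::import(path, format = "bed")
}

#' Read gene models from a GFF-like table
#'
#' Accepts a GFF3-style tab table with `gene` rows (attribute `ID`) and
#' `exon` / `CDS` rows pointing at their gene through `Parent`. The CDS
#' extent is taken as the span of the CDS rows; a gene whose summed CDS
#' length is not divisible by 3 is rejected by name.
#'
#' @param path GFF file path.
#' @return a named list of [GeneModel] objects.
#' @export
readGeneModels <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    gff <- tryCatch(rtracklayer::import(path, format = "gff3"),
                    error = function(e) stop("malformed GFF: ",
                                             conditionMessage(e)))
    if (!length(gff)) return(list())
    type <- as.character(gff$type)
    genes <- gff[type == "gene"]
    out <- list()
    for (i in seq_along(genes)) {
        gid <- genes$ID[i]
        par <- vapply(gff$Parent, function(p)
            length(p) > 0L && gid %in% p, logical(1))
        exons <- gff[type == "exon" & par]
        cds <- gff[type == "CDS" & par]
        if (!length(exons)) exons <- cds
        if (!length(exons)) next
        ex <- sort(IRanges(start(exons), end(exons)))
        model <- new("GeneModel", geneId = gid,
                     chrom = as.character(seqnames(genes)[i]),
                     strand = as.character(BiocGenerics::strand(genes)[i]),
                     exons = ex,
                     cdsStart = if (length(cds)) min(start(cds)) else 1L,
                     cdsEnd = if (length(cds)) max(end(cds)) else 0L)
        out[[gid]] <- model
    }
    out
}

#' Exons in coding (5' to 3') order
#'
#' @param model a [GeneModel].
#' @return an [IRanges::IRanges]; reversed genomic order for minus-strand
#'   genes.
#' @export
exonsInCodingOrder <- function(model) {
    stopifnot(is(model, "GeneModel"))
    if (model@strand == "+") model@exons else rev(model@exons)
}

#' Write / read a phylogenetic tree in newick format
#'
#' Thin validated wrappers over `ape`: duplicate leaf labels and negative
#' branch lengths are rejected before writing.
#'
#' @param tree an [ape::phylo] tree with labeled leaves.
#' @param path file path.
#' @return `writeNewick`: `path` invisibly; `readNewick`: a `phylo`.
#' @export
writeNewick <- function(tree, path) {
    stopifnot(inherits(tree, "phylo"))
    if (anyDuplicated(tree$tip.label))
        stop("duplicate leaf labels: ",
             paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
                   collapse = ", "))
    if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
        stop("negative branch lengths")
    ape::write.tree(tree, file = path)
    invisible(path)
}

#' @rdname writeNewick
#' @export
readNewick <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    ape::read.tree(path)
}
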