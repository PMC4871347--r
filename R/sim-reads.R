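# alternate-allele count (0/1) carried by one haplotype at each panel site
.haplotypeAllele <- function(hap, chromV, posV, classV, keyV = NULL) {
    allele <- logical(length(posV))
    m <- hap$mosaic
    for (chr in unique(chromV)) {
        sel <- chromV == chr
        seg <- m[m$chrom == chr, , drop = FALSE]
        seg <- seg[order(seg$start), , drop = FALSE]
        anc <- seg$ancestry[findInterval(posV[sel], seg$start)]
        allele[sel] <- (classV[sel] == "donor-diagnostic" & anc == "donor") |
            (classV[sel] == "parent2-diagnostic" & anc == "parent2")
    }
    x <- hap$extras
    if (nrow(x)) {
        if (is.null(keyV)) keyV <- .siteKey(chromV, posV)
        hit <- match(.siteKey(x$chrom, x$pos), keyV)
        allele[hit[!is.na(hit)]] <- TRUE
    }
    as.integer(allele)
}

# true alt-allele dosage (0/1/2) of one plant at every panel site
.plantDosage <- function(plant, panel, panelCols = NULL) {
    pc <- panelCols %||% .panelCols(panel)
    .haplotypeAllele(plant@haplotypes[[1]], pc$chrom, pc$pos, pc$class,
                     pc$key) +
        .haplotypeAllele(plant@haplotypes[[2]], pc$chrom, pc$pos, pc$class,
                         pc$key)
}

.panelCols <- function(panel) {
    chrom <- as.character(seqnames(panel))
    pos <- start(panel)
    list(chrom = chrom, pos = pos, class = mcols(panel)$class,
         key = .siteKey(chrom, pos))
}

#' True allele dosages of plants or pools at every marker
#'
#' For a single plant the dosage at a site is the number of haplotypes
#' carrying the alternate allele (0, 1 or 2). For a pool (a list of plants)
#' it is the mean dosage of the members --- equivalent, under binomial read
#' sampling, to mixing the members' DNA equimolarly.
#'
#' @param plants a named list of [SimPlant]s and/or pools (unnamed lists of
#'   `SimPlant`s); names become column names.
#' @param panel the marker panel ([GenomicRanges::GRanges]).
#' @return numeric matrix, sites x samples, values in `[0, 2]`.
#' @export
dosageMatrix <- function(plants, panel) {
    if (is(plants, "SimPlant")) plants <- list(plants)
    pc <- .panelCols(panel)
    cols <- lapply(plants, function(p) {
        if (is(p, "SimPlant")) return(.plantDosage(p, panel, pc))
        if (!length(p)) stop("empty pool")
        m <- vapply(p, .plantDosage, numeric(length(panel)), panel, pc)
        if (is.null(dim(m))) m <- matrix(m, nrow = length(panel))
        rowMeans(m)
    })
    m <- do.call(cbind, cols)
    colnames(m) <- names(plants)
    m
}

#' Sample sequencing read counts at every marker
#'
#' Per site and sample, depth is Poisson(`depthMean`) and the alternate
#' read count is Binomial(depth, p') where p = dosage / 2 and
#' p' = p(1 - e) + (1 - p)e accounts for the per-base error rate `e`.
#'
#' @param dosages numeric matrix from [dosageMatrix()] (sites x samples).
#' @param depthMean mean sequencing depth (default 15, the study's
#'   per-sample scale).
#' @param errorRate per-base error rate `e` in `[0, 0.5)` (default 0.005).
#' @return list of two integer matrices, `ref` and `alt`.
#' @export
sampleReads <- function(dosages, depthMean = 15, errorRate = 0.005) {
    .assertScalarNum(depthMean, "depthMean", lo = 1e-12)
    if (errorRate < 0 || errorRate >= 0.5)
        stop("'errorRate' must be in [0, 0.5)")
    dosages <- as.matrix(dosages)
    n <- length(dosages)
    depth <- matrix(stats::rpois(n, depthMean), nrow(dosages))
    p <- dosages / 2
    pErr <- p * (1 - errorRate) + (1 - p) * errorRate
    alt <- matrix(stats::rbinom(n, depth, pErr), nrow(dosages))
    dimnames(alt) <- dimnames(dosages)
    ref <- depth - alt
    dimnames(ref) <- dimnames(dosages)
    list(ref = ref, alt = alt)
}

#' Call genotypes from allele counts
#'
#' Threshold-based diploid calls: missing below `minDepth` total reads;
#' hom-alt when the alternate fraction is at least `homFrac`; hom-ref when
#' it is at most `1 - homFrac`; heterozygous otherwise.
#'
#' @param ref,alt integer matrices (or vectors) of allele counts.
#' @param minDepth minimum total depth for a call (default 4).
#' @param homFrac homozygosity threshold on the allele fraction
#'   (default 0.8).
#' @return integer matrix of calls: 0 (hom-ref), 1 (het), 2 (hom-alt),
#'   `NA` (missing).
#' @examples
#' genotypeFromCounts(c(10, 5, 1, 0), c(0, 5, 2, 12))
#' @export
genotypeFromCounts <- function(ref, alt, minDepth = 4L, homFrac = 0.8) {
    if (any(ref < 0, na.rm = TRUE) || any(alt < 0, na.rm = TRUE))
        stop("counts must be >= 0")
    tot <- ref + alt
    frac <- ifelse(tot > 0, alt / tot, NA_real_)
    eps <- sqrt(.Machine$double.eps)   # boundary counts as homozygous
    gt <- ifelse(tot < minDepth, NA_integer_,
          ifelse(frac >= homFrac - eps, 2L,
          ifelse(frac <= 1 - homFrac + eps, 0L, 1L)))
    if (is.matrix(ref)) {
        gt <- matrix(as.integer(gt), nrow(ref), dimnames = dimnames(ref))
    } else gt <- as.integer(gt)
    gt
}

#' Assemble a VariantTable from panel, calls and counts
#'
#' @param panel marker [GenomicRanges::GRanges] with `ref`, `alt` columns.
#' @param gt integer call matrix (sites x samples).
#' @param refDepth,altDepth count matrices matching `gt`.
#' @return a [VariantTable].
#' @export
makeVariantTable <- function(panel, gt, refDepth = NULL, altDepth = NULL) {
    gt <- as.matrix(gt)
    if (is.null(refDepth))
        refDepth <- matrix(NA_integer_, nrow(gt), ncol(gt),
                           dimnames = dimnames(gt))
    if (is.null(altDepth))
        altDepth <- matrix(NA_integer_, nrow(gt), ncol(gt),
                           dimnames = dimnames(gt))
    se <- SummarizedExperiment(
        assays = SimpleList(GT = gt, refDepth = as.matrix(refDepth),
                            altDepth = as.matrix(altDepth)),
        rowRanges = panel)
    new("VariantTable", se)
}

#' Write a VariantTable (or simulated calls) as VCF 4.2
#'
#' Emits an uncompressed VCF with per-sample `GT`, `AD` and `DP` fields and
#' contig header lines from the genome. The writer is deliberately plain
#' text with no timestamp so that a fixed-seed simulation reproduces a
#' byte-identical file; [readVariantTable()] (backed by an independent VCF
#' parser) round-trips it at the record level.
#'
#' @param vt a [VariantTable].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
emitVcf <- function(vt, path) {
    stopifnot(is(vt, "VariantTable"))
    rr <- rowRanges(vt)
    gt <- assay(vt, "GT")
    rd <- assay(vt, "refDepth")
    ad <- assay(vt, "altDepth")
    lens <- seqlengths(seqinfo(rr))
    con <- file(path, "wb")  # binary mode: LF line endings everywhere
    on.exit(close(con))
    wl <- function(x) writeLines(x, con, sep = "\n")
    wl("##fileformat=VCFv4.2")
    wl("##source=introTrace")
    if (length(lens) && !any(is.na(lens)))
        wl(sprintf("##contig=<ID=%s,length=%d>", names(lens), lens))
    wl('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
    wl(paste0('##FORMAT=<ID=AD,Number=R,Type=Integer,',
              'Description="Allelic depths for the ref and alt alleles">'))
    wl('##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">')
    hdr <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
    if (ncol(vt)) hdr <- c(hdr, "FORMAT", colnames(vt))
    wl(paste(hdr, collapse = "\t"))
    if (nrow(vt)) {
        lines <- paste(as.character(seqnames(rr)), start(rr), ".",
                       mcols(rr)$ref, mcols(rr)$alt, ".", "PASS", ".",
                       sep = "\t")
        if (ncol(vt)) lines <- paste(lines, "GT:AD:DP", sep = "\t")
        if (ncol(vt)) {
            gtStr <- matrix(c("0/0", "0/1", "1/1")[gt + 1L], nrow(gt))
            gtStr[is.na(gt)] <- "./."
            adStr <- matrix(paste0(ifelse(is.na(rd), ".", rd), ",",
                                   ifelse(is.na(ad), ".", ad)), nrow(gt))
            dp <- rd + ad
            dpStr <- matrix(ifelse(is.na(dp), ".", dp), nrow(gt))
            fields <- matrix(paste(gtStr, adStr, dpStr, sep = ":"),
                             nrow(gt))
            lines <- paste(lines, apply(fields, 1L, paste, collapse = "\t"),
                           sep = "\t")
        }
        wl(lines)
    }
    invisible(path)
}
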