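suppressPackageStartupMessages({
    library(GenomicRanges)
    library(S4Vectors)
    library(SummarizedExperiment)
    library(Biostrings)
})

# VariantTable from explicit vectors: gt is a sites x samples matrix
makeVt <- function(chrom, pos, gt, lens, ref = NULL, alt = NULL,
                   refDepth = NULL, altDepth = NULL) {
    gt <- as.matrix(gt)
    chrom <- rep(chrom, length.out = length(pos))
    o <- order(match(chrom, names(lens)), pos)
    si <- GenomeInfoDb::Seqinfo(names(lens), as.integer(lens),
                                genome = "sim")
    gr <- GRanges(chrom[o], IRanges(pos[o], width = 1L), seqinfo = si)
    mcols(gr)$ref <- if (is.null(ref)) rep("A", length(gr)) else ref[o]
    mcols(gr)$alt <- if (is.null(alt)) rep("T", length(gr)) else alt[o]
    makeVariantTable(gr, gt[o, , drop = FALSE],
                     if (is.null(refDepth)) NULL else
                         as.matrix(refDepth)[o, , drop = FALSE],
                     if (is.null(altDepth)) NULL else
                         as.matrix(altDepth)[o, , drop = FALSE])
}

jaccard <- function(a, b) {
    i <- sum(width(GenomicRanges::intersect(a, b)))
    u <- sum(width(GenomicRanges::union(a, b)))
    if (u == 0) 1 else i / u
}

# genotype calls for a set of simulated plants / pools, default thresholds
simCalls <- function(units, panel, depth = 15, errorRate = 0.005) {
    dos <- dosageMatrix(units, panel)
    reads <- sampleReads(dos, depth, errorRate)
    gt <- genotypeFromCounts(reads$ref, reads$alt)
    makeVariantTable(panel, gt, reads$ref, reads$alt)
}

# random toy gene on a random sequence, for effect-classifier checks
randomToyGene <- function(chromLen = 600L, nExons = 2L, strand = "+") {
    sq <- paste(sample(c("A", "C", "G", "T"), chromLen, TRUE),
                collapse = "")
    # exon widths multiples adjusted so total CDS %% 3 == 0
    repeat {
        starts <- sort(sample(seq(50L, chromLen - 80L, by = 10L), nExons))
        widths <- sample(seq(15L, 45L, by = 3L), nExons, replace = TRUE)
        ends <- starts + widths - 1L
        if (all(diff(starts) > widths[-nExons] + 10L) &&
            max(ends) < chromLen - 10L) break
    }
    total <- sum(ends - starts + 1L)
    trim <- total %% 3L     # trim the last exon to a codon multiple
    ends[nExons] <- ends[nExons] - trim
    model <- new("GeneModel", geneId = "toy", chrom = "chrT",
                 strand = strand,
                 exons = IRanges(starts, ends),
                 cdsStart = min(starts), cdsEnd = max(ends))
    list(model = model,
         refSeqs = Biostrings::DNAStringSet(c(chrT = sq)),
         seq = sq,
         cdsPos = unlist(Map(base::seq, starts, ends)))
}

# oracle: effect by translating the whole CDS, ref vs alt
oracleEffect <- function(toy, pos, altBase) {
    m <- toy$model
    sq <- toy$seq
    mut <- sq
    substr(mut, pos, pos) <- altBase
    getCds <- function(s) {
        pieces <- vapply(seq_along(m@exons), function(i)
            substr(s, IRanges::start(m@exons)[i], IRanges::end(m@exons)[i]),
            "")
        cds <- paste(pieces, collapse = "")
        if (m@strand == "-")
            cds <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
        cds
    }
    aaR <- as.character(Biostrings::translate(Biostrings::DNAString(getCds(sq)),
                                              no.init.codon = TRUE))
    aaA <- as.character(Biostrings::translate(Biostrings::DNAString(getCds(mut)),
                                              no.init.codon = TRUE))
    if (aaR == aaA) return("synonymous")
    d <- which(strsplit(aaR, "")[[1]] != strsplit(aaA, "")[[1]])[1]
    if (substr(aaA, d, d) == "*") "stop_gained" else "nonsynonymous"
}
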