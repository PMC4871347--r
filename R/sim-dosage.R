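# dosage of a plant at a handful of sites, without scanning a whole panel
.dosageAtSites <- function(plant, chrom, pos, class) {
    n <- length(pos)
    total <- integer(n)
    for (h in 1:2) {
        hap <- plant@haplotypes[[h]]
        m <- hap$mosaic
        x <- hap$extras
        for (k in seq_len(n)) {
            seg <- m[m$chrom == chrom[k], , drop = FALSE]
            seg <- seg[order(seg$start), , drop = FALSE]
            anc <- seg$ancestry[findInterval(pos[k], seg$start)]
            hit <- (class[k] == "donor-diagnostic" && anc == "donor") ||
                (class[k] == "parent2-diagnostic" && anc == "parent2") ||
                (nrow(x) > 0L &&
                     any(x$chrom == chrom[k] & x$pos == pos[k]))
            total[k] <- total[k] + as.integer(hit)
        }
    }
    total
}
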