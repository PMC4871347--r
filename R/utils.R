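# Internal helpers shared across modules.

.assertScalarNum <- function(x, name, lo = -Inf, hi = Inf) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
        stop(sprintf("'%s' must be a single number in [%s, %s]",
                     name, format(lo), format(hi)), call. = FALSE)
    invisible(x)
}

.assertSample <- function(vt, sample) {
    bad <- setdiff(sample, colnames(vt))
    if (length(bad))
        stop("sample(s) not in table: ", paste(bad, collapse = ", "),
             call. = FALSE)
    invisible(sample)
}

# chromosome lengths as a named numeric vector
.chromLengths <- function(genome) {
    lens <- seqlengths(genome)
    if (any(is.na(lens))) stop("genome has chromosomes of unknown length")
    lens
}

# order (chrom by seqlevels, then pos)
.genomeOrder <- function(chrom, pos, levels) {
    order(match(chrom, levels), pos)
}

# paste keys used to match sites
.siteKey <- function(chrom, pos) paste(chrom, pos, sep = ":")

.DNA <- c("A", "C", "G", "T")
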