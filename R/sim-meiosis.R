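#' Simulate one meiosis
#'
#' Produces a gamete haplotype from a diploid plant. Per chromosome the
#' crossover count is Poisson(`lambda`), breakpoint positions are uniform,
#' and the gamete alternates between the two parental copies starting from a
#' fair-coin choice; there is no crossover interference. Tissue-culture
#' mutations and the T-DNA pseudo-marker travel with the physical haplotype
#' segment that carries them.
#'
#' @param plant a [SimPlant].
#' @param lambda mean crossovers per chromosome per meiosis (default 1.25,
#'   roughly the rice genetic map length divided over 12 chromosomes).
#' @return a haplotype (list with `mosaic` and `extras` data.frames) suitable
#'   as one of the two haplotypes of an offspring; see [selfPlant()].
#' @export
meiosis <- function(plant, lambda = 1.25) {
    stopifnot(is(plant, "SimPlant"))
    .assertScalarNum(lambda, "lambda", 0)
    lens <- .chromLengths(plant@genome)
    # flat vectors with per-chromosome index lists: fast interval clipping
    hapData <- lapply(plant@haplotypes, function(h) {
        m <- h$mosaic
        x <- h$extras
        list(start = m$start, end = m$end, anc = m$ancestry,
             idx = split(seq_len(nrow(m)), m$chrom),
             xpos = x$pos, xclass = x$class,
             xidx = split(seq_len(nrow(x)), x$chrom))
    })
    oChrom <- list(); oStart <- list(); oEnd <- list(); oAnc <- list()
    eChrom <- list(); ePos <- list(); eClass <- list()
    n <- 0L
    for (i in seq_along(lens)) {
        chr <- names(lens)[i]
        L <- lens[[i]]
        nco <- stats::rpois(1L, lambda)
        bp <- if (nco > 0L)
            sort(unique(as.integer(ceiling(stats::runif(nco) * (L - 1L)))))
        else integer()
        bounds <- c(0L, bp, L)
        nIv <- length(bounds) - 1L
        first <- sample.int(2L, 1L)
        src <- rep_len(if (first == 1L) c(1L, 2L) else c(2L, 1L), nIv)
        for (k in seq_len(nIv)) {
            s <- bounds[k] + 1L
            e <- bounds[k + 1L]
            hd <- hapData[[src[k]]]
            ii <- hd$idx[[chr]]
            sel <- ii[hd$end[ii] >= s & hd$start[ii] <= e]
            n <- n + 1L
            oChrom[[n]] <- rep(chr, length(sel))
            oStart[[n]] <- pmax(hd$start[sel], s)
            oEnd[[n]] <- pmin(hd$end[sel], e)
            oAnc[[n]] <- hd$anc[sel]
            xi <- hd$xidx[[chr]]
            xs <- xi[hd$xpos[xi] >= s & hd$xpos[xi] <= e]
            eChrom[[n]] <- rep(chr, length(xs))
            ePos[[n]] <- hd$xpos[xs]
            eClass[[n]] <- hd$xclass[xs]
        }
    }
    chrom <- unlist(oChrom); st <- unlist(oStart)
    en <- unlist(oEnd); anc <- unlist(oAnc)
    # merge adjacent same-ancestry segments (vectorized run detection)
    m <- length(chrom)
    b <- if (m > 1L) c(TRUE, !(chrom[-1L] == chrom[-m] &
                                   anc[-1L] == anc[-m] &
                                   st[-1L] == en[-m] + 1L)) else TRUE
    ends <- c(which(b)[-1L] - 1L, m)
    mosaic <- data.frame(chrom = chrom[b], start = st[b], end = en[ends],
                         ancestry = anc[b], stringsAsFactors = FALSE)
    extras <- data.frame(chrom = unlist(eChrom),
                         pos = as.integer(unlist(ePos)),
                         class = as.character(unlist(eClass)),
                         stringsAsFactors = FALSE)
    list(mosaic = mosaic, extras = extras)
}

.offspring <- function(id, g1, g2, genome) {
    new("SimPlant", id = id, genome = genome, haplotypes = list(g1, g2))
}

#' Self-pollinate or cross simulated plants
#'
#' An offspring is formed from two independent meiosis products --- both from
#' the same plant (`selfPlant`) or one from each parent (`crossPlants`).
#'
#' @param plant,p1,p2 parent [SimPlant]s.
#' @param lambda mean crossovers per chromosome per meiosis.
#' @param id identifier for the offspring.
#' @return a [SimPlant].
#' @export
selfPlant <- function(plant, lambda = 1.25, id = paste0(plant@id, "_self")) {
    .offspring(id, meiosis(plant, lambda), meiosis(plant, lambda),
               plant@genome)
}

#' @rdname selfPlant
#' @export
crossPlants <- function(p1, p2, lambda = 1.25,
                        id = paste0(p1@id, "x", p2@id)) {
    if (!identical(seqlengths(p1@genome), seqlengths(p2@genome)))
        stop("parents have different genomes")
    .offspring(id, meiosis(p1, lambda), meiosis(p2, lambda), p1@genome)
}
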