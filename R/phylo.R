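#' Allele-sharing distance matrix
#'
#' Pairwise distance between samples from genotype dosages: per shared
#' genotyped site the distance is |dosage_i - dosage_j| / 2, and the pair
#' distance is the mean over those sites (within `region` when given,
#' whole genome otherwise). Missing genotypes are pairwise-deleted; a pair
#' sharing fewer than `minSites` genotyped sites is an error naming the
#' pair.
#'
#' @param vt a [VariantTable].
#' @param samples at least two sample names.
#' @param region optional [GenomicRanges::GRanges] restriction.
#' @param minSites minimum shared genotyped sites per pair (default 100).
#' @return symmetric numeric matrix in `[0, 1]` with zero diagonal;
#'   attribute `nSites` holds the per-pair informative-site counts.
#' @export
alleleSharingDistance <- function(vt, samples, region = NULL,
                                  minSites = 100L) {
    if (length(samples) < 2L) stop("need at least two samples")
    .assertSample(vt, samples)
    gt <- assay(vt, "GT")[, samples, drop = FALSE]
    if (!is.null(region))
        gt <- gt[overlapsAny(rowRanges(vt), region), , drop = FALSE]
    n <- length(samples)
    d <- matrix(0, n, n, dimnames = list(samples, samples))
    ns <- matrix(0L, n, n, dimnames = list(samples, samples))
    bad <- character()
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        ok <- !is.na(gt[, i]) & !is.na(gt[, j])
        ns[i, j] <- ns[j, i] <- sum(ok)
        if (sum(ok) < minSites) {
            bad <- c(bad, paste(samples[i], samples[j], sep = "~"))
            next
        }
        d[i, j] <- d[j, i] <- mean(abs(gt[ok, i] - gt[ok, j])) / 2
    }
    if (length(bad))
        stop("pair(s) below minSites shared genotyped sites: ",
             paste(bad, collapse = ", "))
    attr(d, "nSites") <- ns
    d
}

#' Neighbor-joining tree
#'
#' Standard neighbor-joining agglomeration (Saitou-Nei with the usual
#' Q-criterion and Studier-Keppler updates) implemented directly, used in
#' place of the original study's SNPhylo pipeline: the claim under test is
#' clustering, which the allele-sharing distance supports at this scale.
#' Negative branch lengths are clamped to zero and the clamped deficit
#' reported in the `clamped` attribute.
#'
#' @param dm complete symmetric distance matrix with >= 3 labeled rows.
#' @return an unrooted [ape::phylo] tree with branch lengths.
#' @export
njTree <- function(dm) {
    dm <- as.matrix(dm)
    if (nrow(dm) < 3L) stop("need at least 3 samples")
    if (any(is.na(dm))) stop("incomplete distance matrix")
    labs <- rownames(dm)
    if (is.null(labs)) stop("distance matrix must have row names")
    clamped <- 0
    fix <- function(x) {
        clamped <<- clamped + sum(pmax(-x, 0))
        pmax(x, 0)
    }
    sub <- labs                      # newick fragment per active node
    D <- dm
    while (length(sub) > 3L) {
        n <- length(sub)
        r <- rowSums(D)
        Q <- (n - 2) * D - outer(r, r, "+")
        diag(Q) <- Inf
        ij <- which(Q == min(Q), arr.ind = TRUE)[1L, ]
        i <- min(ij); j <- max(ij)
        li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
        lj <- D[i, j] - li
        li <- fix(li); lj <- fix(lj)
        merged <- sprintf("(%s:%.10g,%s:%.10g)", sub[i], li, sub[j], lj)
        dNew <- (D[i, ] + D[j, ] - D[i, j]) / 2
        keep <- setdiff(seq_len(n), c(i, j))
        D <- rbind(cbind(D[keep, keep, drop = FALSE], dNew[keep]),
                   c(dNew[keep], 0))
        sub <- c(sub[keep], merged)
    }
    l1 <- fix((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
    l2 <- fix((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
    l3 <- fix((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
    nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                   sub[1], l1, sub[2], l2, sub[3], l3)
    tree <- ape::read.tree(text = nwk)
    attr(tree, "clamped") <- clamped
    tree
}

#' Assign focal samples to the donor or recipient group on a tree
#'
#' The tree is midpoint-rooted; each focal sample is assigned to the group
#' (donor or recipient) whose members dominate its smallest enclosing
#' clade that contains any group member, walking rootward until the tie is
#' broken. This formalizes reading "clusters with" off the published
#' trees.
#'
#' @param tree an [ape::phylo].
#' @param focalSamples leaf labels to assign.
#' @param donorGroup,recipientGroup leaf labels of the reference groups.
#' @return named character vector, `"donor"` or `"recipient"` per focal
#'   sample.
#' @export
placementCheck <- function(tree, focalSamples, donorGroup, recipientGroup) {
    miss <- setdiff(c(focalSamples, donorGroup, recipientGroup),
                    tree$tip.label)
    if (length(miss))
        stop("not leaves of the tree: ", paste(miss, collapse = ", "))
    rooted <- phangorn::midpoint(tree)
    ntip <- length(rooted$tip.label)
    parent <- integer(max(rooted$edge))
    parent[rooted$edge[, 2L]] <- rooted$edge[, 1L]
    tipsUnder <- function(node) {
        if (node <= ntip) return(rooted$tip.label[node])
        kids <- rooted$edge[rooted$edge[, 1L] == node, 2L]
        unlist(lapply(kids, tipsUnder))
    }
    vapply(focalSamples, function(f) {
        node <- which(rooted$tip.label == f)
        repeat {
            node <- parent[node]
            if (node == 0L) return(NA_character_)
            tips <- setdiff(tipsUnder(node), f)
            nd <- sum(tips %in% donorGroup)
            nr <- sum(tips %in% recipientGroup)
            if (nd > nr) return("donor")
            if (nr > nd) return("recipient")
            if (node == ntip + 1L) return(NA_character_)  # root tie
        }
    }, "")
}
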