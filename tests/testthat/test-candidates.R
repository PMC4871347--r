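test_that("co-segregation filter equals the exhaustive-enumeration oracle", {
    # every genotype pattern over 2 affected + 2 unaffected samples,
    # including missing, becomes one marker; the filter must agree with a
    # direct evaluation of the predicate at every marker
    states <- c(0L, 1L, 2L, NA)
    grid <- expand.grid(a1 = states, a2 = states, u1 = states,
                        u2 = states)
    gt <- as.matrix(grid)
    vt <- makeVt("chr1", seq_len(nrow(gt)) * 10, gt,
                 c(chr1 = 1e5))
    for (maxMissing in c(0L, 1L, 4L)) {
        got <- cosegregatingSnps(vt, c("a1", "a2"), c("u1", "u2"),
                                 maxMissing = maxMissing)
        oracle <- vapply(seq_len(nrow(gt)), function(i) {
            x <- gt[i, ]
            a <- x[1:2]; u <- x[3:4]
            nMiss <- sum(is.na(x))
            if (nMiss > maxMissing) return(FALSE)
            if (sum(!is.na(a)) == 0) return(FALSE)
            all(a[!is.na(a)] == 2L) && !any(u[!is.na(u)] == 2L)
        }, TRUE)
        # rows were sorted by position = 10 * original index
        expect_setequal(got$pos, which(oracle) * 10)
    }
    expect_error(cosegregatingSnps(vt, c("a1", "u1"), c("u1", "u2")),
                 "both groups")
    expect_error(cosegregatingSnps(vt, character(0), "u1"), "non-empty")
})

test_that("region filter restricts the candidate scan", {
    gt <- cbind(a1 = c(2L, 2L), a2 = c(2L, 2L), u1 = c(0L, 0L))
    vt <- makeVt("chr1", c(100, 5000), gt, c(chr1 = 1e4))
    reg <- GRanges("chr1", IRanges(1, 1000))
    got <- cosegregatingSnps(vt, c("a1", "a2"), "u1", region = reg)
    expect_equal(got$pos, 100)
})

test_that("effect classifier matches known codon changes", {
    # plus-strand gene: exon 11-40 (CDS start), intron 41-60, exon 61-90
    sq <- paste0(strrep("A", 10),
                 "ATGTACGGGCTTAGCGATCGATCGATCGTA",   # exon 1 (30 bp)
                 "GTTTTTTTTTTTTTTTTTAG",             # intron (20 bp)
                 "CTTAGCGATCGATCGATCGATCGATCGCCC",   # exon 2 (30 bp)
                 strrep("A", 60))
    refSeqs <- Biostrings::DNAStringSet(c(chrT = sq))
    model <- new("GeneModel", geneId = "g", chrom = "chrT", strand = "+",
                 exons = IRanges(c(11, 61), c(40, 90)),
                 cdsStart = 11L, cdsEnd = 90L)
    gm <- list(g = model)
    # codon 2 TAC -> TAA (C->A at its third base, position 16): stop
    expect_equal(classifyEffect("chrT", 16, "C", "A", gm, refSeqs)$effect,
                 "stop_gained")
    # codon 3 GGG -> GGA: synonymous
    expect_equal(classifyEffect("chrT", 19, "G", "A", gm, refSeqs)$effect,
                 "synonymous")
    # codon 2 TAC -> AAC: nonsynonymous
    expect_equal(classifyEffect("chrT", 14, "T", "A", gm, refSeqs)$effect,
                 "nonsynonymous")
    # 1-2 bp into the intron on either side: splice site
    expect_equal(classifyEffect("chrT", 41, substr(sq, 41, 41), "C",
                                gm, refSeqs)$effect, "splice_site")
    expect_equal(classifyEffect("chrT", 59, substr(sq, 59, 59), "C",
                                gm, refSeqs)$effect, "splice_site")
    # intron interior and intergenic: noncoding
    expect_equal(classifyEffect("chrT", 50, substr(sq, 50, 50), "C",
                                gm, refSeqs)$effect, "noncoding")
    expect_equal(classifyEffect("chrT", 120, substr(sq, 120, 120), "C",
                                gm, refSeqs)$effect, "noncoding")
    # frameshift for a 1-bp deletion inside the CDS
    expect_equal(classifyEffect("chrT", 19, "GC", "G", gm,
                                refSeqs)$effect, "frameshift")
    expect_error(classifyEffect("chrT", 16, "G", "A", gm, refSeqs),
                 "ref mismatch")
    expect_error(classifyEffect("chrT", 9999, "A", "C", gm, refSeqs),
                 "outside")
    expect_error(classifyEffect("chrX", 16, "C", "A", gm, refSeqs),
                 "no reference")
})

test_that("effect classifier agrees with whole-CDS translation on random toy genes", {
    set.seed(99)
    nChecked <- 0L
    while (nChecked < 1000L) {
        toy <- randomToyGene(nExons = sample(1:3, 1),
                             strand = sample(c("+", "-"), 1))
        gm <- list(toy = toy$model)
        cds <- toy$cdsPos
        for (rep in seq_len(25)) {
            pos <- sample(cds, 1)
            ref <- substr(toy$seq, pos, pos)
            alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
            got <- classifyEffect("chrT", pos, ref, alt, gm,
                                  toy$refSeqs)$effect
            expect_equal(got, oracleEffect(toy, pos, alt),
                         info = sprintf("pos %d %s>%s strand %s", pos,
                                        ref, alt, toy$model@strand))
            nChecked <- nChecked + 1L
        }
    }
})

test_that("candidate report ranks by effect severity then position", {
    cand <- data.frame(
        chrom = c("chr1", "chr1", "chr2", "chr1"),
        pos = c(500L, 100L, 50L, 300L),
        ref = c("A", "A", "A", "A"), alt = c("T", "T", "T", "T"),
        pattern = "22|00", stringsAsFactors = FALSE)
    # no gene models: everything noncoding, ordered by position
    rep0 <- candidateReport(cand)
    expect_equal(rep0$pos, c(100L, 300L, 500L, 50L))
    expect_equal(rep0$rank, 1:4)
    # empty input keeps the header
    repE <- candidateReport(cand[0, ])
    expect_equal(nrow(repE), 0L)
    expect_true(all(c("effect", "rank") %in% names(repE)))
})

test_that("planted causal culture SNP is recovered from a regenerant family", {
    set.seed(123)
    g <- riceGenome(4, 1e6)
    recovered <- 0L
    falseTotal <- 0L
    nSeeds <- 25L
    for (s in seq_len(nSeeds)) {
        f <- makeFounders(g, 2e-4, 0)
        causal <- data.frame(chrom = "chr2", pos = 637000L)
        res <- applyCultureMutations(f$recipient, f$panel, mu = 1.5e-6,
                                     forcedMutations = causal)
        t0 <- res$plant
        panel <- res$panel
        # 4 affected (hom causal) and 3 unaffected T1 sibs
        draw <- function(want) {
            repeat {
                p <- selfPlant(t0)
                d <- introTrace:::.dosageAtSites(p, causal$chrom,
                                                 causal$pos,
                                                 "culture-mutation")
                if (d %in% want) return(p)
            }
        }
        fam <- c(lapply(1:4, function(i) draw(2L)),
                 lapply(1:3, function(i) draw(0:1)))
        names(fam) <- c(paste0("aff", 1:4), paste0("un", 1:3))
        vt <- simCalls(fam, panel, depth = 30, errorRate = 0.005)
        got <- cosegregatingSnps(vt, paste0("aff", 1:4), paste0("un", 1:3))
        hit <- any(got$chrom == causal$chrom & got$pos == causal$pos)
        recovered <- recovered + hit
        falseTotal <- falseTotal + (nrow(got) - hit)
    }
    expect_gte(recovered / nSeeds, 0.95)
    expect_lte(falseTotal / nSeeds, 1)
})
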