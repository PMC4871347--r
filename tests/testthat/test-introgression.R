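lens1 <- c(chr1 = 2e6)

test_that("density track counts sliding windows and rescales to per-2-Mb", {
    # sample identical to reference: all densities zero
    vt0 <- makeVt("chr1", c(10, 500, 900), cbind(s = c(0L, 0L, 0L)), lens1)
    tr0 <- snpDensityTrack(vt0, "s")
    expect_true(all(mcols(tr0)$density == 0))
    # 100 SNPs uniform in one 2-Mb chromosome, width = chromosome: the
    # full window holds all 100
    set.seed(1)
    pos <- sort(sample.int(2e6, 100))
    vt <- makeVt("chr1", pos, cbind(s = rep(1L, 100)), lens1)
    tr <- snpDensityTrack(vt, "s", width = 2e6, step = 5e3)
    expect_equal(mcols(tr)$snpCount[1], 100L)
    expect_equal(mcols(tr)$density[1], 100)
    # a SNP is counted in every window containing it
    w <- tr[start(tr) <= pos[1] & end(tr) >= pos[1]]
    expect_true(all(mcols(w)$snpCount >= 1))
    # truncated-window rescaling: 37 SNPs in a 500-kb window -> 148/2 Mb
    lensS <- c(chr1 = 5e5)
    set.seed(2)
    posS <- sort(sample.int(5e5, 37))
    vtS <- makeVt("chr1", posS, cbind(s = rep(2L, 37)), lensS)
    trS <- snpDensityTrack(vtS, "s", width = 5e5, step = 5e5)
    expect_equal(mcols(trS)$snpCount[1], 37L)
    expect_equal(mcols(trS)$density[1], 37 * 4)
    # het_only counts only heterozygous calls
    vtH <- makeVt("chr1", c(100, 200, 300),
                  cbind(s = c(1L, 2L, NA)), lens1)
    trH <- snpDensityTrack(vtH, "s", include = "het_only")
    expect_equal(mcols(trH)$snpCount[1], 1L)
    expect_error(snpDensityTrack(vt, "s", width = 100, step = 500),
                 "width")
})

mkTrack <- function(dens, width = 2e5, step = 1e5, chrom = "chr1",
                    L = 2e6) {
    anchors <- seq(1L, L, by = step)[seq_along(dens)]
    gr <- GRanges(chrom, IRanges(anchors,
                                 pmin(anchors + width - 1L, L)))
    mcols(gr)$snpCount <- as.integer(dens)
    mcols(gr)$density <- dens
    S4Vectors::metadata(gr) <- list(width = width, step = step)
    gr
}

test_that("high-density calling applies fold and floor rules and merges runs", {
    ctrl <- mkTrack(rep(2, 20))
    # sample equal to control everywhere: nothing called
    expect_equal(length(callHighDensityRegions(mkTrack(rep(2, 20)),
                                               list(ctrl))), 0L)
    # windows 10-15 high above floor and fold
    dens <- rep(2, 20); dens[10:15] <- 500
    reg <- callHighDensityRegions(mkTrack(dens), list(ctrl))
    expect_equal(length(reg), 1L)
    expect_equal(start(reg), (10 - 1) * 1e5 + 1)
    # two runs separated by more than a window width stay two regions
    dens2 <- rep(2, 40); dens2[3:5] <- 500; dens2[30:33] <- 500
    reg2 <- callHighDensityRegions(mkTrack(dens2, L = 4.2e6), list(ctrl2 <-
        mkTrack(rep(2, 40), L = 4.2e6)))
    expect_equal(length(reg2), 2L)
    # below the absolute floor nothing is called even with zero controls
    dens3 <- rep(0, 20); dens3[5:8] <- 30   # fold over ctrl 0->1 is 30x
    reg3 <- callHighDensityRegions(mkTrack(dens3),
                                   list(mkTrack(rep(0, 20))), minAbs = 50)
    expect_equal(length(reg3), 0L)
    expect_error(callHighDensityRegions(mkTrack(rep(2, 20)), list()),
                 "control")
    expect_error(callHighDensityRegions(mkTrack(rep(2, 20)),
                                        list(mkTrack(rep(2, 10)))),
                 "grid")
})

test_that("border refinement follows the 10-kb outermost-specific-SNP rule", {
    # sample-specific SNPs spanning 100,000-150,000 -> region 90,000-160,000
    pos <- seq(100000, 150000, by = 5000)
    n <- length(pos)
    gt <- cbind(s = rep(2L, n), c1 = rep(0L, n), c2 = rep(0L, n))
    vt <- makeVt("chr1", pos, gt, lens1)
    raw <- GRanges("chr1", IRanges(1, 2e6))
    reg <- refineBorders(raw, vt, "s", c("c1", "c2"))
    expect_equal(start(reg), 90000L)
    expect_equal(end(reg), 160000L)
    expect_equal(mcols(reg)$snpCount, n)
    # clipping at the chromosome start
    vt2 <- makeVt("chr1", c(5000, 5100, 5200), cbind(s = rep(1L, 3),
                                                     c1 = rep(0L, 3)),
                  lens1)
    reg2 <- refineBorders(GRanges("chr1", IRanges(1, 1e6)), vt2, "s", "c1",
                          minRegionSnps = 3L)
    expect_equal(start(reg2), 1L)
    # SNPs shared with controls do not extend the border
    pos3 <- c(pos, 160500)
    gt3 <- cbind(s = rep(2L, n + 1), c1 = c(rep(0L, n), 2L),
                 c2 = rep(0L, n + 1))
    vt3 <- makeVt("chr1", pos3, gt3, lens1)
    reg3 <- refineBorders(raw, vt3, "s", c("c1", "c2"))
    expect_equal(end(reg3), 160000L)
    # a missing control call keeps a site sample-specific
    gt4 <- cbind(s = rep(2L, n), c1 = rep(NA_integer_, n),
                 c2 = rep(0L, n))
    vt4 <- makeVt("chr1", pos, gt4, lens1)
    expect_equal(mcols(refineBorders(raw, vt4, "s",
                                     c("c1", "c2")))$snpCount, n)
    # too few specific SNPs: dropped with a message
    expect_message(
        regE <- refineBorders(GRanges("chr1", IRanges(1.5e6, 2e6)), vt,
                              "s", c("c1", "c2")),
        "dropped")
    expect_equal(length(regE), 0L)
})

test_that("border refinement splits events at SNP deserts", {
    posA <- seq(100000, 140000, by = 2000)
    posB <- seq(900000, 940000, by = 2000)
    pos <- c(posA, posB)
    gt <- cbind(s = rep(2L, length(pos)), c1 = rep(0L, length(pos)))
    vt <- makeVt("chr1", pos, gt, lens1)
    reg <- refineBorders(GRanges("chr1", IRanges(1, 2e6)), vt, "s", "c1",
                         maxGap = 1e5)
    expect_equal(length(reg), 2L)
    expect_equal(start(reg), c(90000L, 890000L))
    expect_equal(end(reg), c(150000L, 950000L))
})

test_that("zygosity classification thresholds work", {
    pos <- seq(1000, 20000, by = 1000)
    n <- length(pos)
    region <- GRanges("chr1", IRanges(1, 1e5))
    vtHet <- makeVt("chr1", pos, cbind(s = rep(1L, n)), lens1)
    expect_equal(classifyZygosity(region, vtHet, "s"), "heterozygous")
    vtHom <- makeVt("chr1", pos, cbind(s = rep(2L, n)), lens1)
    expect_equal(classifyZygosity(region, vtHom, "s"), "homozygous")
    gtMix <- rep(c(1L, 2L), n / 2)
    vtMix <- makeVt("chr1", pos, cbind(s = gtMix), lens1)
    expect_equal(classifyZygosity(region, vtMix, "s"), "mixed")
    vtNA <- makeVt("chr1", pos, cbind(s = rep(NA_integer_, n)), lens1)
    expect_error(classifyZygosity(region, vtNA, "s"), "no genotyped")
})

test_that("donor similarity is the shared-alt fraction", {
    region <- GRanges("chr1", IRanges(1, 1e6))
    # perfect copy of the donor
    pos <- seq(1000, 50000, by = 1000)
    n <- length(pos)
    vt <- makeVt("chr1", pos, cbind(s = rep(1L, n), d = rep(2L, n)), lens1)
    expect_equal(donorSimilarity(region, vt, "s", "d"), 1.0)
    # culture mutations only: donor is reference there
    vt0 <- makeVt("chr1", pos, cbind(s = rep(1L, n), d = rep(0L, n)),
                  lens1)
    expect_equal(donorSimilarity(region, vt0, "s", "d"), 0.0)
    # 200 donor sites plus 2 culture SNPs -> 200/202
    pos2 <- seq(1000, 202000, by = 1000)
    dGt <- c(rep(2L, 200), 0L, 0L)
    vt2 <- makeVt("chr1", pos2, cbind(s = rep(2L, 202), d = dGt),
                  lens1)
    expect_equal(donorSimilarity(region, vt2, "s", "d"), 200 / 202)
    vtRef <- makeVt("chr1", pos, cbind(s = rep(0L, n), d = rep(2L, n)),
                    lens1)
    expect_error(donorSimilarity(region, vtRef, "s", "d"),
                 "no non-reference")
})

test_that("het profile bins heterozygous calls with 1-based closed bins", {
    pos <- c(50, 99999, 100000, 100001, 250000)
    gt <- cbind(s = c(1L, 1L, 1L, 1L, 2L))
    vt <- makeVt("chr1", pos, gt, lens1)
    prof <- hetProfile(vt, "s", bin = 1e5)
    expect_equal(length(prof), 20L)
    expect_equal(mcols(prof)$hetCount[1], 3L)   # 100,000 is still bin 1
    expect_equal(mcols(prof)$hetCount[2], 1L)
    expect_equal(mcols(prof)$hetCount[3], 0L)   # hom call not counted
    # homozygous sample: all zeros
    vtHom <- makeVt("chr1", pos, cbind(s = rep(c(0L, 2L), c(2, 3))), lens1)
    expect_true(all(mcols(hetProfile(vtHom, "s"))$hetCount == 0))
})

test_that("genome state classifier separates the three regimes", {
    mkProf <- function(counts) {
        gr <- GRanges("chr1", IRanges(seq(1, by = 1e5,
                                          length.out = length(counts)),
                                      width = 1e5))
        mcols(gr)$hetCount <- as.integer(counts)
        gr
    }
    none <- GRanges()
    expect_equal(classifyGenomeState(mkProf(rep(200, 50)), none),
                 "genome_wide_heterozygous")
    expect_equal(classifyGenomeState(mkProf(rep(0, 50)), none), "clean")
    expect_equal(classifyGenomeState(mkProf(rep(c(200, 0), c(10, 40))),
                                     none), "segmental_introgression")
    # regions present forbid the clean label
    reg <- GRanges("chr1", IRanges(1, 1e5))
    expect_equal(classifyGenomeState(mkProf(rep(0, 50)), reg),
                 "segmental_introgression")
})

test_that("lowering the fold threshold never shrinks the called set", {
    set.seed(33)
    g <- riceGenome(4, 1e6)
    f <- makeFounders(g, 1e-3, 1e-4)
    f1 <- crossPlants(f$recipient, f$donor)
    f3 <- selfPlant(selfPlant(f1))
    vt <- simCalls(list(s = f3, rec = f$recipient,
                        c1 = selfPlant(f$recipient, id = "c1")),
                   f$panel, depth = 20, errorRate = 0.002)
    st <- snpDensityTrack(vt, "s")
    cts <- list(snpDensityTrack(vt, "rec"), snpDensityTrack(vt, "c1"))
    loose <- callHighDensityRegions(st, cts, fold = 3)
    strict <- callHighDensityRegions(st, cts, fold = 10)
    # every strict window is inside the loose set
    expect_true(all(overlapsAny(strict, loose)))
    expect_gte(sum(width(GenomicRanges::intersect(loose, strict))),
               sum(width(strict)))
})

test_that("mixed regions are split into het and hom parts", {
    # 60 het SNPs then 60 hom SNPs, all sample-specific
    pos <- seq(10000, 129000, by = 1000)
    gt <- cbind(s = rep(c(1L, 2L), each = 60), c1 = rep(0L, 120))
    rd <- matrix(10L, 120, 2, dimnames = list(NULL, c("s", "c1")))
    ad <- matrix(c(rep(c(10L, 20L), each = 60), rep(0L, 120)), 120,
                 dimnames = list(NULL, c("s", "c1")))
    vt <- makeVt("chr1", pos, gt, lens1, refDepth = rd, altDepth = ad)
    reg <- suppressMessages(
        detectIntrogression(vt, "s", "c1", minAbs = 10))
    expect_equal(length(reg), 2L)
    expect_setequal(mcols(reg)$zygosity, c("heterozygous", "homozygous"))
    expect_error(detectIntrogression(vt, "s", character(0)), "control")
})
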