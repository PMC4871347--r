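test_that("founders honour marker densities, homozygosity and determinism", {
    g <- riceGenome(3, 1e6)
    set.seed(10)
    f <- makeFounders(g, donorDensity = 2e-3, parent2Density = 2e-4)
    cls <- mcols(f$panel)$class
    nDonor <- sum(cls == "donor-diagnostic")
    nP2 <- sum(cls == "parent2-diagnostic")
    # Poisson(density x genome length), within 4 SD
    expect_lt(abs(nDonor - 6000), 4 * sqrt(6000))
    expect_lt(abs(nP2 - 600), 4 * sqrt(600) + 10)
    expect_true(all(mcols(f$panel)$ref != mcols(f$panel)$alt))
    # positions strictly increasing within chromosome
    byChrom <- split(start(f$panel), as.character(seqnames(f$panel)))
    expect_true(all(vapply(byChrom, function(p) all(diff(p) > 0), TRUE)))
    dos <- dosageMatrix(list(r = f$recipient, d = f$donor,
                             p2 = f$parent2), f$panel)
    expect_true(all(dos[, "r"] == 0))
    expect_true(all(dos[cls == "donor-diagnostic", "d"] == 2))
    expect_true(all(dos[cls == "parent2-diagnostic", "d"] == 0))
    expect_true(all(dos[cls == "parent2-diagnostic", "p2"] == 2))
    # zero parent2 density -> no parent2 markers
    set.seed(11)
    f0 <- makeFounders(g, donorDensity = 1e-3, parent2Density = 0)
    expect_equal(sum(mcols(f0$panel)$class == "parent2-diagnostic"), 0)
    # seeded determinism
    set.seed(12); a <- makeFounders(g, 1e-3, 1e-4)
    set.seed(12); b <- makeFounders(g, 1e-3, 1e-4)
    expect_identical(as.data.frame(a$panel), as.data.frame(b$panel))
    # absurd density rejected
    expect_error(makeFounders(g, donorDensity = 1.5), "spacing")
})

test_that("meiosis: no crossovers copies a parental chromosome; rate matches lambda", {
    g <- riceGenome(2, 5e5)
    set.seed(20)
    f <- makeFounders(g, 1e-3, 1e-4)
    f1 <- crossPlants(f$recipient, f$donor)
    gam <- meiosis(f1, lambda = 0)
    for (chr in c("chr1", "chr2")) {
        seg <- gam$mosaic[gam$mosaic$chrom == chr, ]
        expect_equal(nrow(seg), 1L)     # whole parental copy
        expect_true(seg$ancestry %in% c("recipient", "donor"))
    }
    # homozygous plant: gamete ancestry identical to either copy
    gamR <- meiosis(f$recipient, lambda = 3)
    expect_true(all(gamR$mosaic$ancestry == "recipient"))
    # Monte-Carlo: ancestry switches in an F1 gamete count crossovers
    set.seed(21)
    nSwitch <- replicate(3000, {
        m <- meiosis(f1, lambda = 1.25)$mosaic
        sum(vapply(c("chr1", "chr2"), function(chr)
            nrow(m[m$chrom == chr, ]) - 1L, 0L))
    })
    mcMean <- mean(nSwitch) / 2        # per chromosome
    se <- sd(nSwitch / 2) / sqrt(3000)
    expect_lt(abs(mcMean - 1.25), 3 * se + 0.01)
})

test_that("selfing and crossing obey Mendelian expectations", {
    g <- riceGenome(1, 1e6)
    set.seed(30)
    f <- makeFounders(g, 5e-5, 0)   # sparse panel: fast genotyping
    # self of homozygous recipient stays homozygous recipient
    off <- selfPlant(f$recipient)
    expect_true(all(dosageMatrix(off, f$panel) == 0))
    # F1 heterozygous at every donor marker
    f1 <- crossPlants(f$recipient, f$donor)
    expect_true(all(dosageMatrix(f1, f$panel) == 1))
    # genotype frequencies at one marker over 10,000 selfings
    marker <- f$panel[ceiling(length(f$panel) / 2)]
    chrom <- as.character(seqnames(marker)); pos <- start(marker)
    set.seed(31)
    dos <- replicate(10000, {
        introTrace:::.dosageAtSites(selfPlant(f1), chrom, pos,
                                    "donor-diagnostic")
    })
    freq <- tabulate(dos + 1L, 3L) / 10000
    se <- sqrt(c(.25 * .75, .5 * .5, .25 * .75) / 10000)
    expect_true(all(abs(freq - c(.25, .5, .25)) < 3 * se))
})

test_that("culture mutations are Poisson-many, collision-free and heterozygous", {
    g <- riceGenome(2, 1e6)
    set.seed(40)
    f <- makeFounders(g, 1e-4, 0)
    # mu = 0: nothing happens
    r0 <- applyCultureMutations(f$recipient, f$panel, mu = 0)
    expect_identical(length(r0$panel), length(f$panel))
    # Poisson mean over replicates: mu * genome bp = 2e-6 * 2e6 = 4
    set.seed(41)
    counts <- replicate(300, {
        r <- applyCultureMutations(f$recipient, f$panel, mu = 2e-6)
        length(r$panel) - length(f$panel)
    })
    expect_lt(abs(mean(counts) - 4), 3 * sqrt(4 / 300) + 0.05)
    # every new site is heterozygous in the regenerant and in the panel once
    set.seed(42)
    r <- applyCultureMutations(f$recipient, f$panel, mu = 2e-5)
    newIdx <- mcols(r$panel)$class == "culture-mutation"
    expect_gt(sum(newIdx), 0)
    dos <- dosageMatrix(r$plant, r$panel)
    expect_true(all(dos[newIdx, 1] == 1))
    expect_false(anyDuplicated(paste(seqnames(r$panel),
                                     start(r$panel))) > 0)
})

test_that("T-DNA pseudo-marker segregates 1:2:1 after selfing", {
    g <- riceGenome(1, 1e6)
    set.seed(50)
    f <- makeFounders(g, 1e-4, 0)
    res <- insertTdna(f$recipient, f$panel, "chr1", 5e5)
    expect_equal(tdnaDosage(res$plant), 1L)
    expect_error(insertTdna(f$recipient, f$panel, "chr1", 2e6),
                 "outside")
    # azygous parent -> all offspring azygous
    expect_equal(tdnaDosage(selfPlant(f$recipient)), 0L)
    set.seed(51)
    dos <- replicate(10000, tdnaDosage(selfPlant(res$plant)))
    freq <- tabulate(dos + 1L, 3L) / 10000
    se <- sqrt(c(.25 * .75, .5 * .5, .25 * .75) / 10000)
    expect_true(all(abs(freq - c(.25, .5, .25)) < 3 * se))
})

test_that("phenotypes derive deterministically from causal dosage", {
    g <- riceGenome(2, 1e6)
    set.seed(60)
    forced <- data.frame(chrom = "chr1", pos = 4e5)
    f <- makeFounders(g, 1e-4, 0, forcedDonorMarkers = forced)
    causal <- data.frame(chrom = "chr1", pos = 4e5, label = "large-grain",
                         origin = "donor")
    expect_identical(phenotypeOf(f$donor, f$panel, causal), "large-grain")
    f1 <- crossPlants(f$recipient, f$donor)
    expect_identical(phenotypeOf(f1, f$panel, causal), character())
    expect_identical(phenotypeOf(f$recipient, f$panel, causal),
                     character())
    bad <- data.frame(chrom = "chr2", pos = 123L, label = "x",
                      origin = "donor")
    expect_error(phenotypeOf(f$donor, f$panel, bad), "not in panel")
})

test_that("read sampling follows the dosage/error model", {
    dos <- matrix(c(2, 1, 0), 3, 1, dimnames = list(NULL, "s"))
    set.seed(70)
    r <- sampleReads(dos, depthMean = 20, errorRate = 0)
    expect_equal(unname(r$ref[1, 1]), 0L)   # dosage 2, e=0: all reads alt
    expect_equal(unname(r$alt[3, 1]), 0L)   # dosage 0, e=0
    # dosage 1: alt fraction converges to 0.5
    dosHet <- matrix(1, 2000, 1)
    set.seed(71)
    r <- sampleReads(dosHet, depthMean = 30, errorRate = 0)
    frac <- sum(r$alt) / sum(r$alt + r$ref)
    expect_lt(abs(frac - 0.5), 0.01)
    # pool of hom-alt plants, e = 0: alt fraction exactly 1 where depth > 0
    poolDos <- matrix(2, 50, 1)
    set.seed(72)
    r <- sampleReads(poolDos, depthMean = 15, errorRate = 0)
    expect_true(all(r$ref == 0))
    expect_error(sampleReads(dos, 15, 0.6), "errorRate")
})

test_that("genotype calling thresholds behave at the boundaries", {
    expect_identical(genotypeFromCounts(10, 0), 0L)
    expect_identical(genotypeFromCounts(5, 5), 1L)
    expect_true(is.na(genotypeFromCounts(1, 2)))   # depth 3 < 4
    expect_identical(genotypeFromCounts(2, 8), 2L)  # frac 0.8 >= 0.8
    expect_identical(genotypeFromCounts(8, 2), 0L)  # frac 0.2 <= 0.2
    expect_identical(genotypeFromCounts(0, 4), 2L)
    expect_error(genotypeFromCounts(-1, 2), ">= 0")
    m <- genotypeFromCounts(matrix(c(10, 5, 1, 0), 2),
                            matrix(c(0, 5, 2, 12), 2))
    expect_identical(dim(m), c(2L, 2L))
})

test_that("VCF emission round-trips through the independent reader", {
    g <- riceGenome(2, 2e5)
    set.seed(80)
    f <- makeFounders(g, 5e-4, 1e-4)
    f1 <- crossPlants(f$recipient, f$donor)
    vt <- simCalls(list(a = f1, b = f$donor), f$panel, depth = 12)
    path <- tempfile(fileext = ".vcf")
    emitVcf(vt, path)
    vt2 <- readVariantTable(path)
    expect_identical(assay(vt, "GT"), assay(vt2, "GT"))
    expect_identical(assay(vt, "refDepth"), assay(vt2, "refDepth"))
    expect_identical(assay(vt, "altDepth"), assay(vt2, "altDepth"))
    expect_identical(start(rowRanges(vt)), start(rowRanges(vt2)))
    expect_identical(mcols(rowRanges(vt))$alt, mcols(rowRanges(vt2))$alt)
    # het serialized unphased with both alleles
    lines <- readLines(path)
    body <- lines[!startsWith(lines, "#")]
    gtField <- sub(":.*", "", sub("^([^\t]*\t){9}", "", body))
    hasHet <- any(assay(vt, "GT") == 1L, na.rm = TRUE)
    expect_identical(hasHet, any(gtField == "0/1"))
    expect_false(any(grepl("0\\|1", body)))
    # zero samples: header-only file, reader returns empty table
    vt0 <- vt[, character(0)]
    p0 <- tempfile(fileext = ".vcf")
    emitVcf(vt0, p0)
    lines0 <- readLines(p0)
    expect_true(all(startsWith(lines0, "#") |
                        !nzchar(lines0) |
                        grepl("\t", lines0)))
    vt0r <- readVariantTable(p0)
    expect_equal(ncol(vt0r), 0L)
})

test_that("pedigree simulation is seed-deterministic down to VCF bytes", {
    spec <- m0028590Pedigree(genome = riceGenome(4, 8e5), f2Size = 130L)
    spec$sequence <- c("recipient", "donor", "T1a", "wtPool")
    run <- function() {
        sim <- simulatePedigree(spec, seed = 99L)
        vt <- simulatedVariantTable(sim)
        p <- tempfile(fileext = ".vcf")
        emitVcf(vt, p)
        readBin(p, "raw", file.size(p))
    }
    expect_identical(run(), run())
})

test_that("pedigree events validate their inputs", {
    spec <- list(genome = riceGenome(1, 1e5),
                 events = list(list(op = "self", id = "x",
                                    parent = "ghost")))
    expect_error(simulatePedigree(spec, 1), "undefined plant")
    spec2 <- list(genome = riceGenome(1, 1e5),
                  events = list(list(op = "warp", id = "x")))
    expect_error(simulatePedigree(spec2, 1), "unknown pedigree op")
})
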