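#' Run configuration
#'
#' All pipeline stages are driven by a single declarative configuration
#' (a YAML file or an equivalent named list) with one section per stage.
#' Unknown keys are rejected, defaults are filled in, and every run writes
#' its fully resolved configuration next to its outputs so that
#' threshold-heavy analyses stay reproducible.
#'
#' @name RunConfig
NULL

.configDefaults <- function() list(
    seed = 1L,
    outDir = "introtrace_out",
    simulate = list(preset = "m0028590", f2Size = 200L, nChrom = 12L,
                    chromLength = 2.5e6, config = list()),
    detect = list(samples = c("T1a", "T1b", "T1c", "T2a", "T2b",
                              "T3a", "T3b"),
                  controls = c("recipient", "ctrlTRIM1", "ctrlTRIM2"),
                  donorSample = "donor", width = 2e6, step = 5e3,
                  fold = 10, minAbs = 20, pad = 1e4, minRegionSnps = 10L,
                  maxGap = 1e5, hetHi = 0.8, hetLo = 0.2),
    track = list(generations = list(T1 = c("T1a", "T1b", "T1c"),
                                    T2 = c("T2a", "T2b"),
                                    T3 = c("T3a", "T3b"))),
    bsa = list(mutPool = "lgPool", wtPool = "wtPool",
               mutantParent = "T2lg", otherParent = "parent2",
               minDepth = 5L, windowSnps = 20L, stepSnps = 1L,
               high = 0.9, controlMax = 0.7, minWindows = 5L),
    candidates = list(affected = c("T1c", "T2b", "T3a", "T3b"),
                      unaffected = c("T1a", "T1b", "T2a"),
                      maxMissing = 0L, gff = NULL, fasta = NULL),
    phylo = list(samples = NULL, focal = c("T1b", "T1c"),
                 donorGroup = "donor",
                 recipientGroup = c("recipient", "parent2", "ctrlTRIM1",
                                    "ctrlTRIM2"),
                 minSites = 100L, regionRestricted = TRUE))

.mergeConfig <- function(user, defaults = .configDefaults(),
                         path = "config") {
    if (is.null(user)) return(defaults)
    bad <- setdiff(names(user), names(defaults))
    if (length(bad))
        stop("unknown ", path, " key(s): ", paste(bad, collapse = ", "))
    for (k in names(user)) {
        defaults[[k]] <- if (is.list(defaults[[k]]) && is.list(user[[k]]) &&
                             !is.null(names(defaults[[k]])))
            .mergeConfig(user[[k]], defaults[[k]], paste(path, k, sep = "$"))
        else user[[k]]
    }
    defaults
}

#' Read and resolve a run configuration
#'
#' @param config a YAML file path or a named list (possibly partial);
#'   `NULL` yields the full defaults.
#' @return the resolved configuration list.
#' @export
readRunConfig <- function(config = NULL) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    .mergeConfig(config)
}

.provenance <- function(cfg) {
    sprintf("# introTrace %s; seed=%s",
            as.character(utils::packageVersion("introTrace")), cfg$seed)
}

.writeTsv <- function(df, path, cfg) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(.provenance(cfg), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

.resolveDir <- function(cfg) {
    dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
    yaml::write_yaml(cfg, file.path(cfg$outDir, "resolved_config.yaml"))
    cfg$outDir
}

#' Pipeline stages
#'
#' Orchestration functions mirroring the pipeline's shell subcommands:
#' `runSimulate` writes the simulated VCF, truth BED and manifest;
#' `runDetect` calls introgression regions per sample (TSV + BED + genome
#' state); `runTrack` summarizes fractions and fixation trajectories
#' across generations; `runBsa` writes SNP-index tracks and peak regions;
#' `runCandidates` writes the co-segregation report; `runPhylo` writes
#' distance matrices, newick trees and placement calls; `runAll` chains
#' all stages in one output directory. Every stage is deterministic given
#' the config seed and records the resolved configuration.
#'
#' @param config a YAML path or named list, see [readRunConfig()].
#' @return named vector/list of output paths (and, for `runAll`, the main
#'   in-memory results), invisibly.
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
runSimulate <- function(config = NULL) {
    cfg <- readRunConfig(config)
    dir <- .resolveDir(cfg)
    sc <- cfg$simulate
    if (!identical(sc$preset, "m0028590"))
        stop("unknown simulate preset: ", sc$preset)
    spec <- m0028590Pedigree(
        genome = riceGenome(sc$nChrom, sc$chromLength),
        f2Size = sc$f2Size, config = sc$config)
    sim <- simulatePedigree(spec, seed = cfg$seed)
    vt <- simulatedVariantTable(sim)
    files <- writeSimOutputs(sim, vt, dir)
    invisible(list(files = files, sim = sim, vt = vt, spec = spec))
}

#' @rdname pipeline
#' @param vt a [VariantTable]; when omitted the stage reads
#'   `simulated.vcf` from the configured output directory.
#' @export
runDetect <- function(config = NULL, vt = NULL) {
    cfg <- readRunConfig(config)
    dir <- .resolveDir(cfg)
    dc <- cfg$detect
    if (!length(dc$controls)) stop("detect requires control samples")
    if (is.null(vt)) vt <- readVariantTable(file.path(dir, "simulated.vcf"))
    allRegions <- list()
    rows <- list()
    for (s in dc$samples) {
        reg <- detectIntrogression(vt, s, dc$controls,
                                   donorSample = dc$donorSample,
                                   width = dc$width, step = dc$step,
                                   fold = dc$fold, minAbs = dc$minAbs,
                                   pad = dc$pad,
                                   minRegionSnps = dc$minRegionSnps,
                                   maxGap = dc$maxGap, hetHi = dc$hetHi,
                                   hetLo = dc$hetLo)
        allRegions[[s]] <- reg
        state <- classifyGenomeState(hetProfile(vt, s), reg)
        rows[[s]] <- data.frame(
            sample = s, nRegions = length(reg), genomeState = state,
            stringsAsFactors = FALSE)
        if (length(reg)) {
            mcols(reg)$name <- paste(s, mcols(reg)$zygosity, sep = "|")
            writeBed(reg, file.path(dir, sprintf("regions_%s.bed", s)))
        }
        df <- as.data.frame(reg)
        df$sample <- rep(s, nrow(df))
        .writeTsv(df, file.path(dir, sprintf("regions_%s.tsv", s)), cfg)
    }
    .writeTsv(do.call(rbind, rows), file.path(dir, "genome_state.tsv"), cfg)
    message(sprintf("detect: %d sample(s), %d region(s) total",
                    length(dc$samples),
                    sum(lengths(allRegions))))
    invisible(list(regions = allRegions,
                   dir = dir))
}

#' @rdname pipeline
#' @param regions named list of per-sample region [GenomicRanges::GRanges],
#'   e.g. from `runDetect()$regions`.
#' @param genome a [GenomeInfoDb::Seqinfo] for fraction denominators.
#' @export
runTrack <- function(config = NULL, regions, genome) {
    cfg <- readRunConfig(config)
    dir <- .resolveDir(cfg)
    tc <- cfg$track
    perPlant <- lapply(names(regions), function(s) {
        fr <- introgressionFraction(regions[[s]], genome)
        hom <- introgressionFraction(regions[[s]], genome, "hom")
        het <- introgressionFraction(regions[[s]], genome, "het")
        data.frame(sample = s, fracAny = fr$overall,
                   fracHom = hom$overall, fracHet = het$overall,
                   stringsAsFactors = FALSE)
    })
    perPlant <- do.call(rbind, perPlant)
    .writeTsv(perPlant, file.path(dir, "fractions_per_plant.tsv"), cfg)
    uf <- unionFraction(regions, genome)
    byGen <- lapply(tc$generations, function(ids) {
        ids <- intersect(ids, names(regions))
        do.call(c, unname(lapply(regions[ids], identity)))
    })
    traj <- trackFixation(byGen)
    .writeTsv(traj, file.path(dir, "fixation_trajectories.tsv"), cfg)
    hetByGen <- vapply(tc$generations, function(ids) {
        ids <- intersect(ids, names(regions))
        mean(vapply(ids, function(s) {
            f <- introgressionFraction(regions[[s]], genome, "het")$overall
            a <- introgressionFraction(regions[[s]], genome)$overall
            if (a > 0) f / a else NA_real_
        }, 0), na.rm = TRUE)
    }, 0)
    summ <- data.frame(generation = names(tc$generations),
                       hetShareOfIntrogressed = hetByGen,
                       stringsAsFactors = FALSE)
    .writeTsv(summ, file.path(dir, "generation_summary.tsv"), cfg)
    message(sprintf("track: union introgressed fraction %.3f", uf))
    invisible(list(perPlant = perPlant, unionFraction = uf,
                   trajectories = traj))
}

#' @rdname pipeline
#' @export
runBsa <- function(config = NULL, vt = NULL) {
    cfg <- readRunConfig(config)
    dir <- .resolveDir(cfg)
    bc <- cfg$bsa
    if (is.null(vt)) vt <- readVariantTable(file.path(dir, "simulated.vcf"))
    mc <- poolCounts(vt, bc$mutPool, bc$mutantParent, bc$otherParent)
    wc <- poolCounts(vt, bc$wtPool, bc$mutantParent, bc$otherParent)
    tr <- bsaTracks(mc, wc, bc$minDepth, bc$windowSnps, bc$stepSnps)
    perChromDefined <- table(tr$smoothMut$chrom)
    if (!nrow(tr$smoothMut))
        warning("no chromosome has enough defined markers to smooth")
    peaks <- callPeakRegions(tr$smoothMut, tr$smoothWt, bc$high,
                             bc$controlMax, bc$minWindows)
    .writeTsv(tr$rawMut, file.path(dir, "snpindex_raw_mutant.tsv"), cfg)
    .writeTsv(tr$rawWt, file.path(dir, "snpindex_raw_wildtype.tsv"), cfg)
    .writeTsv(tr$smoothMut, file.path(dir, "snpindex_smooth_mutant.tsv"),
              cfg)
    .writeTsv(tr$smoothWt, file.path(dir, "snpindex_smooth_wildtype.tsv"),
              cfg)
    .writeTsv(tr$delta, file.path(dir, "snpindex_delta.tsv"), cfg)
    if (length(peaks)) {
        mcols(peaks)$name <- rep("snpindex_peak", length(peaks))
        writeBed(peaks, file.path(dir, "bsa_peaks.bed"))
    }
    message(sprintf("bsa: %d informative markers, %d peak region(s)",
                    nrow(mc), length(peaks)))
    invisible(list(tracks = tr, peaks = peaks))
}

#' @rdname pipeline
#' @export
runCandidates <- function(config = NULL, vt = NULL) {
    cfg <- readRunConfig(config)
    dir <- .resolveDir(cfg)
    cc <- cfg$candidates
    if (is.null(vt)) vt <- readVariantTable(file.path(dir, "simulated.vcf"))
    cand <- cosegregatingSnps(vt, cc$affected, cc$unaffected,
                              maxMissing = cc$maxMissing)
    models <- if (!is.null(cc$gff)) readGeneModels(cc$gff) else NULL
    refSeqs <- if (!is.null(cc$fasta))
        Biostrings::readDNAStringSet(cc$fasta) else NULL
    rep <- candidateReport(cand, models, refSeqs)
    .writeTsv(rep, file.path(dir, "candidates.tsv"), cfg)
    message(sprintf("candidates: %d co-segregating SNP(s)", nrow(rep)))
    invisible(rep)
}

#' @rdname pipeline
#' @export
runPhylo <- function(config = NULL, vt = NULL, regions = NULL) {
    cfg <- readRunConfig(config)
    dir <- .resolveDir(cfg)
    pc <- cfg$phylo
    if (is.null(vt)) vt <- readVariantTable(file.path(dir, "simulated.vcf"))
    samples <- pc$samples %||%
        intersect(c(pc$focal, pc$donorGroup, pc$recipientGroup),
                  colnames(vt))
    build <- function(region, tag) {
        dm <- alleleSharingDistance(vt, samples, region, pc$minSites)
        tree <- njTree(dm)
        utils::write.table(dm, file.path(dir, sprintf("dist_%s.tsv", tag)),
                           sep = "\t", quote = FALSE)
        writeNewick(tree, file.path(dir, sprintf("tree_%s.nwk", tag)))
        tree
    }
    wholeTree <- build(NULL, "whole_genome")
    placeWhole <- placementCheck(wholeTree, pc$focal, pc$donorGroup,
                                 pc$recipientGroup)
    out <- list(wholeTree = wholeTree, placementWhole = placeWhole)
    if (isTRUE(pc$regionRestricted) && !is.null(regions)) {
        focalSets <- lapply(regions[intersect(names(regions), pc$focal)],
                            function(r) reduce(granges(r)))
        # the regions introgressed in EVERY focal plant (the analysis
        # region of the published tree was chosen the same way)
        common <- Reduce(GenomicRanges::intersect, focalSets)
        if (!length(common))
            common <- reduce(do.call(c, unname(focalSets)))
        if (length(common)) {
            regTree <- build(common, "introgressed_regions")
            out$regionTree <- regTree
            out$placementRegion <- placementCheck(
                regTree, pc$focal, pc$donorGroup, pc$recipientGroup)
        }
    }
    place <- data.frame(
        sample = pc$focal,
        wholeGenome = out$placementWhole[pc$focal],
        introgressedRegions =
            (out$placementRegion %||%
                 stats::setNames(rep(NA_character_, length(pc$focal)),
                                 pc$focal))[pc$focal],
        stringsAsFactors = FALSE)
    .writeTsv(place, file.path(dir, "placement.tsv"), cfg)
    message(sprintf("phylo: %d leaves", length(samples)))
    invisible(out)
}

#' @rdname pipeline
#' @export
runAll <- function(config = NULL) {
    cfg <- readRunConfig(config)
    simRes <- runSimulate(cfg)
    detRes <- runDetect(cfg, vt = simRes$vt)
    trackRes <- runTrack(cfg, regions = detRes$regions,
                         genome = simRes$sim$genome)
    bsaRes <- runBsa(cfg, vt = simRes$vt)
    candRes <- runCandidates(cfg, vt = simRes$vt)
    phyRes <- runPhylo(cfg, vt = simRes$vt, regions = detRes$regions)
    invisible(list(sim = simRes, detect = detRes, track = trackRes,
                   bsa = bsaRes, candidates = candRes, phylo = phyRes,
                   dir = cfg$outDir))
}
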