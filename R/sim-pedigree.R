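#' Declarative pedigree simulation
#'
#' `simulatePedigree()` interprets a declarative description of the
#' crossing / selfing / tissue-culture history and returns every plant with
#' its haplotype truth. A pedigree spec is a list with elements:
#'
#' * `genome` -- a [GenomeInfoDb::Seqinfo];
#' * `config` -- simulation parameters (`lambda`, `mu`, `depthMean`,
#'   `poolDepth`, `errorRate`, `minDepth`, `homFrac`, `donorDensity`,
#'   `parent2Density`), missing entries filled from [defaultSimConfig()];
#' * `causalLoci` -- data.frame `chrom`, `pos`, `label`, `origin`
#'   (`"donor"` loci are forced into the founder marker panel; `"culture"`
#'   loci are planted as forced mutations by the tissue-culture event);
#' * `events` -- ordered list of events, each a list with an `op` field:
#'   `founders`, `outcross`/`cross` (`id`, `p1`, `p2`), `self` (`id`,
#'   `parent`), `tissue_culture` (`id`, `parent`, `tdnaChrom`, `tdnaPos`),
#'   `f2_population` (`id`, `parent`, `size`) and `pool` (`id`,
#'   `population`, `label`, `has`, `size`). Every event's inputs must name
#'   previously defined plants.
#' * `sequence` -- sample ids (plants and pools) to expose as VCF columns.
#'
#' `self`, `cross` and `outcross` events accept a `require` list of
#' `list(chrom, pos, dosage)` conditions (dosage may be a set) and/or a
#' `list(maxDonorShare = x)` bound on the plant's truth donor share; the
#' event is redrawn until the offspring satisfies them, which conditions
#' the simulation on the genotypes the study actually observed in its
#' named plants.
#'
#' @param spec a pedigree spec as above, e.g. from [m0028590Pedigree()].
#' @param seed integer seed; the full run is reproducible from it.
#' @return a list (class `simPedigree`) with `plants` (named list of
#'   [SimPlant]), `pools` (named list of member-id vectors), `panel`,
#'   `genome`, `config`, `causalLoci`, `sequence` and a `manifest`
#'   data.frame (id, op, parents, generation, T-DNA dosage, phenotypes).
#' @seealso [simulatedVariantTable()], [writeSimOutputs()]
#' @export
simulatePedigree <- function(spec, seed = 1L) {
    set.seed(as.integer(seed))
    config <- utils::modifyList(defaultSimConfig(), spec$config %||% list())
    genome <- spec$genome %||% riceGenome()
    causal <- spec$causalLoci %||%
        data.frame(chrom = character(), pos = integer(),
                   label = character(), origin = character())
    plants <- list()
    pools <- list()
    rows <- list()
    panel <- NULL
    getPlant <- function(id) {
        if (is.null(plants[[id]]))
            stop("event refers to undefined plant '", id, "'")
        plants[[id]]
    }
    note <- function(id, op, parents, gen) {
        rows[[length(rows) + 1L]] <<- data.frame(
            id = id, op = op, parents = paste(parents, collapse = ","),
            generation = gen, stringsAsFactors = FALSE)
    }
    genOf <- function(id) {
        for (r in rows) if (r$id == id) return(r$generation)
        0L
    }
    classAt <- function(cond) {
        i <- which(as.character(seqnames(panel)) == cond$chrom &
                       start(panel) == cond$pos)
        if (!length(i)) stop("require condition at unknown marker ",
                             cond$chrom, ":", cond$pos)
        mcols(panel)$class[i[1L]]
    }
    satisfies <- function(plant, require) {
        if (is.null(require)) return(TRUE)
        for (cond in require) {
            if (!is.null(cond$maxDonorShare)) {
                if (ancestryShare(plant) > cond$maxDonorShare)
                    return(FALSE)
                next
            }
            dos <- .dosageAtSites(plant, cond$chrom, cond$pos,
                                  classAt(cond))
            if (!dos %in% cond$dosage) return(FALSE)
        }
        TRUE
    }
    drawUntil <- function(fn, require, maxTries = 2000L) {
        for (k in seq_len(maxTries)) {
            p <- fn()
            if (satisfies(p, require)) return(p)
        }
        stop("could not satisfy 'require' conditions in ", maxTries,
             " draws")
    }
    for (ev in spec$events) {
        op <- ev$op
        if (op == "founders") {
            forced <- causal[causal$origin == "donor", , drop = FALSE]
            f <- makeFounders(genome,
                              donorDensity = ev$donorDensity %||%
                                  config$donorDensity,
                              parent2Density = ev$parent2Density %||%
                                  config$parent2Density,
                              forcedDonorMarkers =
                                  if (nrow(forced)) forced else NULL)
            panel <- f$panel
            plants$recipient <- f$recipient
            plants$donor <- f$donor
            plants$parent2 <- f$parent2
            note("recipient", "founder", character(), 0L)
            note("donor", "founder", character(), 0L)
            note("parent2", "founder", character(), 0L)
        } else if (op %in% c("outcross", "cross")) {
            p1 <- getPlant(ev$p1); p2 <- getPlant(ev$p2)
            plants[[ev$id]] <- drawUntil(
                function() crossPlants(p1, p2, config$lambda, id = ev$id),
                ev$require)
            note(ev$id, op, c(ev$p1, ev$p2),
                 max(genOf(ev$p1), genOf(ev$p2)) + 1L)
        } else if (op == "self") {
            parent <- getPlant(ev$parent)
            gens <- ev$generations %||% 1L
            p <- parent
            for (g in seq_len(gens))
                p <- drawUntil(function() selfPlant(p, config$lambda,
                                                    id = ev$id),
                               if (g == gens) ev$require else NULL)
            plants[[ev$id]] <- p
            note(ev$id, "self", ev$parent, genOf(ev$parent) + gens)
        } else if (op == "tissue_culture") {
            p <- getPlant(ev$parent)
            forced <- causal[causal$origin == "culture", , drop = FALSE]
            res <- applyCultureMutations(p, panel, ev$mu %||% config$mu,
                                         forcedMutations =
                                             if (nrow(forced)) forced else NULL)
            panel <- res$panel
            p <- res$plant
            if (!is.null(ev$tdnaChrom)) {
                res <- insertTdna(p, panel, ev$tdnaChrom, ev$tdnaPos)
                panel <- res$panel
                p <- res$plant
            }
            p@id <- ev$id
            plants[[ev$id]] <- p
            note(ev$id, "tissue_culture", ev$parent, genOf(ev$parent))
        } else if (op == "f2_population") {
            parent <- getPlant(ev$parent)
            ids <- sprintf("%s_%03d", ev$id, seq_len(ev$size))
            for (i in seq_len(ev$size))
                plants[[ids[i]]] <- selfPlant(parent, config$lambda,
                                              id = ids[i])
            pools[[ev$id]] <- ids   # the population itself, for filtering
            note(ev$id, "f2_population", ev$parent, genOf(ev$parent) + 1L)
        } else if (op == "pool") {
            members <- pools[[ev$population]] %||% ev$members
            if (is.null(members)) stop("pool without population/members")
            if (!is.null(ev$label)) {
                hasLabel <- vapply(members, function(id)
                    ev$label %in% phenotypeOf(plants[[id]], panel, causal),
                    logical(1))
                members <- members[hasLabel == (ev$has %||% TRUE)]
            }
            if (length(members) < ev$size)
                stop(sprintf("pool '%s': only %d of %d plants available",
                             ev$id, length(members), ev$size))
            pools[[ev$id]] <- members[seq_len(ev$size)]
            note(ev$id, "pool", ev$population %||% "", genOf(ev$population))
        } else stop("unknown pedigree op: ", op)
    }
    manifest <- do.call(rbind, rows)
    isPlant <- manifest$id %in% names(plants)
    manifest$tdnaDosage <- ifelse(isPlant, vapply(manifest$id, function(id)
        if (id %in% names(plants)) tdnaDosage(plants[[id]]) else NA_integer_,
        0L), NA_integer_)
    manifest$phenotypes <- vapply(manifest$id, function(id) {
        if (!id %in% names(plants)) return(NA_character_)
        paste(phenotypeOf(plants[[id]], panel, causal), collapse = ",")
    }, "")
    structure(list(plants = plants, pools = pools, panel = panel,
                   genome = genome, config = config, causalLoci = causal,
                   sequence = spec$sequence %||% names(plants),
                   manifest = manifest),
              class = "simPedigree")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default simulation parameters
#'
#' Central defaults of the forward simulator: crossover mean `lambda = 1.25`
#' per chromosome per meiosis, tissue-culture mutation rate `mu = 1.5e-6`
#' per site per diploid genome (inside the measured somaclonal range of
#' 8.9--21.0 x 10^-7), mean sequencing depth 15 for single plants and for
#' 20-plant pools, base-error rate 0.005, and genotype-call thresholds
#' `minDepth = 4`, `homFrac = 0.8`.
#'
#' @return named list of parameters.
#' @export
defaultSimConfig <- function() {
    list(lambda = 1.25, mu = 1.5e-6, depthMean = 15, poolDepth = 15,
         errorRate = 0.005, minDepth = 4L, homFrac = 0.8,
         donorDensity = 2e-3, parent2Density = 1.7e-4)
}

#' Pedigree preset mimicking the studied transformant line
#'
#' The reconstructed history of the studied line: a spontaneous outcross of
#' the *japonica* recipient to an *indica* donor one generation before the
#' seed entered tissue culture, so the regenerant (T0) is an F2 and the
#' T1/T2/T3 plants are F3/F4/F5 equivalents. Tissue culture adds the T-DNA
#' insertion and somaclonal point mutations, among them the recessive
#' tillering-dwarf SNP; a recessive grain-size locus rides on the donor
#' haplotype. The roster of named plants reproduces the observed zygosity
#' pattern (T-DNA hom in T1c/T2a, het in T1a/T1b, azygous in T2b/T3a/T3b),
#' and a mapping cross of a large-grain T2 plant to a second *japonica*
#' parent yields an F2 population with 20-plant wild-type and large-grain
#' DNA pools. Two sequenced TRIM-like regenerant controls and a genome-wide
#' heterozygous outcross regenerant are included.
#'
#' @param genome a [GenomeInfoDb::Seqinfo] (default desk-scale 12 x 2.5 Mb).
#' @param f2Size F2 mapping-population size (default 200; the pools draw 20
#'   plants per phenotype from it).
#' @param config overrides merged over [defaultSimConfig()].
#' @return a pedigree spec for [simulatePedigree()].
#' @export
m0028590Pedigree <- function(genome = riceGenome(), f2Size = 200L,
                             config = list()) {
    lens <- .chromLengths(genome)
    if (length(lens) < 4L)
        stop("the preset needs at least 4 chromosomes")
    relPos <- function(chr, frac) as.integer(round(lens[[chr]] * frac))
    gs3 <- list(chrom = "chr3", pos = relPos("chr3", 0.385))   # grain locus
    d17 <- list(chrom = "chr4", pos = relPos("chr4", 0.637))   # dwarf locus
    tdna <- list(chrom = "chr3", pos = relPos("chr3", 0.70))
    # control-line T-DNA landing chromosomes, wrapped for small genomes
    ctrlChr1 <- names(lens)[(4L %% length(lens)) + 1L]
    ctrlChr2 <- names(lens)[(5L %% length(lens)) + 1L]
    causal <- data.frame(
        chrom = c(gs3$chrom, d17$chrom), pos = c(gs3$pos, d17$pos),
        label = c("large-grain", "tillering-dwarf"),
        origin = c("donor", "culture"), stringsAsFactors = FALSE)
    req <- function(locus, dosage) list(chrom = locus$chrom,
                                        pos = locus$pos, dosage = dosage)
    events <- list(
        list(op = "founders"),
        list(op = "outcross", id = "F1", p1 = "recipient", p2 = "donor"),
        # the seed that entered tissue culture: grain locus still het, and
        # a minority donor share as observed in the studied line
        list(op = "self", id = "F2seed", parent = "F1",
             require = list(req(gs3, 1L),
                            list(maxDonorShare = 0.35))),
        list(op = "tissue_culture", id = "T0", parent = "F2seed",
             tdnaChrom = tdna$chrom, tdnaPos = tdna$pos),
        # TRIM-like regenerant controls from the clean recipient
        list(op = "tissue_culture", id = "ctrlTRIM1", parent = "recipient",
             tdnaChrom = ctrlChr1, tdnaPos = relPos(ctrlChr1, 0.3)),
        list(op = "tissue_culture", id = "ctrlTRIM2", parent = "recipient",
             tdnaChrom = ctrlChr2, tdnaPos = relPos(ctrlChr2, 0.6)),
        # a regenerant from an un-selfed outcross: heterozygous genome-wide
        list(op = "outcross", id = "RF1", p1 = "recipient", p2 = "donor"),
        list(op = "tissue_culture", id = "RegenerantR", parent = "RF1"),
        # T1 plants conditioned on the observed zygosity roster
        list(op = "self", id = "T1a", parent = "T0",
             require = list(req(gs3, 0:1), req(d17, 0:1), req(tdna, 1L))),
        list(op = "self", id = "T1b", parent = "T0",
             require = list(req(gs3, 1L), req(d17, 1L), req(tdna, 1L))),
        list(op = "self", id = "T1c", parent = "T0",
             require = list(req(gs3, 2L), req(d17, 2L), req(tdna, 2L))),
        list(op = "self", id = "T2a", parent = "T1a",
             require = list(req(gs3, 0L), req(d17, 0L), req(tdna, 2L))),
        list(op = "self", id = "T2b", parent = "T1b",
             require = list(req(gs3, 1L), req(d17, 2L), req(tdna, 0L))),
        list(op = "self", id = "T3a", parent = "T2b",
             require = list(req(gs3, 1L))),
        list(op = "self", id = "T3b", parent = "T2b",
             require = list(req(gs3, 1L))),
        # mapping cross: a large-grain T2 sib x the second japonica parent
        list(op = "self", id = "T2lg", parent = "T1c",
             require = list(req(gs3, 2L))),
        list(op = "cross", id = "F1map", p1 = "T2lg", p2 = "parent2"),
        list(op = "f2_population", id = "F2map", parent = "F1map",
             size = as.integer(f2Size)),
        list(op = "pool", id = "wtPool", population = "F2map",
             label = "large-grain", has = FALSE, size = 20L),
        list(op = "pool", id = "lgPool", population = "F2map",
             label = "large-grain", has = TRUE, size = 20L))
    list(genome = genome, config = config, causalLoci = causal,
         events = events,
         sequence = c("recipient", "parent2", "donor", "ctrlTRIM1",
                      "ctrlTRIM2", "T1a", "T1b", "T1c", "T2a", "T2b",
                      "T3a", "T3b", "RegenerantR", "T2lg", "wtPool",
                      "lgPool"),
         tdna = tdna, gs3 = gs3, d17 = d17)
}

#' Sequence a simulated pedigree into a VariantTable
#'
#' Draws read counts for the requested samples (plants at `depthMean`,
#' pools at `poolDepth`) and calls genotypes with the configured
#' thresholds.
#'
#' @param sim result of [simulatePedigree()].
#' @param samples sample ids to sequence; default the spec's `sequence`
#'   roster. Pool ids yield pooled counts over their member plants.
#' @param config overrides merged over the simulation's config.
#' @return a [VariantTable] whose metadata records the config used.
#' @export
simulatedVariantTable <- function(sim, samples = sim$sequence,
                                  config = list()) {
    cfg <- utils::modifyList(sim$config, config)
    units <- lapply(samples, function(id) {
        if (id %in% names(sim$pools))
            return(unname(sim$plants[sim$pools[[id]]]))
        if (id %in% names(sim$plants)) return(sim$plants[[id]])
        stop("unknown sample '", id, "'")
    })
    names(units) <- samples
    dos <- dosageMatrix(units, sim$panel)
    isPool <- samples %in% names(sim$pools)
    reads <- sampleReads(dos[, !isPool, drop = FALSE],
                         cfg$depthMean, cfg$errorRate)
    ref <- matrix(NA_integer_, nrow(dos), ncol(dos),
                  dimnames = dimnames(dos))
    alt <- ref
    ref[, !isPool] <- reads$ref
    alt[, !isPool] <- reads$alt
    if (any(isPool)) {
        readsP <- sampleReads(dos[, isPool, drop = FALSE],
                              cfg$poolDepth, cfg$errorRate)
        ref[, isPool] <- readsP$ref
        alt[, isPool] <- readsP$alt
    }
    gt <- genotypeFromCounts(ref, alt, cfg$minDepth, cfg$homFrac)
    vt <- makeVariantTable(sim$panel, gt, ref, alt)
    metadata(vt)$simConfig <- cfg
    vt
}

#' Write simulator outputs to disk
#'
#' Emits the VCF (via [emitVcf()]), the truth ancestry segments of every
#' named plant as a BED file whose name column is
#' `plant|haplotype|ancestry`, and the pedigree manifest as TSV.
#'
#' @param sim result of [simulatePedigree()].
#' @param vt the matching [VariantTable] from [simulatedVariantTable()].
#' @param dir output directory (created if needed).
#' @return named character vector of the files written.
#' @export
writeSimOutputs <- function(sim, vt, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    vcf <- file.path(dir, "simulated.vcf")
    emitVcf(vt, vcf)
    named <- sim$manifest$id[sim$manifest$op != "f2_population" &
                                 sim$manifest$op != "pool"]
    truth <- do.call(c, lapply(named, function(id) {
        hr <- haplotypeRanges(sim$plants[[id]])
        mcols(hr)$name <- paste(id, hr$haplotype, hr$ancestry, sep = "|")
        hr[, "name"]
    }))
    bed <- file.path(dir, "truth_segments.bed")
    writeBed(truth, bed)
    man <- file.path(dir, "manifest.tsv")
    utils::write.table(sim$manifest, man, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    c(vcf = vcf, truth = bed, manifest = man)
}

#' Simulate a bulk-segregant mapping experiment
#'
#' The mapping design behind the SNP-index analysis: a mutant parent
#' carrying a fully penetrant recessive causal allele (homozygous) is
#' crossed to a second inbred parent segregating `~density x genome`
#' biallelic markers; F2 plants are phenotyped and two DNA pools (mutant
#' and phenotypic wild type) are sequenced. Returned counts are oriented so
#' the "mutant SNP" allele --- the allele diagnostic for the mutant parent
#' --- is the counted allele at every marker, fixed at table construction.
#'
#' @param genome a [GenomeInfoDb::Seqinfo].
#' @param markerDensity informative markers per bp (default `1.7e-4`,
#'   ~5,000 markers on the desk-scale genome).
#' @param causalChrom,causalPos the recessive causal locus.
#' @param nF2 F2 population size (default 300).
#' @param poolSize plants per pool (default 20).
#' @param depthMean mean pool sequencing depth (default 15).
#' @param errorRate per-base error rate (default 0.005).
#' @param lambda crossovers per chromosome per meiosis.
#' @return list with `counts` --- data.frame `chrom`, `pos`,
#'   `mutMutant`/`totalMutant`, `mutWt`/`totalWt` (mutant-allele and total
#'   reads per pool) --- plus `causal`, `phenotype` (per-F2 labels),
#'   `genome`, and the pool member indices.
#' @export
simulateBsaExperiment <- function(genome = riceGenome(),
                                  markerDensity = 1.7e-4,
                                  causalChrom = "chr3", causalPos = NULL,
                                  nF2 = 300L, poolSize = 20L,
                                  depthMean = 15, errorRate = 0.005,
                                  lambda = 1.25) {
    lens <- .chromLengths(genome)
    if (is.null(causalPos))
        causalPos <- as.integer(round(lens[[causalChrom]] / 2))
    sites <- do.call(rbind, lapply(names(lens), function(chr) {
        n <- min(stats::rpois(1L, markerDensity * lens[[chr]]), lens[[chr]])
        data.frame(chrom = chr, pos = sort(sample.int(lens[[chr]], n)),
                   stringsAsFactors = FALSE)
    }))
    sites <- sites[!(sites$chrom == causalChrom & sites$pos == causalPos), ]
    chrom <- c(sites$chrom, causalChrom)
    pos <- c(sites$pos, as.integer(causalPos))
    class <- rep(c("parent2-diagnostic", "culture-mutation"),
                 c(nrow(sites), 1L))
    panel <- .panelFromSites(genome, chrom, pos, class)
    mutantParent <- .foundPlant("mutantParent", genome, "recipient")
    causalExtra <- data.frame(chrom = causalChrom,
                              pos = as.integer(causalPos),
                              class = "culture-mutation",
                              stringsAsFactors = FALSE)
    mutantParent@haplotypes[[1]]$extras <- causalExtra
    mutantParent@haplotypes[[2]]$extras <- causalExtra
    parent2 <- .foundPlant("parent2", genome, "parent2")
    f1 <- crossPlants(mutantParent, parent2, lambda, id = "F1")
    f2 <- lapply(seq_len(nF2), function(i)
        selfPlant(f1, lambda, id = sprintf("F2_%04d", i)))
    causalDosage <- vapply(f2, function(p)
        .dosageAtSites(p, causalChrom, as.integer(causalPos),
                       "culture-mutation"), 0L)
    phenotype <- ifelse(causalDosage == 2L, "mutant", "wildtype")
    mutIdx <- which(phenotype == "mutant")
    wtIdx <- which(phenotype == "wildtype")
    if (length(mutIdx) < poolSize || length(wtIdx) < poolSize)
        stop(sprintf("nF2 = %d yielded %d mutant / %d wild-type plants; need %d per pool",
                     nF2, length(mutIdx), length(wtIdx), poolSize))
    pools <- list(mutPool = f2[mutIdx[seq_len(poolSize)]],
                  wtPool = f2[wtIdx[seq_len(poolSize)]])
    dos <- dosageMatrix(pools, panel)
    reads <- sampleReads(dos, depthMean, errorRate)
    # orient to the mutant-parent allele: at parent2-diagnostic markers the
    # mutant parent carries REF; at the causal site it carries ALT
    mutantIsAlt <- mcols(panel)$class == "culture-mutation"
    orient <- function(pool) {
        mut <- ifelse(mutantIsAlt, reads$alt[, pool], reads$ref[, pool])
        data.frame(chrom = as.character(seqnames(panel)),
                   pos = start(panel), mut = as.integer(mut),
                   total = as.integer(reads$ref[, pool] + reads$alt[, pool]),
                   stringsAsFactors = FALSE)
    }
    m <- orient("mutPool"); w <- orient("wtPool")
    counts <- data.frame(chrom = m$chrom, pos = m$pos,
                         mutMutant = m$mut, totalMutant = m$total,
                         mutWt = w$mut, totalWt = w$total,
                         stringsAsFactors = FALSE)
    list(counts = counts,
         causal = list(chrom = causalChrom, pos = as.integer(causalPos)),
         phenotype = phenotype, genome = genome,
         poolMembers = list(mutPool = mutIdx[seq_len(poolSize)],
                            wtPool = wtIdx[seq_len(poolSize)]))
}
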