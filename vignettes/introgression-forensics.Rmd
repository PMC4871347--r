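---
title: "Forensics of unintended introgression in a T-DNA rice line: models and methods"
author: "introTrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forensics of unintended introgression in a T-DNA rice line}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(introTrace)
```

## The problem

Insertional mutant collections (such as T-DNA populations in rice) are
screened on the assumption that a mutant phenotype co-segregates with the
insertion. In practice a line can carry phenotypes with entirely different
causes: a spontaneous outcross to a neighbouring *indica* variety one or two
generations before tissue culture leaves large chromosome segments of donor
origin ("introgression"), and the tissue-culture passage itself introduces
somaclonal point mutations. Both can produce heritable phenotypes that have
nothing to do with the transgene.

`introTrace` implements the post-variant-calling forensic analysis of such a
line: detecting and delimiting donor segments from multi-sample SNP calls,
classifying their zygosity and tracking them over selfing generations,
mapping a recessive trait by bulk-segregant SNP-index analysis, screening
SNPs that co-segregate with a phenotype, and checking donor/recipient
clustering on an allele-sharing phylogeny. A forward simulator of the
crossing/tissue-culture history generates data with known haplotype truth,
so every stage is testable without any sequencing download.

## The forward simulator

The simulator models a diploid genome as a per-chromosome mosaic of ancestry
segments (`recipient`, `donor`, `parent2`). Its components:

* **Marker panel.** Founders differ at biallelic SNP markers placed by a
  Poisson process: the *indica* donor at `donorDensity` (default
  2×10⁻³/bp, echoing the millions of SNPs that separate an indica variety
  from a japonica reference, desk-scaled) and a second *japonica* mapping
  parent at `parent2Density` (default 1.7×10⁻⁴/bp, echoing the tens of
  thousands of SNPs in a japonica × japonica cross, which on the default
  genome yields the ~5,000 informative markers used in the mapping
  analyses).
* **Meiosis.** Per chromosome the crossover count is Poisson with mean
  `lambda` (default 1.25 ≈ rice map length spread over 12 chromosomes),
  breakpoints are uniform, and the gamete alternates parental copies from a
  fair-coin start. No crossover interference — the simplest model consistent
  with the observed generation-to-generation recombination.
* **Tissue culture.** Somaclonal point mutations arrive at rate `mu` per
  site per diploid genome (default 1.5×10⁻⁶, inside the measured range of
  8.9–21.0×10⁻⁷ for this material), each heterozygous in the regenerant on
  one random haplotype. The T-DNA is a presence/absence pseudo-marker
  carried on one haplotype; it segregates Mendelianly and its
  flanking-sequence mechanics are out of scope.
* **Phenotype.** Causal loci are fully penetrant recessives: the label is
  asserted exactly when both haplotypes carry the causal allele. One causal
  locus (grain size) rides on a donor haplotype; the other (tillering
  dwarf) is a culture mutation.
* **Reads.** Per site and sample, depth ~ Poisson(`depthMean`, default 15,
  matching the study's per-sample coverage) and alternate reads ~
  Binomial(depth, p′) with p = dosage/2 and p′ = p(1−e) + (1−p)e for
  base-error e (default 0.005). Pools are modeled at the allele-dosage
  level — the mean dosage of the 20 member plants — which is equivalent to
  read-level mixing under binomial sampling. Genotypes are re-called from
  counts with explicit thresholds (missing below depth 4; homozygous beyond
  an allele fraction of 0.8), because the original variant-caller defaults
  are not reproducible; all thresholds are configurable.
* **Pedigree.** `simulatePedigree()` interprets a declarative event list
  (founders, outcross, self, tissue culture, cross, F2 population, pool).
  Events may carry `require` conditions (genotypes at named loci, or a
  bound on the truth donor share); the event is redrawn until satisfied.
  This conditions the simulation on what was actually observed in the
  studied line — e.g. the preset's tissue-culture seed is heterozygous at
  the grain locus and carries a minority (≤ 35%) donor share, matching a
  line whose realized introgression summed to about a quarter of the
  genome.

The default genome is 12 chromosomes of 2.5 Mb ("desk scale") so that the
full pipeline runs in seconds; all sizes are configurable, and several
property tests run on smaller configured genomes (stated below). Every
simulated plant exposes its haplotype truth (`haplotypeRanges()`,
`truthSegments()`, `ancestryShare()`) so detector output can be scored
against it.

What the generator does *not* emulate: read-level artifacts (mapping bias,
indels, base-quality structure), segregation distortion and selection
during tissue culture, epigenetic somaclonal variation, and donor-panel
uncertainty (the donor is a single specified haplotype; the original study
could not identify the exact donor variety among local *indica*
candidates). Passing tests therefore demonstrate the correctness of the
*inference rules* under the stated stochastic model, not robustness to
alignment artifacts in real resequencing data.

## Introgression detection

Detection follows the published rule set, made explicit:

1. **Density screen.** Non-reference calls are counted in 2-Mb windows
   sliding by 5 kb (both configurable); truncated trailing windows are
   rescaled to SNPs per 2 Mb.
2. **High windows.** A window is "high" when the sample density reaches an
   absolute floor (`minAbs`, default 20 SNPs/2 Mb) *and* exceeds `fold`
   (default 10) times the maximum control density, controls floored at
   1 SNP/2 Mb. The original screen judged "high" by eye in a genome
   browser; these two numbers are this package's explicit stand-ins. The
   floor is set at 20 so that any segment carrying the guaranteed minimum
   of 20 sample-specific SNPs can clear it — a larger floor would
   contradict the detection guarantee the test suite enforces.
3. **Borders.** Within each merged run of high windows, borders are placed
   exactly 10 kb outside the outermost *sample-specific* SNP (non-reference
   in the focal sample, reference or missing in every control), clipped at
   chromosome ends. Because a 2-Mb window bridges nearby events, a run is
   first split wherever consecutive sample-specific SNPs are more than
   `maxGap` (default 100 kb) apart — at the default donor marker spacing of
   ~500 bp, a 100-kb SNP desert is unambiguous recipient material.
   Events with fewer than `minRegionSnps` (default 10) SNPs are dropped
   with a message.
4. **Zygosity.** A region is heterozygous when ≥ 80% of its non-reference
   calls are heterozygous, homozygous when ≤ 20%, otherwise mixed; mixed
   regions are split recursively at the boundary of their longest
   same-zygosity run while both halves keep `minRegionSnps` SNPs —
   chromosomes in this material really do carry adjacent het and hom
   introgression blocks.
5. **Donor similarity** is the fraction of the sample's non-reference sites
   in the region at which the donor carries the same alternate allele
   (≈ 1 for introgressed material, 0 for culture mutations).

A 100-kb heterozygosity profile supports a genome-state classifier:
`genome_wide_heterozygous` (≥ 90% of bins above a het floor — the signature
of a regenerant from an un-selfed outcross), `clean` (no regions, ≤ 1% of
bins above the floor) or `segmental_introgression`.

## Lineage arithmetic

Fractions of the genome covered by introgression regions (any / hom / het,
per chromosome and overall, and the union over plants) are plain interval
arithmetic over `GRanges`. The generation of the founding outcross is
inferred from heterozygosity decay: material heterozygous in the F1 remains
heterozygous with probability (½)^g after g selfing generations, the two
homozygous states absorbing the rest symmetrically. Crucially, the het
fraction must be taken over *all* initially heterozygous material —
including segments since fixed back to the recipient — because only that
denominator decays as (½)^g; conditioning on "still donor-containing"
material would converge to 0.4 at g = 2 rather than 0.25. For detected (not
simulated) data the family-level union of introgression regions
approximates that denominator, which is why the recovery test averages the
het fraction over a family of 24 simulated sibs per seed rather than a
single plant. Region identity across generations is tracked by reciprocal
overlap ≥ 0.5, yielding het→het / het→hom / het→lost / hom→hom
trajectories.

## Bulk-segregant SNP index

For a mapping cross between the mutant line and a second inbred parent, the
"mutant SNP" allele at each informative marker (both parents homozygous and
different) is fixed at table construction as the allele carried by the
mutant parent. The per-marker SNP index is mutant reads / total reads,
undefined below 5 total reads. Smoothing averages a moving window of 20
consecutive *defined* markers, shifting one marker at a time; windows are
anchored at the midpoint of their first and last marker (the source
figure legends describe a "midpoint between the first and fifth SNP",
which cannot be literal for a 20-SNP window — the choice made here is
recorded in the track's attributes). The two pool tracks are aligned on
the markers defined in both pools before smoothing so that peak calling
compares identical windows.

Peaks are maximal runs of ≥ 5 windows with mutant index ≥ 0.9 and
wild-type index ≤ 0.7 — explicit stand-ins for a contrast the original
analysis read off a plot (mutant pool approaching 1 against a wild-type
pool near 0.4). Under the Mendelian model the wild-type pool at the causal
locus is expected at 1/3 (1 AA : 2 Aa among phenotypic wild types); the
observed "about 0.4" is consistent with that expectation at the study's
sequencing depth, and the test suite asserts convergence to 1/3 on
simulation rather than treating 0.4 as ground truth. The exact-value claim
— the affected pool's smoothed index equals 1.0 with error rate 0 — holds
only where the whole 20-SNP window is fully linked to the causal locus;
with ~5,000 genome-wide markers a window spans ~120 kb and the 40 pooled
chromosomes carry on average more than one local recombinant. The test
therefore verifies exactness on a tightly linked marker cluster (± 3 kb)
and verifies the raw index of exactly 1.0 at the causal marker itself in
the genome-wide setting.

## Co-segregation screen and effect classifier

The candidate filter is the exact zygosity pattern used to find the dwarf
mutation, not an association statistic: keep SNPs homozygous-alternate in
*all* affected plants and not homozygous-alternate in *any* unaffected
plant, tolerating missing calls in at most `maxMissing` samples (default
0). On a segregating introgressed background many linked donor SNPs satisfy
the pattern — as they did in the original material — so the report ranks
candidates by coding effect. The effect classifier is deliberately minimal:
strand-aware codon translation through the standard genetic code
(synonymous / nonsynonymous / stop gained), ± 2 intronic bp at exon
boundaries as splice sites (the canonical GT/AG positions), and
frameshift for CDS length changes not divisible by 3; in-frame length
changes are reported as nonsynonymous, and the initiator codon is
translated like any other (start-loss is not a separate class). It is
validated against whole-CDS translation of 1,000 random SNPs in random toy
genes.

## Phylogeny check

The allele-sharing distance between two samples is the mean of
|dosage_i − dosage_j|/2 over shared genotyped sites (pairwise deletion,
≥ 100 shared sites required), optionally restricted to a region set. Trees
are built with a direct neighbor-joining implementation (Q-criterion,
Studier–Keppler updates, negative branches clamped at zero and the deficit
recorded) in place of the original ML pipeline: the claim under test is
*clustering*, which this distance supports at desk scale, and the
implementation is cross-checked against an independent NJ implementation
on random additive matrices. Placement midpoint-roots the tree and assigns
each focal sample to the group dominating its smallest enclosing clade,
walking rootward past ties.

The characteristic signature — a tree restricted to introgressed regions
places the offspring with the donor group while the whole-genome tree
places it with the recipient group — only holds for plants whose realized
introgression covers a minority of the genome, as in the studied line
(26.4% summed over seven plants). An unconditioned F2-descendant has an
expected donor share of 50%, making whole-genome placement a coin flip;
the flip test therefore conditions each simulated offspring on a truth
donor share between 0.10 and 0.35. For region-restricted trees over
several focal plants the pipeline uses the regions introgressed in *every*
focal plant, the same construction as the published analysis region.

## Numerical and testing choices

* Coordinates are 1-based closed everywhere inside the package (the VCF
  convention); BED conversion happens only at the file boundary, via
  `rtracklayer`. Indels are parsed but excluded from SNP statistics.
* The VCF writer is plain deterministic text (no timestamp) so a fixed
  seed reproduces byte-identical output; round-trips are verified through
  the independent `VariantAnnotation` parser.
* Genotype-call thresholds treat the 0.8 boundary as homozygous with a
  square-root-machine-epsilon guard, so 8/10 alternate reads is a
  homozygous call on every platform.
* Problem sizes in the test suite: the detector-recovery and clean-self
  properties run 100 seeds on a 6 × 1.5 Mb genome at depth 30 without
  read errors; generation inference runs 30 seeds × g ∈ {0…4} on a
  6 × 1 Mb genome (~12,000 donor markers) with 24-plant families; the
  placement flip runs 50 seeds on a 4 × 1 Mb genome; bulk-segregant
  neutrality uses the full default genome. These sizes were chosen so the
  whole suite completes on one CPU in minutes while each stochastic band
  retains the stated 3-SE (or 95%-of-seeds) resolution.
* The pipeline preset (`m0028590Pedigree()`) reproduces the studied line's
  roster — three T1, two T2 and two T3 plants with the observed T-DNA
  zygosity pattern, two TRIM-like regenerant controls, a genome-wide
  heterozygous regenerant, and an F2 mapping population with 20-plant
  wild-type and large-grain pools — so `runAll()` exercises every stage on
  one coherent dataset.

## Known limitations

The detector's absolute floor, fold change, peak thresholds and het-count
floor are explicit replacements for judgments the original analysis made
visually; they are configurable and recorded in every run's resolved
configuration, but they are not fitted to data. The generation estimate
assumes neutral selfing with no selection against donor material. The union
introgression fraction of the simulated preset is not calibrated to the
published 26.4% — that number is tied to the original line's realized
recombination history and is deliberately not a target. Pedigree
reconstruction beyond a single outcross followed by selfing, donor-panel
assignment, and statistical association testing for candidates are out of
scope.
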