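---
title: "Methods: linkage-map construction and consensus merging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linkage-map construction and consensus merging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mapforge)
library(dplyr)
```

mapforge builds genetic linkage maps from recombinant inbred line (RIL)
genotype matrices and merges maps from several populations into a single
consensus map, the workflow used for high-density SNP maps in allopolyploid
crops such as hexaploid wheat (genomes A, B and D; homoeologous groups
1–7). This vignette is the package's account of the statistical model, the
algorithmic choices, the tunable parameters, and what the bundled synthetic
data generator does and does not emulate.

## The RIL model and the two-point engine

A selfed RIL panel descends from an F1 between two inbred parents; after
$g$ generations of selfing each line is a near-homozygous mosaic of the two
parental genomes. The observed fraction $R$ of recombinant *lines* between
two loci overstates the per-meiosis recombination fraction $r$ because
recombinants accumulate over successive generations. At complete inbreeding
the Haldane–Waddington relation holds:

$$R = \frac{2r}{1 + 2r}, \qquad r = \frac{R}{2(1 - R)}.$$

`estimate_pair()` counts recombinant lines over lines with homozygous calls
at both markers ($\hat R = k/n$, capped at 0.5), inverts the relation above
(`ril_to_meiotic()`), and scores linkage with the base-10 LOD of the
binomial likelihood at $\hat R$ against independence ($R = 0.5$):

$$\mathrm{LOD} = k \log_{10} \hat R + (n - k) \log_{10}(1 - \hat R)
  - n \log_{10} 0.5 .$$

Numerical choices:

* For $k = 0$ the likelihood is maximized on the boundary; $\hat R$ is
  floored at $1/(2n)$ for the LOD evaluation so that zero-recombinant pairs
  score a finite, large LOD rather than an infinity.
* Heterozygous calls are excluded from pair counts, consistent with the QC
  rule that masks them (below).
* F6/F8 RILs are treated as fully inbred for the $R \leftrightarrow r$
  transform. Generation-specific corrections change two-point distances by
  under a percent at these generations, and the package's job is a single
  documented convention rather than a per-population adjustment.

Distances come from the Kosambi mapping function by default,
$d = 25\,\ln\{(1+2r)/(1-2r)\}$ cM, with Haldane
($d = -50\,\ln(1-2r)$) available by configuration. The tool chain this
workflow descends from defaults to Kosambi; both closed forms are exposed in
`map_distance()` and fractions at or above 0.5 are capped at a configurable
maximum distance with a warning rather than an error.

## Genotype quality control

`apply_qc()` applies three rules in a fixed order: (i) heterozygous calls
become missing; (ii) markers with a missing fraction strictly above
`max_missing_rate` (default 0.10, i.e. "over 10%" drops) are removed;
(iii) markers whose allele-A frequency over the remaining non-missing calls
lies outside `[0.3, 0.7]` (inclusive bounds) are removed. The frequency is
computed after heterozygote masking because the rules are stated — and
therefore applied — in that order. Both boundary conventions are documented
here and asserted exactly in the tests; the attrition report
(`qc_report()`) records every count so the conventions are auditable.

## Building one map per population

`build_map()` runs four steps:

1. **Recombinant bins** (`bin_markers()`): markers with zero observed
   recombinants ($k = 0$ over at least one informative line) are clustered
   by single linkage. The zero-recombinant relation is not transitive under
   missing data; the transitive closure absorbs that. Using observed
   $k = 0$ rather than a recombination-fraction threshold matches the
   convention that a bin is a set of markers with recombination frequency
   estimated as zero. Each bin elects the member with the least missing
   data as its *frame marker* (ties broken by a seeded random draw).
2. **Grouping** (`group_markers()`): frame markers join a group when
   connected by a chain of pairs with LOD at or above `lod_threshold`
   (default 7). This is a single-linkage closure; node-splitting variants
   of the grouping test exist in other software, but only the threshold is
   documented for this workflow, so the simplest closure is used and stated.
   Frames in no qualifying pair are reported unlinked.
3. **Ordering** (`order_markers()`): seriation minimizing SARF, the sum of
   adjacent meiotic recombination fractions. A greedy nearest-neighbour
   chain is refined by 2-opt segment reversals and an exhaustive
   sliding-window ripple (window 4) until neither improves. The upstream
   ordering tool is a black box, so the package's algorithm is validated
   instead by an exhaustive-permutation oracle: on groups of up to 8
   markers the test suite checks that the seriation attains the global SARF
   minimum (50 simulated groups per run).
4. **Assembly** (`assemble_map()`): positions are cumulative Kosambi
   distances between adjacent frames (nonnegative by construction), binned
   markers re-enter at their frame's position, and, when an anchor table is
   supplied, each group is assigned to the chromosome carried by the
   majority of its members (ties leave it unassigned with a warning) and
   oriented along increasing anchor position. Without anchors, orientation
   is canonicalized so the first marker name sorts before the last — group
   orientation is otherwise arbitrary, and a fixed convention makes output
   reproducible.

## Consensus merging

`build_consensus()` merges chromosome-assigned maps one chromosome at a
time:

* **Graph union** (`maps_to_dag()`): each linkage group contributes the
  directed path of its markers in map order, with equal weight 1 per map;
  co-positioned markers are chained in name order at distance zero. Edges
  accumulate a support count and a mean distance. A chromosome split into
  several groups in one population contributes several independent paths.
  Paths are accreted onto the union multi-pass, so a path connected only
  through later maps is still retained; a path sharing no marker with the
  rest is excluded with a warning. A path whose order over three or more
  shared markers runs against its best-overlapping neighbour is flipped
  before merging — a reversed two-marker overlap is indistinguishable from
  a local order conflict and is left to conflict resolution instead.
* **Conflict resolution** (`resolve_conflicts()`): while any strongly
  connected component has more than one vertex, the within-component edge
  with minimal support is deleted (ties: larger distance, then
  lexicographic), and logged. Deleting weak *edges* rather than vertices
  keeps every marker mapped, which is the property the published maps have;
  the log makes each deletion auditable.
* **Linearization** (`linearize_dag()`): the consensus order is a
  topological sort with ties broken by mean anchored source position, then
  name. The position of a marker is the mean of its positions across source
  maps after each map is shifted so that its first marker already placed by
  earlier maps lands on the running mean for that marker. The mean profile
  is then projected onto the consensus order by pool-adjacent-violators
  (isotonic regression, `stats::isoreg`) and shifted to start at zero. The
  upstream merging tool names its linearization a "mean distance
  approximation" without defining it; the mean-plus-isotonic realization is
  this package's documented stand-in, chosen because it is exact for
  consistent inputs — the consensus of a single map reproduces that map to
  numerical precision, a property the tests assert at $10^{-9}$ cM.
* **Rescaling** (`rescale_map()`): merged maps inflate distances; for each
  source map the ordinary least-squares slope of consensus positions on
  source positions over shared markers is computed, and consensus positions
  are divided by the unweighted mean of the slopes (equal weights again).
  Degenerate regressions (fewer than two shared markers, zero variance) are
  skipped with a warning.

Markers at identical consensus positions form recombinant bins.
`consensus_summary()` aggregates markers, bins, length and density per
chromosome, genome letter and homoeologous group, parsing wheat-style
chromosome names (`parse_chromosome()`; other nomenclatures are supplied as
an explicit lookup table rather than guessed).

Printed map statistics round half away from zero (densities to 2 decimals,
coverages to 1), implemented in `round_half_up()` because base R rounds
half to even; this convention reproduces published per-chromosome densities
exactly and is asserted in the acceptance tests.

## Validation, duplication and anchoring statistics

`spearman_order()` computes rank correlations of shared-marker positions
(mid-ranks for ties, undefined below 3 shared markers).
`classify_vs_reference()` labels query markers consistent / inconsistent
(chromosome level — the granularity at which such comparisons are
published) / new, with rank correlations on consistent markers only.
`venn_sharing()` counts markers by the number of maps containing them;
`interval_profile()` counts markers and bins in half-open windows anchored
at 0 cM (default 5 cM; the anchoring convention is fixed here for
reproducibility), reports adjacent-position gaps above a threshold (default
10 cM, strictly greater) and the per-chromosome Pearson correlation between
the marker and bin distributions.

Multi-locus assays — single array probes genotyping several genome
positions — drive the rearrangement analysis. `expand_pairs()` emits all
$m(m-1)/2$ unordered locus pairs per assay; `classify_pairs()` labels each
pair homoeologous (same group, different genome, e.g. 1A–1B), intra-genomic
(same genome, different group, 1A–2A) or inter-genomic (different both,
1A–2B). Two loci of one assay on the same chromosome are not evidence of
rearrangement between chromosomes and are excluded from the categories but
returned separately. All loci of an assay are treated symmetrically; no
locus is designated the "true" signal.

Anchoring consumes precomputed homology hits in the 12-column tabular
format. `best_hit()` keeps hits with E-value strictly below `1e-10` and
selects the minimum-E-value hit per marker (ties: higher identity, then
lexicographic subject), so output is stable under row reordering.
`assign_bins()` joins markers to chromosome deletion bins through linked
ESTs, deduplicating ESTs within a chromosomal location and excluding (but
logging) links whose bin chromosome contradicts the marker's map
chromosome; coverage is the percentage of a chromosome's bins hit.

## The synthetic RIL panel generator

`simulate_true_map()`, `simulate_population()` and `make_panel()` exist so
that the full pipeline can be tested against a known truth. The meiosis
model has no crossover interference: crossover counts per chromosome are
Poisson(length/100) with uniform breakpoints, which makes counts in
disjoint marker intervals independent Poissons — the implementation
exploits this for vectorization, and it gives closed-form two-point
expectations (Haldane distances; RIL fraction $2r/(1+2r)$) that the test
suite checks the simulator against within three binomial standard errors
on pooled replicates of 10,000 lines.

Selfing is simulated generation by generation rather than by sampling the
limiting RIL distribution, so residual heterozygosity halves per generation
and F2:6 versus F2:8 panels genuinely differ. The probability that a truly
heterozygous genotype is *reported* as `H` is `residual_het_rate`
(default 1, faithful reporting; 0 resolves heterozygotes to a random
homozygote). Observed per-population heterozygosity is not published for
the motivating study, so it is a free parameter rather than a calibrated
one. Genotyping errors are symmetric allele flips applied after
inheritance and before missingness; the order only matters in the second
decimal of realistic error rates and is fixed for reproducibility.

Multi-locus assays are emitted as one genotyped locus (the *primary*) plus
a registry of all true loci per assay, mirroring a single probe
hybridizing at several positions; `apply_translocation()` moves a segment
of one chromosome onto another, relabelling the loci in it, so duplicated
assays with one locus in the segment acquire non-homoeologous pairs — the
signature `classify_pairs()` detects.

What the generator does *not* emulate: array hybridization chemistry and
cluster calling, segregation distortion, crossover interference, and
population structure beyond independent biparental RIL panels. Passing
recovery tests on this generator therefore demonstrates correctness of the
pipeline's statistics under its own model assumptions, not robustness to
every artefact of real array data.

## Study conditions used by the tests

The end-to-end acceptance run simulates four populations with 275, 176,
273 and 245 lines (F2:6, F2:6, F2:6, F2:8) — the sizes of the four
motivating mapping populations — on three chromosomes of 150 cM with 60
markers each, 40% per-population marker sampling, 5% missing data and 0.5%
genotyping error. The built consensus is required to reach
$|\rho| \ge 0.95$ per chromosome against the true order, and the consensus
of a single map must reproduce that map within $10^{-9}$ cM. Three
chromosomes rather than 21 keep the default check compact; the generator
scales to the full 21-chromosome genome by passing a longer chromosome
table, as in the examples.

```{r example, eval = FALSE}
tm <- simulate_true_map(
  data.frame(chromosome = c("1A", "1B", "2A"), length = 150),
  n_markers = 60, seed = 42
)
panel <- make_panel(tm, n_populations = 4,
                    n_lines = c(275, 176, 273, 245),
                    selfing_generation = c(6, 6, 6, 8),
                    population_marker_fraction = 0.4,
                    missing_rate = 0.05, error_rate = 0.005, seed = 7)
maps <- lapply(panel$populations,
               function(g) build_map(apply_qc(g), anchors = tm))
cons <- build_consensus(maps)
glance(cons)
consensus_summary(cons)
```

## Known limitations

* Ordering is a heuristic (greedy + 2-opt + ripple); global optimality is
  only guaranteed — and only checked — at oracle-tractable sizes.
* The linearization is a stand-in for an undocumented upstream
  approximation; it is validated by the identity and order-containment
  properties, not by equivalence to the original tool.
* Grouping is single-linkage and can chain distinct chromosomes through a
  single spurious high-LOD pair; the LOD 7 default makes this rare in
  panels of a few hundred lines but it is not impossible.
* Multipoint likelihoods, genotype-error imputation and
  segregation-distortion tests are out of scope.
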