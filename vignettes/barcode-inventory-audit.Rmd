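---
title: "Auditing a field inventory with two-locus DNA barcodes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing a field inventory with two-locus DNA barcodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodeAudit)
```

## The problem

Rapid biodiversity inventories — the kind run for environmental impact
assessments — rely on field identification of specimens by morphology,
often by parataxonomists working with incomplete regional keys. In
difficult groups (small leaf-litter frogs, reed frogs, puddle frogs) the
field species list can be badly wrong in both directions: one variable
species sorted into several morphospecies (splitting), or two cryptic
species sorted into one (lumping), sometimes in the wrong genus
altogether. Because downstream conservation decisions consume the species
*counts*, these errors propagate directly into richness estimates.

`barcodeAudit` implements a barcode-based audit of such an inventory. The
inputs are per-specimen aligned sequences of two mitochondrial loci — a
COI barcode fragment and a 16S fragment — plus a specimen table with
localities, sampling events, field labels, and any named reference
material. The output is a set of species-level OTUs with names and rule
provenance, a per-specimen concordance verdict against the field labels,
and incidence-based richness comparisons between the field inventory and
the barcode inventory.

## Distances

All delimitation operates on uncorrected p-distances with pairwise
deletion: only columns where both sequences carry `A/C/G/T` are compared,
and the distance is the mismatch fraction over those columns
(`pDistance()`, `distanceMatrix()`). Two choices matter:

* **Pairwise, not complete, deletion.** Ambiguous columns (including 16S
  loop regions) stay in the alignment; each pair uses whatever columns it
  can. The per-pair compared-site count is retained, and a pair with
  fewer than `minOverlap` sites (default 100, far below real ~500 bp
  fragments but enough to reject degenerate fragments) is an error rather
  than a number.
* **No substitution-model correction.** The delimitation thresholds used
  in this literature (2.2% BINs, ABGD priors up to 10%) are quoted on the
  uncorrected scale, so correcting distances would silently shift every
  threshold.

All IUPAC ambiguity codes other than `N` are collapsed to `N` on read;
the distance rule treats every ambiguity identically, so nothing is lost.

## Delimitation

Three candidate partitions are produced per dataset:

* **Fixed threshold (BIN proxy), `thresholdPartition()`.** Single-linkage
  connected components at 2.2% COI distance. BOLD's actual BIN algorithm
  (RESL) is proprietary and network-bound; a fixed 2.2% cut is its
  standard characterisation and is used here as a deterministic proxy.
  Single linkage chains deliberately: that is how a sequence cluster
  "grows" in practice.
* **Barcode gap discovery, `abgdPartition()`.** For each prior maximum
  intraspecific divergence $P$ on a geometric grid (defaults
  $P_{\min} = 0.001$, $P_{\max} = 0.1$, 10 steps), the sorted pairwise
  distances are scanned for the first value above $P$ whose gap to its
  predecessor exceeds $X = 1.5$ times the local mean consecutive-gap
  width, estimated over a sliding window of
  $w = \max(3, \lceil N/N_b \rceil)$ sorted distances ($N_b = 20$). If a
  gap is found the set is split by single linkage at the gap midpoint and
  the scan recurses inside each group; the reported partition is the one
  whose group count is stable over the longest run of consecutive priors
  (ties toward smaller priors). Numerical edge choices: the scan starts
  at the second sorted distance (a single-distance window carries no gap
  scale); tied distances give a zero local scale, so the first positive
  jump after a tied block is accepted; an all-zero matrix therefore never
  splits. Recursion matters when a group's internal gap is masked
  globally by another group's distance continuum — the test suite
  constructs exactly that case. At priors far below the intraspecific
  scale, discrete (1/L-quantised) distances can make the detector
  oversplit; this mirrors the method's known behaviour and is why the
  downstream reconciliation step, not the raw partition, carries the
  species decision.
* **Neighbor joining, `neighborJoining()`.** Standard NJ (via `ape`) on
  the p-distance matrix, used as a clustering device, not a phylogeny.
  Ids are pre-sorted so ties resolve identically under input reordering,
  and negative branch-length estimates are clamped to zero. On additive
  matrices NJ is exact; the suite asserts this for up to eight taxa.

16S conspecificity (`conspecificityClusters()`) defaults to
single-linkage clustering at 3% — visual "clade" delimitation is not
computable, and 3% sits between observed conspecific 16S variation
(≈0–2%) and congeneric divergences (≥4–5%) in these frogs. A
`monophyly` mode is provided for label-rich datasets: maximal clades of
the midpoint-rooted NJ tree containing references of at most one name.

## Reconciliation into species

`refineCells()` first intersects the two COI partitions — the finest
defensible starting point; a specimen lacking COI joins the unique cell
its 16S cluster points to (ambiguity is reported, never guessed; a 16S
cluster with no COI-bearing member founds its own cell).
`reconcileCells()` then evaluates every pair of cells:

| 16S clusters | localities | rule | action |
|---|---|---|---|
| same | disjoint | R2 | merge (geographic variation) |
| same | shared | R3 | merge (population-level variation) |
| different | shared | R4 | forbid merge (sympatric species) |
| different | disjoint | R5 | merge only on a shared morphology flag |

Morphology "fits the description of species X" enters as a boolean flag
per specimen (`morph_<name>` columns): diagnosis is expert work outside
the pipeline. OTUs are connected components of the merge graph. If a
merge chain connects an R4-forbidden pair, edges incident to that pair
are dropped (R3 before R2 before R5) until the pair separates, and the
event is logged in `conflicts` — the rule set does not define a winner,
so the package refuses to resolve it silently. Every merge carries a
provenance record; dropped merges are marked, and replaying the
surviving records reproduces the partition exactly (tested).

`assignNames()` names each OTU in a fixed cascade: majority reference
name (ties go alphabetical with `cf` status), then a name adopted from a
reference sharing a 16S cluster, then `Genus cf. epithet` when the
nearest named reference sits within `dCf = 0.05` of 16S distance — above
conspecific variation, below typical congeneric divergence, and
configurable — and finally `Genus sp. A`, `sp. B`, … under the modal
field genus, letters allocated in order of first appearance.

## Concordance

`auditConcordance()` scores each survey specimen: *correct* when its
field name equals its OTU's assigned name or when its field label and
OTU map one-to-one onto each other; when one OTU carries several field
labels, **all** of its members are misidentified — a cluster whose
members were sorted into different field species is evidence that none
of those identifications is trustworthy. `genusSummary()` tallies
distinct field labels per field genus against distinct OTUs per
corrected genus (the genus of the final name, so genus-level
misassignments move counts between rows), per season and combined, with
a totals row; `overestimationPercent()` reports
$(\mathrm{field} - \mathrm{barcode}) / \mathrm{barcode} \times 100$.

## Richness

`buildIncidence()` reduces the survey to binary species × sampling-event
incidence — sample-based rather than individual-based, because vouchers
are not collected for every encountered individual, making abundance
data untrustworthy. Two estimators follow:

* **Sample-based rarefaction** (`rarefactionCurve()`): the analytic
  expectation $\tau(h) = \sum_j [1 - \binom{m-Y_j}{h}/\binom{m}{h}]$,
  identical to the exhaustive mean over all $h$-subsets (asserted by
  enumeration for $m \le 8$). The variance is the unconditional
  (estimator-based) form $\sum_j (1-\alpha_{jh})^2 - \tau(h)^2/\tilde S$
  with $\tilde S$ the Chao2 estimate, which stays positive at full
  effort so that completed surveys remain comparable; it is checked
  against an independent reimplementation and is by construction wider
  than subset-resampling spread at small $h$ (it carries the
  undetected-species component).
* **Chao2** (`chao2Estimate()`): with $k = (m-1)/m$,
  $\hat S = S_{obs} + k\,Q_1^2/(2Q_2)$ for $Q_2 > 0$ and the
  bias-corrected $S_{obs} + k\,Q_1(Q_1-1)/2$ for $Q_2 = 0$; variances by
  the classic published forms, and the 84% interval by the log-normal
  construction on $\hat S - S_{obs}$, whose lower bound cannot fall
  below the observed richness. The classic plug-in variance is cubic and
  quartic in $Q_1/Q_2$ and therefore noisy survey-to-survey; the
  acceptance suite checks it against an event-bootstrap (resampling
  sampling events with replacement, 500 replicates) on the median over
  replicate surveys of a sparse heterogeneous community, where the two
  agree. Coverage of the 84% interval is checked on homogeneous-detection
  communities — the regime where Chao2 is approximately unbiased; under
  strong detection heterogeneity Chao2 is a lower bound and its interval
  undercovers, a known limitation, not a defect of this implementation.

Intervals are 84% two-sided ($z = 1.4051$) because non-overlap of two
84% intervals approximates a two-sample test at $P = 0.05$;
`ciOverlap()` applies exactly that rule, comparing curves at the smaller
of the two maximum efforts so the verdict is deterministic.

## The synthetic community generator

`generateCommunity()` emulates what the pipeline consumes: $K$ species
whose two-locus centroids are built from a shared ancestor and
rejection-sampled until all pairwise centroid p-distances reach
`dMinInter`; specimens derive from their centroids by uniform per-site
substitution at rate `muIntra/2` per copy (so conspecific pairs sit near
`muIntra`); localities host sampling events split into a dry and a wet
season; a fraction of specimens are named references placed off-site.
Defaults — 654/550 bp loci, `muIntra = 0.01`, `dMinInter = 0.08` — put
the community in the clean-barcode-gap regime typical of mitochondrial
barcodes in amphibians. `applyFieldErrors()` then perturbs the survey
labels: within-genus species pairs lump with probability `pLump`,
unlumped species split into 2–4 morphospecies labels with probability
`pSplit`, and each distinct label switches genus with probability
`pWrongGenus` (applied per label, so lumped or split labels stay
internally consistent). The defaults (0.2 / 0.05 / 0.1) are illustrative
of a split-prone field team; no quantitative field-error rates exist to
calibrate against.

What the generator does *not* emulate — gene-tree discordance,
hybridisation, incomplete lineage sorting, alignment error, sequencing
chimeras — bounds what passing tests mean: they certify the pipeline's
logic under congruent loci with a real barcode gap, not its behaviour on
conflicted loci. The substitution model is deliberately minimal
(uniform replacement): delimitation sees only uncorrected distances, so
richer models would add realism the statistics cannot see.

## Problem sizes and determinism

The validation suites use 50-seed batches of $K = 5$–$8$ species with
3–6 specimens each for end-to-end recovery, constructed clean-gap
matrices for gap-discovery exactness, additive matrices up to eight taxa
for NJ, exhaustive subset enumeration up to eight events for
rarefaction, and 500 bootstrap replicates for the Chao2 variance check —
sizes at which the independent oracles are exact or stable while the
whole suite stays fast. Every stochastic step runs from an explicit
seed; `generateCommunity()` and `applyFieldErrors()` seed independent
streams (`seed`, `seed + 1`) so each stage is reproducible on its own.

## Known limitations

* The BIN proxy is a fixed threshold; real BIN assignments can differ
  near the 2.2% boundary.
* Gap discovery at priors below the intraspecific scale oversplits on
  quantised distances (see above); conclusions should rest on the
  stability-selected partition plus reconciliation, as implemented.
* The R4 conflict-resolution order (drop R3 before R2 before R5) is a
  package convention for a case the rule set leaves undefined; conflicts
  are always logged for review.
* Chao2 under detection heterogeneity estimates a lower bound, and its
  84% intervals undercover the true richness there.
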