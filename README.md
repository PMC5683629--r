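# barcodeAudit

Auditing field-based species inventories against two-locus DNA barcode
evidence.

Rapid amphibian inventories identify specimens in the field by
morphology, and in difficult genera those identifications are often
wrong: one polymorphic species gets split into several morphospecies,
cryptic species get lumped under one label, and some specimens land in
the wrong genus entirely. Since conservation assessments consume the
resulting species *counts*, the errors propagate straight into richness
estimates. `barcodeAudit` re-derives the species units from sequence
data and quantifies how far the field inventory drifted from them.

The pipeline, for specimens with aligned COI and 16S fragments:

1. **Distances** — uncorrected p-distances with pairwise deletion
   (`distanceMatrix()`), the common currency of every step.
2. **Delimitation** — candidate OTU partitions from COI: single-linkage
   clustering at a fixed 2.2% threshold (`thresholdPartition()`, a proxy
   for Barcode Index Numbers) and automatic barcode gap discovery
   (`abgdPartition()`), which splits at the first distance gap wider
   than *X* = 1.5 times the local gap scale, scanned over a geometric
   grid of priors (Pmin 0.001, Pmax 0.1, 10 steps, window Nb = 20) with
   recursive refinement and stability selection. Neighbor-joining trees
   (`neighborJoining()`) and 16S clusters (`conspecificityClusters()`,
   3% single linkage or reference-label monophyly) complete the
   evidence.
3. **Reconciliation** — `refineCells()` intersects the COI partitions;
   `reconcileCells()` merges or separates cells by the joint
   16S/locality rules (same 16S clade ⇒ one species with geographic or
   population-level COI variation; different 16S clades in sympatry ⇒
   separate species; allopatric 16S divergence merges only on a shared
   morphology flag), logging rule provenance and conflicts;
   `assignNames()` yields names with `named` / `cf` / `provisional`
   status (`Genus sp. A`, `sp. B`, …).
4. **Concordance** — `auditConcordance()` scores each specimen correct
   iff its field label matches its OTU by name or one-to-one mapping
   (an OTU carrying several field labels is wholly misidentified);
   `genusSummary()` tabulates field vs barcode species per genus and
   season.
5. **Richness** — sample-based rarefaction with the analytic mean and
   unconditional variance (`rarefactionCurve()`), the Chao2 estimator
   $\hat S = S_{obs} + \frac{m-1}{m}\,Q_1^2/(2Q_2)$ with 84% log-normal
   confidence intervals (`chao2Estimate()`), and the 84% CI-overlap
   significance rule (`ciOverlap()`).

A synthetic community generator (`generateCommunity()`,
`applyFieldErrors()`) produces two-locus datasets with known species
truth and a configurable lump/split/wrong-genus field-labelling error
process, so the entire pipeline is testable without external data.

## Worked example

Generate a six-species community whose field crew splits 40% of species
and mislabels 10% of genera, audit it, and compare the two inventories:

```r
library(barcodeAudit)

cfg <- syntheticConfig(K = 6, specimensPerSpecies = c(4, 8),
                       pSplit = 0.4, pLump = 0, pWrongGenus = 0.1,
                       seed = 2024)
com <- generateCommunity(cfg)
fe  <- applyFieldErrors(com$truth, com$records, cfg)
res <- runBarcodeAudit(fe$records, com$alignments)

res$assignment
#> SpeciesAssignment: 37 specimens in 6 OTUs (4 named, 0 cf, 2 provisional); 0 conflict(s)

auditConcordance(fe$records, res$assignment, scope = "LMR")
#> concordanceReport: 31 scored, 87.1% correct, 0 unscored

gs <- genusSummary(fe$records, res$assignment, scope = "LMR")
gs[, c("genus", "field_combined", "barcode_combined")]
#>    genus field_combined barcode_combined
#> 1 GenusA              4                4
#> 2 GenusB              5                2
#> 3 Totals              9                6

incF <- buildIncidence(fe$records, by = "field", scope = "LMR")
incB <- buildIncidence(fe$records, res$assignment, by = "otu", scope = "LMR")
chao2Estimate(incF)
#> chao2: 14.45 (S_obs 9, Q1 4, Q2 0, m 11), CI [10.46, 29.45]
chao2Estimate(incB)
#> chao2: 6.00 (S_obs 6, Q1 0, Q2 0, m 11), CI [6.00, 6.00]
ciOverlap(rarefactionCurve(incF), rarefactionCurve(incB))$verdict
#> [1] "significant"
```

The barcode audit recovers the six true species exactly; the field
inventory carries nine labels (field-over-barcode overestimation of
50%), its Chao2 estimate extrapolates the spurious singletons further
upward, and the two accumulation curves differ significantly under the
84% CI-overlap rule.

The package also ships the summary tables of a completed amphibian
barcode inventory (Gabon road-corridor survey plus regional references)
as plain-text fixtures — see `inventoryFixture()` and
`inventorySummary()`, which recompute its headline numbers (94 BINs vs
85 gap-discovery groups across 524 COI sequences; 48 field vs 28
barcode species, a ~70% overestimate).

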