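---
title: "Methods: scoring, profiling and mapping boron efficiency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, profiling and mapping boron efficiency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boreff)
```

## The scientific problem

A diverse panel of naturally inbred accessions is grown under
B-deficient and B-sufficient conditions, with daily top-view imaging of
projected leaf area (PLA, mm²) between days 9 and 16 after sowing,
endpoint shoot fresh and dry weight (FW/DW, mg) at day 20, and endpoint
root system architecture traits (PRL, LRN, ALRL, TLRL, TRL, LRD; cm and
counts) from plate-grown seedlings. The question is which accessions
tolerate B limitation, what phenotypic strategies they use, and which
loci associate with that tolerance.

Because accessions differ widely in intrinsic vigour, tolerance is
measured against each accession's *own* replete-condition performance:
every trait enters as the deficiency:sufficiency ratio of replicate
means. This is a physiological-efficiency definition — the ability to
maintain native biomass accumulation — rather than absolute performance
under deficiency.

## The B-efficiency index

`beiShoot()` and `beiRoot()` combine two trait ratios into one index.
Three algebraic forms are available behind the `bei_form` switch of
`pipelineConfig()`; the default is the **product**:

$$\mathrm{BEI} = r_1 \cdot r_2$$

The product was chosen over the geometric or arithmetic mean for three
reasons: (1) it reproduces the published reference-accession value —
with a 71 % PLA reduction and an 80 % FW reduction the product gives
0.29 × 0.20 = 0.058 against a printed 0.057, within the rounding of the
inputs; (2) it admits values above 1 exactly when both component ratios
exceed 1, matching the reported behaviour of the most tolerant
accessions; (3) it penalises accessions that collapse in either
component, which an arithmetic mean would mask. The index is strictly
monotone in each ratio (asserted by a property test).

Classification (`classifyAccessions()`) is **rank-based**, not
quantile-interpolated: the top and bottom `ceil(f N)` accessions by
BEI_shoot (f = 0.10 by default) form the efficient and highly-sensitive
classes. With N = 185 this yields exactly 19 accessions per extreme
class, which is the only definition that produces those printed counts;
interpolated percentiles generally would not. Ties are broken by
accession id so the partition is total and deterministic. The
intermediate class (BEI_shoot > 0.400) is evaluated only on the
remainder, so it is disjoint from the efficient set by construction.
Two flags supplement the classes: *highly tolerant* (efficient and
maintaining > 80 % of both FW and DW), and *combined
tolerant/sensitive* (extreme decile of both the shoot and the root
index).

The stated classification rules are applied strictly; no manual
overrides of borderline accessions are supported.

## Growth-rate statistics

Relative growth rate is defined on the natural-log scale,
$\mathrm{RGR}_d = \ln(\mathrm{PLA}_d/\mathrm{PLA}_{d-1})$ (day⁻¹), the
classical definition. It makes fold statements directly interpretable
— a 13.7-fold PLA increase over days 9–16 at constant rate corresponds
to a mean daily RGR of ln(13.7)/7 ≈ 0.374 — and gives two exact
identities used as tests: daily RGRs telescope to the full-period log
fold, and interval RGRs equal the mean of their constituent daily RGRs
on gap-free series. Replicate aggregation is the arithmetic mean with
`min_reps = 3` per side; days are integer days-after-sowing and
endpoint traits carry an `NA` day rather than a fabricated one.

## Response profiling

`centerScale()` builds the accession × feature matrix of trait ratios
(daily PLA ratios, RGR ratios, interval-RGR ratios, endpoint shoot and
root ratios — 25 features on the default synthetic panel; the feature
list is configurable). Missing cells are imputed with the column mean
*before* scaling, so imputed cells are exactly 0 afterwards and do not
bias cluster geometry; columns are centred and divided by the sample
(n−1) SD, the convention of `scale()`. Zero-SD columns are dropped with
a warning.

`kmeansProfile()` runs Lloyd's algorithm through `stats::kmeans()` with
k-means++ seeding (written here, as base R has none) and takes the best
of 25 restarts by total within-cluster SS, all under one seed, so
results are reproducible. k defaults to 12; since no principled k is
claimed, k is a plain parameter and an elbow inspection is left to the
user. Labels are renumbered by descending cluster size (ties by
smallest member id) so cluster 1 is always the largest.

## Phylogeny and clade enrichment

Distances are SNP p-distances: mismatches over shared non-missing
calls. Under the package's infinite-sites generator these distances are
exactly additive on the generating tree, which is why neighbour joining
(`njTree()`, via `ape::nj`, negative branch lengths clamped to 0)
recovers planted topologies exactly — an oracle test asserts this on
4–8 taxon additive matrices. A maximum-parsimony tree search is
deliberately not performed: the downstream use is clade grouping, which
needs topology clusters, not the optimal MP tree. The Fitch
small-parsimony score of the NJ topology is available
(`fitchScore()`, missing states treated as the full state set) and is
validated against brute-force enumeration and against an independent
parsimony implementation. An NNI hill-climb to reduce the score was
considered and omitted — it would not change clade membership, the
quantity used downstream.

`cutClades()` converts the tree into k clades by removing internal
edges in decreasing length order. A cut is kept only if it increases
the number of tip-bearing components: removing adjacent internal edges
can otherwise strand a component containing no leaves, silently
producing fewer clades than requested (this occurred in roughly 2 of 5
simulated panels before the guard was added). Enrichment of an
efficiency class within a clade is the ratio of in-clade to population
frequency, with an upper-tail hypergeometric p
(`P(X ≥ k)`), cross-checked against explicit pmf summation.

## The association stage

`markerScan()` is a single-marker OLS of the trait on the 0/1 allele
code with marker-wise NA dropping — closed-form, vectorised, and tested
to 1e-10 against per-marker `lm()` fits. **It applies no kinship or
population-structure correction**; multi-locus mixed-model scans (e.g.
FarmCPU) are prior published methods and intentionally out of scope.
The consequence, visible in the worked example, is that when a real
effect exists in a structured panel, clade-correlated markers far from
the causal locus can also reach significance. The downstream rules are
scan-agnostic: Bonferroni control at α = 0.05; QTL windows defined per
chromosome by clumping markers with −log10 p ≥ 4 (markers ≤ 1 Mb apart
share a clump) and padding the outermost qualifying positions by
± 3365 bp, half the LD decay distance of the emulated population,
clipped at position 1; the efficiency allele at each significant marker
is the one whose carriers have the higher mean BEI_shoot (ties go to
the reference allele with a flag). The MAF rule retains the boundary
(MAF ≥ 0.05): "excluding markers with MAF of 0.05" is read as
excluding markers *below* 0.05.

Significance stars for allelic ANOVAs use the levels 0.05, 0.001 and
0.0001.

## The synthetic-data generator

`simConfig()` defaults *are* the study conditions: 185 accessions, 11
clades, 5000 markers on five 30-Mb chromosomes, 6 replicates per
treatment, days 9–16 plus endpoints, replicate CV 0.25, one planted
pleiotropic QTL. The generative model:

* **Genotypes.** A random bifurcating tree with long backbone branches
  (lengths U(2,4)) separating clades and short within-clade branches
  (U(0.04, 0.4)). Each marker mutates once on a branch chosen with
  probability proportional to branch length (classic infinite sites);
  tips below carry the alternative allele. Every marker is polymorphic
  by construction, and distances are exactly additive. Length-weighted
  placement matters: with uniform placement every branch receives equal
  expected mutations, the NJ tree then has no long backbone edges, and
  clade recovery by edge cutting is impossible in principle.
* **Latent tolerance.** `m = 1.3 · logistic(μ + Σβx + clade + ε)` with
  μ = −0.9, clade SD 0.5, residual SD 0.5. Causal markers default to
  the 0.05–0.15 MAF band, matching the low prevalence of efficiency
  alleles at reported lead markers; effect sizes default to β = 2.
* **Shoot growth.** Sufficient-treatment PLA is exponential,
  `A·exp(r(t−9))` with `log A ~ N(log 30, 0.45)` and
  `r ~ N(0.374, 0.03)`. Under deficiency the growth rate is multiplied
  by a factor that phases in linearly over days 13–14 and settles at
  `m`, so treatments diverge only after day 12 — deficiency symptoms
  in this system become visible from about 13 days after sowing. The
  phase-in shape (linear over two days) is a modelling choice.
* **Endpoints.** FW at day 20 is proportional to day-16 PLA with
  multiplicative lognormal noise (sdlog 0.10) plus an extra deficiency
  penalty `m^0.25`; these sizes give cor(FW, PLA16) ≈ 0.92–0.95 across
  accessions, the level seen in real panels. DW = 0.1·FW with sdlog
  0.10 noise.
* **Roots.** PRL and TLRL ratios are separate powers of the same `m`
  (0.8·m^0.55 and 0.95·m^0.9) — the planted pleiotropy. Fifteen
  accessions (scaled 15/185 for smaller panels), the most tolerant,
  are forced to *increase* TLRL under deficiency (ratio U(1.01,
  1.69)). Within every replicate, LRN, ALRL and PRL receive the noise
  and TLRL = LRN·ALRL, TRL = PRL + TLRL, LRD = LRN/PRL are derived, so
  these identities hold exactly in every fixture row.
* **Replicates and ionome.** All replicate values are multiplicative
  lognormal with CV 0.25 (mean-preserving), giving observed replicate
  relative SDs of ~0.24. Shoot B concentration is U(51, 92) mg kg⁻¹ DW
  under sufficiency, multiplied by U(0.12, 0.17) and a tolerance factor
  (0.75 + 0.5·min(m,1)) under deficiency, so efficient accessions run
  ~40 % higher under deficiency while both groups drop ~85 %.

With these defaults the synthetic panel reproduces the distributional
signatures of the real one: mean BEI_shoot ≈ 0.23–0.31 with maxima
near 1.5, strong right skew (Shapiro–Wilk p ≪ 0.001), and
Spearman ≥ 0.9 between the latent tolerance and the estimated index.

**What the generator does not emulate:** linkage disequilibrium decay
within chromosomes (marker positions are exchangeable; the 3.365 kb
padding is applied but cannot be validated against simulated LD),
selection, geographic structure, early-day deficiency effects on leaf
shape and colour phenes, and measurement artefacts of the imaging
platform. Passing tests therefore demonstrate correctness of the
computations and calibration under this generative model, not fidelity
to any particular real panel.

## Numerical and testing choices

* Ratios are `NA` (never Inf) when a side has fewer than `min_reps`
  replicates or a zero sufficient mean; NA propagates through scoring.
* The trait TSV writer prints doubles with `%.17g`, so
  `read(write(x))` is bit-exact; pipeline runs with the same seed are
  byte-identical (asserted on md5 sums).
* Heterozygous VCF calls map to `NA` with a warning — the panel is
  inbred by construction; multi-allelic records are skipped with a
  warning; duplicate (chrom, pos) is an error.
* The null-calibration check of scan p-value uniformity uses an
  independent-marker panel (iid Bernoulli genotypes, trait drawn
  independently). Tree-structured panels of this size yield only a few
  dozen distinct, strongly dependent genotype patterns after MAF
  filtering, and a KS statistic over them is unstable regardless of
  scan correctness; family-wise false-positive rates and planted-QTL
  recovery are still measured on tree-structured fixtures.
* Stochastic test suites use 800–1500 markers and 185 accessions over
  20 seeds (calibration) or 5 seeds (recovery) — sizes at which every
  property has a comfortable margin while the whole suite runs in
  about a minute.

## Known limitations

* Without structure correction the scan's hit list on structured
  panels mixes causal and clade-correlated markers; windows and
  ledgers faithfully report what the scan found, not a fine-mapped
  locus.
* The exact algebraic form of the published efficiency index is not
  printed in the main text of its source; the product form is a
  reconstruction validated against the printed reference-accession
  value and the documented above-1 behaviour.
* Clade cutting is a reproducible surrogate for expert manual clade
  assignment; memberships need not match any particular published
  figure.
* Shapiro–Wilk is limited to 3 ≤ n ≤ 5000 (`stats::shapiro.test`),
  ample for panel-scale score vectors.
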