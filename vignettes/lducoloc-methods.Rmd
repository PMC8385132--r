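---
title: "Mapping disease-regulated mitochondrial genes with LDU co-location"
author: "lducoloc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping disease-regulated mitochondrial genes with LDU co-location}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lducoloc)
```

## The problem

Genome-wide association signals for complex disease are overwhelmingly
non-coding, so each risk locus needs to be connected to the gene(s) it
regulates before any biology can be read off.  `lducoloc` implements a
co-location strategy for doing this on **linkage disequilibrium unit (LDU)
genetic maps**: causal-variant location estimates for disease
and for tissue gene expression (eQTL) are each mapped independently by a
multi-marker association model, and a shared causal signal is inferred when
the two location estimates fall within a small *genetic* — not physical —
distance of one another.  The package was built around the type-2-diabetes
(T2D) use case: nominating nuclear-encoded mitochondrial genes (NEMGs) whose
adipose expression is controlled by T2D risk loci, and then validating those
nominations in independent case/control expression data.

The LDU scale is what makes the co-location criterion meaningful.  An LDU
map is a monotone curve of cumulative genetic distance against physical
position: flat runs ("blocks") are regions of extended LD, vertical rises
("steps") mark LD breakdown.  Two association signals separated by 500 kb of
unbroken LD block are effectively the same signal; two signals 3 kb apart
across a sharp step are independent.  A fixed 1-LDU threshold therefore
translates to a locus-specific, asymmetric physical window.

## Coordinate algebra on LDU maps

A `GeneticMap` stores ordered anchor pairs (bp, cumulative LDU) for one
chromosome and is interpreted by piecewise-linear interpolation — the
simplest monotone interpolant, and the way such maps are conventionally
plotted.  Three operations cover all downstream needs:

* `lduAt(map, pos)` — LDU coordinate of a physical position;
* `lduDistance(map, a, b)` — `|lduAt(a) − lduAt(b)|`, zero within a block;
* `bpWindow(map, center, delta)` — the inverse image: the largest physical
  interval whose LDU span stays within ±`delta` of the center.  Blocks are
  absorbed whole; steps cut the window short; edges clamp to the map extent.

Positions outside the map are an error, never an extrapolation: LD structure
beyond the genotyped extent is unknowable.  `kbPerLduSummary()` reports the
kb widths of ±1-LDU windows evaluated **at the anchor positions** — anchors
are the only sampling scheme that does not impose an arbitrary bp grid.  On
real European maps the per-chromosome median of such widths is of order tens
of kb; on synthetic maps it is set by the block/step geometry.  Because the
sampling scheme behind published medians of this statistic is not
standardized, ours is a documented convention rather than a reproduction.

```{r map-example}
gm <- GeneticMap("13", pos = c(0, 100000, 100001, 200000),
                 ldu = c(0, 0, 2, 2))
bpWindow(gm, 50000, delta = 1)   # asymmetric: block absorbed, step blocks
```

## Colocalization calls

Disease estimates (p < 1e-3, the nominal tier; 1e-5 for the
multiple-testing-corrected tier, reflecting roughly 5,000 independent
genomic tests of the mapping model) are clustered per chromosome by
single-linkage at 1 LDU.  In one dimension single linkage is exact by
chaining sorted adjacent gaps, which is how `replicateLoci()` implements it;
the pairwise rule stated for two estimates extends to more by transitive
closure, which is the least arbitrary reading.  A cluster becomes a
**replicated locus** when it spans ≥ 2 distinct cohorts; it is
*cosmopolitan* when an African-American cohort contributes (AA estimates are
carried onto the European map via their physical position), and its
representative position is the most significant member's — again a
convention, chosen because it is reproducible and logged.

An eQTL (p < 0.05) becomes a **disease-eQTL** when it lies within 1 LDU of
*any* member estimate of a locus.  The any-member ("OR") rule is the
permissive reading and matches how ±1-LDU windows are drawn around each
estimate separately; an all-members variant is available via
`thresholdConfig(eqtlRule = "all")`.  Genes are attached when their
annotated span padded by ±1.5 Mb covers the locus representative position,
probes resolving to genes through the platform's designated annotation.
NEMG flagging is a case-insensitive symbol/id match against a
MitoCarta-style reference, after `normalizeSymbols()` repairs
spreadsheet-mangled aliases (`Mar-05` → `MARCH5`) — without this repair a
published listing that contains such an alias undercounts its own NEMGs.

## Differential-expression validation

`geneZscore()` summarises each gene's case-vs-control differential
expression as a signed standard-normal-scale statistic: OLS of probe
expression on phenotype for single-probe genes; for multi-probe genes a
linear mixed model on the long (probe, sample) layout with fixed phenotype
(+ age/BMI where available) effects and random intercepts.  The grouping of
the random intercepts is genuinely open in the classic description; we fit
intercepts for **probe and sample** (each subject is measured repeatedly
across probes) with probe-only as an option, and report the Wald z of the
phenotype coefficient because the pipeline's currency is a signed per-gene
Z.  Mixed-fit failures fall back to probe-averaged OLS and are flagged —
the pipeline must be total on messy data.  A dosage variant
(`familyHistoryZscore()`) regresses on the number of affected parents
(0/1/2) to probe pre-onset changes.

Per-tissue combination uses the DerSimonian–Laird moment estimator on the z
scale with within-study variance fixed at 1 (`randomEffectsCombine()`):
weights `1/v`, heterogeneity Q, truncated moment estimate of the
between-study variance τ², re-weighted mean and `z_meta = mu * sqrt(sum
w*)`.  Operating on z rather than converting to standardized mean
differences is a deliberate choice — the per-study statistic already is a
z — and carries no small-sample Hedges correction; genes missing from some
studies combine over the studies that measured them (union policy), with k
recorded.

## Enrichment machinery

Two distinct enrichment engines are deliberately kept apart:

**Competitive GSEA on genewise z** (`permutationP()`, `gseaBattery()`):
Wilcoxon rank-sum of the set against its background with midranks, a
**gene-sampling** null (random same-size gene sets, never sample-label
permutation), and the +1-corrected empirical p.  Three directional classes
are always computed — decreased (`z`), increased (`-z`), mixed (`|z|`) —
and the reported class is the smallest p, mirroring the arrow convention of
enrichment tables; the mixed class uses `|z|` as the stated definition of
"differential in either direction".  Benjamini–Hochberg FDR is applied
within each (tissue, comparison) family.  The standard battery compares
cis genes and cis-NEMGs against the genome, cis-NEMGs against all NEMGs,
and three random non-cis NEMG control sets against the NEMG background.

**Count-based pathway enrichment** (`countEnrichment()`): the observed
number of cis genes in a set against two nulls — uniform random gene draws,
and **structured** draws that reproduce the observed multiset of per-locus
cis-gene counts as physical clusters within ±1.5 Mb of a random anchor
gene.  The structured null controls for the fact that cis-gene discovery
produces physically clustered genes, which inflates overlap with physically
clustered pathways.  Reproducing the full per-locus size multiset (rather
than only the total count) is the faithful-variance choice; anchors define
the neighbourhoods because cis genes relate to a single locus position.
Empirical p values are one-sided (enrichment only) and never zero.

## The correlation-stratified NEMG regression

NEMG expression is strongly co-regulated, which saps competitive GSEA power
for a small NEMG subset against the NEMG background.  The complementary
analysis asks: among NEMGs *not* called cis, does differential expression
track correlation with the cis-NEMG group?  `meanCorrelationProfile()`
computes, on control samples only (gene level = probe average), each
non-cis NEMG's mean Pearson correlation with the cis-NEMGs;
`correlationDeRegression()` then regresses the meta z on that mean
correlation with mean control expression as covariate.  Controls-only is
our convention for both the correlation substrate and the covariate — the
point is baseline co-expression, uncontaminated by case effects.

The robust variant emulates the classic iterative robust-regression recipe:
drop points with Cook's distance > 1, iterate weighted least squares with
Huber weights (c = 1.345) to convergence, continue with biweight
(c = 4.685), and report points with final weight < 0.01 as outliers; the
tuning constants are the conventional defaults and configurable.  The
number of excluded outliers is data-dependent and is never asserted on
synthetic data.

## The synthetic-data generators

`scenarioConfig()` fixes the study conditions; `makeScenario()` writes a
complete input bundle plus a `truth.txt` manifest, atomically (temp-dir
rename) and byte-identically for a fixed seed.  The defaults are the
conditions under which all recovery and calibration tests run, chosen once
at desk scale: 3 chromosomes × 30 Mb; anchor spacing 10 kb with step
probability 0.2 and mean step 1 LDU (≈ 1 LDU per 50 kb, the order seen on
real European maps); ~7 genes/Mb (~630 genes); 20 true loci observed by two
European cohorts and — for 60% of loci — an African-American one, with
0.2-LDU estimate jitter and 30 single-cohort decoys ≥ 3 LDU from any
truth; planted eQTL within 1 LDU of their locus; a planted case effect of
−0.5 log2 units on true cis genes (half that per affected parent in the
family-history study); NEMG co-expression via a one-factor model with
loading 0.4; 2 studies per tissue at 30 samples on an RMA-like log2 scale
(baselines 6–12) with 1–4 probes per gene; mildly case-confounded age/BMI
covariates; and 8 pathway sets of 30 genes of which 2 contain 8 true cis
genes each (~4× the null expectation).

What the generator does **not** emulate: array-specific probe biases and
batch effects, LD-driven correlation between neighbouring genes' eQTL,
non-Gaussian expression tails, population stratification, or any genotype
data (location estimates are generated directly, the mapping model itself
being out of scope).  Green recovery tests therefore demonstrate that the
pipeline's logic is correct under its stated model, not that the original
cohort results are reproduced — the published headline counts (763 cis
genes, 50 cis-NEMGs, 174/167 loci) and the published regression and GSEA p
values depend on the original cohort data, which the package deliberately
does not ship.

## Numerical choices and edge cases

* Positions are 1-based bp internally; kb appears only in reports.
* Interpolation anchors are validated on load (strictly increasing
  positions, non-decreasing LDU); the first violating line is named.
* Cross-chromosome LDU distance is infinite — no inter-chromosomal
  co-location.
* Permutation p values use the +1 correction and are never zero.
* The DL τ² truncates at zero; k = 1 passes the study effect through.
* Mixed-model singular fits are accepted (variance components may be
  legitimately zero); only hard failures fall back, flagged.
* Ties in rank-sum statistics use midranks throughout.
* Set curation against the NEMG list uses a strict `> 25%` overlap.
* Zero-variance genes are excluded pairwise from correlation profiles with
  a message, and degenerate genes become flagged rows, never aborts.

## Problem sizes used by the tests

The test and acceptance suites run the default scenario (above) end to end
twice to confirm byte-identical reruns, use 10,000 permutations where a
permutation law is being compared against an exact law, and 500-replicate
calibration sweeps for uniformity checks; parameter-recovery checks use
200-replicate averages.  These sizes were chosen as the smallest at which
the sampling error of the check is well below the tolerance being asserted.

## Limitations

* The package consumes location estimates; it cannot assess the mapping
  model that produced them, and garbage estimates yield garbage calls.
* The 1-LDU threshold, ±1.5 Mb window and p-value tiers are configurable
  but their defaults are inherited conventions, not optimized quantities.
* The representative-position and any-member co-location rules are
  documented conventions where the underlying procedure is underspecified;
  both have configurable alternatives.
* Locus counts after eQTL support (e.g. how 174 replicated loci reduce to
  167 with calls) depend on cluster-merge details that published analyses
  rarely state; the package derives all such counts from its own calls.
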