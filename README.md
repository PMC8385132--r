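# lducoloc

Colocalization of disease and expression QTL on linkage-disequilibrium-unit
(LDU) genetic maps, with expression-based validation — built around the
type-2-diabetes (T2D) use case of nominating nuclear-encoded mitochondrial
genes (NEMGs) regulated by disease risk loci.

## What it does

Risk loci for complex disease are mostly non-coding; the gene a locus
regulates must be inferred.  `lducoloc` infers it by **genetic, not
physical, co-location**: causal-variant location estimates for disease
(Ŝ_disease, per cohort) and for tissue gene expression (Ŝ_eQTL, per gene)
are placed on a metric LDU map — a monotone curve of cumulative LD distance
against bp, where flat "blocks" are extended LD and "steps" are LD
breakdown — and a shared signal is called when estimates fall within
**1 LDU**.  Because the bp width of 1 LDU varies with local LD, the
physical window is locus-specific and asymmetric.

The pipeline stages, each an exported function group:

1. **Map algebra** — `lduAt`, `lduDistance`, `bpWindow` (inverse ±δ-LDU
   window), `kbPerLduSummary`.
2. **Colocalization** — `replicateLoci` (single-linkage clustering of
   disease estimates at 1 LDU; replication = ≥ 2 cohorts), `callT2dEqtl`
   (eQTL within 1 LDU of a locus member), `assignCisGenes` (±1.5 Mb
   window), `flagNemg` (+ `normalizeSymbols` repair of Excel-mangled
   symbols), `nemgProportionTest`.
3. **Differential expression** — `geneZscore` / `studyZscores`: per-gene
   signed Z from OLS (single probe) or a probe×sample mixed model with
   random intercepts; `familyHistoryZscore` for the 0/1/2
   affected-parents design.
4. **Meta-analysis** — `randomEffectsCombine`, `metaByTissue`:
   DerSimonian–Laird on the z scale,
   `z_meta = μ̂·√Σw*`, with `w*_i = 1/(1 + τ²)` and τ² the truncated
   moment estimator from Q.
5. **Competitive GSEA** — `wilcoxonSetStat`, `permutationP`,
   `gseaBattery`: rank-sum statistics with gene-sampling permutation
   nulls, directional classes (down / up / mixed), BH FDR per family.
6. **NEMG correlation regression** — `meanCorrelationProfile`,
   `correlationDeRegression`: meta z of non-cis NEMGs regressed on their
   mean control-sample correlation with the cis-NEMG group, with a robust
   (Cook's pre-drop, Huber→biweight IRLS) variant.
7. **Count enrichment** — `countEnrichment` with uniform and
   locus-structured (±1.5 Mb cluster) permutation nulls;
   `curateMitoSets`.
8. **Synthetic data** — `scenarioConfig`, `makeScenario`: seeded
   generators for every input with a planted-truth manifest.
9. **Pipeline** — `runAll`, `summarizeRun`; a thin CLI wrapper ships at
   `inst/scripts/lducoloc.R`.

## Worked example

```r
library(lducoloc)

# generate a synthetic scenario with planted loci and run end to end
d <- tempfile(); out <- tempfile()
makeScenario(scenarioConfig(seed = 7), d)
res <- runAll(d, out, nPerm = 1000, seed = 7)

res$summary[c("n_cis_genes", "n_cis_nemgs", "genes_per_locus")]
#> $n_cis_genes     38
#> $n_cis_nemgs      3
#> $genes_per_locus  1.9

res$truthScore[c("sensitivity", "false_call_rate")]
#> $sensitivity      1
#> $false_call_rate  0
```

All 20 planted loci were recovered with no false calls, and the planted
pathway sets surface at the smallest attainable permutation p
(1/1001 ≈ 1e-3) in `res$enrichment`.

On the packaged listing of 50 published cis-NEMGs
(`inst/extdata/table1_cis_nemg.tsv`) and the four curated mitochondrial
pathway sets (`inst/extdata/mito_pathways.gmt`):

```r
tab  <- read.delim(system.file("extdata", "table1_cis_nemg.tsv",
                               package = "lducoloc"))
sets <- readGmt(system.file("extdata", "mito_pathways.gmt",
                            package = "lducoloc"))
setOverlapCount(tab$gene, sets$BCAA_DEGRADATION)
#> [1] 5   # PCCA, MCCC1, ABAT, ACADS, ALDH2
summarizeCounts(763, 167, 50)[c("genes_per_locus", "nemg_percent")]
#> $genes_per_locus 4.6
#> $nemg_percent    6.6
```

## Layout

```
R/                  implementation (S4 classes GeneticMap, ExpressionStudy)
tests/testthat/     unit, property and acceptance suites
scripts/acceptance.R
inst/extdata/       published cis-NEMG listing, curated pathway GMT
inst/scripts/       CLI wrapper
vignettes/          methods vignette (model, conventions, limitations)
```
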