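smallCfg <- function(seed = 1)
  scenarioConfig(seed = seed, nChrom = 2, chromLengthBp = 8e6,
                 genesPerMb = 5, nTrueLoci = 5, nDecoys = 6,
                 samplesPerStudy = 16,
                 studiesPerTissue = c(adipose = 1, muscle = 1))

test_that("scenario generation is byte-identical at a fixed seed", {
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  d3 <- file.path(tempdir(), "det3")
  unlink(c(d1, d2, d3), recursive = TRUE)
  makeScenario(smallCfg(101), d1)
  makeScenario(smallCfg(101), d2)
  makeScenario(smallCfg(202), d3)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  for (f in f1)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  expect_false(identical(readLines(file.path(d1, "truth.txt")),
                         readLines(file.path(d3, "truth.txt"))))
})

test_that("generated maps satisfy the GeneticMap invariants across seeds", {
  for (seed in 1:100) {
    set.seed(seed)
    maps <- simulateMap(scenarioConfig(seed = seed, nChrom = 1,
                                       chromLengthBp = 1e6))
    m <- maps[[1]]
    expect_true(all(diff(mapPositions(m)) > 0))
    expect_true(all(diff(mapLdu(m)) >= 0))
    expect_gte(mapLdu(m)[1], 0)
  }
})

test_that("map geometry controls the kb-per-LDU scale", {
  set.seed(1)
  dense <- simulateMap(scenarioConfig(nChrom = 1, chromLengthBp = 5e6,
                                      stepProb = 0.8))[[1]]
  set.seed(1)
  blocky <- simulateMap(scenarioConfig(nChrom = 1, chromLengthBp = 5e6,
                                       stepProb = 0.05))[[1]]
  expect_lt(kbPerLduSummary(dense)$median_kb,
            kbPerLduSummary(blocky)$median_kb)
})

test_that("every emitted file loads through its consuming module", {
  d <- file.path(tempdir(), "loaders")
  unlink(d, recursive = TRUE)
  makeScenario(smallCfg(7), d)
  maps <- readGeneticMap(file.path(d, "map.tsv"))
  expect_gt(length(maps), 0)
  est <- readLocationEstimates(file.path(d, "estimates.tsv"))
  expect_true(all(est$trait %in% c("disease", "expression")))
  ann <- readGeneAnnotation(file.path(d, "annotation.tsv"))
  expect_true(all(ann$end > ann$start))
  sets <- readGmt(file.path(d, "sets.gmt"))
  expect_true(all(unlist(sets) %in% ann$hgnc))
  studies <- read.delim(file.path(d, "studies.tsv"))
  st <- readExpressionStudy(file.path(d, studies$exprs[1]),
                            file.path(d, studies$pheno[1]),
                            file.path(d, studies$probe_map[1]),
                            tissue = studies$tissue[1])
  expect_s4_class(st, "ExpressionStudy")
  truth <- readTruth(d)
  expect_true(all(truth$true_cis_genes %in% ann$hgnc))
  # truth locus sizes are consistent with the cis-gene list
  expect_equal(sum(as.integer(truth$locus_sizes)),
               length(truth$true_cis_genes))
})

test_that("zero jitter puts all cohort estimates of a locus at zero LDU distance", {
  cfg <- smallCfg(9); cfg$jitterLdu <- 0; cfg$nDecoys <- 0
  set.seed(cfg$seed)
  maps <- simulateMap(cfg)
  ann <- lducoloc:::simulateAnnotation(cfg)
  sim <- simulateEstimates(cfg, maps, ann)
  dis <- sim$estimates[sim$estimates$trait == "disease", ]
  for (i in seq_len(nrow(sim$truth$loci))) {
    L <- sim$truth$loci[i, ]
    mem <- dis[dis$chrom == L$chrom &
                 abs(lduAt(maps[[L$chrom]], dis$pos_bp) - L$ldu) < 0.5, ]
    ldus <- lduAt(maps[[L$chrom]], mem$pos_bp)
    expect_lt(max(ldus) - min(ldus), 1e-6)
  }
})

test_that("decoy-only estimates never replicate and planted eQTL sit within 1 LDU", {
  cfg <- smallCfg(12)
  set.seed(cfg$seed)
  maps <- simulateMap(cfg)
  ann <- lducoloc:::simulateAnnotation(cfg)
  sim <- simulateEstimates(cfg, maps, ann)
  # strip true-locus estimates: decoys alone yield no replicated loci
  truthLdu <- sim$truth$loci
  dis <- sim$estimates[sim$estimates$trait == "disease", ]
  isDecoy <- vapply(seq_len(nrow(dis)), function(i) {
    tl <- truthLdu[truthLdu$chrom == dis$chrom[i], ]
    !nrow(tl) ||
      min(abs(lduAt(maps[[dis$chrom[i]]], dis$pos_bp[i]) - tl$ldu)) >=
        cfg$decoyMinLdu - 1
  }, logical(1))
  repDecoy <- replicateLoci(dis[isDecoy, ], maps)
  expect_equal(nrow(repDecoy$loci), 0L)
  # planted eQTL are within 1 LDU of their locus
  eq <- sim$estimates[sim$estimates$trait == "expression", ]
  cisProbes <- sim$probeMap$probe[sim$probeMap$gene %in% sim$truth$cisGenes]
  for (i in which(eq$target %in% cisProbes)) {
    tl <- truthLdu[truthLdu$chrom == eq$chrom[i], ]
    expect_lte(min(abs(lduAt(maps[[eq$chrom[i]]], eq$pos_bp[i]) - tl$ldu)),
               1 + 1e-9)
  }
})

test_that("factor loading controls NEMG co-expression", {
  cfg <- smallCfg(15)
  set.seed(cfg$seed)
  ann <- lducoloc:::simulateAnnotation(cfg)
  nemg <- ann$hgnc[ann$nemg]
  # lambda = 0: correlations near zero
  cfg0 <- cfg; cfg0$factorLoading <- 0
  set.seed(1)
  st0 <- simulateExpression(cfg0, ann, character(0))[[1]]
  ex0 <- SummarizedExperiment::assay(st0, "exprs")
  g0 <- rowsum(ex0, probeGenes(st0))
  g0 <- g0[rownames(g0) %in% nemg, ][1:10, ]
  c0 <- cor(t(g0))
  expect_lt(mean(abs(c0[upper.tri(c0)])), 0.3)
  # strong loading: clearly positive mean pairwise correlation
  cfg1 <- cfg; cfg1$factorLoading <- 0.8
  set.seed(1)
  st1 <- simulateExpression(cfg1, ann, character(0))[[1]]
  ex1 <- SummarizedExperiment::assay(st1, "exprs")
  g1 <- rowsum(ex1, probeGenes(st1))
  g1 <- g1[rownames(g1) %in% nemg, ][1:10, ]
  c1 <- cor(t(g1))
  expect_gt(mean(c1[upper.tri(c1)]), mean(c0[upper.tri(c0)]) + 0.2)
})

test_that("scenario writing is atomic", {
  d <- file.path(tempdir(), "atomic")
  unlink(d, recursive = TRUE)
  dir.create(d); writeLines("x", file.path(d, "junk"))
  expect_error(makeScenario(smallCfg(1), d), "not empty")
  expect_false(file.exists(file.path(d, "truth.txt")))
})
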