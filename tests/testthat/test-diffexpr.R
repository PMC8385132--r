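test_that("single-probe gene z equals the OLS t-statistic", {
  st <- makeStudy(nGenes = 5, nSamples = 20, probes = 1, shift = -1,
                  shiftGenes = "g001", noise = 0.5, seed = 2)
  res <- geneZscore(st, "g001")
  expect_equal(res$model, "single-probe")
  expect_lt(res$z, -3)
  # oracle: direct lm on the probe values
  y <- SummarizedExperiment::assay(st, "exprs")[1, ]
  fit <- summary(lm(y ~ phenotype(st)))
  expect_equal(res$z, fit$coefficients[2, 3], tolerance = 1e-10)
})

test_that("multi-probe mixed-model z tracks the probe-average oracle", {
  st <- makeStudy(nGenes = 4, nSamples = 30, probes = 3, shift = -0.8,
                  shiftGenes = "g002", noise = 0.4, seed = 3,
                  probeOffsets = c(-1, 0, 1))
  res <- geneZscore(st, "g002")
  expect_true(res$model %in% c("mixed", "fallback"))
  expect_equal(res$n_probes, 3L)
  # oracle: average the probes per sample, then OLS
  pg <- probeGenes(st)
  ex <- SummarizedExperiment::assay(st, "exprs")[pg == "g002", ]
  yAvg <- colMeans(ex)
  zOracle <- summary(lm(yAvg ~ phenotype(st)))$coefficients[2, 3]
  expect_equal(res$z, zOracle, tolerance = 0.2)
})

test_that("the sign convention is positive z for higher expression in cases", {
  st <- makeStudy(nGenes = 3, nSamples = 40, probes = 2, shift = +1,
                  shiftGenes = "g001", noise = 0.3, seed = 4)
  expect_gt(geneZscore(st, "g001")$z, 3)
})

test_that("gene z is invariant to probe order and global constants", {
  st <- makeStudy(nGenes = 3, nSamples = 20, probes = 3, shift = -0.5,
                  shiftGenes = "g001", seed = 5)
  z0 <- geneZscore(st, "g001")$z
  ex <- SummarizedExperiment::assay(st, "exprs")
  perm <- rev(seq_len(nrow(ex)))
  st2 <- ExpressionStudy(ex[perm, ], phenotype(st),
                         probeGenes(st)[perm], studyId = "p")
  expect_equal(geneZscore(st2, "g001")$z, z0, tolerance = 1e-6)
  st3 <- ExpressionStudy(ex + 100, phenotype(st), probeGenes(st),
                         studyId = "c")
  expect_equal(geneZscore(st3, "g001")$z, z0, tolerance = 1e-6)
})

test_that("null z-scores are calibrated to unit standard deviation", {
  set.seed(10)
  zs <- replicate(1000, {
    y <- rnorm(20)
    ph <- rep(0:1, 10)
    summary(lm(y ~ ph))$coefficients[2, 3]
  })
  # sanity on the oracle itself (t with 18 df): sd slightly above 1
  expect_gt(sd(zs), 0.9); expect_lt(sd(zs), 1.15)
  # the package path on single-probe null genes matches
  st <- makeStudy(nGenes = 200, nSamples = 20, probes = 1, seed = 11)
  z <- studyZscores(st, useCovariates = FALSE)$z
  expect_gt(sd(z), 0.85); expect_lt(sd(z), 1.15)
})

test_that("null z is approximately standard normal with covariates present", {
  set.seed(12)
  n <- 24
  age <- rnorm(n, 50, 8); bmi <- rnorm(n, 28, 4)
  ph <- rep(0:1, n / 2)
  zs <- vapply(seq_len(2000), function(i) {
    y <- rnorm(n) + 0.02 * age
    summary(lm(y ~ ph + age + bmi))$coefficients[2, 3]
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(zs, "pnorm"))
  expect_gt(ks$p.value, 0.01)
})

test_that("covariate adjustment only matters when covariates confound", {
  n <- 40
  ph <- rep(0:1, n / 2)
  age <- rnorm(n, 50, 5) + 6 * ph        # confounded with phenotype
  st <- makeStudy(nGenes = 10, nSamples = n, probes = 1, seed = 13,
                  phenotype = ph, age = age)
  ex <- SummarizedExperiment::assay(st, "exprs")
  ex[1, ] <- ex[1, ] + 0.1 * age         # gene driven by age, not status
  st2 <- ExpressionStudy(ex, ph, probeGenes(st), studyId = "cf", age = age)
  zAdj <- geneZscore(st2, "g001", useCovariates = TRUE)$z
  zRaw <- geneZscore(st2, "g001", useCovariates = FALSE)$z
  expect_gt(abs(zRaw - zAdj), 0.5)
  # a gene unrelated to age moves much less
  zAdj2 <- geneZscore(st2, "g005", useCovariates = TRUE)$z
  zRaw2 <- geneZscore(st2, "g005", useCovariates = FALSE)$z
  expect_lt(abs(zRaw2 - zAdj2), abs(zRaw - zAdj))
})

test_that("family-history dosage design recovers planted per-parent effects", {
  n <- 36
  dose <- rep(0:2, each = n / 3)
  st <- makeStudy(nGenes = 5, nSamples = n, probes = 2, shift = -0.5,
                  shiftGenes = "g001", seed = 14, phenotype = dose,
                  phenotypeType = "dosage")
  res <- familyHistoryZscore(st, "g001")
  expect_lt(res$z, -2)
  # permuted labels are null: |z| <= 3 nearly always
  set.seed(15)
  zs <- vapply(1:300, function(i) {
    y <- rnorm(n)
    summary(lm(y ~ sample(dose)))$coefficients[2, 3]
  }, numeric(1))
  expect_gte(mean(abs(zs) <= 3), 0.99)
  stDeg <- makeStudy(nGenes = 2, nSamples = 10, probes = 1, seed = 16,
                     phenotype = rep(1, 10), phenotypeType = "dosage")
  expect_error(familyHistoryZscore(stDeg, "g001"), "distinct dosage")
})

test_that("studyZscores is total: degenerate genes become flagged rows", {
  st <- makeStudy(nGenes = 10, nSamples = 16, probes = 2, seed = 17)
  tab <- studyZscores(st)
  expect_equal(nrow(tab), 10L)
  expect_true(all(tab$model %in% c("mixed", "single-probe", "fallback")))
  # a constant-expression gene errors out but the study completes
  ex <- SummarizedExperiment::assay(st, "exprs")
  ex[probeGenes(st) == "g001", ] <- 5
  st2 <- ExpressionStudy(ex, phenotype(st), probeGenes(st), studyId = "dg")
  tab2 <- studyZscores(st2)
  expect_equal(tab2$model[tab2$gene == "g001"], "error")
  expect_true(all(is.finite(tab2$z[tab2$gene != "g001"])))
})

test_that("permuting sample labels decorrelates the gene-wise z profile", {
  st <- makeStudy(nGenes = 200, nSamples = 24, probes = 1, shift = -0.6,
                  shiftGenes = sprintf("g%03d", 1:20), seed = 18)
  z1 <- studyZscores(st, useCovariates = FALSE)$z
  set.seed(20)
  st2 <- ExpressionStudy(SummarizedExperiment::assay(st, "exprs"),
                         sample(phenotype(st)), probeGenes(st),
                         studyId = "perm")
  z2 <- studyZscores(st2, useCovariates = FALSE)$z
  expect_lt(abs(cor(z1, z2)), 0.25)
})
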