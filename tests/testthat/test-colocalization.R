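# Fixture map for the chr13 worked example: 1 LDU per 50 kb across the
# region containing the two disease estimates and the PCCA eQTL.
chr13Map <- function() {
  pos <- seq(102.3e6, 102.6e6, by = 1e4)
  GeneticMap("13", pos, (pos - pos[1]) / 5e4)
}

chr13Estimates <- function() {
  data.frame(
    trait = c("disease", "disease", "expression"),
    cohort = c("GWAS-E", "GWAS-A", "MuTHER"),
    population = c("EUR", "AA", "EUR"),
    chrom = "13",
    pos_bp = c(102408534, 102452781, 102428282),
    p_value = c(1e-6, 5e-6, 0.01),
    target = c(NA, NA, "PCCA"))
}

test_that("two cohorts within 1 LDU form one cosmopolitan locus; its eQTL is called", {
  maps <- list("13" = chr13Map())
  est <- chr13Estimates()
  rep <- replicateLoci(est, maps)
  expect_equal(nrow(rep$loci), 1L)
  expect_true(rep$loci$cosmopolitan)
  expect_equal(rep$loci$tier, "bonferroni")
  expect_equal(rep$loci$rep_pos, 102408534)   # most significant member
  eq <- callT2dEqtl(rep, est, maps)
  expect_equal(nrow(eq$calls), 1L)
  expect_equal(eq$calls$target, "PCCA")
  expect_lte(eq$calls$ldu_dist, 1)
  ann <- data.frame(chrom = "13", start = 102410000, end = 102440000,
                    gene_id = "ENSG_PCCA", hgnc = "PCCA")
  cis <- assignCisGenes(eq, ann, probeMap = NULL)
  expect_equal(cis$calls$hgnc, "PCCA")
  expect_equal(cis$calls$n_loci, 1L)
})

test_that("replication requires at least two distinct cohorts", {
  maps <- list("13" = chr13Map())
  est <- chr13Estimates()[c(1, 1), ]
  est$pos_bp[2] <- est$pos_bp[1] + 1e4
  rep <- replicateLoci(est, maps)
  expect_equal(nrow(rep$loci), 0L)
})

test_that("single-linkage chaining matches a brute-force clustering oracle", {
  # three cohorts, pairwise LDU distances 0.6 / 0.6 / 1.2: one locus by
  # transitive closure
  gm <- uniformMap(len = 1e6, lduPerBp = 1e-5)  # 1 LDU per 100 kb
  maps <- list("1" = gm)
  pos <- c(1e5, 1.6e5, 2.2e5)
  est <- data.frame(trait = "disease",
                    cohort = c("A", "B", "C"), population = "EUR",
                    chrom = "1", pos_bp = pos, p_value = 1e-4,
                    target = NA)
  rep <- replicateLoci(est, maps)
  expect_equal(nrow(rep$loci), 1L)
  expect_equal(rep$loci$n_members, 3L)
  # brute-force oracle on random instances
  set.seed(11)
  for (i in 1:20) {
    n <- sample(3:8, 1)
    ldus <- runif(n, 0, 6)
    cl <- lducoloc:::.chainClusters(ldus, 1)
    oracle <- bruteSingleLinkage(ldus, 1)
    expect_equal(as.integer(factor(cl, unique(cl[order(ldus)]))),
                 as.integer(factor(oracle, unique(oracle[order(ldus)]))))
  }
})

test_that("co-location is decided in LDU, not physical distance", {
  # flat block [1, 100kb], sharp step, flat block [101kb, 200kb]
  maps <- list("1" = blockStepMap())
  est <- data.frame(
    trait = c("disease", "disease", "expression", "expression"),
    cohort = c("A", "B", "MuTHER", "MuTHER"),
    population = "EUR", chrom = "1",
    pos_bp = c(10000, 50000, 99000, 102000),
    #            ^ locus members in block 1; eQTL at 99kb is 89kb away in bp
    #              but 0 LDU; eQTL at 102kb is only 3kb from 99kb but across
    #              the 5-LDU step
    p_value = c(1e-4, 1e-4, 0.01, 0.01),
    target = c(NA, NA, "NEAR_LDU", "NEAR_BP"))
  rep <- replicateLoci(est, maps)
  eq <- callT2dEqtl(rep, est, maps)
  expect_equal(eq$calls$target, "NEAR_LDU")
})

test_that("raising the co-location threshold is monotone in calls", {
  set.seed(3)
  cfg <- scenarioConfig(seed = 3, nChrom = 2, chromLengthBp = 1e7,
                        nTrueLoci = 6, nDecoys = 8)
  d <- file.path(tempdir(), "coloc_mono")
  unlink(d, recursive = TRUE)
  makeScenario(cfg, d)
  maps <- readGeneticMap(file.path(d, "map.tsv"))
  est <- readLocationEstimates(file.path(d, "estimates.tsv"))
  c1 <- thresholdConfig(colocThreshold = 1)
  c2 <- thresholdConfig(colocThreshold = 2)
  r1 <- replicateLoci(est, maps, c1); r2 <- replicateLoci(est, maps, c2)
  e1 <- callT2dEqtl(r1, est, maps, c1); e2 <- callT2dEqtl(r2, est, maps, c2)
  k1 <- unique(e1$calls$target); k2 <- unique(e2$calls$target)
  expect_true(all(k1 %in% k2))
})

test_that("cis-gene calls trace back to loci through eQTL (referential closure)", {
  cfg <- scenarioConfig(seed = 5, nChrom = 2, chromLengthBp = 1e7,
                        nTrueLoci = 6, nDecoys = 5)
  d <- file.path(tempdir(), "coloc_closure")
  unlink(d, recursive = TRUE)
  makeScenario(cfg, d)
  maps <- readGeneticMap(file.path(d, "map.tsv"))
  est <- readLocationEstimates(file.path(d, "estimates.tsv"))
  ann <- readGeneAnnotation(file.path(d, "annotation.tsv"))
  pm <- read.delim(file.path(d, "eqtl_probe_map.tsv"))
  rep <- replicateLoci(est, maps)
  eq <- callT2dEqtl(rep, est, maps)
  cis <- assignCisGenes(eq, ann, pm)
  expect_gt(nrow(cis$calls), 0)
  for (i in seq_len(nrow(cis$calls))) {
    loci <- strsplit(cis$calls$loci[i], ",")[[1]]
    expect_true(all(loci %in% rep$loci$locus_id))
    expect_gte(cis$calls$n_eqtl[i], 1)
  }
  # every supporting pair respects the LDU threshold
  expect_true(all(cis$pairs$ldu_dist <= 1))
})

test_that("out-of-range and unmapped estimates are excluded with reasons", {
  maps <- list("1" = uniformMap())
  est <- data.frame(trait = "disease", cohort = c("A", "B", "C"),
                    population = "EUR", chrom = c("1", "1", "99"),
                    pos_bp = c(5e5, 5e6, 100), p_value = 1e-4, target = NA)
  conv <- convertToMap(est, maps)
  expect_equal(nrow(conv$kept), 1L)
  expect_setequal(conv$excluded$reason,
                  c("position outside map extent", "no map for chromosome"))
  # identity on the target map: physical position unchanged
  expect_equal(conv$kept$pos_bp, 5e5)
})

test_that("NEMG flagging repairs spreadsheet-mangled symbols", {
  calls <- data.frame(gene_id = c("ENSG1", "ENSG2", "ENSG3"),
                      hgnc = c("Mar-05", "PCCA", "NOTAMITO"))
  flagged <- suppressMessages(flagNemg(calls, c("MARCH5", "pcca")))
  expect_equal(flagged$nemg, c(TRUE, TRUE, FALSE))
  empty <- flagNemg(calls, character(0))
  expect_false(any(empty$nemg))
  expect_equal(normalizeSymbols(c("Mar-05", "5-Mar", "Sep-07")),
               c("MARCH5", "MARCH5", "SEPT7"))
})

test_that("Fisher proportion test matches hypergeometric enumeration", {
  # identical proportions -> p = 1
  res <- nemgProportionTest(100, 10, 1100, 110)
  expect_equal(res$p_value, 1)
  # small 2x2 against full enumeration over tables with fixed margins
  a <- 3; b <- 7; c <- 10; d <- 80
  res2 <- nemgProportionTest(a + b, a, (a + b) + (c + d), a + c)
  m <- a + c; n0 <- b + d; k <- a + b
  probs <- vapply(max(0, k - n0):min(k, m), function(x)
    choose(m, x) * choose(n0, k - x) / choose(m + n0, k), numeric(1))
  pObs <- choose(m, a) * choose(n0, k - a) / choose(m + n0, k)
  pEnum <- sum(probs[probs <= pObs * (1 + 1e-7)])
  expect_equal(res2$p_value, pEnum, tolerance = 1e-10)
  expect_error(nemgProportionTest(10, 5, 100, 3), "valid 2x2")
  # the published proportions: 50 of 763 is 6.6% to one decimal
  expect_equal(round(nemgProportionTest(763, 50, 21215, 1146)$cis_percent, 1),
               6.6)
})

test_that("planted co-locations are recovered with decoys rejected", {
  cfg <- scenarioConfig(seed = 21)
  d <- file.path(tempdir(), "coloc_recov")
  unlink(d, recursive = TRUE)
  makeScenario(cfg, d)
  maps <- readGeneticMap(file.path(d, "map.tsv"))
  est <- readLocationEstimates(file.path(d, "estimates.tsv"))
  rep <- replicateLoci(est, maps)
  score <- scoreLocusRecovery(rep$loci, readTruth(d), maps)
  expect_gte(score$sensitivity, 0.9)
  expect_lte(score$false_call_rate, 0.1)
})
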