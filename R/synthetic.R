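#' Scenario configuration for the synthetic-data generators
#'
#' Fixes the conditions the generators emulate: block/step LDU map geometry,
#' three case-control cohorts (two European, one African-American) with
#' planted 1-LDU co-locations plus isolated decoys, probe-level log2
#' expression (RMA-like, values ~4-14) with planted case effects for the
#' true cis genes, a shared-factor co-expression structure among NEMGs,
#' age/BMI covariates, and pathway sets with planted count enrichment.
#' Defaults are desk-scale: 3 chromosomes x 30 Mb, ~600 genes, 20 true
#' loci, 2 studies per tissue at 30 samples.
#'
#' @param seed integer RNG seed; every generated byte derives from it.
#' @param nChrom,chromLengthBp genome shape.
#' @param anchorSpacingBp map anchor spacing; `stepProb` is the chance an
#'   inter-anchor interval is an LD step, `meanStepLdu` the mean step
#'   height, giving ~1 LDU per `anchorSpacingBp / (stepProb * meanStepLdu)`
#'   bp (default ~50 kb, the order seen on real European maps).
#' @param genesPerMb gene density.
#' @param nTrueLoci planted disease loci; `jitterLdu` the per-cohort
#'   location-estimate jitter (LDU); `nDecoys` isolated single-cohort
#'   decoys at least `decoyMinLdu` from any truth.
#' @param aaShare fraction of true loci also observed in the AA cohort
#'   (cosmopolitan).
#' @param cisGenesPerLocus mean cis genes per locus (>= 1 drawn).
#' @param eqtlJitterLdu eQTL placement jitter around the locus (truncated
#'   so planted eQTL stay within 1 LDU).
#' @param nemgFraction fraction of genes on the NEMG reference list;
#'   `cisNemgBias` the preference for NEMGs when drawing cis genes.
#' @param caseShift planted log2 case effect for true cis genes (negative:
#'   decreased in cases); the family-history dosage effect is half of it
#'   per affected parent.
#' @param factorLoading shared-factor loading for NEMG co-expression.
#' @param geneSd,probeSd,probeOffsetSd expression noise components (log2).
#' @param ageBetaSd,bmiBetaSd per-gene covariate coefficient spread;
#'   `covariateConfounding` shifts case age/BMI upward.
#' @param studiesPerTissue named integer vector (tissue -> study count).
#' @param samplesPerStudy samples per study (balanced cases/controls).
#' @param maxProbes probes per gene drawn uniformly from 1..maxProbes.
#' @param nSets,setSize,nEnrichedSets,enrichedCisCount pathway-set shape:
#'   `nEnrichedSets` sets each contain `enrichedCisCount` true cis genes.
#' @return list of class `scenarioConfig`.
#' @export
scenarioConfig <- function(seed = 1,
                           nChrom = 3, chromLengthBp = 30e6,
                           anchorSpacingBp = 10000, stepProb = 0.2,
                           meanStepLdu = 1,
                           genesPerMb = 7,
                           nTrueLoci = 20, jitterLdu = 0.2,
                           nDecoys = 30, decoyMinLdu = 3,
                           aaShare = 0.6,
                           cisGenesPerLocus = 2,
                           eqtlJitterLdu = 0.3,
                           nemgFraction = 0.15, cisNemgBias = 0.4,
                           caseShift = -0.5,
                           factorLoading = 0.4,
                           geneSd = 0.5, probeSd = 0.3, probeOffsetSd = 0.3,
                           ageBetaSd = 0.02, bmiBetaSd = 0.02,
                           covariateConfounding = 1,
                           studiesPerTissue = c(adipose = 2, muscle = 2),
                           samplesPerStudy = 30,
                           maxProbes = 4,
                           nSets = 8, setSize = 30,
                           nEnrichedSets = 2, enrichedCisCount = 8) {
  cfg <- as.list(environment())
  stopifnot(cfg$nChrom >= 1, cfg$nTrueLoci >= 1, cfg$jitterLdu >= 0,
            cfg$factorLoading >= 0, cfg$factorLoading <= 1,
            cfg$samplesPerStudy >= 6)
  structure(cfg, class = "scenarioConfig")
}

#' Simulate block/step LDU genetic maps
#'
#' Anchors on a regular bp grid; each inter-anchor interval is flat (an LD
#' block) with probability `1 - stepProb`, otherwise rises by an
#' exponential step.  Resulting maps satisfy the GeneticMap invariants.
#'
#' @param cfg a [scenarioConfig()].
#' @return named list of [GeneticMap-class].
#' @export
simulateMap <- function(cfg) {
  maps <- list()
  for (ch in seq_len(cfg$nChrom)) {
    chrom <- as.character(ch)
    pos <- seq(1, cfg$chromLengthBp, by = cfg$anchorSpacingBp)
    inc <- ifelse(runif(length(pos) - 1L) < cfg$stepProb,
                  stats::rexp(length(pos) - 1L, rate = 1 / cfg$meanStepLdu),
                  0)
    maps[[chrom]] <- GeneticMap(chrom, pos, cumsum(c(0, inc)))
  }
  maps
}

## Gene annotation with NEMG flags; genes uniform along each chromosome.
simulateAnnotation <- function(cfg) {
  rows <- list()
  gid <- 0L
  for (ch in seq_len(cfg$nChrom)) {
    nG <- round(cfg$genesPerMb * cfg$chromLengthBp / 1e6)
    start <- sort(round(runif(nG, 1e5, cfg$chromLengthBp - 2e5)))
    width <- round(runif(nG, 5e3, 1e5))
    idx <- gid + seq_len(nG)
    rows[[ch]] <- data.frame(
      chrom = as.character(ch), start = start, end = start + width,
      gene_id = sprintf("ENSG%06d", idx),
      hgnc = sprintf("GENE%04d", idx))
    gid <- gid + nG
  }
  ann <- do.call(rbind, rows)
  ann$nemg <- runif(nrow(ann)) < cfg$nemgFraction
  rownames(ann) <- NULL
  ann
}

## Smallest bp position whose LDU is >= target (inverse map helper).
.lduToBp <- function(map, targetLdu) .bpAtLduLeft(map, targetLdu)

#' Simulate disease and eQTL location estimates with planted truth
#'
#' True loci are placed uniformly in LDU space (well inside the map and
#' pairwise separated).  Each cohort contributes an estimate at
#' truth +/- Normal(0, jitter) LDU mapped back to bp, with p-values below
#' the nominal disease threshold (each locus gets at least one estimate
#' below the corrected tier threshold with probability 1/2); the AA cohort
#' observes a subset of loci (cosmopolitan).  Decoys are single-cohort
#' estimates isolated by at least `decoyMinLdu` from every truth.  Each
#' true cis gene receives an eQTL within 1 LDU of its locus (p < 0.05);
#' a matched number of non-cis genes receive far eQTL (> 2 LDU) or
#' non-significant ones.
#'
#' @param cfg a [scenarioConfig()].
#' @param maps from [simulateMap()].
#' @param annotation from the scenario's annotation step.
#' @return list: `estimates` (data.frame), `probeMap`, `truth` (list with
#'   `loci` data.frame and `cisGenes` per-locus assignments).
#' @export
simulateEstimates <- function(cfg, maps, annotation) {
  cohorts <- data.frame(cohort = c("GWAS-E", "metabo-E", "GWAS-A"),
                        population = c("EUR", "EUR", "AA"))
  lduRange <- lapply(maps, function(m) range(mapLdu(m)))
  # spread loci over chromosomes, uniform in LDU, >= 3 LDU apart
  lociChrom <- sort(rep_len(names(maps), cfg$nTrueLoci))
  truthRows <- list()
  for (chrom in unique(lociChrom)) {
    k <- sum(lociChrom == chrom)
    lo <- lduRange[[chrom]][1] + 2; hi <- lduRange[[chrom]][2] - 2
    pts <- numeric(0)
    guard <- 0
    while (length(pts) < k && guard < 10000) {
      cand <- runif(1, lo, hi)
      if (all(abs(cand - pts) >= cfg$decoyMinLdu + 2)) pts <- c(pts, cand)
      guard <- guard + 1
    }
    if (length(pts) < k)
      stop("could not place ", k, " separated loci on chromosome ", chrom)
    truthRows[[chrom]] <- data.frame(chrom = chrom, ldu = sort(pts))
  }
  truth <- do.call(rbind, truthRows)
  truth$pos_bp <- mapply(function(ch, l) .lduToBp(maps[[ch]], l),
                         truth$chrom, truth$ldu)
  truth$locus <- sprintf("true_%02d", seq_len(nrow(truth)))
  truth$cosmopolitan <- runif(nrow(truth)) < cfg$aaShare
  rownames(truth) <- NULL

  est <- list()
  for (i in seq_len(nrow(truth))) {
    coh <- if (truth$cosmopolitan[i]) cohorts else
      cohorts[cohorts$population == "EUR", ]
    tier <- runif(1) < 0.5
    for (j in seq_len(nrow(coh))) {
      ldu <- truth$ldu[i] + rnorm(1, 0, cfg$jitterLdu)
      p <- if (tier && j == 1L) 10^(-runif(1, 5.5, 8)) else
        10^(-runif(1, 3.1, 5))
      est[[length(est) + 1L]] <- data.frame(
        trait = "disease", cohort = coh$cohort[j],
        population = coh$population[j], chrom = truth$chrom[i],
        pos_bp = .lduToBp(maps[[truth$chrom[i]]], ldu),
        p_value = p, target = NA_character_)
    }
  }
  # decoys: single-cohort, isolated
  for (d in seq_len(cfg$nDecoys)) {
    repeat {
      chrom <- sample(names(maps), 1L)
      lo <- lduRange[[chrom]][1] + 1; hi <- lduRange[[chrom]][2] - 1
      ldu <- runif(1, lo, hi)
      nearTruth <- truth$ldu[truth$chrom == chrom]
      if (!length(nearTruth) || min(abs(ldu - nearTruth)) >= cfg$decoyMinLdu)
        break
    }
    est[[length(est) + 1L]] <- data.frame(
      trait = "disease", cohort = sample(cohorts$cohort, 1L),
      population = "EUR", chrom = chrom,
      pos_bp = .lduToBp(maps[[chrom]], ldu),
      p_value = 10^(-runif(1, 3.1, 5)), target = NA_character_)
  }

  # cis genes: genes within the cis window of each locus, NEMG-biased
  cisAssign <- list()
  usedGenes <- character(0)
  for (i in seq_len(nrow(truth))) {
    near <- which(annotation$chrom == truth$chrom[i] &
                    annotation$end >= truth$pos_bp[i] - 1.4e6 &
                    annotation$start <= truth$pos_bp[i] + 1.4e6 &
                    !(annotation$hgnc %in% usedGenes))
    if (!length(near)) next
    k <- min(length(near), 1L + stats::rpois(1, cfg$cisGenesPerLocus - 1))
    w <- ifelse(annotation$nemg[near], cfg$cisNemgBias, 1 - cfg$cisNemgBias)
    pick <- near[sample.int(length(near), k, prob = w)]
    usedGenes <- c(usedGenes, annotation$hgnc[pick])
    cisAssign[[truth$locus[i]]] <- annotation$hgnc[pick]
  }
  cisGenes <- unlist(cisAssign, use.names = FALSE)

  # eQTL estimates: planted co-locations for cis genes, decoy eQTL otherwise
  probeMap <- list(); pe <- 0L
  for (i in seq_len(nrow(truth))) {
    genes <- cisAssign[[truth$locus[i]]]
    for (g in genes) {
      pe <- pe + 1L
      probe <- sprintf("eprobe%04d", pe)
      probeMap[[pe]] <- data.frame(probe = probe, gene = g)
      jit <- max(-0.9, min(0.9, rnorm(1, 0, cfg$eqtlJitterLdu)))
      est[[length(est) + 1L]] <- data.frame(
        trait = "expression", cohort = "MuTHER", population = "EUR",
        chrom = truth$chrom[i],
        pos_bp = .lduToBp(maps[[truth$chrom[i]]], truth$ldu[i] + jit),
        p_value = runif(1, 1e-6, 0.049), target = probe)
    }
  }
  nonCis <- setdiff(annotation$hgnc, cisGenes)
  nNon <- min(length(nonCis), length(cisGenes) + 20L)
  for (g in sample(nonCis, nNon)) {
    pe <- pe + 1L
    probe <- sprintf("eprobe%04d", pe)
    probeMap[[pe]] <- data.frame(probe = probe, gene = g)
    chrom <- annotation$chrom[annotation$hgnc == g]
    onChrom <- which(truth$chrom == chrom)
    far <- runif(1) < 0.5 || !length(onChrom)
    if (far) {
      repeat {
        ldu <- runif(1, lduRange[[chrom]][1], lduRange[[chrom]][2])
        nearTruth <- truth$ldu[truth$chrom == chrom]
        if (!length(nearTruth) || min(abs(ldu - nearTruth)) > 2) break
      }
      pos <- .lduToBp(maps[[chrom]], ldu)
      p <- runif(1, 1e-4, 0.049)
    } else {
      i <- onChrom[sample.int(length(onChrom), 1L)]
      pos <- .lduToBp(maps[[chrom]], truth$ldu[i] + rnorm(1, 0, 0.3))
      p <- runif(1, 0.05, 1)          # near but non-significant
    }
    est[[length(est) + 1L]] <- data.frame(
      trait = "expression", cohort = "MuTHER", population = "EUR",
      chrom = chrom, pos_bp = pos, p_value = p, target = probe)
  }
  estimates <- do.call(rbind, est)
  rownames(estimates) <- NULL
  list(estimates = estimates,
       probeMap = do.call(rbind, probeMap),
       truth = list(loci = truth, cisAssign = cisAssign,
                    cisGenes = cisGenes))
}

#' Simulate case/control expression studies with planted effects
#'
#' Gene scores follow a one-factor model: NEMGs load on a shared
#' per-sample factor F with loading lambda, so their pairwise correlation
#' under the null is lambda^2.  True cis genes receive the planted case
#' shift (dosage-proportional at half strength in the family-history
#' study).  Probe values add per-probe offsets and noise on an RMA-like
#' log2 scale; age and BMI covariates are mildly confounded with case
#' status and have small per-gene effects.
#'
#' @param cfg a [scenarioConfig()].
#' @param annotation scenario annotation (with `nemg`).
#' @param cisGenes character vector of true differentially expressed genes.
#' @return list of [ExpressionStudy-class]; the last muscle study is the
#'   family-history (dosage) design.
#' @export
simulateExpression <- function(cfg, annotation, cisGenes) {
  genes <- annotation$hgnc
  nG <- length(genes)
  lambda <- ifelse(annotation$nemg, cfg$factorLoading, 0)
  baseline <- runif(nG, 6, 12)
  ageBeta <- rnorm(nG, 0, cfg$ageBetaSd)
  bmiBeta <- rnorm(nG, 0, cfg$bmiBetaSd)
  isDe <- genes %in% cisGenes
  studies <- list()
  sid <- 0L
  for (tissue in names(cfg$studiesPerTissue)) {
    for (s in seq_len(cfg$studiesPerTissue[[tissue]])) {
      sid <- sid + 1L
      lastMuscle <- tissue == "muscle" && s == cfg$studiesPerTissue[[tissue]]
      n <- cfg$samplesPerStudy
      if (lastMuscle) {
        pheno <- rep(0:2, length.out = n)
        phenoType <- "dosage"
        shift <- cfg$caseShift / 2
      } else {
        pheno <- rep(0:1, length.out = n)
        phenoType <- "case_control"
        shift <- cfg$caseShift
      }
      age <- rnorm(n, 50, 8) + cfg$covariateConfounding * pheno
      bmi <- rnorm(n, 28, 4) + 0.5 * cfg$covariateConfounding * pheno
      f <- rnorm(n)
      score <- matrix(0, nG, n)
      eps <- matrix(rnorm(nG * n), nG, n)
      score <- cfg$geneSd * (lambda %o% f + sqrt(1 - lambda^2) * eps)
      score <- score + baseline +
        outer(ageBeta, age - 50) + outer(bmiBeta, bmi - 28)
      if (any(isDe))
        score[isDe, ] <- score[isDe, ] +
          matrix(shift * pheno, sum(isDe), n, byrow = TRUE)
      nProbes <- sample.int(cfg$maxProbes, nG, replace = TRUE)
      probeGene <- rep(genes, times = nProbes)
      offs <- rnorm(length(probeGene), 0, cfg$probeOffsetSd)
      ex <- score[rep(seq_len(nG), times = nProbes), , drop = FALSE] +
        offs + matrix(rnorm(length(probeGene) * n, 0, cfg$probeSd),
                      length(probeGene), n)
      rownames(ex) <- sprintf("p%05d", seq_along(probeGene))
      colnames(ex) <- sprintf("s%02d", seq_len(n))
      studies[[sid]] <- ExpressionStudy(
        ex, phenotype = pheno, probeGene = probeGene,
        studyId = sprintf("%s_%d", tissue, s), tissue = tissue,
        age = age, bmi = bmi, phenotypeType = phenoType)
    }
  }
  studies
}

#' Simulate pathway gene sets and the NEMG reference list
#'
#' The NEMG list covers the annotation's NEMG-flagged genes.  Planted
#' enriched sets contain `enrichedCisCount` true cis genes each (plus
#' random non-cis fillers); distractor sets are uniform draws.
#'
#' @param cfg a [scenarioConfig()].
#' @param annotation scenario annotation.
#' @param cisGenes true cis genes.
#' @return list with `sets` (named list), `nemgList`, `enrichedSets`
#'   (names of planted sets).
#' @export
simulateGeneSets <- function(cfg, annotation, cisGenes) {
  genes <- annotation$hgnc
  nemgList <- genes[annotation$nemg]
  sets <- list()
  enriched <- character(0)
  for (i in seq_len(cfg$nSets)) {
    nm <- sprintf("SET_%02d", i)
    if (i <= cfg$nEnrichedSets) {
      kCis <- min(cfg$enrichedCisCount, length(cisGenes))
      members <- c(sample(cisGenes, kCis),
                   sample(setdiff(genes, cisGenes), cfg$setSize - kCis))
      enriched <- c(enriched, nm)
    } else {
      members <- sample(genes, cfg$setSize)
    }
    sets[[nm]] <- members
  }
  list(sets = sets, nemgList = nemgList, enrichedSets = enriched)
}

#' Generate a complete synthetic input bundle with a truth manifest
#'
#' Writes every file the pipeline consumes (maps, location estimates,
#' annotation, probe maps, expression matrices and phenotypes, NEMG list,
#' GMT sets) plus a `truth.txt` manifest sufficient to score every stage.
#' Writing is atomic: files land in a temporary sibling directory which is
#' renamed into place, so a partial write leaves no manifest.  A fixed
#' seed reproduces the bundle byte for byte.
#'
#' @param cfg a [scenarioConfig()].
#' @param dir output directory (must not exist or be empty).
#' @return `dir`, invisibly; side effect: the bundle on disk.
#' @export
makeScenario <- function(cfg = scenarioConfig(), dir) {
  if (missing(dir)) stop("an output directory is required")
  if (dir.exists(dir) && length(list.files(dir)))
    stop("output directory exists and is not empty: ", dir)
  tmp <- paste0(dir, ".tmp")
  unlink(tmp, recursive = TRUE)
  dir.create(tmp, recursive = TRUE)
  set.seed(cfg$seed)
  maps <- simulateMap(cfg)
  annotation <- simulateAnnotation(cfg)
  simEst <- simulateEstimates(cfg, maps, annotation)
  studies <- simulateExpression(cfg, annotation, simEst$truth$cisGenes)
  genesets <- simulateGeneSets(cfg, annotation, simEst$truth$cisGenes)

  writeGeneticMap(maps, file.path(tmp, "map.tsv"))
  write.table(simEst$estimates, file.path(tmp, "estimates.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(annotation[, c("chrom", "start", "end", "gene_id", "hgnc")],
              file.path(tmp, "annotation.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(simEst$probeMap, file.path(tmp, "eqtl_probe_map.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(genesets$nemgList, file.path(tmp, "nemg_list.txt"))
  writeGmt(genesets$sets, file.path(tmp, "sets.gmt"))

  studyRows <- list()
  for (st in studies) {
    id <- studyId(st)
    ex <- SummarizedExperiment::assay(st, "exprs")
    exDf <- data.frame(probe = rownames(ex), ex, check.names = FALSE)
    write.table(exDf, file.path(tmp, sprintf("expr_%s.tsv", id)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    cd <- SummarizedExperiment::colData(st)
    phDf <- data.frame(sample = rownames(cd), phenotype = cd$phenotype,
                       age = cd$age, bmi = cd$bmi)
    write.table(phDf, file.path(tmp, sprintf("pheno_%s.tsv", id)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    pmDf <- data.frame(probe = rownames(ex),
                       gene = SummarizedExperiment::rowData(st)$gene)
    write.table(pmDf, file.path(tmp, sprintf("probe_map_%s.tsv", id)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    studyRows[[id]] <- data.frame(
      study = id, tissue = studyTissue(st),
      phenotype_type = S4Vectors::metadata(st)$phenotypeType,
      exprs = sprintf("expr_%s.tsv", id),
      pheno = sprintf("pheno_%s.tsv", id),
      probe_map = sprintf("probe_map_%s.tsv", id))
  }
  write.table(do.call(rbind, studyRows), file.path(tmp, "studies.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  truth <- simEst$truth
  manifest <- c(
    sprintf("seed=%d", cfg$seed),
    sprintf("n_true_loci=%d", nrow(truth$loci)),
    sprintf("true_locus_pos=%s",
            paste(sprintf("%s:%d", truth$loci$chrom,
                          round(truth$loci$pos_bp)), collapse = ",")),
    sprintf("true_locus_ldu=%s",
            paste(sprintf("%s:%.6f", truth$loci$chrom, truth$loci$ldu),
                  collapse = ",")),
    sprintf("true_cis_genes=%s", paste(truth$cisGenes, collapse = ",")),
    sprintf("locus_sizes=%s",
            paste(vapply(truth$cisAssign, length, integer(1)),
                  collapse = ",")),
    sprintf("enriched_sets=%s", paste(genesets$enrichedSets, collapse = ",")),
    sprintf("n_nemg=%d", length(genesets$nemgList)))
  writeLines(manifest, file.path(tmp, "truth.txt"))

  unlink(dir, recursive = TRUE)
  file.rename(tmp, dir)
  invisible(dir)
}

#' Read a scenario truth manifest
#'
#' @param path path to `truth.txt` (or a scenario directory).
#' @return named list of character values (comma-joined lists split).
#' @export
readTruth <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "truth.txt")
  lines <- readLines(path)
  kv <- strsplit(lines, "=", fixed = TRUE)
  out <- lapply(kv, function(x) strsplit(x[2], ",", fixed = TRUE)[[1]])
  names(out) <- vapply(kv, `[`, character(1), 1L)
  out
}
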