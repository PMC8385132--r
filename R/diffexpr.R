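## Fit machinery shared by the case-control and family-history designs.
## Sign convention: positive z = higher expression in cases (or per affected
## parent), since the phenotype enters as the numeric predictor.
.zFromFit <- function(fit, term = "pheno") {
  est <- fixefOrCoef(fit)[term]
  se <- sqrt(diag(as.matrix(vcov(fit)))[term])
  unname(est / se)
}

fixefOrCoef <- function(fit) {
  if (inherits(fit, "merMod")) lme4::fixef(fit) else coef(fit)
}

.covariateMatrix <- function(study, useCovariates) {
  cd <- SummarizedExperiment::colData(study)
  covs <- intersect(c("age", "bmi"), colnames(cd))
  if (!useCovariates || !length(covs)) return(NULL)
  as.data.frame(cd[, covs, drop = FALSE])
}

#' Gene-level differential-expression Z-score for one gene
#'
#' Summarises case-vs-control differential expression of one gene as a
#' standard-normal-scale statistic, by regressing normalized probe
#' expression on phenotype (0 control / 1 case), plus age and BMI where
#' available.  Genes measured by a single probe use ordinary least squares
#' (z = coefficient / standard error).  Genes with several annotated probes
#' use a linear mixed model over the long (probe, sample) layout with a
#' fixed phenotype effect and random intercepts for probe and, by default,
#' for sample (each subject is measured once per probe).  If the mixed fit
#' fails, probes are averaged per sample and OLS is used (flagged
#' `fallback`).
#'
#' @param study an [ExpressionStudy-class].
#' @param gene gene id (must own >= 1 probe in the study).
#' @param useCovariates include age/BMI columns when present.
#' @param randomSample include the per-sample random intercept in the
#'   multi-probe model (probe-only grouping if `FALSE`).
#' @param predictor column of `colData` to use as the predictor
#'   (internal; [familyHistoryZscore()] sets the dosage design).
#' @return one-row data.frame: `study`, `gene`, `z`, `n_probes`, `model`
#'   (`single-probe`, `mixed`, or `fallback`).
#' @export
geneZscore <- function(study, gene, useCovariates = TRUE,
                       randomSample = TRUE, predictor = "phenotype") {
  stopifnot(is(study, "ExpressionStudy"))
  pg <- probeGenes(study)
  probes <- names(pg)[pg == gene]
  if (!length(probes)) stop("gene ", gene, " has no probes in study")
  ex <- SummarizedExperiment::assay(study, "exprs")[probes, , drop = FALSE]
  pheno <- as.numeric(SummarizedExperiment::colData(study)[[predictor]])
  if (var(pheno) == 0) stop("zero variance in phenotype")
  if (all(apply(ex, 1, var) == 0))
    stop("zero residual variance for gene ", gene)
  covs <- .covariateMatrix(study, useCovariates)
  nS <- ncol(ex)
  if (length(probes) == 1L) {
    df <- data.frame(y = as.numeric(ex[1L, ]), pheno = pheno)
    if (!is.null(covs)) df <- cbind(df, covs)
    fit <- lm(y ~ ., data = df)
    z <- .zFromFit(fit)
    if (!is.finite(z)) stop("zero residual variance for gene ", gene)
    return(data.frame(study = studyId(study), gene = gene, z = z,
                      n_probes = 1L, model = "single-probe"))
  }
  long <- data.frame(
    y = as.numeric(t(ex)),
    pheno = rep(pheno, times = length(probes)),
    probe = factor(rep(probes, each = nS)),
    sample = factor(rep(colnames(ex), times = length(probes))))
  if (!is.null(covs))
    long <- cbind(long, covs[rep(seq_len(nS), times = length(probes)), ,
                             drop = FALSE])
  fixed <- paste(c("pheno", colnames(covs)), collapse = " + ")
  rand <- if (randomSample) "(1 | probe) + (1 | sample)" else "(1 | probe)"
  form <- stats::as.formula(paste("y ~", fixed, "+", rand))
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(form, data = long, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore")))),
    error = function(e) NULL)
  z <- if (!is.null(fit)) tryCatch(.zFromFit(fit), error = function(e) NA_real_)
    else NA_real_
  if (is.null(fit) || !is.finite(z)) {
    # fallback: average probes per sample, then OLS
    df <- data.frame(y = colMeans(ex), pheno = pheno)
    if (!is.null(covs)) df <- cbind(df, covs)
    z <- .zFromFit(lm(y ~ ., data = df))
    if (!is.finite(z)) stop("zero residual variance for gene ", gene)
    return(data.frame(study = studyId(study), gene = gene, z = z,
                      n_probes = length(probes), model = "fallback"))
  }
  data.frame(study = studyId(study), gene = gene, z = z,
             n_probes = length(probes), model = "mixed")
}

#' Family-history dosage Z-score for one gene
#'
#' Same machinery as [geneZscore()] with expression regressed on the number
#' of T2D-affected parents (0, 1 or 2), probing pre-onset expression changes
#' in unaffected subjects.
#'
#' @inheritParams geneZscore
#' @return as [geneZscore()].
#' @export
familyHistoryZscore <- function(study, gene, useCovariates = TRUE,
                                randomSample = TRUE) {
  ph <- phenotype(study)
  if (!all(ph %in% 0:2))
    stop("family-history phenotype must be the number of affected parents (0, 1 or 2)")
  if (length(unique(ph)) < 2L)
    stop("fewer than 2 distinct dosage levels")
  geneZscore(study, gene, useCovariates = useCovariates,
             randomSample = randomSample)
}

#' Differential-expression Z-scores for every gene in a study
#'
#' Applies [geneZscore()] (or [familyHistoryZscore()] for dosage designs)
#' over the probe-to-gene partition.  Per-gene failures are reported as
#' flagged rows (model `"error"`, `z = NA`) rather than aborting the study.
#'
#' @inheritParams geneZscore
#' @return data.frame with one row per gene: `study`, `gene`, `z`,
#'   `n_probes`, `model`, `note`.
#' @export
studyZscores <- function(study, useCovariates = TRUE, randomSample = TRUE) {
  stopifnot(is(study, "ExpressionStudy"))
  dosage <- identical(S4Vectors::metadata(study)$phenotypeType, "dosage")
  genes <- unique(SummarizedExperiment::rowData(study)$gene)
  rows <- lapply(genes, function(g) {
    res <- tryCatch({
      out <- if (dosage)
        familyHistoryZscore(study, g, useCovariates, randomSample)
      else geneZscore(study, g, useCovariates, randomSample)
      out$note <- ""
      out
    }, error = function(e)
      data.frame(study = studyId(study), gene = g, z = NA_real_,
                 n_probes = sum(SummarizedExperiment::rowData(study)$gene == g),
                 model = "error", note = conditionMessage(e)))
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read an expression study from TSV files
#'
#' `exprsPath`: probe x sample matrix with probe ids in the first column
#' and sample ids in the header.  `phenoPath`: TSV `sample phenotype [age]
#' [bmi]`.  `probeMapPath`: TSV `probe gene`.
#'
#' @param exprsPath,phenoPath,probeMapPath input TSV paths.
#' @param studyId,tissue,phenotypeType passed to [ExpressionStudy()].
#' @return an [ExpressionStudy-class].
#' @export
readExpressionStudy <- function(exprsPath, phenoPath, probeMapPath,
                                studyId = "study", tissue = "adipose",
                                phenotypeType = "case_control") {
  ex <- read.delim(exprsPath, check.names = FALSE)
  probes <- ex[[1L]]
  ex <- as.matrix(ex[, -1L, drop = FALSE])
  rownames(ex) <- probes
  ph <- read.delim(phenoPath)
  ph <- ph[match(colnames(ex), ph$sample), , drop = FALSE]
  if (anyNA(ph$sample)) stop("phenotype file missing samples present in matrix")
  pm <- read.delim(probeMapPath)
  gene <- pm$gene[match(probes, pm$probe)]
  if (anyNA(gene)) stop("probe map does not cover all probes")
  ExpressionStudy(ex, phenotype = ph$phenotype, probeGene = gene,
                  studyId = studyId, tissue = tissue,
                  age = if ("age" %in% names(ph)) ph$age else NULL,
                  bmi = if ("bmi" %in% names(ph)) ph$bmi else NULL,
                  phenotypeType = phenotypeType)
}
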