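#' Mean correlation of each non-cis NEMG with the cis-NEMG group
#'
#' Gene-level expression is the average of a gene's annotated probes over
#' control samples.  For each non-cis NEMG, pairwise Pearson correlations
#' with every cis-NEMG are computed across the control samples and
#' averaged.  Zero-variance genes have undefined correlations and are
#' excluded pairwise with a message.  `mean_expr` (mean control-sample
#' gene-level expression) is carried along as the regression covariate.
#'
#' @param exprs probe x sample matrix of control-only normalized values.
#' @param probeGene character vector mapping rows of `exprs` to genes.
#' @param cisNemgs,nonT2dNemgs gene-id vectors for the two groups.
#' @return data.frame `gene mean_r mean_expr n_pairs`.
#' @export
meanCorrelationProfile <- function(exprs, probeGene, cisNemgs, nonT2dNemgs) {
  if (ncol(exprs) < 3L) stop("need at least 3 control samples")
  geneLevel <- rowsum(exprs, group = probeGene)
  counts <- table(probeGene)
  geneLevel <- geneLevel / as.vector(counts[rownames(geneLevel)])
  cis <- intersect(unique(cisNemgs), rownames(geneLevel))
  non <- intersect(unique(nonT2dNemgs), rownames(geneLevel))
  if (length(cis) < 1L || length(non) < 1L)
    stop("both gene groups must be present on the platform")
  sdCis <- apply(geneLevel[cis, , drop = FALSE], 1, sd)
  sdNon <- apply(geneLevel[non, , drop = FALSE], 1, sd)
  if (any(sdCis == 0))
    message(sum(sdCis == 0), " zero-variance cis-NEMG(s) excluded pairwise")
  cis <- cis[sdCis > 0]
  rMat <- matrix(NA_real_, length(non), length(cis),
                 dimnames = list(non, cis))
  if (length(cis))
    rMat[] <- cor(t(geneLevel[non, , drop = FALSE]),
                  t(geneLevel[cis, , drop = FALSE]))
  ok <- sdNon > 0
  if (any(!ok))
    message(sum(!ok), " zero-variance gene(s) excluded")
  data.frame(gene = non[ok],
             mean_r = rowMeans(rMat[ok, , drop = FALSE], na.rm = TRUE),
             mean_expr = rowMeans(geneLevel[non, , drop = FALSE])[ok],
             n_pairs = length(cis))
}

## Iteratively reweighted least squares with a given psi weight function.
.irls <- function(X, y, w0, weightFun, tol = 1e-6, maxIter = 100) {
  w <- w0
  for (iter in seq_len(maxIter)) {
    fit <- stats::lm.wfit(X, y, w = w)
    res <- y - X %*% fit$coefficients
    s <- median(abs(res)) / 0.6745            # robust scale (MAD about 0)
    if (s <= 0) s <- sd(res)
    if (s <= 0) break
    wNew <- weightFun(as.numeric(res) / s)
    if (max(abs(wNew - w)) < tol) { w <- wNew; break }
    w <- wNew
  }
  list(w = w, fit = stats::lm.wfit(X, y, w = w))
}

.huberW <- function(u, c = 1.345) pmin(1, c / abs(u))
.biweightW <- function(u, c = 4.685) ifelse(abs(u) < c, (1 - (u / c)^2)^2, 0)

#' Regress differential expression on cis-NEMG correlation
#'
#' Fits `z ~ mean_r + mean_expr`: does a gene's case-control
#' differential-expression statistic depend on how strongly its control
#' expression correlates with the cis-NEMG group, adjusting for absolute
#' expression level?  `robust = FALSE` is ordinary least squares.
#' `robust = TRUE` follows the classic iterative robust-regression recipe:
#' points with Cook's distance > 1 are dropped, then iteratively reweighted
#' least squares runs with Huber weights (tuning constant 1.345) to
#' convergence, then biweight (4.685) to convergence (weight change
#' < 1e-6); points with final weight < 0.01 are reported as outliers and
#' the fit line comes from the converged weights.
#'
#' @param records data.frame with columns `z`, `mean_r`, `mean_expr`
#'   (e.g. [meanCorrelationProfile()] joined with a meta z table).
#' @param robust use the robust procedure.
#' @param huberC,biweightC tuning constants.
#' @return list with `slope`, `intercept`, `expr_coef`, `p_value` (slope,
#'   two-sided), `n_used`, `n_outliers_removed`, `outliers` (gene ids or
#'   row indices), `method`.
#' @export
correlationDeRegression <- function(records, robust = TRUE,
                                    huberC = 1.345, biweightC = 4.685) {
  stopifnot(all(c("z", "mean_r", "mean_expr") %in% names(records)))
  records <- records[complete.cases(records[, c("z", "mean_r", "mean_expr")]), ]
  if (nrow(records) < 10L) stop("need at least 10 records")
  ids <- if ("gene" %in% names(records)) records$gene
    else as.character(seq_len(nrow(records)))
  X <- cbind(`(Intercept)` = 1, mean_r = records$mean_r,
             mean_expr = records$mean_expr)
  if (qr(X)$rank < ncol(X))
    stop("collinear predictors: mean_r and mean_expr are linearly dependent")
  y <- records$z
  n <- length(y)
  if (!robust) {
    fit <- lm(y ~ mean_r + mean_expr, data = records)
    sm <- summary(fit)$coefficients
    return(list(slope = sm["mean_r", 1], intercept = sm["(Intercept)", 1],
                expr_coef = sm["mean_expr", 1],
                p_value = sm["mean_r", 4], n_used = n,
                n_outliers_removed = 0L, outliers = character(0),
                method = "plain"))
  }
  fit0 <- lm(y ~ X - 1)
  cook <- stats::cooks.distance(fit0)
  keep <- cook <= 1 & is.finite(cook)
  Xk <- X[keep, , drop = FALSE]; yk <- y[keep]
  hub <- .irls(Xk, yk, rep(1, nrow(Xk)), function(u) .huberW(u, huberC))
  biw <- .irls(Xk, yk, hub$w, function(u) .biweightW(u, biweightC))
  w <- biw$w
  outlier <- w < 0.01
  # weighted-least-squares inference at the converged weights
  wls <- lm(yk ~ Xk[, "mean_r"] + Xk[, "mean_expr"], weights = w)
  sm <- summary(wls)$coefficients
  outIds <- c(ids[!keep], ids[keep][outlier])
  list(slope = sm[2, 1], intercept = sm[1, 1], expr_coef = sm[3, 1],
       p_value = sm[2, 4],
       n_used = sum(keep) - sum(outlier),
       n_outliers_removed = sum(!keep) + sum(outlier),
       outliers = outIds, method = "robust")
}
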