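#' DerSimonian-Laird random-effects combination of per-study effects
#'
#' Combines per-study gene-level Z-scores (within-study variance taken as 1
#' on the z scale) by the DerSimonian-Laird moment estimator:
#' with weights \eqn{w_i = 1/v_i}, the fixed-effect mean
#' \eqn{\bar z_w = \sum w_i z_i / \sum w_i}, heterogeneity
#' \eqn{Q = \sum w_i (z_i - \bar z_w)^2}, between-study variance
#' \eqn{\tau^2 = \max(0, (Q - (k-1)) / (\sum w_i - \sum w_i^2/\sum w_i))},
#' re-weights \eqn{w^*_i = 1/(v_i + \tau^2)}, combined mean
#' \eqn{\hat\mu = \sum w^*_i z_i / \sum w^*_i} and combined statistic
#' \eqn{z_{meta} = \hat\mu \sqrt{\sum w^*_i}}.
#'
#' @param z numeric vector of per-study effects (k >= 1).
#' @param v within-study variances (default 1 for z-scale effects).
#' @return list with `k`, `Q`, `tau2`, `mu`, `se`, `z_meta`.
#' @examples
#' randomEffectsCombine(c(2.0, 0.5, -1.0))  # Q = 4.5, tau2 = 1.25
#' @export
randomEffectsCombine <- function(z, v = rep(1, length(z))) {
  keep <- is.finite(z)
  if (any(!keep))
    message(sum(!keep), " non-finite effect(s) excluded from combination")
  z <- z[keep]; v <- v[keep]
  k <- length(z)
  if (k == 0L) stop("no finite effects to combine")
  w <- 1 / v
  zbar <- sum(w * z) / sum(w)
  Q <- sum(w * (z - zbar)^2)
  tau2 <- if (k > 1L) max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
    else 0
  ws <- 1 / (v + tau2)
  mu <- sum(ws * z) / sum(ws)
  se <- sqrt(1 / sum(ws))
  list(k = k, Q = Q, tau2 = tau2, mu = mu, se = se, z_meta = mu / se)
}

#' Random-effects meta-analysis of gene Z-scores by tissue
#'
#' Combines per-study differential-expression tables (from
#' [studyZscores()]) within each tissue, gene by gene, with
#' [randomEffectsCombine()].  Genes absent from some studies are combined
#' over the studies where they appear (union policy); the number of
#' contributing studies is recorded as `k`.
#'
#' @param effectTables list of per-study data.frames with columns `study`,
#'   `gene`, `z` (rows with non-finite `z` are dropped).
#' @param tissues character vector assigning each table to a tissue
#'   (recycled if length 1).
#' @return data.frame with one row per (tissue, gene): `tissue`, `gene`,
#'   `k`, `Q`, `tau2`, `z_meta`.
#' @export
metaByTissue <- function(effectTables, tissues) {
  stopifnot(length(effectTables) >= 1L)
  if (length(tissues) == 1L) tissues <- rep(tissues, length(effectTables))
  stopifnot(length(tissues) == length(effectTables))
  out <- list()
  for (tis in unique(tissues)) {
    tabs <- effectTables[tissues == tis]
    all <- do.call(rbind, lapply(tabs, function(t)
      t[is.finite(t$z), c("gene", "z"), drop = FALSE]))
    if (!nrow(all)) next
    sp <- split(all$z, all$gene)
    rows <- lapply(names(sp), function(g) {
      r <- randomEffectsCombine(sp[[g]])
      data.frame(tissue = tis, gene = g, k = r$k, Q = r$Q, tau2 = r$tau2,
                 z_meta = r$z_meta)
    })
    out[[tis]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
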