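#' Threshold configuration for colocalization calls
#'
#' Bundles the tunable thresholds of the co-location pipeline.  Defaults
#' follow the standard analysis: co-location within 1 LDU; disease location
#' estimates admitted at nominal p < 1e-3 and tiered at the
#' multiple-testing-corrected p < 1e-5 (about 5,000 independent genomic
#' tests); eQTL admitted at nominal p < 0.05; cis genes assigned within
#' +/- 1.5 Mb; replication requires estimates from at least 2 cohorts.
#'
#' @param colocThreshold LDU co-location threshold (> 0).
#' @param t2dPNominal,t2dPBonferroni disease-estimate p-value thresholds;
#'   `t2dPBonferroni <= t2dPNominal`.
#' @param eqtlP eQTL p-value threshold.
#' @param cisWindow physical cis window half-width in bp.
#' @param minCohorts minimum distinct cohorts for a replicated locus.
#' @param eqtlRule `"any"`: an eQTL co-locates with a locus if within
#'   `colocThreshold` of any member estimate; `"all"`: of every member.
#' @return list of class `thresholdConfig`.
#' @export
thresholdConfig <- function(colocThreshold = 1, t2dPNominal = 1e-3,
                            t2dPBonferroni = 1e-5, eqtlP = 0.05,
                            cisWindow = 1.5e6, minCohorts = 2,
                            eqtlRule = c("any", "all")) {
  eqtlRule <- match.arg(eqtlRule)
  stopifnot(colocThreshold > 0, t2dPNominal > 0, t2dPBonferroni > 0,
            eqtlP > 0, cisWindow > 0, minCohorts >= 1,
            t2dPBonferroni <= t2dPNominal)
  structure(list(colocThreshold = colocThreshold, t2dPNominal = t2dPNominal,
                 t2dPBonferroni = t2dPBonferroni, eqtlP = eqtlP,
                 cisWindow = cisWindow, minCohorts = minCohorts,
                 eqtlRule = eqtlRule),
            class = "thresholdConfig")
}

#' Read causal-variant location estimates
#'
#' TSV with header `trait cohort population chrom pos_bp p_value target`.
#' `trait` is `disease` or `expression`; expression rows carry a `target`
#' (probe or gene id), disease rows do not.
#'
#' @param path TSV path.
#' @return data.frame of location estimates.
#' @export
readLocationEstimates <- function(path) {
  df <- read.delim(path, colClasses = c(chrom = "character"), na.strings = c("NA", ""))
  need <- c("trait", "cohort", "population", "chrom", "pos_bp", "p_value", "target")
  if (!all(need %in% names(df)))
    stop("estimates file must have columns ", paste(need, collapse = ", "))
  validateEstimates(df)
  df
}

validateEstimates <- function(df) {
  stopifnot(all(df$p_value > 0 & df$p_value <= 1),
            all(df$pos_bp > 0))
  expr <- df$trait == "expression"
  if (any(expr & (is.na(df$target) | !nzchar(df$target))))
    stop("expression estimates must carry a target")
  invisible(df)
}

#' Annotate location estimates with an LDU coordinate on a target map
#'
#' Places each estimate on the target population's LDU map via its physical
#' position (the standard way to carry an African-American estimate onto the
#' European map).  The physical position is unchanged; estimates whose
#' position lies outside the target map's extent are excluded with a logged
#' reason.
#'
#' @param estimates data.frame as from [readLocationEstimates()].
#' @param maps named list of [GeneticMap-class], keyed by chromosome.
#' @return list with `kept` (estimates plus an `ldu` column) and `excluded`
#'   (dropped rows plus a `reason` column).
#' @export
convertToMap <- function(estimates, maps) {
  est <- estimates
  est$ldu <- NA_real_
  reason <- rep(NA_character_, nrow(est))
  for (i in seq_len(nrow(est))) {
    m <- maps[[est$chrom[i]]]
    if (is.null(m)) {
      reason[i] <- "no map for chromosome"
      next
    }
    rng <- range(mapPositions(m))
    if (est$pos_bp[i] < rng[1L] || est$pos_bp[i] > rng[2L]) {
      reason[i] <- "position outside map extent"
      next
    }
    est$ldu[i] <- lduAt(m, est$pos_bp[i])
  }
  drop <- !is.na(reason)
  excluded <- est[drop, , drop = FALSE]
  excluded$reason <- reason[drop]
  list(kept = est[!drop, , drop = FALSE], excluded = excluded)
}

## Single-linkage clustering on the 1-D LDU coordinate: sort and chain
## adjacent points whose gap is <= threshold (exact in one dimension).
.chainClusters <- function(ldu, threshold) {
  ord <- order(ldu)
  gaps <- diff(ldu[ord])
  cl <- cumsum(c(1L, as.integer(gaps > threshold)))
  out <- integer(length(ldu))
  out[ord] <- cl
  out
}

#' Cluster disease location estimates into replicated loci
#'
#' Disease estimates below the nominal p threshold are clustered by
#' single-linkage under LDU distance at the co-location threshold,
#' chromosome by chromosome.  Clusters supported by at least `minCohorts`
#' distinct cohorts become replicated loci.  The representative position is
#' that of the most significant member; a locus is cosmopolitan if any
#' member comes from an African-American (AA) cohort, and its significance
#' tier is `bonferroni` if any member p-value is below the corrected
#' threshold, else `nominal`.
#'
#' @param estimates disease-trait location estimates (data.frame).
#' @param maps named list of [GeneticMap-class].
#' @param cfg a [thresholdConfig()].
#' @return list with `loci` (one row per replicated locus: `locus_id`,
#'   `chrom`, `rep_pos`, `rep_ldu`, `n_members`, `n_cohorts`,
#'   `cosmopolitan`, `tier`, `min_p`), `members` (member estimates with
#'   `locus_id`), and `excluded` (map-range exclusions).
#' @export
replicateLoci <- function(estimates, maps, cfg = thresholdConfig()) {
  est <- estimates[estimates$trait == "disease" &
                     estimates$p_value < cfg$t2dPNominal, , drop = FALSE]
  empty <- list(
    loci = data.frame(locus_id = character(), chrom = character(),
                      rep_pos = numeric(), rep_ldu = numeric(),
                      n_members = integer(), n_cohorts = integer(),
                      cosmopolitan = logical(), tier = character(),
                      min_p = numeric()),
    members = data.frame(), excluded = data.frame())
  if (nrow(est) == 0L) return(empty)
  conv <- convertToMap(est, maps)
  est <- conv$kept
  if (nrow(est) == 0L) { empty$excluded <- conv$excluded; return(empty) }
  est$locus_id <- NA_character_
  lociRows <- list()
  for (chr in unique(est$chrom)) {
    idx <- which(est$chrom == chr)
    cl <- .chainClusters(est$ldu[idx], cfg$colocThreshold)
    for (k in unique(cl)) {
      mem <- idx[cl == k]
      if (length(unique(est$cohort[mem])) < cfg$minCohorts) next
      id <- sprintf("locus_%s_%d", chr, min(round(est$pos_bp[mem])))
      est$locus_id[mem] <- id
      best <- mem[which.min(est$p_value[mem])]
      lociRows[[id]] <- data.frame(
        locus_id = id, chrom = chr,
        rep_pos = est$pos_bp[best], rep_ldu = est$ldu[best],
        n_members = length(mem),
        n_cohorts = length(unique(est$cohort[mem])),
        cosmopolitan = any(est$population[mem] == "AA"),
        tier = if (any(est$p_value[mem] < cfg$t2dPBonferroni))
          "bonferroni" else "nominal",
        min_p = min(est$p_value[mem]))
    }
  }
  loci <- if (length(lociRows)) do.call(rbind, lociRows) else empty$loci
  rownames(loci) <- NULL
  members <- est[!is.na(est$locus_id), , drop = FALSE]
  list(loci = loci[order(loci$chrom, loci$rep_pos), , drop = FALSE],
       members = members, excluded = conv$excluded)
}

#' Call T2D-eQTL by 1-LDU co-location with replicated loci
#'
#' An expression location estimate (below the eQTL p threshold) is called a
#' disease-eQTL if its LDU distance to a replicated locus is within the
#' co-location threshold.  Under the default `"any"` rule the distance to a
#' locus is the minimum over that locus's member estimates; `"all"` requires
#' every member within threshold.  Co-location is decided purely on the LDU
#' scale — physical proximity across an LD step does not qualify.
#'
#' @param loci result of [replicateLoci()].
#' @param eqtls expression-trait location estimates (data.frame).
#' @inheritParams replicateLoci
#' @return list with `calls` (one row per locus x eQTL pair: locus fields
#'   plus `target`, `eqtl_pos`, `eqtl_p`, `ldu_dist`) and `excluded`.
#' @export
callT2dEqtl <- function(loci, eqtls, maps, cfg = thresholdConfig()) {
  eq <- eqtls[eqtls$trait == "expression" &
                eqtls$p_value < cfg$eqtlP, , drop = FALSE]
  conv <- convertToMap(eq, maps)
  eq <- conv$kept
  calls <- list()
  memb <- loci$members
  for (i in seq_len(nrow(loci$loci))) {
    L <- loci$loci[i, ]
    mIdx <- which(memb$locus_id == L$locus_id)
    cand <- which(eq$chrom == L$chrom)
    for (j in cand) {
      d <- abs(eq$ldu[j] - memb$ldu[mIdx])
      dist <- if (cfg$eqtlRule == "any") min(d) else max(d)
      if (dist <= cfg$colocThreshold) {
        calls[[length(calls) + 1L]] <- data.frame(
          locus_id = L$locus_id, chrom = L$chrom, rep_pos = L$rep_pos,
          tier = L$tier, cosmopolitan = L$cosmopolitan,
          target = eq$target[j], eqtl_pos = eq$pos_bp[j],
          eqtl_p = eq$p_value[j], ldu_dist = dist)
      }
    }
  }
  calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(locus_id = character(), chrom = character(),
               rep_pos = numeric(), tier = character(),
               cosmopolitan = logical(), target = character(),
               eqtl_pos = numeric(), eqtl_p = numeric(),
               ldu_dist = numeric())
  list(calls = calls, excluded = conv$excluded)
}

#' Read a BED-like gene annotation table
#'
#' TSV with header `chrom start end gene_id hgnc`.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
readGeneAnnotation <- function(path) {
  df <- read.delim(path, colClasses = c(chrom = "character"))
  need <- c("chrom", "start", "end", "gene_id", "hgnc")
  if (!all(need %in% names(df)))
    stop("annotation must have columns ", paste(need, collapse = ", "))
  df
}

#' Assign cis genes to called disease-eQTL
#'
#' Resolves each called eQTL's target to a gene (via the probe map, falling
#' back to a direct gene-id/symbol match in the annotation), then attaches
#' the gene to the locus iff its annotated span, padded by the cis window,
#' overlaps the locus representative position.  A gene supported by several
#' loci yields a single call with `n_loci > 1`.
#'
#' @param t2dEqtls result of [callT2dEqtl()].
#' @param annotation data.frame as from [readGeneAnnotation()].
#' @param probeMap data.frame with columns `probe`, `gene` (the designated
#'   annotated gene for probes overlapping several genes), or `NULL`.
#' @param cfg a [thresholdConfig()].
#' @return list with `calls` (one row per gene: `gene_id`, `hgnc`,
#'   `n_loci`, `n_eqtl`, `loci` comma-joined) , `pairs` (the supporting
#'   locus x eQTL x gene rows) and `excluded`.
#' @export
assignCisGenes <- function(t2dEqtls, annotation, probeMap = NULL,
                           cfg = thresholdConfig()) {
  calls <- t2dEqtls$calls
  excluded <- list()
  if (nrow(calls) == 0L)
    return(list(calls = data.frame(gene_id = character(), hgnc = character(),
                                   n_loci = integer(), n_eqtl = integer(),
                                   loci = character()),
                pairs = calls, excluded = data.frame()))
  # resolve targets to genes
  gene <- rep(NA_character_, nrow(calls))
  if (!is.null(probeMap)) {
    m <- match(calls$target, probeMap$probe)
    gene[!is.na(m)] <- probeMap$gene[m[!is.na(m)]]
  }
  direct <- is.na(gene) &
    (calls$target %in% annotation$gene_id | calls$target %in% annotation$hgnc)
  gene[direct] <- calls$target[direct]
  bad <- is.na(gene)
  if (any(bad))
    excluded$probe <- data.frame(calls[bad, ], reason = "unresolvable target")
  calls <- calls[!bad, , drop = FALSE]
  calls$gene_id <- gene[!bad]
  # gene coordinates
  aIdx <- match(calls$gene_id, annotation$gene_id)
  alt <- is.na(aIdx)
  aIdx[alt] <- match(calls$gene_id[alt], annotation$hgnc)
  noCoord <- is.na(aIdx)
  if (any(noCoord))
    excluded$coord <- data.frame(calls[noCoord, setdiff(names(calls), "gene_id"),
                                       drop = FALSE],
                                 gene_id = calls$gene_id[noCoord],
                                 reason = "gene missing coordinates")
  calls <- calls[!noCoord, , drop = FALSE]
  aIdx <- aIdx[!noCoord]
  if (nrow(calls)) {
    # element-wise: locus i against its own gene's padded span
    inWindow <- calls$chrom == annotation$chrom[aIdx] &
      calls$rep_pos >= annotation$start[aIdx] - cfg$cisWindow &
      calls$rep_pos <= annotation$end[aIdx] + cfg$cisWindow
    if (any(!inWindow))
      excluded$window <- data.frame(calls[!inWindow, , drop = FALSE],
                                    reason = "gene outside cis window")
    calls <- calls[inWindow, , drop = FALSE]
    aIdx <- aIdx[inWindow]
    calls$hgnc <- annotation$hgnc[aIdx]
  } else calls$hgnc <- character(0)
  pairs <- calls
  geneCalls <- if (nrow(pairs)) {
    sp <- split(pairs, pairs$gene_id)
    do.call(rbind, lapply(sp, function(g) data.frame(
      gene_id = g$gene_id[1L], hgnc = g$hgnc[1L],
      n_loci = length(unique(g$locus_id)),
      n_eqtl = nrow(g),
      loci = paste(sort(unique(g$locus_id)), collapse = ","))))
  } else data.frame(gene_id = character(), hgnc = character(),
                    n_loci = integer(), n_eqtl = integer(),
                    loci = character())
  rownames(geneCalls) <- NULL
  excluded <- if (length(excluded))
    do.call(rbind, lapply(excluded, function(d)
      d[, c("locus_id", "target", "reason")])) else data.frame()
  list(calls = geneCalls, pairs = pairs, excluded = excluded)
}

#' Normalize gene symbols, repairing spreadsheet-mangled names
#'
#' Uppercases, trims, and undoes the classic Excel date mangling of symbol
#' families (e.g. `Mar-05` / `5-Mar` for `MARCH5`, `Sep-07` for `SEPT7`,
#' `Dec-01` for `DEC1`).
#'
#' @param x character vector of symbols.
#' @return normalized character vector.
#' @examples
#' normalizeSymbols(c("Mar-05", "pcca", " GPAM "))
#' @export
normalizeSymbols <- function(x) {
  s <- toupper(trimws(as.character(x)))
  s <- sub("^MAR-0?([0-9]+)$", "MARCH\\1", s)
  s <- sub("^0?([0-9]+)-MAR$", "MARCH\\1", s)
  s <- sub("^SEP-0?([0-9]+)$", "SEPT\\1", s)
  s <- sub("^0?([0-9]+)-SEP$", "SEPT\\1", s)
  s <- sub("^DEC-0?([0-9]+)$", "DEC\\1", s)
  s <- sub("^0?([0-9]+)-DEC$", "DEC\\1", s)
  s
}

#' Flag nuclear-encoded mitochondrial genes among cis-gene calls
#'
#' Case-insensitive match of each call's HGNC symbol or gene id against a
#' MitoCarta-style reference list, after symbol normalization (including
#' repair of spreadsheet-mangled aliases on both sides).
#'
#' @param calls gene-level calls data.frame (from [assignCisGenes()]).
#' @param nemgList character vector of NEMG symbols/ids.
#' @return `calls` with a logical `nemg` column.
#' @export
flagNemg <- function(calls, nemgList) {
  if (!length(nemgList)) {
    calls$nemg <- rep(FALSE, nrow(calls))
    return(calls)
  }
  ref <- unique(normalizeSymbols(nemgList))
  calls$nemg <- normalizeSymbols(calls$hgnc) %in% ref |
    normalizeSymbols(calls$gene_id) %in% ref
  message(sum(calls$nemg), " of ", nrow(calls), " calls flagged as NEMG")
  calls
}

#' Fisher exact comparison of NEMG proportions
#'
#' Compares the NEMG fraction among cis genes with the genomic background
#' (background counts exclude the cis genes to form a disjoint 2x2 table).
#' The two-sided exact p comes from the hypergeometric tail sum.
#'
#' @param cisTotal,cisNemg cis-gene counts (total and NEMG).
#' @param backgroundTotal,backgroundNemg genomic background counts
#'   (including the cis genes; they are subtracted internally).
#' @return list with `cis_percent`, `background_percent`, `p_value`,
#'   `table` (the 2x2 used).
#' @export
nemgProportionTest <- function(cisTotal, cisNemg, backgroundTotal,
                               backgroundNemg) {
  tab <- matrix(c(cisNemg, cisTotal - cisNemg,
                  backgroundNemg - cisNemg,
                  (backgroundTotal - cisTotal) - (backgroundNemg - cisNemg)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("cis", "background"),
                                c("nemg", "other")))
  if (any(tab < 0)) stop("counts do not form a valid 2x2 table")
  list(cis_percent = 100 * cisNemg / cisTotal,
       background_percent = 100 * backgroundNemg / backgroundTotal,
       p_value = fisher.test(tab)$p.value,
       table = tab)
}
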