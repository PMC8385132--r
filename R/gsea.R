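#' Read gene sets from a GMT file
#'
#' @param path GMT path (name, description, then member genes per line).
#' @return named list of character vectors (members deduplicated).
#' @export
readGmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  lapply(sets, unique)
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description optional per-set description column (recycled).
#' @return `path`, invisibly.
#' @export
writeGmt <- function(sets, path, description = "na") {
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], description[i], unique(sets[[i]])),
          collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

.directionTransform <- function(z, direction) {
  switch(direction, down = z, up = -z, mixed = abs(z),
         stop("direction must be down, up or mixed"))
}

#' Wilcoxon rank-sum statistic of a gene set against a background
#'
#' Rank-sum of the set members among the background gene statistics, with
#' midranks for ties.  Direction `down` ranks the z-scores as-is (small
#' rank-sum = set enriched for decreased expression), `up` ranks `-z`, and
#' `mixed` ranks `|z|` (large rank-sum = enriched for differential
#' expression in either direction).
#'
#' @param stats named numeric vector of genewise z-scores.
#' @param set character vector of member gene ids.
#' @param background character vector of background gene ids (must be
#'   covered by `stats`); the set is intersected with it.
#' @param direction `"down"`, `"up"` or `"mixed"`.
#' @return list with `stat` (rank-sum), `n_set`, `n_background`.
#' @export
wilcoxonSetStat <- function(stats, set, background, direction = "down") {
  background <- unique(background)
  background <- background[background %in% names(stats)]
  inSet <- unique(set)
  inSet <- inSet[inSet %in% background]
  if (length(inSet) < 2L || length(background) - length(inSet) < 2L)
    stop("set too small after intersection with background")
  r <- rank(.directionTransform(stats[background], direction))
  list(stat = sum(r[match(inSet, background)]),
       n_set = length(inSet), n_background = length(background))
}

#' Gene-sampling permutation p-value for a set statistic
#'
#' Competitive null: draws `nPerm` random gene sets of the same size from
#' the background without replacement and compares their rank-sum to the
#' observed one.  For `down`/`up` small rank-sums are extreme (`p` counts
#' permutations with statistic <= observed); for `mixed` large ones are
#' (`>=`).  The +1 correction keeps p in (0, 1].
#'
#' @inheritParams wilcoxonSetStat
#' @param nPerm number of permutations (default 10000).
#' @param seed optional integer seed for the draw.
#' @return list with `p`, `stat`, `n_set`, `n_perm`.
#' @export
permutationP <- function(stats, set, background, direction = "down",
                         nPerm = 10000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  obs <- wilcoxonSetStat(stats, set, background, direction)
  background <- unique(background)
  background <- background[background %in% names(stats)]
  r <- rank(.directionTransform(stats[background], direction))
  N <- length(r); m <- obs$n_set
  permStats <- vapply(seq_len(nPerm), function(i)
    sum(r[sample.int(N, m)]), numeric(1))
  hits <- if (direction == "mixed") sum(permStats >= obs$stat)
    else sum(permStats <= obs$stat)
  list(p = (1 + hits) / (nPerm + 1), stat = obs$stat, n_set = m,
       n_perm = nPerm)
}

#' Battery of competitive GSEA comparisons over meta-analyzed tissues
#'
#' For each tissue table and each (set, background) comparison, computes
#' the gene-sampling permutation p for the three directional classes
#' (down, up, mixed); the reported class is the one with the smallest p.
#' Benjamini-Hochberg FDR is applied within each (tissue, comparison)
#' family across its sets.  Undersized or oversized comparisons are
#' skipped with a message.
#'
#' @param metaTables named list of per-tissue data.frames with columns
#'   `gene`, `z_meta` (names are tissue labels), or a single data.frame
#'   with a `tissue` column.
#' @param sets named list of gene-id vectors.
#' @param comparisons data.frame with columns `comparison`, `set`,
#'   `background`; `background` names either another entry of `sets` or
#'   `"genome"` (all genes in the tissue table).
#' @param nPerm permutations per test.
#' @param seed integer seed.
#' @return data.frame `tissue comparison set direction stat p fdr p_down
#'   p_up p_mixed n_set`.
#' @export
gseaBattery <- function(metaTables, sets, comparisons, nPerm = 10000,
                        seed = 1) {
  if (is.data.frame(metaTables))
    metaTables <- split(metaTables, metaTables$tissue)
  set.seed(seed)
  rows <- list()
  for (tis in names(metaTables)) {
    tab <- metaTables[[tis]]
    stats <- setNames(tab$z_meta, tab$gene)
    stats <- stats[is.finite(stats)]
    for (i in seq_len(nrow(comparisons))) {
      cmp <- comparisons[i, ]
      setGenes <- sets[[cmp$set]]
      bg <- if (identical(cmp$background, "genome")) names(stats)
        else sets[[cmp$background]]
      res <- tryCatch({
        ps <- vapply(c("down", "up", "mixed"), function(d)
          permutationP(stats, setGenes, bg, d, nPerm = nPerm)$p,
          numeric(1))
        best <- names(ps)[which.min(ps)]
        data.frame(tissue = tis, comparison = cmp$comparison, set = cmp$set,
                   direction = best, p = min(ps),
                   p_down = ps[["down"]], p_up = ps[["up"]],
                   p_mixed = ps[["mixed"]],
                   n_set = sum(unique(setGenes) %in% names(stats)))
      }, error = function(e) {
        message("skipping ", cmp$set, " vs ", cmp$background, " in ", tis,
                ": ", conditionMessage(e))
        NULL
      })
      if (!is.null(res)) rows[[length(rows) + 1L]] <- res
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame())
  rownames(out) <- NULL
  out$fdr <- NA_real_
  for (key in unique(paste(out$tissue, out$comparison))) {
    idx <- paste(out$tissue, out$comparison) == key
    out$fdr[idx] <- p.adjust(out$p[idx], method = "BH")
  }
  out
}

#' Draw random NEMG control sets
#'
#' Negative-control sets of NEMGs drawn from the NEMG background excluding
#' the identified cis-NEMGs ("non-disease" NEMGs), one per requested set.
#'
#' @param nemgList character vector of all NEMG ids.
#' @param cisNemgs cis-NEMGs to exclude from the draw.
#' @param size set size (defaults to `length(cisNemgs)`).
#' @param nSets number of control sets.
#' @param seed integer seed.
#' @return named list of character vectors.
#' @export
randomNemgSets <- function(nemgList, cisNemgs, size = length(cisNemgs),
                           nSets = 3, seed = 1) {
  pool <- setdiff(unique(nemgList), unique(cisNemgs))
  if (length(pool) < size) stop("NEMG pool smaller than requested set size")
  set.seed(seed)
  sets <- lapply(seq_len(nSets), function(i) sample(pool, size))
  names(sets) <- paste0("random_nemg_", seq_len(nSets))
  sets
}
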