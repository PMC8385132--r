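#' Summary statistics for a colocalization run
#'
#' Derived counts and ratios of the kind reported for a co-location
#' analysis: total cis genes, cis NEMGs, loci with calls, NEMG percentage
#' (1 d.p.), average genes per locus (1 d.p.), and the split of loci into
#' European-specific and cosmopolitan.  Degenerate inputs (zero loci)
#' yield zeros, not division errors.
#'
#' @param nCisGenes,nLociWithCalls,nCisNemgs counts; alternatively pass
#'   `calls`/`loci` data.frames via the convenience wrapper
#'   [summarizeRun()].
#' @param nCosmopolitan,nEuropeanOnly optional locus-split counts.
#' @return named list of summary values.
#' @examples
#' summarizeCounts(763, 167, 50)  # genes_per_locus 4.6, nemg 6.6%
#' @export
summarizeCounts <- function(nCisGenes, nLociWithCalls, nCisNemgs,
                            nCosmopolitan = NA_integer_,
                            nEuropeanOnly = NA_integer_) {
  list(n_cis_genes = nCisGenes,
       n_loci_with_calls = nLociWithCalls,
       n_cis_nemgs = nCisNemgs,
       nemg_percent = if (nCisGenes > 0)
         round(100 * nCisNemgs / nCisGenes, 1) else 0,
       genes_per_locus = if (nLociWithCalls > 0)
         round(nCisGenes / nLociWithCalls, 1) else 0,
       n_cosmopolitan = nCosmopolitan,
       n_european_only = nEuropeanOnly)
}

#' @rdname summarizeCounts
#' @param calls gene-level calls with `nemg` column ([flagNemg()]).
#' @param loci replicated-locus table ([replicateLoci()]`$loci`).
#' @export
summarizeRun <- function(calls, loci) {
  called <- unique(unlist(strsplit(calls$loci, ",", fixed = TRUE)))
  lociCalled <- loci[loci$locus_id %in% called, , drop = FALSE]
  summarizeCounts(nrow(calls), length(called),
                  sum(calls$nemg),
                  nCosmopolitan = sum(lociCalled$cosmopolitan),
                  nEuropeanOnly = sum(!lociCalled$cosmopolitan))
}

.writeTsv <- function(df, path)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)

#' Run the full pipeline on a scenario directory
#'
#' Orchestrates colocalization (replication clustering, 1-LDU co-location
#' calls, cis-gene assignment, NEMG flagging), per-study differential
#' expression, per-tissue random-effects meta-analysis, the GSEA battery
#' (cis genes and cis NEMGs vs genome, cis NEMGs vs all NEMGs, random NEMG
#' controls vs NEMGs), the correlation-stratified NEMG regression, and
#' count-based set enrichment with random and structured nulls.  Emits TSV
#' report tables plus a deterministic `run.log`; re-running with the same
#' inputs and seed reproduces every byte.  If the scenario carries a
#' `truth.txt` manifest, locus recovery is scored against it.
#'
#' @param scenarioDir directory as produced by [makeScenario()] (or
#'   hand-assembled with the same file layout; expression stages are
#'   skipped, with a log line, when the expression files are absent).
#' @param outDir output directory (created).
#' @param cfg a [thresholdConfig()].
#' @param nPerm permutations for GSEA and count enrichment.
#' @param seed integer seed controlling every permutation draw.
#' @param gseaNPerm optional distinct permutation count for the GSEA
#'   battery (defaults to `nPerm`).
#' @return invisible list with the main in-memory results (`loci`,
#'   `cisCalls`, `meta`, `gsea`, `regression`, `enrichment`, `summary`,
#'   `truthScore`).
#' @export
runAll <- function(scenarioDir, outDir, cfg = thresholdConfig(),
                   nPerm = 2000, seed = 1, gseaNPerm = nPerm) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  log <- character(0)
  say <- function(...) log <<- c(log, paste0(...))
  say("lducoloc pipeline run; seed=", seed, "; nPerm=", nPerm)

  p <- function(f) file.path(scenarioDir, f)
  maps <- readGeneticMap(p("map.tsv"))
  estimates <- readLocationEstimates(p("estimates.tsv"))
  annotation <- readGeneAnnotation(p("annotation.tsv"))
  probeMap <- read.delim(p("eqtl_probe_map.tsv"))
  nemgList <- readLines(p("nemg_list.txt"))
  sets <- readGmt(p("sets.gmt"))

  ## --- colocalization ---
  rep <- replicateLoci(estimates, maps, cfg)
  say("replicated loci: ", nrow(rep$loci),
      " (excluded estimates: ", nrow(rep$excluded), ")")
  eq <- callT2dEqtl(rep, estimates, maps, cfg)
  cis <- assignCisGenes(eq, annotation, probeMap, cfg)
  calls <- suppressMessages(flagNemg(cis$calls, nemgList))
  say("disease-eQTL pairs: ", nrow(eq$calls), "; cis genes: ", nrow(calls),
      "; cis NEMGs: ", sum(calls$nemg))
  .writeTsv(rep$loci, file.path(outDir, "loci.tsv"))
  .writeTsv(eq$calls, file.path(outDir, "t2d_eqtl.tsv"))
  .writeTsv(calls, file.path(outDir, "cis_genes.tsv"))
  # Table-1-style listing: locus members x gene x eQTL position
  t1 <- merge(cis$pairs, calls[, c("gene_id", "nemg")], by = "gene_id")
  t1 <- t1[t1$nemg, c("chrom", "locus_id", "rep_pos", "tier", "hgnc",
                      "eqtl_pos")]
  t1 <- t1[order(t1$chrom, t1$rep_pos, t1$hgnc), ]
  .writeTsv(t1, file.path(outDir, "cis_nemg_listing.tsv"))

  smry <- summarizeRun(calls, rep$loci)
  truthScore <- NULL
  if (file.exists(p("truth.txt"))) {
    truth <- readTruth(p("truth.txt"))
    truthScore <- scoreLocusRecovery(rep$loci, truth, maps)
    say("locus recovery vs truth: sensitivity=",
        round(truthScore$sensitivity, 3), " false_call_rate=",
        round(truthScore$false_call_rate, 3))
  }

  ## --- expression stages (skipped when no study table) ---
  metaTab <- NULL; gsea <- NULL; regression <- NULL
  if (file.exists(p("studies.tsv"))) {
    studyTab <- read.delim(p("studies.tsv"))
    studies <- lapply(seq_len(nrow(studyTab)), function(i)
      readExpressionStudy(p(studyTab$exprs[i]), p(studyTab$pheno[i]),
                          p(studyTab$probe_map[i]),
                          studyId = studyTab$study[i],
                          tissue = studyTab$tissue[i],
                          phenotypeType = studyTab$phenotype_type[i]))
    zTables <- lapply(studies, studyZscores)
    for (zt in zTables)
      .writeTsv(zt, file.path(outDir,
                              sprintf("zscores_%s.tsv", zt$study[1L])))
    caseControl <- vapply(studies, function(s)
      S4Vectors::metadata(s)$phenotypeType == "case_control", logical(1))
    metaTab <- metaByTissue(zTables[caseControl],
                            vapply(studies[caseControl], studyTissue,
                                   character(1)))
    .writeTsv(metaTab, file.path(outDir, "meta.tsv"))

    cisSet <- calls$hgnc
    cisNemgSet <- calls$hgnc[calls$nemg]
    gseaSets <- list(cis_genes = cisSet, cis_nemgs = cisNemgSet,
                     nemg_background = nemgList)
    gseaSets <- c(gseaSets,
                  randomNemgSets(nemgList, cisNemgSet,
                                 size = max(5, length(cisNemgSet)),
                                 nSets = 3, seed = seed))
    comparisons <- data.frame(
      comparison = c("A_cis_vs_genome", "B_cisnemg_vs_genome",
                     "C_cisnemg_vs_nemg", "D_random1_vs_nemg",
                     "D_random2_vs_nemg", "D_random3_vs_nemg"),
      set = c("cis_genes", "cis_nemgs", "cis_nemgs",
              paste0("random_nemg_", 1:3)),
      background = c("genome", "genome", "nemg_background",
                     rep("nemg_background", 3)))
    gsea <- gseaBattery(metaTab, gseaSets, comparisons,
                        nPerm = gseaNPerm, seed = seed)
    .writeTsv(gsea, file.path(outDir, "gsea.tsv"))

    ## Fig-3-style analysis: adipose study with most controls
    adipose <- studies[vapply(studies, studyTissue, character(1)) ==
                         "adipose"]
    if (length(adipose) && length(cisNemgSet) >= 1L) {
      nCtrl <- vapply(adipose, function(s) sum(phenotype(s) == 0),
                      integer(1))
      st <- adipose[[which.max(nCtrl)]]
      ctrl <- phenotype(st) == 0
      ex <- SummarizedExperiment::assay(st, "exprs")[, ctrl, drop = FALSE]
      nonT2d <- setdiff(nemgList, cisNemgSet)
      records <- meanCorrelationProfile(ex, probeGenes(st), cisNemgSet,
                                        nonT2d)
      adiMeta <- metaTab[metaTab$tissue == "adipose", ]
      records$z <- adiMeta$z_meta[match(records$gene, adiMeta$gene)]
      records <- records[is.finite(records$z), ]
      .writeTsv(records, file.path(outDir, "correlation_records.tsv"))
      regression <- tryCatch(
        correlationDeRegression(records, robust = TRUE),
        error = function(e) { say("regression skipped: ",
                                  conditionMessage(e)); NULL })
      if (!is.null(regression)) {
        .writeTsv(data.frame(slope = regression$slope,
                             intercept = regression$intercept,
                             expr_coef = regression$expr_coef,
                             p_value = regression$p_value,
                             n_used = regression$n_used,
                             n_outliers = regression$n_outliers_removed,
                             method = regression$method),
                  file.path(outDir, "correlation_fit.tsv"))
        say("correlation regression: slope=",
            signif(regression$slope, 4), " p=",
            signif(regression$p_value, 3))
      }
    }
  } else {
    say("stages skipped: differential expression, meta-analysis, GSEA, ",
        "correlation regression (no studies.tsv)")
  }

  ## --- count enrichment ---
  # per-locus cis-gene counts; each gene attributed to its first locus
  firstLocus <- vapply(split(cis$pairs$locus_id, cis$pairs$gene_id),
                       function(x) sort(x)[1L], character(1))
  locusSizes <- as.integer(table(firstLocus))
  enrichment <- if (nrow(calls)) {
    countEnrichment(calls$hgnc, sets, annotation,
                    locusSizes = locusSizes, window = cfg$cisWindow,
                    nPerm = nPerm, seed = seed)
  } else NULL
  if (!is.null(enrichment))
    .writeTsv(enrichment, file.path(outDir, "enrichment.tsv"))

  sm <- data.frame(key = names(smry),
                   value = vapply(smry, function(v)
                     as.character(v), character(1)))
  .writeTsv(sm, file.path(outDir, "summary.tsv"))
  writeLines(log, file.path(outDir, "run.log"))
  invisible(list(loci = rep$loci, cisCalls = calls, meta = metaTab,
                 gsea = gsea, regression = regression,
                 enrichment = enrichment, summary = smry,
                 truthScore = truthScore))
}

#' Score replicated-locus recovery against a truth manifest
#'
#' A true locus counts as recovered if a replicated locus lies within 1
#' LDU of it on the same chromosome; a called locus is a false call if no
#' truth lies within 1 LDU of it.
#'
#' @param loci replicated-locus table.
#' @param truth manifest list from [readTruth()].
#' @param maps named list of [GeneticMap-class].
#' @param tol LDU matching tolerance.
#' @return list with `sensitivity`, `false_call_rate`, `n_true`,
#'   `n_called`.
#' @export
scoreLocusRecovery <- function(loci, truth, maps, tol = 1) {
  tl <- strsplit(truth$true_locus_ldu, ":", fixed = TRUE)
  tChrom <- vapply(tl, `[`, character(1), 1L)
  tLdu <- as.numeric(vapply(tl, `[`, character(1), 2L))
  recovered <- logical(length(tLdu))
  falseCall <- logical(nrow(loci))
  for (i in seq_len(nrow(loci))) {
    d <- ifelse(tChrom == loci$chrom[i], abs(tLdu - loci$rep_ldu[i]), Inf)
    if (any(d <= tol)) recovered[d <= tol] <- TRUE
    else falseCall[i] <- TRUE
  }
  list(sensitivity = mean(recovered),
       false_call_rate = if (nrow(loci)) mean(falseCall) else 0,
       n_true = length(tLdu), n_called = nrow(loci))
}
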