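#' @import methods
#' @importFrom stats approx lm coef vcov median mad pnorm p.adjust rnorm runif
#'   setNames complete.cases fisher.test quantile sd cor var weighted.mean
#' @importFrom utils read.delim write.table head
NULL

#' GeneticMap: a per-chromosome LDU genetic map
#'
#' A metric genetic map for one chromosome, stored as ordered anchor pairs of
#' physical position (bp, 1-based, GRCh37-style) and cumulative genetic
#' distance in linkage disequilibrium units (LDU).  Flat runs of the
#' cumulative-LDU curve correspond to LD "blocks" (extended LD), steep rises
#' to "steps" (LD breakdown).  Between anchors the map is interpreted by
#' piecewise-linear interpolation.
#'
#' @slot chrom single chromosome label.
#' @slot pos numeric vector of anchor positions in bp, strictly increasing.
#' @slot ldu numeric vector of cumulative LDU at each anchor, non-decreasing,
#'   first value >= 0.
#'
#' @seealso [lduAt()], [bpWindow()], [lduDistance()], [readGeneticMap()]
#' @export
setClass("GeneticMap",
  representation(chrom = "character", pos = "numeric", ldu = "numeric"))

setValidity("GeneticMap", function(object) {
  msg <- character()
  if (length(object@chrom) != 1L || is.na(object@chrom) || !nzchar(object@chrom))
    msg <- c(msg, "'chrom' must be a single non-empty label")
  if (length(object@pos) != length(object@ldu))
    msg <- c(msg, "'pos' and 'ldu' must have equal length")
  if (length(object@pos) < 2L)
    msg <- c(msg, "a map needs at least 2 anchors")
  if (anyNA(object@pos) || anyNA(object@ldu))
    msg <- c(msg, "anchors must be finite")
  else {
    if (any(diff(object@pos) <= 0))
      msg <- c(msg, "anchor positions must be strictly increasing")
    if (any(diff(object@ldu) < 0))
      msg <- c(msg, "cumulative LDU must be non-decreasing")
    if (object@ldu[1L] < 0)
      msg <- c(msg, "first anchor cumulative LDU must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GeneticMap
#'
#' @param chrom chromosome label (e.g. `"13"`).
#' @param pos anchor positions in bp, strictly increasing.
#' @param ldu cumulative LDU at each anchor, non-decreasing.
#' @return A [GeneticMap-class] object.
#' @examples
#' gm <- GeneticMap("13", pos = c(100, 200, 300), ldu = c(0, 0, 3))
#' lduAt(gm, 250)
#' @export
GeneticMap <- function(chrom, pos, ldu) {
  new("GeneticMap", chrom = as.character(chrom),
      pos = as.numeric(pos), ldu = as.numeric(ldu))
}

#' @describeIn GeneticMap-class chromosome label accessor
#' @param x,object a `GeneticMap`.
#' @export
mapChrom <- function(x) x@chrom

#' @describeIn GeneticMap-class anchor positions (bp)
#' @export
mapPositions <- function(x) x@pos

#' @describeIn GeneticMap-class cumulative LDU at the anchors
#' @export
mapLdu <- function(x) x@ldu

setMethod("show", "GeneticMap", function(object) {
  cat("GeneticMap for chromosome ", object@chrom, "\n",
      "  ", length(object@pos), " anchors spanning ",
      format(object@pos[1L], big.mark = ","), "-",
      format(object@pos[length(object@pos)], big.mark = ","), " bp, ",
      format(object@ldu[length(object@ldu)] - object@ldu[1L], digits = 4),
      " LDU\n", sep = "")
})

#' ExpressionStudy: one case/control expression dataset
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' probe x sample matrix of normalized log-scale intensities (RMA-like, log2)
#' together with the sample phenotype, optional age/BMI covariates and the
#' probe-to-gene map.  Phenotype is coded 0 control / 1 case, or, for a
#' family-history design, the number of affected parents (0, 1 or 2).
#'
#' Row metadata must contain a `gene` column (one gene per probe); column
#' metadata must contain a `phenotype` column with no missing values;
#' `metadata()` carries `studyId`, `tissue` and `phenotypeType`
#' (`"case_control"` or `"dosage"`).
#'
#' @seealso [ExpressionStudy()], [geneZscore()], [studyZscores()]
#' @export
setClass("ExpressionStudy", contains = "SummarizedExperiment")

setValidity("ExpressionStudy", function(object) {
  msg <- character()
  if (!"exprs" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'exprs' is required")
  else if (!all(is.finite(SummarizedExperiment::assay(object, "exprs"))))
    msg <- c(msg, "expression matrix must be finite")
  cd <- SummarizedExperiment::colData(object)
  if (!"phenotype" %in% colnames(cd))
    msg <- c(msg, "colData must contain 'phenotype'")
  else if (anyNA(cd$phenotype))
    msg <- c(msg, "phenotype must have no missing values")
  rd <- SummarizedExperiment::rowData(object)
  if (!"gene" %in% colnames(rd))
    msg <- c(msg, "rowData must contain 'gene'")
  else if (anyNA(rd$gene))
    msg <- c(msg, "every probe must map to exactly one gene")
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionStudy
#'
#' @param exprs numeric probe x sample matrix of normalized log-scale values;
#'   rownames are probe ids, colnames sample ids.
#' @param phenotype numeric per-sample phenotype (0/1 case-control or 0/1/2
#'   affected-parent dosage), in column order of `exprs`.
#' @param probeGene character vector mapping each row of `exprs` to a gene id
#'   (same length/order as `nrow(exprs)`).
#' @param studyId,tissue identifying labels (tissue one of adipose, muscle,
#'   liver, pancreas, or any label).
#' @param age,bmi optional per-sample covariates.
#' @param phenotypeType `"case_control"` or `"dosage"`.
#' @return An [ExpressionStudy-class].
#' @export
ExpressionStudy <- function(exprs, phenotype, probeGene, studyId = "study",
                            tissue = "adipose", age = NULL, bmi = NULL,
                            phenotypeType = c("case_control", "dosage")) {
  phenotypeType <- match.arg(phenotypeType)
  exprs <- as.matrix(exprs)
  if (is.null(rownames(exprs)))
    rownames(exprs) <- paste0("probe", seq_len(nrow(exprs)))
  if (is.null(colnames(exprs)))
    colnames(exprs) <- paste0("s", seq_len(ncol(exprs)))
  cd <- S4Vectors::DataFrame(phenotype = as.numeric(phenotype),
                             row.names = colnames(exprs))
  if (!is.null(age)) cd$age <- as.numeric(age)
  if (!is.null(bmi)) cd$bmi <- as.numeric(bmi)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = exprs),
    rowData = S4Vectors::DataFrame(gene = as.character(probeGene),
                                   row.names = rownames(exprs)),
    colData = cd,
    metadata = list(studyId = studyId, tissue = tissue,
                    phenotypeType = phenotypeType))
  new("ExpressionStudy", se)
}

#' @describeIn ExpressionStudy-class study identifier
#' @param x an `ExpressionStudy`.
#' @export
studyId <- function(x) S4Vectors::metadata(x)$studyId

#' @describeIn ExpressionStudy-class tissue label
#' @export
studyTissue <- function(x) S4Vectors::metadata(x)$tissue

#' @describeIn ExpressionStudy-class per-sample phenotype vector
#' @export
phenotype <- function(x) SummarizedExperiment::colData(x)$phenotype

#' @describeIn ExpressionStudy-class per-probe gene assignment
#' @export
probeGenes <- function(x) {
  setNames(SummarizedExperiment::rowData(x)$gene, rownames(x))
}

setMethod("show", "ExpressionStudy", function(object) {
  cat("ExpressionStudy '", studyId(object), "' (", studyTissue(object), ")\n",
      "  ", nrow(object), " probes x ", ncol(object), " samples; ",
      length(unique(SummarizedExperiment::rowData(object)$gene)), " genes\n",
      "  phenotype: ", S4Vectors::metadata(object)$phenotypeType,
      " (", paste(table(phenotype(object)), collapse = "/"), ")\n", sep = "")
})
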