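# Shared in-code fixtures for the suite.

# Uniform map: `lduPerBp` LDU per bp over [1, len].
uniformMap <- function(chrom = "1", len = 1e6, lduPerBp = 1e-4) {
  pos <- seq(1, len, length.out = 101)
  GeneticMap(chrom, pos, (pos - 1) * lduPerBp)
}

# Block/step map used across colocalization tests: a long flat block
# followed by a sharp step and another block.
blockStepMap <- function(chrom = "1") {
  GeneticMap(chrom,
             pos = c(1, 100000, 101000, 200000),
             ldu = c(0, 0, 5, 5))
}

# Small single- or multi-probe study with a planted case shift.
makeStudy <- function(nGenes = 20, nSamples = 20, probes = 1,
                      shift = 0, shiftGenes = character(0),
                      noise = 0.5, seed = 1, tissue = "adipose",
                      phenotype = rep(0:1, length.out = nSamples),
                      phenotypeType = "case_control",
                      age = NULL, bmi = NULL, probeOffsets = NULL) {
  set.seed(seed)
  genes <- sprintf("g%03d", seq_len(nGenes))
  probeGene <- rep(genes, each = probes)
  nP <- length(probeGene)
  base <- rep(runif(nGenes, 6, 10), each = probes)
  offs <- if (is.null(probeOffsets)) rnorm(nP, 0, 0.2) else
    rep_len(probeOffsets, nP)
  ex <- matrix(rnorm(nP * nSamples, 0, noise), nP, nSamples) + base + offs
  for (g in shiftGenes) {
    rows <- which(probeGene == g)
    ex[rows, ] <- ex[rows, ] +
      matrix(shift * phenotype, length(rows), nSamples, byrow = TRUE)
  }
  rownames(ex) <- sprintf("p%04d", seq_len(nP))
  ExpressionStudy(ex, phenotype = phenotype, probeGene = probeGene,
                  studyId = paste0("fix", seed), tissue = tissue,
                  age = age, bmi = bmi, phenotypeType = phenotypeType)
}

# Annotation of evenly spaced genes on one or more chromosomes.
gridAnnotation <- function(nGenes = 200, nChrom = 2, spacing = 4e5,
                           width = 2e4) {
  per <- ceiling(nGenes / nChrom)
  rows <- lapply(seq_len(nChrom), function(ch) {
    start <- (seq_len(per) - 1) * spacing + 1e5
    n0 <- (ch - 1) * per
    data.frame(chrom = as.character(ch), start = start,
               end = start + width,
               gene_id = sprintf("ENSG%05d", n0 + seq_len(per)),
               hgnc = sprintf("G%04d", n0 + seq_len(per)))
  })
  head(do.call(rbind, rows), nGenes)
}

# Brute-force single-linkage clustering of 1-D points (test oracle).
bruteSingleLinkage <- function(x, threshold) {
  n <- length(x)
  cl <- seq_len(n)
  repeat {
    merged <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (cl[i] != cl[j] && abs(x[i] - x[j]) <= threshold) {
        cl[cl == cl[j]] <- cl[i]
        merged <- TRUE
      }
    }
    if (!merged) break
  }
  match(cl, unique(cl))
}

extdataPath <- function(f) system.file("extdata", f, package = "lducoloc")
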