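#' Packaged reference fixtures
#'
#' Two small plain-text fixtures ship under `inst/extdata/`:
#'
#' * `table1_cis_nemg.tsv` — the published listing of 50 cis-regulated
#'   nuclear-encoded mitochondrial genes with their per-cohort disease
#'   location estimates and eQTL locations (GRCh37 bp), in two
#'   significance tiers.  One gene symbol is spreadsheet-mangled in the
#'   source (`Mar-05` for `MARCH5`) and is kept verbatim so that symbol
#'   repair ([normalizeSymbols()]) is exercised on real input.
#' * `mito_pathways.gmt` — four curated mitochondrial pathway gene sets
#'   (branched-chain amino-acid degradation, the manually defined
#'   biotin-dependent carboxylases, propanoate and butanoate metabolism),
#'   with MSigDB/KEGG-style membership recorded in the description field
#'   of each GMT line.
#'
#' @examples
#' tab <- read.delim(system.file("extdata", "table1_cis_nemg.tsv",
#'                               package = "lducoloc"))
#' length(unique(normalizeSymbols(tab$gene)))  # 50
#' sets <- readGmt(system.file("extdata", "mito_pathways.gmt",
#'                             package = "lducoloc"))
#' setOverlapCount(tab$gene, sets$BCAA_DEGRADATION)  # 5
#' @name lducoloc-fixtures
#' @keywords internal
NULL
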