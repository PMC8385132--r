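#' Interpolate cumulative LDU at physical positions
#'
#' Evaluates the map's cumulative-LDU curve at `position` by piecewise-linear
#' interpolation between the bracketing anchors.  Exact anchor positions
#' return the anchor values.
#'
#' @param map a [GeneticMap-class].
#' @param position numeric bp position(s), each within the map extent.
#' @return numeric LDU coordinate(s).
#' @examples
#' gm <- GeneticMap("1", c(100, 200, 300), c(0, 0, 3))
#' lduAt(gm, c(100, 250))  # 0, 1.5
#' @export
lduAt <- function(map, position) {
  stopifnot(is(map, "GeneticMap"))
  position <- as.numeric(position)
  lo <- map@pos[1L]
  hi <- map@pos[length(map@pos)]
  bad <- !is.finite(position) | position < lo | position > hi
  if (any(bad))
    stop("position ", paste(position[bad], collapse = ", "),
         " outside map extent [", lo, ", ", hi, "] on chromosome ",
         map@chrom, call. = FALSE)
  approx(map@pos, map@ldu, xout = position, method = "linear",
         ties = "ordered")$y
}

#' LDU distance between two positions on one chromosome
#'
#' `|lduAt(a) - lduAt(b)|`: symmetric, and zero iff the two positions
#' coincide or fall within the same flat LD block.  Positions on different
#' chromosomes are never co-located; use `Inf` for that case at a higher
#' level (see [replicateLoci()]).
#'
#' @inheritParams lduAt
#' @param posA,posB bp positions within the map extent.
#' @return numeric LDU distance(s).
#' @export
lduDistance <- function(map, posA, posB) {
  abs(lduAt(map, posA) - lduAt(map, posB))
}

## Smallest position whose LDU is >= target (target clamped to map range).
## The LDU curve is non-decreasing, so {p : f(p) >= t} = [x*, end].
.bpAtLduLeft <- function(map, target) {
  ldu <- map@ldu; pos <- map@pos
  target <- min(max(target, ldu[1L]), ldu[length(ldu)])
  i <- which(ldu >= target)[1L]
  if (i == 1L) return(pos[1L])
  # crossing strictly inside segment (i-1, i]; i is minimal so ldu[i-1] < target
  pos[i - 1L] + (target - ldu[i - 1L]) / (ldu[i] - ldu[i - 1L]) *
    (pos[i] - pos[i - 1L])
}

## Largest position whose LDU is <= target.
.bpAtLduRight <- function(map, target) {
  ldu <- map@ldu; pos <- map@pos
  n <- length(ldu)
  target <- min(max(target, ldu[1L]), ldu[n])
  j <- max(which(ldu <= target))
  if (j == n) return(pos[n])
  # ldu[j] <= target < ldu[j+1]; flat runs end at j by maximality
  pos[j] + (target - ldu[j]) / (ldu[j + 1L] - ldu[j]) *
    (pos[j + 1L] - pos[j])
}

#' Physical window spanning +/- delta LDU around a position
#'
#' Inverts the cumulative-LDU curve: returns the largest physical interval
#' whose endpoints lie within `delta` LDU of `center` on the genetic scale.
#' The interval is generally asymmetric about `center` — it extends further
#' through LD blocks (flat runs, which are absorbed whole) than through
#' steps — and is clamped to the map extent.
#'
#' @inheritParams lduAt
#' @param center bp position within the map extent.
#' @param delta window half-width in LDU (> 0, default 1).
#' @return named numeric `c(lo, hi)` in bp.
#' @examples
#' gm <- GeneticMap("1", c(0, 100000, 100001), c(0, 0, 2))
#' bpWindow(gm, 50000)   # left edge clamps to 0; right edge stops in the step
#' @export
bpWindow <- function(map, center, delta = 1) {
  stopifnot(is(map, "GeneticMap"), length(center) == 1L, delta > 0)
  centerLdu <- lduAt(map, center)
  c(lo = .bpAtLduLeft(map, centerLdu - delta),
    hi = .bpAtLduRight(map, centerLdu + delta))
}

#' Physical widths of +/- delta LDU windows across a map
#'
#' Evaluates [bpWindow()] at every anchor position and summarises the
#' window widths in kb (median, min, max).  On real European maps the
#' median width of a 1-LDU half-width window is of order tens of kb and
#' varies by chromosome with LD structure.
#'
#' @inheritParams bpWindow
#' @return data.frame with columns `chrom`, `median_kb`, `min_kb`,
#'   `max_kb`, `n_anchors`.
#' @export
kbPerLduSummary <- function(map, delta = 1) {
  stopifnot(is(map, "GeneticMap"))
  totalLdu <- map@ldu[length(map@ldu)] - map@ldu[1L]
  span <- map@pos[length(map@pos)] - map@pos[1L]
  if (totalLdu < delta) {
    warning("total map LDU (", format(totalLdu, digits = 4),
            ") below window half-width; returning chromosome span")
    return(data.frame(chrom = map@chrom, median_kb = span / 1000,
                      min_kb = span / 1000, max_kb = span / 1000,
                      n_anchors = length(map@pos)))
  }
  widths <- vapply(map@pos, function(p) {
    w <- bpWindow(map, p, delta = delta)
    (w[["hi"]] - w[["lo"]]) / 1000
  }, numeric(1))
  data.frame(chrom = map@chrom, median_kb = median(widths),
             min_kb = min(widths), max_kb = max(widths),
             n_anchors = length(map@pos))
}

#' Read LDU genetic maps from a TSV file
#'
#' Expects a header `chrom  pos_bp  cum_ldu`; one file may hold several
#' chromosomes (sections keyed by `chrom`).  Invariants (strictly
#' increasing positions, non-decreasing LDU, first LDU >= 0) are validated
#' per chromosome; the first violating line is named in the error.
#'
#' @param path path to the TSV file.
#' @return named list of [GeneticMap-class], keyed by chromosome.
#' @export
readGeneticMap <- function(path) {
  df <- read.delim(path, colClasses = c(chrom = "character"))
  need <- c("chrom", "pos_bp", "cum_ldu")
  if (!all(need %in% names(df)))
    stop("map file must have columns ", paste(need, collapse = ", "))
  out <- lapply(split(seq_len(nrow(df)), df$chrom), function(idx) {
    sub <- df[idx, ]
    bad <- which(diff(sub$pos_bp) <= 0)
    if (length(bad))
      stop("map file ", path, ": positions not strictly increasing at line ",
           idx[bad[1L] + 1L] + 1L, " (chrom ", sub$chrom[1L], ")",
           call. = FALSE)
    bad <- which(diff(sub$cum_ldu) < 0)
    if (length(bad))
      stop("map file ", path, ": cumulative LDU decreases at line ",
           idx[bad[1L] + 1L] + 1L, " (chrom ", sub$chrom[1L], ")",
           call. = FALSE)
    GeneticMap(sub$chrom[1L], sub$pos_bp, sub$cum_ldu)
  })
  out[order(names(out))]
}

#' Write a list of genetic maps to TSV
#'
#' @param maps named list of [GeneticMap-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeGeneticMap <- function(maps, path) {
  df <- do.call(rbind, lapply(maps, function(m)
    data.frame(chrom = mapChrom(m), pos_bp = mapPositions(m),
               cum_ldu = mapLdu(m))))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
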