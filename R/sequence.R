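#' A/T content of DNA sequences
#'
#' Fraction (#A + #T) / (length - #N); ambiguous N bases are excluded from
#' numerator and denominator. MNase cleaves much faster 5' of A/T, so A/T
#' content is the main sequence covariate of digestion rates.
#'
#' @param x a character vector of sequences or a
#'   \code{\link[Biostrings]{DNAStringSet}}.
#' @return Numeric vector of fractions in [0, 1]; \code{NA} for empty or
#'   all-N sequences.
#' @examples
#' at_content(c("ATAT", "GCGC", "ATGC"))
#' @export
at_content <- function(x) {
  if (!inherits(x, "DNAStringSet")) x <- Biostrings::DNAStringSet(toupper(x))
  counts <- Biostrings::letterFrequency(x, c("A", "T", "N"))
  denom <- Biostrings::width(x) - counts[, "N"]
  unname(ifelse(denom > 0, (counts[, "A"] + counts[, "T"]) / denom, NA_real_))
}

#' Standard A/T-content bin edges
#'
#' The eight bins used for fragment stratification: 0-0.5, then 0.05-wide
#' bins up to 0.8, then 0.8-1. The wide outer bins reflect how concentrated
#' genomic A/T content is around its mean.
#'
#' @return Numeric vector of 9 strictly increasing edges spanning [0, 1].
#' @export
at_bins <- function() c(0, 0.5, 0.55, 0.6, 0.65, 0.7, 0.75, 0.8, 1)

#' Bin an A/T fraction
#'
#' Bins are half-open [lo, hi) except the last, which is closed at 1.
#'
#' @param at A/T fractions in [0, 1].
#' @param edges bin edges (default \code{\link{at_bins}}).
#' @return Integer bin indices, 1-based.
#' @export
at_bin <- function(at, edges = at_bins()) {
  if (any(!is.finite(at) | at < 0 | at > 1))
    stop("A/T fractions must lie in [0, 1]")
  findInterval(at, edges, rightmost.closed = TRUE)
}

#' Fragment-length by A/T-content 2D occupancy matrix
#'
#' Stratifies fragments jointly by length and by the A/T content of their
#' own footprint sequence. Early digestion enriches long, A/T-rich
#' fragments; extensive digestion trims fragments and destroys the A/T-rich
#' ones first, shifting weight toward short, G/C-rich cells.
#'
#' @param fragments length-filtered target fragment data frame.
#' @param genome a \code{\link[Biostrings]{DNAStringSet}} (or named character
#'   vector) covering all fragment intervals.
#' @param edges A/T bin edges.
#' @param length_range inclusive fragment-length window (rows of the matrix).
#' @param weight scalar or per-fragment scaled weights.
#' @param fraction if TRUE, divide by the total weight so cells sum to 1.
#' @return Numeric matrix with one row per length and one column per A/T
#'   bin; rownames are lengths, colnames are bin labels.
#' @export
two_d_occupancy <- function(fragments, genome, edges = at_bins(),
                            length_range = c(100, 200), weight = 1,
                            fraction = FALSE) {
  if (!inherits(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(unlist(genome))
  lens <- seq(length_range[1], length_range[2])
  labels <- paste0(utils::head(edges, -1), "-", edges[-1])
  mat <- matrix(0, nrow = length(lens), ncol = length(edges) - 1,
                dimnames = list(lens, labels))
  w <- rep_len(weight, nrow(fragments))
  for (ch in unique(fragments$chrom)) {
    if (!ch %in% names(genome)) stop("chromosome not in genome: ", ch)
    i <- which(fragments$chrom == ch)
    if (any(fragments$start[i] < 0 |
            fragments$end[i] > length(genome[[ch]])))
      stop("fragment outside genome sequence on ", ch)
    seqs <- Biostrings::extractAt(
      genome[[ch]],
      IRanges::IRanges(fragments$start[i] + 1L, fragments$end[i]))
    at <- at_content(seqs)
    len <- fragments$end[i] - fragments$start[i]
    ok <- len >= length_range[1] & len <= length_range[2] & !is.na(at)
    if (!any(ok)) next
    ridx <- len[ok] - length_range[1] + 1L
    cidx <- at_bin(at[ok], edges)
    cell <- (cidx - 1L) * length(lens) + ridx
    agg <- rowsum(w[i][ok], cell)
    mat[as.integer(rownames(agg))] <- mat[as.integer(rownames(agg))] + agg[, 1]
  }
  if (fraction) {
    tot <- sum(mat)
    if (tot > 0) mat <- mat / tot
  }
  mat
}

#' Per-A/T-bin share of fragment weight
#'
#' Column sums of the 2D occupancy matrix, normalized to 1: the share of a
#' sample's fragments originating from each A/T-content stratum.
#'
#' @param mat matrix from \code{\link{two_d_occupancy}}.
#' @return Numeric vector of shares summing to 1 (all-zero input gives
#'   zeros).
#' @export
at_bin_shares <- function(mat) {
  cs <- colSums(mat)
  tot <- sum(cs)
  if (tot > 0) cs / tot else cs
}
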