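#' Pool normalized dyad tracks across digestion levels
#'
#' Nucleosome positions are called from the combined dyad counts of all
#' digestion time points, so nucleosomes released at any stage of the
#' digestion contribute. Samples must share the same chromosome set and have
#' been normalized to the same spike-in target.
#'
#' @param tracks list of dyad tracks (each a named list of per-base vectors).
#' @return A single combined dyad track.
#' @export
pool_dyads <- function(tracks) {
  if (!length(tracks)) stop("no tracks to pool")
  chroms <- names(tracks[[1]])
  for (tr in tracks)
    if (!identical(sort(names(tr)), sort(chroms)))
      stop("mismatched chromosome sets across samples")
  out <- tracks[[1]]
  for (tr in tracks[-1])
    for (ch in chroms) out[[ch]] <- out[[ch]] + tr[[ch]]
  out
}

gaussian_kernel <- function(sd) {
  half <- max(1L, ceiling(3 * sd))
  k <- stats::dnorm(seq(-half, half), sd = sd)
  k / sum(k)
}

smooth_track <- function(v, sd) {
  k <- gaussian_kernel(sd)
  half <- (length(k) - 1L) %/% 2L
  padded <- c(numeric(half), v, numeric(half))
  sm <- stats::filter(padded, k, sides = 2)
  as.numeric(sm[(half + 1L):(half + length(v))])
}

# Weighted median over positions pos with weights w; ties toward the lower
# coordinate (smallest position where the cumulative weight reaches half).
weighted_median_pos <- function(pos, w) {
  o <- order(pos)
  pos <- pos[o]; w <- w[o]
  cw <- cumsum(w)
  pos[which(cw >= cw[length(cw)] / 2)[1]]
}

call_chrom <- function(v, chrom, bandwidth, min_separation, min_support) {
  nz <- which(v > 0)
  if (!length(nz)) return(NULL)
  sm <- smooth_track(v, bandwidth / 2)
  # local maxima (first base of any plateau)
  n <- length(sm)
  left <- c(-Inf, sm[-n]); right <- c(sm[-1], -Inf)
  peaks <- which(sm > left & sm >= right & sm > 0)
  if (!length(peaks)) return(NULL)
  # greedy acceptance in decreasing height (ties: lower coordinate first)
  ord <- peaks[order(-sm[peaks], peaks)]
  accepted <- integer(0)
  for (p in ord) {
    if (!length(accepted) || all(abs(accepted - p) >= min_separation))
      accepted <- c(accepted, p)
  }
  accepted <- sort(accepted)
  # assign raw dyads to the nearest accepted peak within min_separation/2
  pos <- nz - 1L                 # 0-based dyad coordinates
  w <- v[nz]
  pk0 <- accepted - 1L
  idx <- findInterval(pos, pk0)
  lo <- pmax(idx, 1L); hi <- pmin(idx + 1L, length(pk0))
  d_lo <- abs(pos - pk0[lo]); d_hi <- abs(pos - pk0[hi])
  nearest <- ifelse(d_hi < d_lo, hi, lo)
  dist <- pmin(d_lo, d_hi)
  keep <- dist <= min_separation / 2
  if (!any(keep)) return(NULL)
  pos <- pos[keep]; w <- w[keep]; cl <- nearest[keep]
  calls <- lapply(split(seq_along(pos), cl), function(i) {
    data.frame(chrom = chrom,
               dyad_pos = weighted_median_pos(pos[i], w[i]),
               support = sum(w[i]),
               span_lo = min(pos[i]), span_hi = max(pos[i]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, calls)
  out <- out[out$support >= min_support, , drop = FALSE]
  if (!nrow(out)) return(NULL)
  out <- out[order(out$dyad_pos), , drop = FALSE]
  # enforce the minimum separation on the reported medians (cluster medians
  # can drift closer than the accepted peaks were): keep the better-supported
  # call of any too-close pair.
  repeat {
    gap <- diff(out$dyad_pos)
    bad <- which(gap < min_separation)
    if (!length(bad)) break
    i <- bad[1]
    drop <- if (out$support[i] < out$support[i + 1]) i else i + 1L
    out <- out[-drop, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Call typical nucleosome positions from a dyad track
#'
#' Reconstruction of cluster-median nucleosome calling: (i) smooth the dyad
#' track with a symmetric Gaussian kernel; (ii) take local maxima, accepted
#' greedily in decreasing height subject to a minimum separation of one
#' nucleosome footprint; (iii) assign every raw dyad to its nearest accepted
#' maximum within half the separation; (iv) report the weighted median of
#' each cluster's dyads as the nucleosome position. The procedure is fully
#' deterministic.
#'
#' @param track dyad track: a named list of per-base vectors, or a single
#'   numeric vector (then \code{chrom} names it).
#' @param bandwidth smoothing bandwidth in bp; the Gaussian sd is
#'   \code{bandwidth / 2}.
#' @param min_separation minimum distance between calls (default 147 bp, one
#'   nucleosome footprint).
#' @param min_support minimum total dyad weight per call; default 1\% of the
#'   genome-wide mean dyad weight per 147 bp, suppressing noise calls.
#' @param chrom chromosome name when \code{track} is a bare vector.
#' @return Data frame of calls: \code{chrom}, \code{dyad_pos} (0-based),
#'   \code{support}, \code{span_lo}, \code{span_hi}; sorted, with calls at
#'   least \code{min_separation} apart. Empty tracks give zero rows.
#' @export
call_nucleosomes <- function(track, bandwidth = 30, min_separation = 147,
                             min_support = NULL, chrom = "chr") {
  if (is.numeric(track)) track <- stats::setNames(list(track), chrom)
  if (any(vapply(track, function(v) any(v < 0), TRUE)))
    stop("dyad track must be nonnegative")
  if (is.null(min_support)) {
    total <- sum(vapply(track, sum, 0))
    glen <- sum(lengths(track))
    min_support <- if (glen > 0) 0.01 * (total / glen) * 147 else 0
  }
  pieces <- lapply(names(track), function(ch)
    call_chrom(track[[ch]], ch, bandwidth, min_separation, min_support))
  pieces <- pieces[!vapply(pieces, is.null, TRUE)]
  if (!length(pieces))
    return(data.frame(chrom = character(), dyad_pos = integer(),
                      support = numeric(), span_lo = integer(),
                      span_hi = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Write nucleosome calls as BED6
#'
#' @param calls data frame from \code{\link{call_nucleosomes}}.
#' @param path output path. Each call is a 1 bp dyad interval; the score is
#'   the (rounded) support.
#' @export
write_calls_bed <- function(calls, path) {
  lines <- sprintf("%s\t%d\t%d\tnuc_%d\t%d\t.",
                   calls$chrom, calls$dyad_pos, calls$dyad_pos + 1L,
                   seq_len(nrow(calls)), as.integer(round(calls$support)))
  writeLines(lines, path)
  invisible(path)
}

match_chrom <- function(a, b, tolerance) {
  if (!length(a) || !length(b))
    return(data.frame(i = integer(), j = integer(), shift = numeric()))
  sb <- sort(b, index.return = TRUE)
  idx <- findInterval(a, sb$x)
  lo <- pmax(idx, 1L); hi <- pmin(idx + 1L, length(b))
  cand <- unique(rbind(data.frame(i = seq_along(a), j = sb$ix[lo]),
                       data.frame(i = seq_along(a), j = sb$ix[hi])))
  cand$shift <- b[cand$j] - a[cand$i]
  cand <- cand[abs(cand$shift) <= tolerance, , drop = FALSE]
  cand <- cand[order(abs(cand$shift), cand$i, cand$j), , drop = FALSE]
  used_a <- logical(length(a)); used_b <- logical(length(b))
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    i <- cand$i[r]; j <- cand$j[r]
    if (!used_a[i] && !used_b[j]) {
      keep[r] <- TRUE; used_a[i] <- TRUE; used_b[j] <- TRUE
    }
  }
  cand[keep, , drop = FALSE]
}

#' Match two sets of nucleosome positions
#'
#' Greedy one-to-one nearest-neighbor matching within a tolerance (default
#' 20 bp, the conventional window for calling two positions "the same").
#' Pairs are accepted in order of increasing absolute shift.
#'
#' @param calls_a,calls_b call data frames (\code{chrom}, \code{dyad_pos}) or
#'   bare numeric position vectors (then a single chromosome is assumed).
#' @param tolerance maximum absolute shift for a match, in bp.
#' @return List with \code{matched_fraction} (matched / nrow(calls_a)),
#'   \code{shifts} (signed b - a distances of the matched pairs), and
#'   \code{n_matched}.
#' @export
match_positions <- function(calls_a, calls_b, tolerance = 20) {
  as_df <- function(x) {
    if (is.numeric(x)) data.frame(chrom = "chr", dyad_pos = x) else x
  }
  a <- as_df(calls_a); b <- as_df(calls_b)
  shifts <- numeric(0); n_matched <- 0L
  for (ch in unique(a$chrom)) {
    m <- match_chrom(a$dyad_pos[a$chrom == ch], b$dyad_pos[b$chrom == ch],
                     tolerance)
    shifts <- c(shifts, m$shift)
    n_matched <- n_matched + nrow(m)
  }
  list(matched_fraction = if (nrow(a)) n_matched / nrow(a) else NA_real_,
       shifts = shifts, n_matched = n_matched)
}
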