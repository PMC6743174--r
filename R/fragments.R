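#' Read paired-end fragments from BED or BEDPE
#'
#' Fragments are strandless genomic intervals in 0-based half-open BED
#' coordinates. Spike-in fragments (exogenous calibration DNA aligned to a
#' second genome) are recognized by a chromosome-name prefix, emulating the
#' two-genome alignment in a single file.
#'
#' @param path file to read (plain text, tab separated).
#' @param format \code{"bed"} (chrom, start, end; extra columns ignored) or
#'   \code{"bedpe"} (both mates; the fragment spans their union and the two
#'   mates must share a chromosome).
#' @param spikein_prefix chromosome-name prefix identifying spike-in
#'   fragments (default \code{"sc_"}).
#' @return A data frame with columns \code{chrom}, \code{start}, \code{end},
#'   \code{length}, \code{genome} (\code{"target"} or \code{"spikein"}).
#'   Malformed lines raise an error naming the line number; an empty file
#'   yields an empty data frame with a warning.
#' @export
read_fragments <- function(path, format = c("bed", "bedpe"),
                           spikein_prefix = "sc_") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("fragment file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    warning("empty fragment file: ", path)
    return(fragment_frame(character(), integer(), integer(), spikein_prefix))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  need <- if (format == "bed") 3L else 6L
  short <- which(lengths(parts) < need)
  if (length(short))
    stop(sprintf("%s line %d: expected at least %d tab-separated fields",
                 path, lineno[short[1]], need))
  get <- function(i) vapply(parts, `[[`, "", i)
  num <- function(i, what) {
    x <- suppressWarnings(as.numeric(get(i)))
    bad <- which(!is.finite(x))
    if (length(bad))
      stop(sprintf("%s line %d: non-numeric %s", path, lineno[bad[1]], what))
    x
  }
  if (format == "bed") {
    chrom <- get(1); start <- num(2, "start"); end <- num(3, "end")
  } else {
    c1 <- get(1); c2 <- get(4)
    bad <- which(c1 != c2)
    if (length(bad))
      stop(sprintf("%s line %d: BEDPE mates on different chromosomes",
                   path, lineno[bad[1]]))
    chrom <- c1
    start <- pmin(num(2, "start"), num(5, "start"))
    end <- pmax(num(3, "end"), num(6, "end"))
  }
  bad <- which(end <= start | start < 0)
  if (length(bad))
    stop(sprintf("%s line %d: invalid interval (end <= start or start < 0)",
                 path, lineno[bad[1]]))
  fragment_frame(chrom, as.integer(start), as.integer(end), spikein_prefix)
}

fragment_frame <- function(chrom, start, end, spikein_prefix = "sc_") {
  data.frame(chrom = as.character(chrom), start = start, end = end,
             length = end - start,
             genome = ifelse(startsWith(as.character(chrom), spikein_prefix),
                             "spikein", "target"),
             stringsAsFactors = FALSE)
}

#' Write fragments as BED3
#'
#' @param fragments a fragment data frame (see \code{\link{read_fragments}}).
#' @param path output path.
#' @export
write_fragments <- function(fragments, path) {
  utils::write.table(fragments[, c("chrom", "start", "end")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Retain mononucleosome-sized fragments
#'
#' Keeps fragments whose length lies between the bounds, both ends inclusive
#' (default 100-200 bp, the mononucleosome size window used for both target
#' and spike-in counting).
#'
#' @param fragments fragment data frame.
#' @param min_len,max_len inclusive length bounds in bp.
#' @export
filter_by_length <- function(fragments, min_len = 100, max_len = 200) {
  if (min_len > max_len) stop("min_len must be <= max_len")
  len <- fragments$end - fragments$start
  fragments[len >= min_len & len <= max_len, , drop = FALSE]
}

#' Count spike-in fragments in a sample
#'
#' @param fragments length-filtered fragment data frame.
#' @return Integer count of spike-in fragments; zero spike-ins is an error
#'   because normalization is then impossible.
#' @export
count_spikein <- function(fragments) {
  n <- sum(fragments$genome == "spikein")
  if (n == 0) stop("no spike-in fragments: cannot normalize this sample")
  n
}

#' Spike-in scale factors
#'
#' @param spikein_counts positive raw spike-in counts, one per sample.
#' @param target common spike-in total after normalization (default 10000).
#' @return Numeric scale factors \code{target / spikein_counts}.
#' @export
spikein_scale_factors <- function(spikein_counts, target = 10000) {
  if (any(spikein_counts <= 0)) stop("spike-in counts must be > 0")
  target / spikein_counts
}

#' Normalize samples to a common spike-in total
#'
#' Rescales every sample's tracks so that its spike-in fragment total equals
#' the target (default 10,000) — the calibration that makes absolute
#' mononucleosome yields comparable across digestion levels. Renormalizing an
#' already-normalized sample is the identity.
#'
#' @param samples list of samples; each a list with \code{spikein_count}
#'   (positive scalar) and \code{tracks} (a numeric vector, or a list of
#'   numeric vectors keyed by chromosome). Other elements are carried
#'   through.
#' @param target spike-in total to normalize to.
#' @return The input list with tracks multiplied by \code{target /
#'   spikein_count}, plus per-sample \code{raw_spikein_count},
#'   \code{scale_factor}, and \code{spikein_count} reset to \code{target}
#'   (so the operation is idempotent).
#' @export
spikein_normalize <- function(samples, target = 10000) {
  lapply(samples, function(s) {
    if (is.null(s$spikein_count) || s$spikein_count <= 0)
      stop("every sample needs spikein_count > 0")
    f <- target / s$spikein_count
    s$raw_spikein_count <- s$spikein_count
    s$scale_factor <- f
    s$tracks <- if (is.list(s$tracks)) lapply(s$tracks, function(v) v * f)
                else s$tracks * f
    s$spikein_count <- target
    s
  })
}

track_skeleton <- function(chrom_sizes) {
  lapply(chrom_sizes, function(n) numeric(n))
}

#' Per-base dyad count track
#'
#' Each fragment contributes its weight at its dyad, the floor of the
#' interval midpoint (the nucleosome center proxy for mononucleosome-sized
#' fragments).
#'
#' @param fragments length-filtered fragment data frame.
#' @param chrom_sizes named integer vector of chromosome lengths; every
#'   fragment must fall inside its chromosome.
#' @param weight scalar or per-fragment weights (scaled weight after
#'   normalization).
#' @return Named list of per-base numeric vectors, one per chromosome in
#'   \code{chrom_sizes}.
#' @export
dyad_track <- function(fragments, chrom_sizes, weight = 1) {
  w <- rep_len(weight, nrow(fragments))
  dyad <- (fragments$start + fragments$end) %/% 2L
  out <- track_skeleton(chrom_sizes)
  for (ch in unique(fragments$chrom)) {
    if (!ch %in% names(chrom_sizes))
      stop("chromosome not in chrom_sizes: ", ch)
    i <- fragments$chrom == ch
    d <- dyad[i]
    if (any(d < 0 | d >= chrom_sizes[[ch]]))
      stop("dyad outside chromosome ", ch, ": inconsistent chrom_sizes")
    agg <- rowsum(w[i], d)
    out[[ch]][as.integer(rownames(agg)) + 1L] <- out[[ch]][as.integer(rownames(agg)) + 1L] + agg[, 1]
  }
  out
}

#' Per-base coverage (apparent occupancy) track
#'
#' Each fragment adds its weight to every base of its half-open interval.
#'
#' @inheritParams dyad_track
#' @return Named list of per-base numeric vectors.
#' @export
coverage_track <- function(fragments, chrom_sizes, weight = 1) {
  w <- rep_len(weight, nrow(fragments))
  out <- track_skeleton(chrom_sizes)
  for (ch in unique(fragments$chrom)) {
    if (!ch %in% names(chrom_sizes))
      stop("chromosome not in chrom_sizes: ", ch)
    i <- which(fragments$chrom == ch)
    n <- chrom_sizes[[ch]]
    if (any(fragments$start[i] < 0 | fragments$end[i] > n))
      stop("fragment outside chromosome ", ch, ": inconsistent chrom_sizes")
    delta <- numeric(n + 1L)
    sagg <- rowsum(w[i], fragments$start[i])
    delta[as.integer(rownames(sagg)) + 1L] <-
      delta[as.integer(rownames(sagg)) + 1L] + sagg[, 1]
    eagg <- rowsum(w[i], fragments$end[i])
    delta[as.integer(rownames(eagg)) + 1L] <-
      delta[as.integer(rownames(eagg)) + 1L] - eagg[, 1]
    # cumsum of float weights can drift a hair below zero; clamp
    out[[ch]] <- pmax(out[[ch]] + cumsum(delta)[seq_len(n)], 0)
  }
  out
}

#' Read a two-column chrom.sizes file
#'
#' @param path tab-separated file: chromosome name, length.
#' @return Named integer vector.
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "size"),
                           colClasses = c("character", "integer"))
  stats::setNames(tab$size, tab$chrom)
}

#' Read a sample sheet
#'
#' @param path TSV with header columns \code{sample_id}, \code{time_min},
#'   \code{fragments_path}. Relative fragment paths are resolved against the
#'   sheet's directory.
#' @return Data frame sorted by digestion time.
#' @export
read_sample_sheet <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("sample_id", "time_min", "fragments_path")
  if (!all(need %in% names(tab)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  rel <- !grepl("^(/|[A-Za-z]:)", tab$fragments_path)
  tab$fragments_path[rel] <- file.path(dirname(path), tab$fragments_path[rel])
  tab[order(tab$time_min), , drop = FALSE]
}

#' Build normalized samples from raw fragments
#'
#' Convenience wrapper over the normalization steps: length-filter each
#' sample's fragments, count its spike-ins, and build spike-in scaled dyad
#' and coverage tracks for the target genome.
#'
#' @param sample_list list of samples; each a list with \code{time_min} and
#'   \code{fragments} (raw fragment data frame).
#' @param chrom_sizes named lengths of the target chromosomes.
#' @param target spike-in total to normalize to.
#' @param min_len,max_len inclusive mononucleosome length window.
#' @return List of normalized samples with elements \code{time_min},
#'   \code{raw_spikein_count}, \code{scale_factor}, \code{fragments}
#'   (filtered target fragments), \code{dyad}, \code{coverage}.
#' @export
normalize_samples <- function(sample_list, chrom_sizes, target = 10000,
                              min_len = 100, max_len = 200) {
  lapply(sample_list, function(s) {
    frags <- filter_by_length(s$fragments, min_len, max_len)
    n_spike <- count_spikein(frags)
    f <- target / n_spike
    tgt <- frags[frags$genome == "target", , drop = FALSE]
    list(time_min = s$time_min,
         raw_spikein_count = n_spike,
         scale_factor = f,
         fragments = tgt,
         dyad = dyad_track(tgt, chrom_sizes, weight = f),
         coverage = coverage_track(tgt, chrom_sizes, weight = f))
  })
}

#' Write a track as bedGraph
#'
#' Runs of equal value are merged; zero runs are omitted.
#'
#' @param track named list of per-base numeric vectors.
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(track)) {
    v <- track[[ch]]
    if (!length(v)) next
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (any(keep))
      writeLines(sprintf("%s\t%d\t%d\t%g", ch, starts[keep], ends[keep],
                         r$values[keep]), con)
  }
  invisible(path)
}
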