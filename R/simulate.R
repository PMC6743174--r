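#' Configuration of the digestion time-course simulator
#'
#' Defines the study conditions the simulator emulates: a genome with A/T
#' composition varying along its length around the fly-like average of 0.58,
#' nucleosomes planted every 200 bp (the typical fly repeat length; each
#' covers 147 bp, so planted footprints tile ~73.5\% of the genome), a
#' six-point digestion time course, per-locus counts Poisson around the
#' kinetic model expectation, digestion-dependent fragment shortening, a
#' small fragile subpopulation with strongly elevated release rates, and
#' constant-expectation spike-in fragments on a dedicated contig.
#'
#' @param genome_length target genome length in bp.
#' @param at_mean genome-average A/T fraction (default 0.58).
#' @param at_concentration concentration of the per-tile Beta distribution of
#'   local A/T level; lower values give more regional A/T variation. The
#'   default (20, sd ~0.107) spreads footprints across all 8 A/T bins.
#' @param at_tile tile size in bp over which the local A/T level is constant.
#' @param spacing nucleosome repeat length (default 200 bp).
#' @param position_jitter planted positions deviate from the regular grid by
#'   uniform +/- this many bp.
#' @param times digestion times in minutes (default 1, 2, 5, 15, 40, 60).
#' @param depth expected fragments from a fully-occupied locus (O = 1) per
#'   unit apparent occupancy; the per-locus, per-time count is
#'   Poisson(depth x apparent occupancy).
#' @param occ_min,occ_max planted occupancies are uniform on this range
#'   (a wide range, as fitted occupancies span one).
#' @param k1_meanlog,k1_sdlog log-normal release rates (median 1/min for
#'   typical nucleosomes).
#' @param k2_meanlog,k2_sdlog log-normal decay rates (median 0.05/min).
#' @param fragile_fraction fraction of loci bound by fragile complexes
#'   (default 0.01, i.e. under 1\%).
#' @param fragile_multiplier release-rate multiplier for fragile loci
#'   (default 30: fragile k1 is one to two orders of magnitude above 1).
#' @param at_coupling exponential tilt of k1 with local A/T content:
#'   k1 <- k1 * exp(at_coupling * (AT - at_mean)). 0 disables the coupling.
#' @param dyad_jitter fragment centers scatter uniformly +/- this many bp
#'   around the planted position.
#' @param len_mean_first,len_mean_last mean fragment length at the first and
#'   last time point; the mean decreases linearly across time points as
#'   MNase trims nucleosomal DNA (165 -> 140 bp by default).
#' @param len_sd fragment length standard deviation.
#' @param spikein_expected expected spike-in fragments per sample (Poisson,
#'   constant across samples).
#' @param spikein_contig,spikein_contig_length name (must carry the spike-in
#'   prefix) and length of the spike-in contig; spike-in fragments are
#'   uniform on it with lengths uniform in 140-160 bp.
#' @param chrom name of the simulated target chromosome.
#' @param seed integer seed; all randomness of a simulation flows from it.
#' @return A validated list of class \code{"sim_config"}.
#' @export
sim_config <- function(genome_length = 1e5,
                       at_mean = 0.58,
                       at_concentration = 20,
                       at_tile = 200,
                       spacing = 200,
                       position_jitter = 10,
                       times = c(1, 2, 5, 15, 40, 60),
                       depth = 200,
                       occ_min = 0.2, occ_max = 1,
                       k1_meanlog = 0, k1_sdlog = 0.5,
                       k2_meanlog = log(0.05), k2_sdlog = 0.5,
                       fragile_fraction = 0.01,
                       fragile_multiplier = 30,
                       at_coupling = 0,
                       dyad_jitter = 20,
                       len_mean_first = 165, len_mean_last = 140,
                       len_sd = 10,
                       spikein_expected = 2500,
                       spikein_contig = "sc_spike",
                       spikein_contig_length = 10000,
                       chrom = "chrS",
                       seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$genome_length < cfg$spacing) stop("genome_length must be >= spacing")
  if (any(diff(cfg$times) <= 0)) stop("times must be strictly increasing")
  if (cfg$fragile_fraction < 0 || cfg$fragile_fraction >= 1)
    stop("fragile_fraction must be in [0, 1)")
  if (cfg$at_mean <= 0 || cfg$at_mean >= 1) stop("at_mean must be in (0, 1)")
  if (cfg$depth < 0) stop("depth must be >= 0")
  if (!startsWith(cfg$spikein_contig, "sc_"))
    stop("spikein_contig must carry the spike-in prefix 'sc_'")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a genome with regional A/T variation and planted positions
#'
#' Draws a per-tile local A/T level from a Beta distribution with mean
#' \code{at_mean}, then i.i.d. bases within each tile (P(A) = P(T) = AT/2).
#' Nucleosome positions are planted every \code{spacing} bp with small
#' uniform jitter. Does not touch the RNG seed; call within
#' \code{\link{simulate_digestion}} or set the seed yourself for
#' reproducibility.
#'
#' @param config a \code{\link{sim_config}}.
#' @return List with \code{sequence} (a one-chromosome
#'   \code{DNAStringSet}), \code{positions} (0-based planted dyads) and
#'   \code{tile_at} (the latent per-tile A/T levels).
#' @export
simulate_genome <- function(config) {
  L <- as.integer(config$genome_length)
  nt <- ceiling(L / config$at_tile)
  nu <- config$at_concentration
  tile_at <- stats::rbeta(nt, config$at_mean * nu, (1 - config$at_mean) * nu)
  bases <- character(nt)
  sizes <- rep(config$at_tile, nt)
  sizes[nt] <- L - (nt - 1L) * config$at_tile
  for (i in seq_len(nt)) {
    p <- c(tile_at[i] / 2, (1 - tile_at[i]) / 2, (1 - tile_at[i]) / 2,
           tile_at[i] / 2)
    bases[i] <- paste(sample(c("A", "C", "G", "T"), sizes[i],
                             replace = TRUE, prob = p), collapse = "")
  }
  seq <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
  names(seq) <- config$chrom
  n_loci <- floor(L / config$spacing)
  centers <- (seq_len(n_loci) - 0.5) * config$spacing
  jit <- round(stats::runif(n_loci, -config$position_jitter,
                            config$position_jitter))
  half <- 74L
  positions <- as.integer(pmin(pmax(centers + jit, half), L - half - 1L))
  list(sequence = seq, positions = positions, tile_at = tile_at)
}

#' Plant per-locus kinetic parameters
#'
#' Draws (O, k1, k2) for every planted position: occupancy uniform, rates
#' log-normal, a Bernoulli fragile subpopulation with multiplied k1, and an
#' optional exponential coupling of k1 to the local A/T content of the
#' 147 bp footprint around the position.
#'
#' @param genome_sim output of \code{\link{simulate_genome}}.
#' @param config a \code{\link{sim_config}}.
#' @return Truth data frame: \code{locus}, \code{chrom}, \code{position},
#'   \code{O}, \code{k1}, \code{k2}, \code{fragile}, \code{at_local}.
#' @export
simulate_truth <- function(genome_sim, config) {
  pos <- genome_sim$positions
  n <- length(pos)
  O <- stats::runif(n, config$occ_min, config$occ_max)
  k1 <- stats::rlnorm(n, config$k1_meanlog, config$k1_sdlog)
  k2 <- stats::rlnorm(n, config$k2_meanlog, config$k2_sdlog)
  fragile <- stats::runif(n) < config$fragile_fraction
  k1[fragile] <- k1[fragile] * config$fragile_multiplier
  seq <- genome_sim$sequence[[1]]
  L <- length(seq)
  lo <- pmax(pos - 73L, 0L); hi <- pmin(pos + 73L, L - 1L)
  at_local <- at_content(Biostrings::extractAt(
    seq, IRanges::IRanges(lo + 1L, hi + 1L)))
  if (config$at_coupling != 0)
    k1 <- k1 * exp(config$at_coupling * (at_local - config$at_mean))
  data.frame(locus = seq_len(n), chrom = config$chrom, position = pos,
             O = O, k1 = k1, k2 = k2, fragile = fragile,
             at_local = at_local, stringsAsFactors = FALSE)
}

#' Simulate the digestion time course as fragment sets
#'
#' For every locus and digestion time, the number of recovered fragments is
#' Poisson with mean \code{depth x apparent_occupancy(t, O, k1, k2)};
#' fragment centers jitter uniformly around the planted position; lengths
#' are normal with a mean that shrinks linearly across the time course (the
#' trimming of nucleosomal footprints by continued digestion). Lengths are
#' emitted uncensored — the mononucleosome length filter is an analysis
#' step, not a property of the sample. Spike-ins are Poisson with a constant
#' expectation per sample, placed uniformly on the spike-in contig.
#'
#' @param truth data frame from \code{\link{simulate_truth}}.
#' @param config a \code{\link{sim_config}}.
#' @return List of samples, each \code{list(time_min, fragments)} with
#'   fragments in BED-style half-open coordinates; plus spike-in counts as
#'   attribute-free columns (genome label distinguishes them).
#' @export
simulate_timecourse <- function(truth, config) {
  L <- as.integer(config$genome_length)
  nt <- length(config$times)
  len_means <- seq(config$len_mean_first, config$len_mean_last,
                   length.out = nt)
  lapply(seq_len(nt), function(ti) {
    t <- config$times[ti]
    lambda <- config$depth * vapply(seq_len(nrow(truth)), function(i)
      apparent_occupancy(t, list(O = truth$O[i], k1 = truth$k1[i],
                                 k2 = truth$k2[i])), 0)
    n_frag <- stats::rpois(nrow(truth), lambda)
    centers <- rep(truth$position, n_frag) +
      round(stats::runif(sum(n_frag), -config$dyad_jitter,
                         config$dyad_jitter))
    lens <- pmax(20L, as.integer(round(stats::rnorm(sum(n_frag),
                                                    len_means[ti],
                                                    config$len_sd))))
    start <- pmin(pmax(centers - lens %/% 2L, 0L), pmax(L - lens, 0L))
    end <- start + lens
    tgt <- data.frame(chrom = rep(config$chrom, length(start)),
                      start = start, end = end, stringsAsFactors = FALSE)
    n_spike <- stats::rpois(1, config$spikein_expected)
    sl <- as.integer(stats::runif(n_spike, 140, 161))
    sstart <- as.integer(stats::runif(n_spike, 0,
                                      config$spikein_contig_length - sl))
    spk <- data.frame(chrom = rep(config$spikein_contig, n_spike),
                      start = sstart, end = sstart + sl,
                      stringsAsFactors = FALSE)
    frags <- rbind(tgt, spk)
    frags <- fragment_frame(frags$chrom, frags$start, frags$end)
    list(time_min = t, fragments = frags)
  })
}

#' Run a full digestion simulation
#'
#' Seeds the RNG from \code{config$seed} and produces the genome, the truth
#' ledger and the per-sample fragment sets in one deterministic call.
#'
#' @param config a \code{\link{sim_config}}.
#' @return List with \code{genome} (the \code{simulate_genome} output),
#'   \code{truth}, \code{samples}, \code{chrom_sizes} (target +
#'   spike-in contig) and the \code{config}.
#' @export
simulate_digestion <- function(config = sim_config()) {
  set.seed(config$seed)
  genome <- simulate_genome(config)
  truth <- simulate_truth(genome, config)
  samples <- simulate_timecourse(truth, config)
  chrom_sizes <- stats::setNames(
    c(as.integer(config$genome_length),
      as.integer(config$spikein_contig_length)),
    c(config$chrom, config$spikein_contig))
  list(genome = genome, truth = truth, samples = samples,
       chrom_sizes = chrom_sizes, config = config)
}

#' Write a simulation bundle to disk
#'
#' Emits the genome FASTA, one BED fragment file per sample, the truth TSV,
#' a chrom.sizes file and a sample sheet — the on-disk interface consumed by
#' \code{\link{run_pipeline}}.
#'
#' @param sim output of \code{\link{simulate_digestion}}.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  # genome FASTA holds the target chromosome plus a placeholder spike-in
  # contig so chrom.sizes and FASTA agree
  spike <- Biostrings::DNAStringSet(paste(
    rep("ACGT", ceiling(sim$config$spikein_contig_length / 4)),
    collapse = ""))
  spike <- Biostrings::subseq(spike, 1, sim$config$spikein_contig_length)
  names(spike) <- sim$config$spikein_contig
  Biostrings::writeXStringSet(c(sim$genome$sequence, spike),
                              file.path(dir, "genome.fa"))
  writeLines(sprintf("%s\t%d", names(sim$chrom_sizes), sim$chrom_sizes),
             file.path(dir, "chrom.sizes"))
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  sheet <- data.frame(
    sample_id = sprintf("t%02gmin", vapply(sim$samples, `[[`, 0, "time_min")),
    time_min = vapply(sim$samples, `[[`, 0, "time_min"),
    fragments_path = sprintf("fragments_t%02gmin.bed",
                             vapply(sim$samples, `[[`, 0, "time_min")))
  for (i in seq_along(sim$samples))
    write_fragments(sim$samples[[i]]$fragments,
                    file.path(dir, sheet$fragments_path[i]))
  utils::write.table(sheet, file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Poisson counts from the kinetic model at a fixed peak expectation
#'
#' Generates one locus's noisy time course: expectations proportional to the
#' model curve, rescaled so the largest expected count equals
#' \code{peak_expectation}, then Poisson sampled. The returned
#' \code{O_scaled} is the planted occupancy on the count scale, the quantity
#' a fit of these counts estimates.
#'
#' @param params a \code{\link{digestion_params}} (or named list/vector).
#' @param times digestion times.
#' @param peak_expectation expected count at the best-sampled time point.
#' @return List with \code{lambda}, \code{counts}, and \code{O_scaled}.
#' @export
simulate_counts <- function(params, times, peak_expectation = 1000) {
  p <- as_dp(params)
  m <- apparent_occupancy(times, p)
  if (max(m) <= 0) stop("model curve is zero at all times")
  depth <- peak_expectation / max(m)
  list(lambda = depth * m,
       counts = stats::rpois(length(times), depth * m),
       O_scaled = depth * p$O)
}

#' End-to-end recovery harness: simulate, analyze, compare to truth
#'
#' Runs the full pipeline on a simulation with known ground truth and
#' reports how well the analysis recovers it: the fraction of planted
#' positions matched by a call within 20 bp, median relative errors of the
#' fitted (O, k1, k2) at matched loci, and fragile-complex sensitivity and
#' specificity. With \code{noise = FALSE} the fragment stage is bypassed
#' and exact model expectations are fitted directly — a degenerate-noise
#' check that the estimator is consistent.
#'
#' Fitted O is in normalized-coverage units while planted O is a fraction,
#' so O errors are measured after one global proportionality rescale (the
#' median fitted/planted ratio); k1 and k2 are compared directly.
#'
#' @param config a \code{\link{sim_config}}.
#' @param noise logical; FALSE replaces Poisson counts by exact expectations
#'   at the planted positions.
#' @param tolerance position-match tolerance in bp.
#' @param window window width (bp) whose mean normalized coverage is the
#'   per-locus count (default one footprint, 147 bp).
#' @return List of class \code{"recovery_report"}: \code{position_match},
#'   \code{n_called}, \code{n_planted}, \code{median_rel_error} (named O,
#'   k1, k2), \code{fragile_sensitivity}, \code{fragile_specificity},
#'   \code{fits}, \code{truth_matched}.
#' @export
recovery_harness <- function(config = sim_config(), noise = TRUE,
                             tolerance = 20, window = 147) {
  if (!noise) {
    set.seed(config$seed)
    genome <- simulate_genome(config)
    truth <- simulate_truth(genome, config)
    counts <- t(vapply(seq_len(nrow(truth)), function(i)
      config$depth * apparent_occupancy(
        config$times, list(O = truth$O[i], k1 = truth$k1[i],
                           k2 = truth$k2[i])),
      numeric(length(config$times))))
    fits <- fit_loci(counts, config$times)
    return(build_report(truth, fits, match = NULL, config = config))
  }
  sim <- simulate_digestion(config)
  norm <- normalize_samples(sim$samples, sim$chrom_sizes)
  pooled <- pool_dyads(lapply(norm, `[[`, "dyad"))
  calls <- call_nucleosomes(pooled)
  truth_pos <- data.frame(chrom = sim$truth$chrom,
                          dyad_pos = sim$truth$position)
  m <- match_positions(truth_pos, calls, tolerance = tolerance)
  # re-derive the matched pairs per chromosome to link loci to calls
  pairs <- match_chrom(sim$truth$position,
                       calls$dyad_pos[calls$chrom == sim$config$chrom],
                       tolerance)
  counts <- t(vapply(seq_len(nrow(pairs)), function(r) {
    call_pos <- calls$dyad_pos[calls$chrom == sim$config$chrom][pairs$j[r]]
    lo <- max(call_pos - window %/% 2L, 0L) + 1L
    hi <- min(call_pos + window %/% 2L,
              sim$chrom_sizes[[sim$config$chrom]] - 1L) + 1L
    vapply(norm, function(s) mean(s$coverage[[sim$config$chrom]][lo:hi]), 0)
  }, numeric(length(norm))))
  truth_matched <- sim$truth[pairs$i, , drop = FALSE]
  fits <- fit_loci(counts, config$times)
  rep <- build_report(truth_matched, fits, match = m, config = config)
  rep$n_called <- nrow(calls)
  rep$n_planted <- nrow(sim$truth)
  rep
}

build_report <- function(truth, fits, match, config) {
  ok <- fits$converged & !fits$unfit
  rel <- function(est, tru) stats::median(abs(est - tru) / tru, na.rm = TRUE)
  ratio <- stats::median(fits$O[ok] / truth$O[ok], na.rm = TRUE)
  err <- c(O = rel(fits$O[ok] / ratio, truth$O[ok]),
           k1 = rel(fits$k1[ok], truth$k1[ok]),
           k2 = rel(fits$k2[ok], truth$k2[ok]))
  frag_true <- truth$fragile[ok]
  frag_est <- fits$fragile[ok]
  sens <- if (any(frag_true)) mean(frag_est[frag_true]) else NA_real_
  spec <- if (any(!frag_true)) mean(!frag_est[!frag_true]) else NA_real_
  structure(list(
    position_match = if (is.null(match)) NA_real_ else match$matched_fraction,
    n_called = NA_integer_, n_planted = nrow(truth),
    convergence_rate = mean(ok),
    median_rel_error = err,
    fragile_sensitivity = sens,
    fragile_specificity = spec,
    O_scale_ratio = ratio,
    fits = fits, truth_matched = truth),
    class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Digestion-simulation recovery report\n")
  if (!is.na(x$position_match))
    cat(sprintf("  planted positions matched within tolerance: %.1f%% (%d planted, %d called)\n",
                100 * x$position_match, x$n_planted, x$n_called))
  cat(sprintf("  fits converged: %.1f%%\n", 100 * x$convergence_rate))
  cat(sprintf("  median relative errors: O %.2f%%, k1 %.2f%%, k2 %.2f%%\n",
              100 * x$median_rel_error["O"], 100 * x$median_rel_error["k1"],
              100 * x$median_rel_error["k2"]))
  cat(sprintf("  fragile classification: sensitivity %s, specificity %s\n",
              format(x$fragile_sensitivity), format(x$fragile_specificity)))
  invisible(x)
}
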