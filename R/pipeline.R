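#' Run the full q-MNase-seq analysis pipeline
#'
#' Orchestrates the post-alignment workflow: read the sample sheet, filter
#' fragments to the mononucleosome window, spike-in normalize, write dyad and
#' coverage bedGraphs, call nucleosome positions from the pooled dyads, fit
#' (O, k1, k2) per call from windowed coverage means, classify loci (time
#' class, fragile flag, occupancy bin), optionally compute per-sample 2D
#' occupancy matrices, and record a run manifest. Outputs are plain text and
#' byte-identical across reruns with the same inputs and seed.
#'
#' @param config a named list (or path to a YAML file) with entries:
#'   \code{samples} (sample sheet path), \code{chrom_sizes} (path),
#'   \code{genome} (optional FASTA path, enables the 2D occupancy output),
#'   \code{out_dir}, and optional \code{spikein_target} (10000),
#'   \code{min_len} (100), \code{max_len} (200), \code{bandwidth} (30),
#'   \code{min_separation} (147), \code{fragile_threshold} (10),
#'   \code{n_bins} (9), \code{window} (147), \code{seed} (1).
#' @return Invisibly, a list with the calls, the fit table, the per-sample
#'   scale factors and the manifest path. Stage failures abort with an error
#'   naming the stage.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dflt <- list(spikein_target = 10000, min_len = 100, max_len = 200,
               bandwidth = 30, min_separation = 147,
               fragile_threshold = 10, n_bins = 9, window = 147, seed = 1L)
  for (nm in names(dflt)) if (is.null(config[[nm]])) config[[nm]] <- dflt[[nm]]

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  stage("configure", {
    for (nm in c("samples", "chrom_sizes", "out_dir"))
      if (is.null(config[[nm]])) stop("missing config entry: ", nm)
    for (nm in c("samples", "chrom_sizes"))
      if (!file.exists(config[[nm]])) stop("file not found: ", config[[nm]])
    if (!is.null(config$genome) && !file.exists(config$genome))
      stop("file not found: ", config$genome)
  })
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)

  sheet <- stage("read_samples", read_sample_sheet(config$samples))
  stage("read_samples", {
    missing <- sheet$fragments_path[!file.exists(sheet$fragments_path)]
    if (length(missing)) stop("fragment file not found: ", missing[1])
  })
  chrom_sizes <- stage("read_samples", read_chrom_sizes(config$chrom_sizes))
  target_chroms <- chrom_sizes[!startsWith(names(chrom_sizes), "sc_")]

  raw <- stage("read_fragments", lapply(seq_len(nrow(sheet)), function(i)
    list(time_min = sheet$time_min[i],
         fragments = read_fragments(sheet$fragments_path[i]))))

  norm <- stage("normalize", normalize_samples(
    raw, target_chroms, target = config$spikein_target,
    min_len = config$min_len, max_len = config$max_len))
  scale_tab <- data.frame(
    sample_id = sheet$sample_id,
    time_min = sheet$time_min,
    raw_spikein_count = vapply(norm, `[[`, 0, "raw_spikein_count"),
    scale_factor = vapply(norm, `[[`, 0, "scale_factor"))
  utils::write.table(scale_tab, file.path(out, "scale_factors.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  stage("tracks", for (i in seq_along(norm)) {
    write_bedgraph(norm[[i]]$dyad,
                   file.path(out, sprintf("dyad_%s.bedgraph",
                                          sheet$sample_id[i])))
    write_bedgraph(norm[[i]]$coverage,
                   file.path(out, sprintf("coverage_%s.bedgraph",
                                          sheet$sample_id[i])))
  })

  calls <- stage("call", {
    pooled <- pool_dyads(lapply(norm, `[[`, "dyad"))
    call_nucleosomes(pooled, bandwidth = config$bandwidth,
                     min_separation = config$min_separation)
  })
  write_calls_bed(calls, file.path(out, "calls.bed"))
  utils::write.table(calls, file.path(out, "calls.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  fits <- stage("fit", {
    counts <- t(vapply(seq_len(nrow(calls)), function(r) {
      ch <- calls$chrom[r]
      lo <- max(calls$dyad_pos[r] - config$window %/% 2L, 0L) + 1L
      hi <- min(calls$dyad_pos[r] + config$window %/% 2L,
                target_chroms[[ch]] - 1L) + 1L
      vapply(norm, function(s) mean(s$coverage[[ch]][lo:hi]), 0)
    }, numeric(length(norm))))
    tab <- fit_loci(counts, sheet$time_min, n_bins = config$n_bins,
                    fragile_threshold = config$fragile_threshold)
    cbind(calls[, c("chrom", "dyad_pos")], tab)
  })
  utils::write.table(format(fits, digits = 10),
                     file.path(out, "fits.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  summary_tab <- stage("summarize", {
    cls <- table(factor(fits$time_class, levels = seq_len(nrow(sheet))))
    data.frame(time_class = as.integer(names(cls)),
               time_min = sheet$time_min,
               n_loci = as.integer(cls),
               share = as.numeric(cls) / max(1L, nrow(fits)))
  })
  utils::write.table(summary_tab, file.path(out, "time_classes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  if (!is.null(config$genome)) stage("plot2do", {
    genome <- Biostrings::readDNAStringSet(config$genome)
    names(genome) <- sub("\\s.*", "", names(genome))
    for (i in seq_along(norm)) {
      mat <- two_d_occupancy(norm[[i]]$fragments, genome,
                             length_range = c(config$min_len, config$max_len),
                             weight = norm[[i]]$scale_factor,
                             fraction = TRUE)
      utils::write.table(mat,
                         file.path(out, sprintf("occupancy2d_%s.tsv",
                                                sheet$sample_id[i])),
                         sep = "\t", quote = FALSE)
    }
  })

  manifest <- list(
    package = "qmnase",
    version = as.character(utils::packageVersion("qmnase")),
    parameters = config[setdiff(names(config), "out_dir")],
    n_samples = nrow(sheet),
    n_calls = nrow(calls),
    n_converged = sum(fits$converged),
    n_fragile = sum(fits$fragile, na.rm = TRUE))
  yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))

  invisible(list(calls = calls, fits = fits, scale_factors = scale_tab,
                 manifest = file.path(out, "manifest.yaml")))
}
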