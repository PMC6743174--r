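test_that("BED fragments parse exactly, with spike-in labeling by prefix", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr2L\t100\t248", "sc_chrI\t0\t150"), path)
  fr <- read_fragments(path)
  expect_equal(fr$chrom, c("chr2L", "sc_chrI"))
  expect_equal(fr$start, c(100L, 0L))
  expect_equal(fr$end, c(248L, 150L))
  expect_equal(fr$genome, c("target", "spikein"))
  expect_equal(fr$length, c(148L, 150L))
})

test_that("malformed fragment lines are reported with their line number", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t50", "chr1\t60\t60", "chr1\t70\t80"), path)
  expect_error(read_fragments(path), "line 2")
  writeLines(c("chr1\t10\t50", "chr1\tx\t70"), path)
  expect_error(read_fragments(path), "line 2")
  writeLines(character(), path)
  expect_warning(fr <- read_fragments(path), "empty")
  expect_equal(nrow(fr), 0L)
})

test_that("BEDPE mates merge into one fragment and must share a chromosome", {
  path <- withr::local_tempfile(fileext = ".bedpe")
  writeLines("chr1\t100\t125\tchr1\t220\t248", path)
  fr <- read_fragments(path, format = "bedpe")
  expect_equal(fr$start, 100L)
  expect_equal(fr$end, 248L)
  writeLines("chr1\t100\t125\tchr2\t220\t248", path)
  expect_error(read_fragments(path, format = "bedpe"), "line 1")
})

test_that("fragments round-trip bit-exactly through write and read", {
  fr <- frag_df(c("chr1", "chr1", "sc_c"), c(0, 500, 3), c(150, 680, 160))
  path <- withr::local_tempfile(fileext = ".bed")
  write_fragments(fr, path)
  expect_identical(read_fragments(path), fr)
})

test_that("mononucleosome length filter is inclusive at both bounds", {
  fr <- frag_df("chr1", c(0, 0, 0, 0), c(99, 100, 200, 201))
  kept <- filter_by_length(fr)
  expect_equal(kept$length, c(100L, 200L))
  expect_equal(nrow(filter_by_length(fr[0, ])), 0L)
  expect_error(filter_by_length(fr, 200, 100), "min_len")
})

test_that("spike-in counting requires at least one spike-in", {
  fr <- frag_df(c("chr1", "sc_c", "sc_c", "chr1", "chr1"),
                rep(0, 5), rep(150, 5))
  expect_equal(count_spikein(fr), 2L)
  expect_error(count_spikein(fr[fr$genome == "target", ]), "spike-in")
  expect_equal(count_spikein(fr[fr$genome == "spikein", ]), 2L)
})

test_that("spike-in normalization hits the target total exactly and is idempotent", {
  s <- list(list(spikein_count = 2500, tracks = c(12, 0, 3)),
            list(spikein_count = 10000, tracks = c(1, 1, 1)),
            list(spikein_count = 5000, tracks = c(2, 2, 2)),
            list(spikein_count = 20000, tracks = c(2, 2, 2)))
  out <- spikein_normalize(s)
  expect_equal(out[[1]]$scale_factor, 4)
  expect_equal(out[[1]]$tracks, c(48, 0, 12))
  expect_equal(out[[2]]$scale_factor, 1)
  # normalized spike-in totals equal the target exactly
  expect_true(all(vapply(out, function(x)
    x$raw_spikein_count * x$scale_factor, 0) == 10000))
  # ratio of scale factors mirrors inverse spike-in ratio
  expect_equal(out[[3]]$scale_factor / out[[4]]$scale_factor, 4)
  # idempotence
  again <- spikein_normalize(out)
  expect_equal(lapply(again, `[[`, "tracks"), lapply(out, `[[`, "tracks"))
  expect_error(spikein_normalize(list(list(spikein_count = 0, tracks = 1))))
})

test_that("dyad track places floor-midpoint weight and conserves totals", {
  sizes <- c(chr1 = 300L)
  fr <- frag_df("chr1", c(100, 100, 100), c(248, 247, 248))
  tr <- dyad_track(fr, sizes)
  expect_equal(tr$chr1[175], 2)  # dyad 174, 0-based
  expect_equal(tr$chr1[174], 1)  # dyad 173 for the odd-length fragment
  expect_equal(sum(tr$chr1), 3)
  # scaled weights propagate
  tr4 <- dyad_track(fr, sizes, weight = 4)
  expect_equal(sum(tr4$chr1), 12)
  expect_error(dyad_track(frag_df("chr1", 290, 440), sizes), "chrom_sizes")
  expect_error(dyad_track(fr, c(chrX = 300L)), "chrom_sizes")
})

test_that("coverage track uses half-open intervals and sums weight x length", {
  sizes <- c(chr1 = 20L)
  fr <- frag_df("chr1", c(10, 11), c(13, 15))
  tr <- coverage_track(fr, sizes)
  expect_equal(tr$chr1, c(rep(0, 10), 1, 2, 2, 1, 1, rep(0, 5)))
  expect_equal(sum(tr$chr1), sum(fr$length))
  tr4 <- coverage_track(fr, sizes, weight = 4)
  expect_equal(sum(tr4$chr1), 4 * sum(fr$length))
})

test_that("normalized samples carry spike-in scaled tracks", {
  sizes <- c(chr1 = 1000L)
  fr <- rbind(frag_df("chr1", c(100, 400), c(250, 550)),
              frag_df("sc_c", c(0, 0, 0, 0, 0), rep(150, 5)),
              frag_df("chr1", 600, 640))  # 40 bp: filtered out
  norm <- normalize_samples(list(list(time_min = 5, fragments = fr)), sizes,
                            target = 10)
  expect_equal(norm[[1]]$raw_spikein_count, 5L)
  expect_equal(norm[[1]]$scale_factor, 2)
  expect_equal(sum(norm[[1]]$dyad$chr1), 2 * 2)
  expect_equal(nrow(norm[[1]]$fragments), 2L)
})

test_that("bedGraph output merges runs and omits zeros", {
  path <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph(list(chr1 = c(0, 0, 2, 2, 0, 1.5)), path)
  expect_equal(readLines(path), c("chr1\t2\t4\t2", "chr1\t5\t6\t1.5"))
})
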