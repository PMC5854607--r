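`%or_empty%` <- function(x, y) if (is.null(x) || length(x) == 0) y else x

mk_aln <- function(starts, ends, target = "t", target_len = 20L,
                   ids = NULL) {
  n <- length(starts)
  data.frame(read_id = if (is.null(ids)) sprintf("r%02d", seq_len(n)) else ids,
             read_len = ends - starts, read_start = 0L,
             read_end = ends - starts, strand = "+",
             target_id = target, target_len = target_len,
             target_start = starts, target_end = ends,
             matches = ends - starts, block_len = ends - starts, mapq = 60L,
             stringsAsFactors = FALSE)
}

test_that("depth counts interval membership per position", {
  aln <- mk_aln(c(0L, 5L), c(10L, 15L))
  d <- compute_depth(aln, "t", 20L)
  expect_equal(as.integer(d), c(rep(1L, 5), rep(2L, 5), rep(1L, 5),
                                rep(0L, 5)))
  expect_equal(as.integer(compute_depth(aln[0, ], "t", 8L)), rep(0L, 8))
})

test_that("depth equals a per-position membership scan on random input", {
  set.seed(500)
  aln <- random_alignment_set(500L, 2000L)
  d <- compute_depth(aln, "t", 2000L)
  expect_equal(as.integer(d), oracle_depth(aln, 2000L))
  # depth conservation
  expect_equal(sum(d), sum(aln$target_end - aln$target_start))
})

test_that("alignments beyond the target bounds are rejected", {
  aln <- mk_aln(15L, 25L, target_len = 20L)
  expect_error(compute_depth(aln, "t", 20L), "bounds")
})

test_that("footprint statistics summarize the covered positions", {
  depth <- structure(c(1L, 2L, 2L, 3L, 10L), target_id = "t")
  aln <- mk_aln(0L, 5L, target_len = 5L)
  expect_equal(footprint_stat(aln, depth, "median"), 2)
  depth2 <- structure(0:10, target_id = "t")
  aln2 <- mk_aln(0L, 11L, target_len = 11L)
  expect_equal(footprint_stat(aln2, depth2, "mean"), 5)
  depth3 <- structure(7L, target_id = "t")
  aln3 <- mk_aln(0L, 1L, target_len = 1L)
  expect_equal(footprint_stat(aln3, depth3, "median"), 7)
})

test_that("bin assignment applies the default thresholds exactly", {
  # constant-depth profiles so the footprint statistic equals the depth
  cases <- list(c(250, "high,low"), c(60, "low"), c(150, "high"),
                c(20, ""), c(115, "high,low"), c(120, "high,low"),
                c(110, "low"), c(25, "low"), c(225, "high"))
  for (cs in cases) {
    depth <- structure(rep(as.integer(cs[1]), 10L), target_id = "t")
    aln <- mk_aln(0L, 10L, target_len = 10L)
    got <- assign_bins(aln, depth)
    expect_equal(paste(sort(got$bins[[1]]), collapse = ","),
                 paste(sort(strsplit(cs[2], ",")[[1]]), collapse = ","),
                 info = paste("stat", cs[1]))
  }
})

test_that("assignment equals brute-force interval membership on random stats", {
  set.seed(42)
  stats <- sample(0:400, 200, replace = TRUE)
  specs <- default_bin_specs()
  for (i in seq_along(stats)) {
    depth <- structure(rep(stats[i], 5L), target_id = "t")
    aln <- mk_aln(0L, 5L, target_len = 5L)
    got <- assign_bins(aln, depth)$bins[[1]]
    s <- stats[i]
    want <- c(if (s > 110) "high",
              if ((s >= 25 && s <= 120) || s > 225) "low")
    expect_setequal(got, want %or_empty% character(0))
  }
})

test_that("binning is order-invariant and deep reads join both bins", {
  set.seed(88)
  aln <- random_alignment_set(300L, 3000L)
  prof <- compute_depth_all(aln)
  a1 <- assign_bins(aln, prof)
  perm <- sample(nrow(aln))
  a2 <- assign_bins(aln[perm, ], prof)
  expect_equal(a2[order(perm), ]$bins, a1$bins, ignore_attr = TRUE)
  deep <- a1[a1$footprint_stat > 225, ]
  if (nrow(deep)) {
    expect_true(all(deep$high & deep$low))
  }
})

test_that("relative thresholds reproduce absolute geometry at scale", {
  set.seed(9)
  # constant 150x profile: scale factor 150/300 halves every cutoff
  depth <- structure(rep(150L, 50L), target_id = "t")
  aln <- mk_aln(c(0L, 10L), c(50L, 20L), target_len = 50L)
  got <- assign_bins(aln, depth, relative = TRUE, calibration_depth = 300)
  # stat 150 vs scaled cutoffs (55, 12.5-60, 112.5): high and low(>112.5)
  expect_true(all(got$high))
  expect_true(all(got$low))
  got_abs <- assign_bins(aln, depth)
  expect_true(all(got_abs$high))      # 150 > 110
  expect_false(any(got_abs$low))      # 150 outside [25,120] and <= 225
})

test_that("bin refinement partitions reads at the depth cutoff", {
  asg <- data.frame(read_id = c("a", "b", "c"),
                    footprint_stat = c(95, 100, 250))
  ref <- refine_bin(asg, 100)
  expect_equal(ref$excluded, "a")
  expect_setequal(c(ref$kept, ref$excluded), asg$read_id)
  ref2 <- refine_bin(data.frame(read_id = "x", footprint_stat = 500), 100)
  expect_length(ref2$excluded, 0L)
})

test_that("deep contigs are selected strictly above the threshold", {
  expect_equal(select_contigs_by_depth(c(c1 = 200, c2 = 150)), "c1")
  expect_equal(select_contigs_by_depth(c(c1 = 190, c2 = 191)), "c2")
  expect_length(select_contigs_by_depth(setNames(numeric(0), character(0))), 0L)
  expect_setequal(select_contigs_by_depth(c(a = 5, b = 2), 0), c("a", "b"))
})

test_that("low-coverage regions are maximal runs with a size filter", {
  d <- c(30, 30, 10, 10, 10, 30)
  got <- low_coverage_regions(d, threshold = 25, min_len = 2)
  expect_equal(got$start, 2L)
  expect_equal(got$end, 5L)
  expect_equal(nrow(low_coverage_regions(c(30, 10, 30), 25, min_len = 2)), 0L)
})

test_that("low-coverage detection equals a brute-force run scan", {
  set.seed(321)
  d <- rpois(3000, 30)
  got <- low_coverage_regions(d, threshold = 25, min_len = 3, max_len = 50)
  want <- oracle_low_runs(d, 25, 3, 50)
  expect_equal(got$start, want$start)
  expect_equal(got$end, want$end)
})

test_that("junction-spanning reads must cover both flanks contiguously", {
  aln <- mk_aln(c(95L, 98L), c(105L, 103L), target_len = 300L)
  expect_equal(spanning_reads(aln[1, ], junction = 100, flank = 5), 1L)
  expect_equal(spanning_reads(aln[2, ], junction = 100, flank = 5), 0L)
  expect_equal(spanning_reads(aln, junction = 100, flank = 5), 1L)
})

test_that("spanning-read counts match the analytic coverage expectation", {
  cfg <- strain_sim_config(backbone_len = 50000,
                           n_unique_regions_per_strain = 2,
                           unique_region_len = 2000, total_depth = 50,
                           seed = 31L)
  set.seed(31)
  g <- c(circ = random_dna(50000))
  sim <- simulate_reads(g, c(circ = 50), cfg, circular = TRUE,
                        emit_sequences = FALSE)
  L <- 50000
  flank <- 100
  count <- spanning_reads(sim$alignments, junction = L, flank = flank)
  lens <- sim$alignments$target_end - sim$alignments$target_start
  expected <- sum(pmax(lens - 2 * flank, 0)) / L
  expect_gt(count, expected - 4 * sqrt(expected))
  expect_lt(count, expected + 4 * sqrt(expected))
})
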