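test_that("GC content and skew follow their definitions", {
  st <- genome_stats("ATGC", window = 4L)
  expect_equal(st$gc_percent, 50)
  st2 <- genome_stats("GGGC", window = 4L)
  expect_equal(st2$windows$gc_skew, 0.5)
  # N excluded from the GC denominator
  expect_equal(genome_stats("ATGCNN", window = 6L)$gc_percent, 50)
})

test_that("per-window statistics equal a direct recount", {
  set.seed(200)
  g <- random_dna(10000)
  st <- genome_stats(g, window = 1000L)
  for (i in seq_len(nrow(st$windows))) {
    w <- substr(g, st$windows$start[i] + 1L, st$windows$end[i])
    chars <- strsplit(w, "")[[1]]
    gc <- sum(chars %in% c("G", "C"))
    expect_equal(st$windows$gc_percent[i], 100 * gc / nchar(w))
    expect_equal(st$windows$gc_skew[i],
                 (sum(chars == "G") - sum(chars == "C")) / gc)
  }
  expect_true(st$windows$partial[nrow(st$windows)] == FALSE)
  st_part <- genome_stats(substr(g, 1, 2500), window = 1000L)
  expect_true(st_part$windows$partial[3])
})

test_that("GC-deviant windows compare full windows to the genome mean", {
  expect_equal(gc_deviant_windows(strrep("ACGT", 1000))$count, 0L)
  set.seed(8)
  # 3 windows at GC 40 / 50 / 41: mean ~43.67, only the middle deviates
  w <- function(gc_frac) {
    n_gc <- round(1000 * gc_frac)
    paste(sample(c(rep(c("G", "C"), length.out = n_gc),
                   rep(c("A", "T"), length.out = 1000 - n_gc))),
          collapse = "")
  }
  g <- paste0(w(0.40), w(0.50), w(0.41))
  res <- gc_deviant_windows(g, window = 1000L, threshold_pp = 5)
  expect_equal(res$count, 1L)
  expect_equal(res$intervals$start, 1000L)
})

test_that("deviant-window detection equals a brute-force scan", {
  set.seed(14)
  parts <- vapply(1:20, function(i) {
    p <- sample(c(0.2, 0.4, 0.5, 0.8), 1)
    paste(sample(c("G", "C", "A", "T"), 500, replace = TRUE,
                 prob = c(p / 2, p / 2, (1 - p) / 2, (1 - p) / 2)),
          collapse = "")
  }, character(1))
  g <- paste(parts, collapse = "")
  res <- gc_deviant_windows(g, window = 1000L, threshold_pp = 5)
  st <- genome_stats(g, window = 1000L)
  full <- st$windows[!st$windows$partial, ]
  want <- sum(abs(full$gc_percent - st$gc_percent) >= 5)
  expect_equal(res$count, want)
})

test_that("local alignment handles identity and all-mismatch inputs", {
  al <- local_align("ACGT", "ACGT")
  expect_equal(al$score, 4)
  expect_equal(al$identity, 100)
  al2 <- local_align("AAAA", "TTTT")
  expect_equal(al2$score, 0)
  expect_equal(al2$columns, 0L)
  expect_error(local_align("", "ACGT"), "empty")
  expect_error(local_align(random_dna(10000), random_dna(10000),
                           size_cap = 1e6), "cap")
})

test_that("local alignment equals exhaustive enumeration on tiny inputs", {
  seqs <- c("A", "C", "AA", "AC", "CA", "CC",
            "AAC", "ACA", "CCA", "ACC", "CAC", "AAA")
  for (a in seqs) {
    for (b in seqs) {
      got <- local_align(a, b, match = 1, mismatch = -1,
                         gap_open = 0, gap_extend = 1)$score
      expect_equal(got, oracle_sw_enum(a, b), info = paste(a, b))
    }
  }
})

test_that("local alignment equals a dynamic-programming oracle at length 6", {
  set.seed(66)
  for (i in 1:40) {
    a <- paste(sample(c("A", "C"), sample(2:6, 1), replace = TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C"), sample(2:6, 1), replace = TRUE),
               collapse = "")
    got <- local_align(a, b, match = 1, mismatch = -1,
                       gap_open = 0, gap_extend = 1)$score
    expect_equal(got, oracle_sw(a, b), info = paste(a, b))
  }
})

test_that("protein alignment uses BLOSUM62 scoring", {
  al <- local_align("MKT", "MKT", alphabet = "protein")
  expect_equal(al$identity, 100)
  expect_gt(al$score, 0)
})

test_that("self-comparison gives ANI 100 with one pair per fragment", {
  set.seed(70)
  g <- random_dna(1020 * 8 + 500)
  r <- orthoani(g, g)
  expect_equal(r$ani, 100)
  expect_equal(r$n_fragment_pairs, 8L)
})

test_that("ANI is symmetric and undefined below one fragment", {
  set.seed(71)
  a <- random_dna(1020 * 6)
  chars <- strsplit(a, "")[[1]]
  pos <- which(runif(length(chars)) < 0.02)
  chars[pos] <- vapply(chars[pos], function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1L)
  }, character(1))
  b <- paste(chars, collapse = "")
  expect_equal(orthoani(a, b)$ani, orthoani(b, a)$ani)
  expect_true(is.na(orthoani(random_dna(500), random_dna(5000))$ani))
})

test_that("hit filtering applies identity and strict coverage bounds", {
  mk_hit <- function(id, ident, alen, qlen) {
    data.frame(query_id = id, subject_id = "s", identity = ident,
               aln_len = alen, query_len = qlen, subject_len = 100L,
               evalue = 1e-10, bitscore = 50, stringsAsFactors = FALSE)
  }
  hits <- rbind(mk_hit("keep", 92, 80, 100),
                mk_hit("low_cov", 92, 75, 100),
                mk_hit("high_cov", 92, 120, 100),
                mk_hit("low_id", 89, 80, 100))
  expect_equal(filter_hits(hits)$query_id, "keep")
})

test_that("hit filtering equals a brute-force predicate filter", {
  set.seed(33)
  n <- 200L
  hits <- data.frame(
    query_id = sprintf("q%03d", seq_len(n)), subject_id = "s",
    identity = runif(n, 70, 100),
    aln_len = sample(50:130, n, replace = TRUE),
    query_len = 100L, subject_len = 100L,
    evalue = 10^-runif(n, 1, 50), bitscore = runif(n, 20, 200),
    stringsAsFactors = FALSE)
  got <- filter_hits(hits)
  want <- oracle_filter_hits(hits, 90, 0.75, 1.20)
  expect_equal(got$query_id, want$query_id)
  # monotone shrinkage under stricter thresholds
  expect_lte(nrow(filter_hits(hits, min_identity = 95)), nrow(got))
  expect_lte(nrow(filter_hits(hits, qcov_low = 0.9, qcov_high = 1.1)),
             nrow(got))
})

test_that("best bidirectional hits require reciprocal best matches", {
  hit <- function(q, s, bs, id = 95) {
    data.frame(query_id = q, subject_id = s, identity = id, aln_len = 100L,
               query_len = 100L, subject_len = 100L, evalue = 1e-20,
               bitscore = bs, stringsAsFactors = FALSE)
  }
  ab <- rbind(hit("a1", "b1", 100), hit("a2", "b1", 90))
  ba <- rbind(hit("b1", "a1", 100))
  expect_equal(best_bidirectional_hits(ab, ba),
               data.frame(a = "a1", b = "b1", stringsAsFactors = FALSE))
  # a2's best is b1, but b1's best is a1: no pair for a2
  ba2 <- rbind(hit("b1", "a1", 100), hit("b2", "a2", 80))
  pairs <- best_bidirectional_hits(rbind(ab, hit("a2", "b2", 85)), ba2)
  expect_equal(pairs, data.frame(a = "a1", b = "b1",
                                 stringsAsFactors = FALSE))
})

test_that("BBH detection equals an exhaustive reciprocal check", {
  set.seed(44)
  n_genes <- 40L
  mk_table <- function(qs, ss) {
    n <- 300L
    data.frame(query_id = sample(qs, n, replace = TRUE),
               subject_id = sample(ss, n, replace = TRUE),
               identity = runif(n, 80, 100), aln_len = 100L,
               query_len = 100L, subject_len = 100L,
               evalue = 10^-round(runif(n, 5, 50)),
               bitscore = round(runif(n, 50, 500)),
               stringsAsFactors = FALSE)
  }
  qs <- sprintf("a%02d", 1:n_genes)
  ss <- sprintf("b%02d", 1:n_genes)
  ab <- mk_table(qs, ss)
  ba <- mk_table(ss, qs)
  got <- best_bidirectional_hits(ab, ba)
  want <- oracle_bbh(ab, ba, 90)
  expect_equal(got[order(got$a), ], want[order(want$a), ],
               ignore_attr = TRUE)
  # partial matching: no gene appears twice
  expect_false(any(duplicated(got$a)))
  expect_false(any(duplicated(got$b)))
})

test_that("unique genes are those with zero surviving hits", {
  hits <- data.frame(query_id = c("g1", "g2"), subject_id = "s",
                     identity = 95, aln_len = 100L, query_len = 100L,
                     subject_len = 100L, evalue = 1e-30, bitscore = 100,
                     stringsAsFactors = FALSE)
  genes <- c("g1", "g2", "g3")
  expect_equal(unique_genes(genes, hits), "g3")
  expect_length(unique_genes(c("g1", "g2"), hits), 0L)
  expect_equal(length(unique_genes(genes, hits)) +
                 length(intersect(genes, hits$query_id)), length(genes))
})

test_that("aligned fraction merges overlapping query intervals", {
  mk <- function(qs, qe, ident = 96) {
    data.frame(read_id = "A", read_len = 1000L, read_start = qs,
               read_end = qe, strand = "+", target_id = "B",
               target_len = 1000L, target_start = qs, target_end = qe,
               matches = round((qe - qs) * ident / 100),
               block_len = qe - qs, mapq = 60L, stringsAsFactors = FALSE)
  }
  expect_equal(aligned_fraction(mk(0L, 500L)), 0.5)
  two <- rbind(mk(0L, 600L), mk(400L, 800L))
  expect_equal(aligned_fraction(two), 0.8)
  expect_equal(aligned_fraction(mk(0L, 500L, ident = 90)), 0)
})

test_that("aligned fraction equals a per-base membership oracle", {
  set.seed(55)
  qlen <- 2000L
  aln <- random_alignment_set(60L, qlen)
  aln$read_id <- "A"
  aln$read_len <- qlen
  aln$read_start <- aln$target_start
  aln$read_end <- aln$target_end
  for (minid in c(0, 95, 99)) {
    ident <- 100 * aln$matches / aln$block_len
    keep <- aln[ident >= minid, , drop = FALSE]
    covered <- logical(qlen)
    for (i in seq_len(nrow(keep))) {
      covered[(keep$read_start[i] + 1L):keep$read_end[i]] <- TRUE
    }
    expect_equal(aligned_fraction(aln, qlen, minid), mean(covered))
  }
  # monotone non-increasing in the identity threshold
  fr <- vapply(c(0, 50, 90, 95, 99, 100), function(m) {
    aligned_fraction(aln, qlen, m)
  }, numeric(1))
  expect_true(all(diff(fr) <= 0))
})

test_that("gene presence classifies absent, partial and present", {
  genes <- data.frame(gene_id = c("absent", "partial", "present"),
                      contig = "chr",
                      start = c(0L, 1000L, 2000L),
                      end = c(500L, 2000L, 2500L),
                      strand = "+", product = NA,
                      stringsAsFactors = FALSE)
  # coverage: nothing on gene 1; 70% of gene 2; 90% of gene 3
  aln <- data.frame(read_id = c("r1", "r2"), read_len = 1000L,
                    read_start = 0L, read_end = 1000L, strand = "+",
                    target_id = "chr", target_len = 3000L,
                    target_start = c(1000L, 2000L),
                    target_end = c(1700L, 2450L),
                    matches = 500L, block_len = 500L, mapq = 60L,
                    stringsAsFactors = FALSE)
  res <- gene_presence(genes, aln)
  expect_equal(res$status, c("absent", "partial", "present"))
  expect_equal(res$covered_fraction, c(0, 0.7, 0.9))
})
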