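mk_site <- function(obs_mean, obs_sd, obs_n, ctrl_mean, ctrl_sd, ctrl_n,
                    base = "A") {
  data.frame(target_id = "g", position = 0L, strand = "+", base = base,
             obs_mean = obs_mean, obs_sd = obs_sd, obs_n = obs_n,
             ctrl_mean = ctrl_mean, ctrl_sd = ctrl_sd, ctrl_n = ctrl_n,
             stringsAsFactors = FALSE)
}

test_that("a null site scores the one-sided p of one half", {
  call <- score_site(mk_site(1, 0.3, 50, 1, 0.3, 50))
  expect_equal(call$qv, -10 * log10(0.5), tolerance = 1e-10)
  expect_equal(call$mod_type, "unknown")
})

test_that("an extreme kinetic shift saturates at the QV cap", {
  call <- score_site(mk_site(1 + 10 * 0.3, 0.3, 100, 1, 0.3, 100))
  expect_equal(call$qv, 1000)
  expect_equal(call$mod_type, "6mA")
  call_c <- score_site(mk_site(4, 0.3, 100, 1, 0.3, 100, base = "C"))
  expect_equal(call_c$mod_type, "4mC")
})

test_that("scores match an independent numeric t-CDF oracle", {
  cases <- list(
    c(1.5, 0.3, 50, 1.0, 0.3, 500),
    c(1.1, 0.4, 20, 1.0, 0.2, 100),
    c(0.9, 0.5, 30, 1.0, 0.5, 30),
    c(2.0, 1.0, 10, 1.5, 0.8, 12))
  for (cs in cases) {
    call <- score_site(mk_site(cs[1], cs[2], cs[3], cs[4], cs[5], cs[6]))
    v1 <- cs[2]^2 / cs[3]; v2 <- cs[5]^2 / cs[6]
    tstat <- (cs[1] - cs[4]) / sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (cs[3] - 1) + v2^2 / (cs[6] - 1))
    p <- oracle_t_pvalue(tstat, df)
    expect_equal(call$qv, -10 * log10(p), tolerance = 1e-6)
  }
})

test_that("QV is monotone in the kinetic shift", {
  qvs <- vapply(seq(1, 2, by = 0.1), function(mu) {
    score_site(mk_site(mu, 0.3, 50, 1, 0.3, 50))$qv
  }, numeric(1))
  expect_true(all(diff(qvs) > 0))
})

test_that("degenerate kinetics are a scoring error", {
  expect_error(score_site(mk_site(1, 0.3, 1, 1, 0.3, 50)), "obs_n")
  expect_error(score_site(mk_site(1, 0, 10, 1, 0.3, 50)), "deviation")
})

test_that("site calling keeps the QV boundary inclusive", {
  calls <- data.frame(qv = c(99.9, 100, 250))
  expect_equal(nrow(call_sites(calls)), 2L)
  expect_equal(nrow(call_sites(calls[0, , drop = FALSE])), 0L)
})

test_that("palindromic motifs are counted once per locus", {
  occ <- count_motif_occurrences("GATCGATC",
                                 iupac_motif("GATC", 1L))
  expect_equal(nrow(occ), 2L)
  expect_equal(occ$locus, c(0L, 4L))
  expect_equal(occ$methyl_pos, c(1L, 5L))
  both <- count_motif_occurrences("GATCGATC", iupac_motif("GATC", 1L),
                                  count_per_strand = TRUE)
  expect_equal(nrow(both), 4L)
})

test_that("minus-strand motif occurrences are found and mapped forward", {
  occ <- count_motif_occurrences("GAAC", iupac_motif("GTTC", 3L))
  expect_equal(nrow(occ), 1L)
  expect_equal(occ$strand, "-")
  expect_equal(occ$methyl_pos, 0L)  # the G at forward position 0 pairs the C
})

test_that("IUPAC matching equals an exhaustive per-position scan", {
  set.seed(60)
  g <- random_dna(10000)
  for (pat in c("CCWGG", "GGNCC", "GCRCAG")) {
    mi <- 2L
    occ <- count_motif_occurrences(g, list(pattern = pat, methyl_index = mi),
                                   count_per_strand = TRUE)
    fwd <- oracle_iupac_match_fwd(g, pat)
    rev <- oracle_iupac_match_fwd(g, oracle_revcomp(pat))
    expect_setequal(occ$locus[occ$strand == "+"], fwd)
    expect_setequal(occ$locus[occ$strand == "-"], rev)
  }
})

test_that("no called sites means no motifs", {
  expect_length(discover_motifs("ACGTACGT", data.frame(position = integer(0),
                                                       strand = character(0))),
                0L)
})

test_that("a single planted motif is recovered exactly", {
  set.seed(11)
  g <- random_dna(60000)
  kin <- simulate_kinetics(
    g, data.frame(pattern = "GATC", methyl_index = 1L, fraction = 1),
    per_strand_depth = 200, delta = 1.5, sigma = 0.5, seed = 11)
  called <- call_sites(score_sites(kin$kinetics))
  found <- discover_motifs(g, called)
  expect_length(found, 1L)
  expect_equal(found[[1]]$pattern, "GATC")
  expect_equal(found[[1]]$methyl_index, 1L)
  expect_equal(found[[1]]$mod_type, "6mA")
})

test_that("motif summaries recompute the planted truth", {
  set.seed(15)
  g <- random_dna(60000)
  kin <- simulate_kinetics(
    g, data.frame(pattern = "GATC", methyl_index = 1L, fraction = 0.9),
    per_strand_depth = 200, seed = 15)
  called <- call_sites(score_sites(kin$kinetics))
  motif <- iupac_motif("GATC", 1L)
  summ <- motif_summary(g, list(motif), called)
  occ <- count_motif_occurrences(g, motif)
  expect_equal(summ$n_detected, nrow(occ))
  # direct recomputation from truth: forward methylated loci
  truth_keys <- paste(kin$truth$position, kin$truth$strand)
  want_meth <- sum(paste(occ$methyl_pos, occ$strand) %in% truth_keys)
  expect_equal(summ$n_methylated, want_meth)
  expect_equal(summ$frac_methylated, 100 * want_meth / nrow(occ))
  expect_equal(summ$mean_coverage, mean(called$coverage[
    paste(called$position, called$strand) %in%
      paste(occ$methyl_pos, occ$strand)]), tolerance = 1e-8)
})

test_that("intergenic fractions follow the gene models", {
  g <- strrep("GATCAAAA", 10)  # GATC at 0, 8, 16, ...
  motif <- iupac_motif("GATC", 1L)
  occ <- count_motif_occurrences(g, motif)
  called <- data.frame(target_id = "g", position = occ$methyl_pos,
                       strand = occ$strand, base = "A", mod_type = "6mA",
                       qv = 200, coverage = 100)
  genes_all <- data.frame(gene_id = "g1", contig = "g", start = 0L,
                          end = nchar(g), strand = "+", product = NA)
  summ <- motif_summary(g, list(motif), called, genes_all)
  expect_equal(summ$frac_intergenic, 0)
  expect_equal(summ$frac_methylated, 100)
  genes_half <- data.frame(gene_id = "g1", contig = "g", start = 0L,
                           end = 40L, strand = "+", product = NA)
  summ2 <- motif_summary(g, list(motif), called, genes_half)
  expect_equal(summ2$frac_intergenic, 50)
})

test_that("summed motif explanations equal the retained calls on clean data", {
  set.seed(19)
  g <- random_dna(60000)
  kin <- simulate_kinetics(
    g, data.frame(pattern = c("GATC", "CCWGG"), methyl_index = c(1L, 1L),
                  fraction = c(1, 1)),
    per_strand_depth = 200, delta = 1.5, seed = 19)
  called <- call_sites(score_sites(kin$kinetics))
  found <- discover_motifs(g, called)
  expect_length(found, 2L)
  explained <- unique(unlist(lapply(found, function(m) {
    occ <- count_motif_occurrences(g, m, count_per_strand = TRUE)
    paste(occ$methyl_pos, occ$strand)
  })))
  keys <- paste(called$position, called$strand)
  expect_true(all(keys %in% explained))
})
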