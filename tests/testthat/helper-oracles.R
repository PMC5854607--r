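# Independent brute-force oracles. These deliberately share no code with
# the package internals: plain loops and per-position scans.

oracle_depth <- function(aln, target_len) {
  d <- integer(target_len)
  for (i in seq_len(target_len)) {
    p <- i - 1L
    d[i] <- sum(aln$target_start <= p & p < aln$target_end)
  }
  d
}

oracle_low_runs <- function(depth, threshold, min_len, max_len = Inf) {
  out <- data.frame(start = integer(0), end = integer(0))
  i <- 1L
  n <- length(depth)
  while (i <= n) {
    if (depth[i] < threshold) {
      j <- i
      while (j <= n && depth[j] < threshold) j <- j + 1L
      len <- j - i
      if (len >= min_len && len <= max_len) {
        out <- rbind(out, data.frame(start = i - 1L, end = j - 1L))
      }
      i <- j
    } else i <- i + 1L
  }
  out
}

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

oracle_iupac_match_fwd <- function(genome, pattern) {
  g <- strsplit(genome, "")[[1]]
  p <- strsplit(pattern, "")[[1]]
  hits <- integer(0)
  for (s in seq_len(length(g) - length(p) + 1L)) {
    ok <- TRUE
    for (k in seq_along(p)) {
      if (!g[s + k - 1L] %in% ORACLE_IUPAC[[p[k]]]) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, s - 1L)
  }
  hits
}

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

# Smith-Waterman with linear gaps by explicit dynamic programming
oracle_sw <- function(a, b, match = 1, mismatch = -1, gap = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  H <- matrix(0, n + 1L, m + 1L)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (av[i] == bv[j]) match else mismatch
      H[i + 1L, j + 1L] <- max(0, H[i, j] + s, H[i, j + 1L] - gap,
                               H[i + 1L, j] - gap)
      best <- max(best, H[i + 1L, j + 1L])
    }
  }
  best
}

# exhaustive local-alignment enumeration: explore every alignment path
# from every start pair (tiny inputs only)
oracle_sw_enum <- function(a, b, match = 1, mismatch = -1, gap = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  rec <- function(i, j, sc) {
    best <- sc
    if (i <= n && j <= m) {
      s <- if (av[i] == bv[j]) match else mismatch
      best <- max(best, rec(i + 1L, j + 1L, sc + s))
    }
    if (i <= n) best <- max(best, rec(i + 1L, j, sc - gap))
    if (j <= m) best <- max(best, rec(i, j + 1L, sc - gap))
    best
  }
  best <- 0
  for (i in seq_len(n + 1L)) {
    for (j in seq_len(m + 1L)) best <- max(best, rec(i, j, 0))
  }
  best
}

oracle_bbh <- function(ab, ba, min_identity) {
  ab <- ab[ab$identity >= min_identity, , drop = FALSE]
  ba <- ba[ba$identity >= min_identity, , drop = FALSE]
  best_of <- function(h, q) {
    sub <- h[h$query_id == q, , drop = FALSE]
    if (nrow(sub) == 0L) return(NA_character_)
    ev <- ifelse(is.na(sub$evalue), Inf, sub$evalue)
    sub <- sub[order(-sub$bitscore, ev, sub$subject_id), , drop = FALSE]
    sub$subject_id[1]
  }
  pairs <- data.frame(a = character(0), b = character(0))
  for (q in unique(ab$query_id)) {
    s <- best_of(ab, q)
    if (is.na(s)) next
    back <- best_of(ba, s)
    if (!is.na(back) && back == q) {
      pairs <- rbind(pairs, data.frame(a = q, b = s))
    }
  }
  pairs
}

oracle_filter_hits <- function(hits, min_identity, qcov_low, qcov_high) {
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    qc <- hits$aln_len[i] / hits$query_len[i]
    keep[i] <- hits$identity[i] >= min_identity &&
      qc > qcov_low && qc < qcov_high
  }
  hits[keep, , drop = FALSE]
}

# one-sided upper-tail p of the t distribution via numeric
# incomplete-beta integration: P(T > t) = I_x(df/2, 1/2)/2, x = df/(df+t^2)
oracle_t_pvalue <- function(tstat, df) {
  x <- df / (df + tstat^2)
  a <- df / 2
  b <- 0.5
  dens <- function(u) u^(a - 1) * (1 - u)^(b - 1)
  num <- integrate(dens, 0, x, rel.tol = 1e-12)$value
  p_half <- num / beta(a, b) / 2
  if (tstat >= 0) p_half else 1 - p_half
}

random_alignment_set <- function(n, target_len, target_id = "t",
                                 max_read = 400L) {
  start <- sample.int(target_len - 1L, n, replace = TRUE) - 1L
  len <- pmin(sample.int(max_read, n, replace = TRUE),
              target_len - start)
  block <- len
  matches <- pmax(1L, block - sample.int(20L, n, replace = TRUE) + 1L)
  data.frame(read_id = sprintf("r%04d", seq_len(n)),
             read_len = len, read_start = 0L, read_end = len,
             strand = sample(c("+", "-"), n, replace = TRUE),
             target_id = target_id, target_len = target_len,
             target_start = start, target_end = start + len,
             matches = matches, block_len = block, mapq = 60L,
             stringsAsFactors = FALSE)
}
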