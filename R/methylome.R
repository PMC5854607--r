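IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

iupac_code_for <- function(bases) {
  key <- paste(sort(unique(bases)), collapse = "")
  names(IUPAC_SETS)[vapply(IUPAC_SETS, function(s) {
    paste(sort(s), collapse = "") == key
  }, logical(1))][1]
}

#' IUPAC methyltransferase recognition motif
#'
#' @param pattern IUPAC pattern string (length <= 12).
#' @param methyl_index 0-based offset of the methylated base; the code at
#'   that position must resolve to A (6mA) or C (4mC).
#' @param mod_type `"6mA"` or `"4mC"`; inferred from the methylated base
#'   when missing.
#' @return An `iupac_motif` list.
#' @export
iupac_motif <- function(pattern, methyl_index, mod_type = NULL) {
  pattern <- toupper(pattern)
  stopifnot(nchar(pattern) <= 12L, methyl_index >= 0,
            methyl_index < nchar(pattern))
  mb <- substr(pattern, methyl_index + 1L, methyl_index + 1L)
  if (!mb %in% c("A", "C")) {
    stop("pattern position ", methyl_index, " must be A or C, found ", mb)
  }
  if (is.null(mod_type)) mod_type <- if (mb == "A") "6mA" else "4mC"
  structure(list(pattern = pattern, methyl_index = as.integer(methyl_index),
                 mod_type = mod_type),
            class = "iupac_motif")
}

#' @export
print.iupac_motif <- function(x, ...) {
  marked <- paste0(substr(x$pattern, 1, x$methyl_index), "(",
                   tolower(x$mod_type), ")",
                   substr(x$pattern, x$methyl_index + 1, x$methyl_index + 1),
                   substr(x$pattern, x$methyl_index + 2, nchar(x$pattern)))
  cat("motif ", x$pattern, " [", marked, "]\n", sep = "")
  invisible(x)
}

iupac_revcomp <- function(pattern) {
  chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN",
         paste(rev(strsplit(pattern, "", fixed = TRUE)[[1]]), collapse = ""))
}

is_palindromic <- function(pattern) identical(pattern, iupac_revcomp(pattern))

# stranded occurrences of an IUPAC pattern: one row per (locus, strand)
# with the methylated-base position in forward-strand coordinates
motif_occurrences_stranded <- function(genome, pattern, methyl_index) {
  subj <- Biostrings::DNAString(genome)
  len <- nchar(pattern)
  fwd <- Biostrings::matchPattern(pattern, subj, fixed = "subject")
  fs <- BiocGenerics::start(fwd) - 1L
  out_f <- data.frame(locus = fs, strand = rep("+", length(fs)),
                      methyl_pos = fs + methyl_index,
                      stringsAsFactors = FALSE)
  rcp <- iupac_revcomp(pattern)
  rev <- Biostrings::matchPattern(rcp, subj, fixed = "subject")
  rs <- BiocGenerics::start(rev) - 1L
  out_r <- data.frame(locus = rs, strand = rep("-", length(rs)),
                      methyl_pos = rs + (len - 1L - methyl_index),
                      stringsAsFactors = FALSE)
  rbind(out_f, out_r)
}

#' Score kinetics sites for base modification
#'
#' One-sided Welch two-sample t-test of `obs_mean > ctrl_mean` on the
#' log-IPD scale, per site. The modification QV is the Phred-like
#' `-10 * log10(p)`, capped at `qv_cap`; a site whose QV reaches
#' `call_threshold` is typed from its base (A to 6mA, C to 4mC, never 5mC
#' since untreated DNA does not expose it), otherwise `unknown`.
#'
#' @param kinetics Kinetics data.frame (see [simulate_kinetics()] /
#'   [read_kinetics()]).
#' @param qv_cap Upper cap on the QV (default 1000).
#' @param call_threshold QV needed to assign a modification type.
#' @return data.frame of modification calls: `target_id`, `position`,
#'   `strand`, `base`, `mod_type`, `qv`, `coverage`.
#' @export
score_sites <- function(kinetics, qv_cap = 1000, call_threshold = 100) {
  k <- kinetics
  if (any(k$obs_n < 2 | k$ctrl_n < 2)) {
    stop("scoring error: every site needs obs_n >= 2 and ctrl_n >= 2")
  }
  if (any(k$obs_sd <= 0 | k$ctrl_sd <= 0)) {
    stop("scoring error: standard deviations must be positive")
  }
  v1 <- k$obs_sd^2 / k$obs_n
  v2 <- k$ctrl_sd^2 / k$ctrl_n
  tstat <- (k$obs_mean - k$ctrl_mean) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (k$obs_n - 1) + v2^2 / (k$ctrl_n - 1))
  log_p <- pt(tstat, df, lower.tail = FALSE, log.p = TRUE)
  qv <- pmin(-10 * log_p / log(10), qv_cap)
  mod_type <- ifelse(qv >= call_threshold & k$base == "A", "6mA",
                     ifelse(qv >= call_threshold & k$base == "C", "4mC",
                            "unknown"))
  data.frame(target_id = k$target_id, position = k$position,
             strand = k$strand, base = k$base, mod_type = mod_type,
             qv = qv, coverage = k$obs_n, stringsAsFactors = FALSE)
}

#' Score a single kinetics site
#'
#' Scalar convenience around [score_sites()].
#'
#' @param site One-row kinetics data.frame (or list with the kinetics
#'   fields).
#' @param ... Passed to [score_sites()].
#' @return One-row modification-call data.frame.
#' @export
score_site <- function(site, ...) {
  score_sites(as.data.frame(site, stringsAsFactors = FALSE), ...)
}

#' Threshold modification calls
#'
#' Retains calls with `qv >= qv_threshold` (boundary inclusive), order
#' preserved.
#'
#' @param calls Modification-call data.frame from [score_sites()].
#' @param qv_threshold QV threshold (default 100).
#' @return Filtered data.frame.
#' @export
call_sites <- function(calls, qv_threshold = 100) {
  calls[calls$qv >= qv_threshold, , drop = FALSE]
}

#' Occurrences of an IUPAC motif in a genome
#'
#' Matches the pattern on both strands. A self-reverse-complementary
#' (palindromic) motif matches the same loci on both strands; those are
#' reported once per locus (forward orientation) unless
#' `count_per_strand = TRUE`. The methylated-base position is reported in
#' forward-strand coordinates.
#'
#' @param genome Genome string.
#' @param motif An [iupac_motif()] (or list with `pattern` and
#'   `methyl_index`).
#' @param count_per_strand Report palindromic matches once per strand.
#' @return data.frame with `locus` (0-based match start), `strand`,
#'   `methyl_pos`.
#' @export
count_motif_occurrences <- function(genome, motif, count_per_strand = FALSE) {
  occ <- motif_occurrences_stranded(genome, motif$pattern, motif$methyl_index)
  if (!count_per_strand && is_palindromic(motif$pattern)) {
    occ <- occ[occ$strand == "+", , drop = FALSE]
  }
  rownames(occ) <- NULL
  occ
}

# ---- motif discovery -------------------------------------------------------

# count exact-word occurrences (stranded) in the genome, per word length,
# via substring tabulation over genome and reverse complement
genome_word_counts <- function(genome, w) {
  count_one <- function(s) {
    L <- nchar(s)
    if (L < w) return(table(character(0)))
    table(substring(s, 1:(L - w + 1L), w:L))
  }
  tf <- count_one(genome)
  tr <- count_one(revcomp(genome))
  all <- union(names(tf), names(tr))
  cnt <- setNames(integer(length(all)), all)
  cnt[names(tf)] <- cnt[names(tf)] + as.integer(tf)
  cnt[names(tr)] <- cnt[names(tr)] + as.integer(tr)
  cnt
}

# stranded methylation evaluation of a candidate pattern
eval_pattern <- function(genome, pattern, methyl_index, called_keys) {
  occ <- motif_occurrences_stranded(genome, pattern, methyl_index)
  n_occ <- nrow(occ)
  if (n_occ == 0L) return(list(n_occ = 0L, n_meth = 0L, frac = 0, occ = occ))
  keys <- paste(occ$methyl_pos, occ$strand)
  n_meth <- sum(keys %in% called_keys)
  list(n_occ = n_occ, n_meth = n_meth, frac = n_meth / n_occ, occ = occ,
       keys = keys)
}

#' Discover methyltransferase recognition motifs around called sites
#'
#' Greedy specific-to-degenerate search. Sequence contexts are extracted
#' around every retained modification call (centered on the methylated
#' base, read 5' to 3' on the called strand). The search seeds with the
#' exact word, anchored at the methylated base, that explains the most
#' remaining called sites while staying genome-wide methylated at
#' `>= min_frac` of its occurrences; it then greedily generalizes
#' positions to IUPAC ambiguity codes as long as that gains methylated
#' occurrences and keeps the genome-wide methylated fraction at
#' `>= min_frac`. Sites explained by an accepted motif are removed and the
#' search repeats until fewer than `min_sites` remain or no word
#' qualifies.
#'
#' @param genome Genome string.
#' @param called Retained modification calls (see [call_sites()]).
#' @param max_len Maximum motif length (default 12).
#' @param max_degenerate Maximum number of degenerate (non-ACGT)
#'   positions (default 3).
#' @param min_sites Minimum called sites a motif must explain (default 20).
#' @param min_frac Minimum genome-wide methylated fraction (default 0.3).
#' @param seed_len_max Longest exact seed word considered (default 8).
#' @return List of [iupac_motif()] objects (possibly empty).
#' @export
discover_motifs <- function(genome, called, max_len = 12L,
                            max_degenerate = 3L, min_sites = 20L,
                            min_frac = 0.3, seed_len_max = 8L) {
  if (nrow(called) == 0L) return(list())
  seed_len_max <- min(seed_len_max, max_len)
  half <- seed_len_max - 1L
  L <- nchar(genome)
  rc <- revcomp(genome)
  # strand-oriented context around each called site, methylated base at
  # position half (0-based) of the context string
  ctx_for <- function(pos, strand) {
    if (strand == "+") {
      lo <- pos - half; hi <- pos + half
      s <- substr(genome, max(1L, lo + 1L), min(L, hi + 1L))
      pad_l <- max(0L, -lo); pad_r <- max(0L, hi - (L - 1L))
    } else {
      p2 <- (L - 1L) - pos
      lo <- p2 - half; hi <- p2 + half
      s <- substr(rc, max(1L, lo + 1L), min(L, hi + 1L))
      pad_l <- max(0L, -lo); pad_r <- max(0L, hi - (L - 1L))
    }
    paste0(strrep("N", pad_l), s, strrep("N", pad_r))
  }
  contexts <- vapply(seq_len(nrow(called)), function(i) {
    ctx_for(called$position[i], called$strand[i])
  }, character(1))
  active <- rep(TRUE, length(contexts))
  called_keys <- paste(called$position, called$strand)
  word_counts <- lapply(setNames(3:seed_len_max, 3:seed_len_max),
                        function(w) genome_word_counts(genome, w))
  motifs <- list()
  repeat {
    if (sum(active) < min_sites) break
    ctx <- contexts[active]
    # seed: best exact word over lengths and anchor offsets
    best <- NULL
    for (w in 3:seed_len_max) {
      counts <- word_counts[[as.character(w)]]
      for (m in 0:(w - 1L)) {
        words <- substr(ctx, half - m + 1L, half - m + w)
        words <- words[!grepl("N", words, fixed = TRUE) &
                         substr(words, m + 1L, m + 1L) %in% c("A", "C")]
        if (!length(words)) next
        tab <- table(words)
        tab <- tab[as.integer(tab) >= min_sites]
        if (!length(tab)) next
        occ <- counts[names(tab)]
        occ[is.na(occ)] <- 0L
        frac <- as.integer(tab) / pmax(1L, occ)
        ok <- frac >= min_frac & occ > 0
        if (!any(ok)) next
        cand <- which(ok)
        pick <- cand[order(-as.integer(tab)[cand], -frac[cand])][1]
        if (is.null(best) || as.integer(tab)[pick] > best$n_ctx ||
            (as.integer(tab)[pick] == best$n_ctx && frac[pick] > best$frac)) {
          best <- list(pattern = names(tab)[pick], methyl_index = m,
                       n_ctx = as.integer(tab)[pick], frac = frac[pick])
        }
      }
    }
    if (is.null(best)) break
    pattern <- best$pattern
    mi <- best$methyl_index
    cur <- eval_pattern(genome, pattern, mi, called_keys)
    # greedy IUPAC generalization
    repeat {
      chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
      n_degen <- sum(!chars %in% c("A", "C", "G", "T"))
      gain_best <- NULL
      for (p in seq_along(chars)) {
        if (p == mi + 1L) next  # methylated base stays fixed
        cur_set <- IUPAC_SETS[[chars[p]]]
        for (code in names(IUPAC_SETS)) {
          new_set <- IUPAC_SETS[[code]]
          if (length(new_set) <= length(cur_set)) next
          if (!all(cur_set %in% new_set)) next
          if (n_degen >= max_degenerate &&
              chars[p] %in% c("A", "C", "G", "T")) next
          cand_chars <- chars
          cand_chars[p] <- code
          cand_pat <- paste(cand_chars, collapse = "")
          ev <- eval_pattern(genome, cand_pat, mi, called_keys)
          if (ev$frac >= min_frac && ev$n_meth > cur$n_meth) {
            if (is.null(gain_best) || ev$n_meth > gain_best$ev$n_meth ||
                (ev$n_meth == gain_best$ev$n_meth &&
                   ev$frac > gain_best$ev$frac)) {
              gain_best <- list(pattern = cand_pat, ev = ev)
            }
          }
        }
      }
      if (is.null(gain_best)) break
      pattern <- gain_best$pattern
      cur <- gain_best$ev
    }
    if (cur$n_meth < min_sites) break
    motifs[[length(motifs) + 1L]] <- iupac_motif(pattern, mi)
    explained <- called_keys %in% cur$keys
    active <- active & !explained
  }
  prune_redundant_motifs(genome, motifs)
}

# drop any motif whose stranded match set is contained in another's
prune_redundant_motifs <- function(genome, motifs) {
  if (length(motifs) <= 1L) return(motifs)
  sets <- lapply(motifs, function(m) {
    occ <- motif_occurrences_stranded(genome, m$pattern, m$methyl_index)
    paste(occ$methyl_pos, occ$strand)
  })
  drop <- rep(FALSE, length(motifs))
  for (i in seq_along(motifs)) {
    for (j in seq_along(motifs)) {
      if (i == j || drop[j]) next
      if (all(sets[[i]] %in% sets[[j]])) { drop[i] <- TRUE; break }
    }
  }
  motifs[!drop]
}

#' Summarize motifs against the modification calls
#'
#' One row per motif: occurrences detected in the genome (palindromic
#' loci counted once), how many of them carry a retained modification
#' call at the methylated base, the methylated percentage, the percentage
#' of occurrences whose methylated base lies outside every gene model,
#' and the mean per-strand coverage over methylated occurrences.
#'
#' @param genome Genome string.
#' @param motifs List of [iupac_motif()] objects.
#' @param called Retained calls ([call_sites()]).
#' @param genes Gene data.frame ([read_annotation()]); may be `NULL`, in
#'   which case every position counts as intergenic.
#' @param count_per_strand Passed to [count_motif_occurrences()].
#' @return data.frame with columns `motif`, `methyl_index`, `mod_type`,
#'   `n_detected`, `n_methylated`, `frac_methylated`, `frac_intergenic`,
#'   `mean_coverage`.
#' @export
motif_summary <- function(genome, motifs, called, genes = NULL,
                          count_per_strand = FALSE) {
  called_keys <- paste(called$position, called$strand)
  cov_by_key <- setNames(called$coverage, called_keys)
  gene_rng <- if (!is.null(genes) && nrow(genes)) {
    IRanges::reduce(IRanges::IRanges(genes$start + 1L, genes$end))
  } else IRanges::IRanges()
  rows <- lapply(motifs, function(m) {
    occ <- count_motif_occurrences(genome, m, count_per_strand)
    n_det <- nrow(occ)
    keys <- paste(occ$methyl_pos, occ$strand)
    meth <- keys %in% called_keys
    n_meth <- sum(meth)
    intergenic <- if (n_det) {
      !IRanges::overlapsAny(IRanges::IRanges(occ$methyl_pos + 1L,
                                             occ$methyl_pos + 1L), gene_rng)
    } else logical(0)
    data.frame(
      motif = m$pattern, methyl_index = m$methyl_index,
      mod_type = m$mod_type,
      n_detected = n_det, n_methylated = n_meth,
      frac_methylated = if (n_det) 100 * n_meth / n_det else NA_real_,
      frac_intergenic = if (n_det) 100 * mean(intergenic) else NA_real_,
      mean_coverage = if (n_meth) {
        mean(unname(cov_by_key[keys[meth]]))
      } else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(motif = character(0), methyl_index = integer(0),
                      mod_type = character(0), n_detected = integer(0),
                      n_methylated = integer(0), frac_methylated = numeric(0),
                      frac_intergenic = numeric(0), mean_coverage = numeric(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Write retained modification calls as GFF3-like text
#'
#' One row per retained call with position, strand, modification type,
#' QV and per-strand coverage.
#'
#' @param called Retained calls ([call_sites()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_modifications <- function(called, path) {
  lines <- paste(called$target_id, "strainsieve", called$mod_type,
                 called$position + 1L, called$position + 1L,
                 formatC(called$qv, format = "f", digits = 2),
                 called$strand, ".",
                 paste0("coverage=", called$coverage), sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}
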