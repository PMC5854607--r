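#' Genome composition statistics
#'
#' Genome length, overall GC percentage (ambiguous bases excluded from
#' the denominator), and per-window GC percentage and GC skew
#' `(G - C)/(G + C)`. Windows are non-overlapping, anchored at position
#' 0; the final partial window is reported but flagged.
#'
#' @param genome Genome string.
#' @param window Window size in bases (default 1000).
#' @return List with `length`, `gc_percent`, and `windows` (data.frame
#'   `start`, `end`, `gc_percent`, `gc_skew`, `skew_defined`, `partial`).
#' @export
genome_stats <- function(genome, window = 1000L) {
  L <- nchar(genome)
  counts <- base_counts(genome)
  acgt <- sum(counts[c("A", "C", "G", "T")])
  gc_percent <- 100 * sum(counts[c("G", "C")]) / acgt
  starts <- seq(0L, L - 1L, by = window)
  ends <- pmin(starts + window, L)
  wstats <- t(vapply(seq_along(starts), function(i) {
    wc <- base_counts(substr(genome, starts[i] + 1L, ends[i]))
    gc <- wc[["G"]] + wc[["C"]]
    at <- wc[["A"]] + wc[["T"]]
    c(gc_percent = if (gc + at > 0) 100 * gc / (gc + at) else NA_real_,
      gc_skew = if (gc > 0) (wc[["G"]] - wc[["C"]]) / gc else 0,
      skew_defined = as.numeric(gc > 0))
  }, numeric(3)))
  windows <- data.frame(start = starts, end = ends,
                        gc_percent = wstats[, "gc_percent"],
                        gc_skew = wstats[, "gc_skew"],
                        skew_defined = wstats[, "skew_defined"] == 1,
                        partial = ends - starts < window)
  list(length = L, gc_percent = gc_percent, windows = windows)
}

base_counts <- function(seq) {
  tab <- table(strsplit(seq, "", fixed = TRUE)[[1]])
  out <- setNames(numeric(4), c("A", "C", "G", "T"))
  common <- intersect(names(tab), names(out))
  out[common] <- as.numeric(tab[common])
  out
}

#' GC-deviant windows
#'
#' Full windows whose GC percentage deviates from the genome-wide GC by
#' at least `threshold_pp` percentage points; the trailing partial window
#' is excluded from the count.
#'
#' @param genome Genome string.
#' @param window Window size (default 1000).
#' @param threshold_pp Deviation cutoff in percentage points (default 5).
#' @return List with `count` and `intervals` (data.frame `start`, `end`,
#'   `gc_percent`, `deviation`).
#' @export
gc_deviant_windows <- function(genome, window = 1000L, threshold_pp = 5) {
  st <- genome_stats(genome, window)
  w <- st$windows[!st$windows$partial, , drop = FALSE]
  dev <- abs(w$gc_percent - st$gc_percent)
  keep <- !is.na(dev) & dev >= threshold_pp
  list(count = sum(keep),
       intervals = data.frame(start = w$start[keep], end = w$end[keep],
                              gc_percent = w$gc_percent[keep],
                              deviation = dev[keep]))
}

#' Optimal local alignment of two sequences
#'
#' Exact Smith-Waterman alignment with affine gaps, used as the hit
#' generator for small synthetic gene sets and as the extension engine of
#' [orthoani()]. DNA uses match/mismatch scoring; protein a standard
#' BLOSUM62 substitution matrix. The empty alignment (score 0) is the
#' floor when no positive-scoring alignment exists.
#'
#' @param a,b Sequences (single strings).
#' @param alphabet `"dna"` or `"protein"`.
#' @param match,mismatch DNA scoring (ignored for protein).
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @param size_cap Refuse exact alignment when `nchar(a) * nchar(b)`
#'   exceeds this (guards against accidental genome-scale calls).
#' @return List with `score`, `columns` (aligned columns), `identity`
#'   (percent of matching columns; `NA` for the empty alignment),
#'   `a_aligned`, `b_aligned` (aligned substrings with gaps).
#' @export
local_align <- function(a, b, alphabet = c("dna", "protein"),
                        match = 1, mismatch = -1,
                        gap_open = 5, gap_extend = 2,
                        size_cap = 4e7) {
  alphabet <- match.arg(alphabet)
  if (nchar(a) == 0L || nchar(b) == 0L) stop("empty sequence")
  if (as.numeric(nchar(a)) * nchar(b) > size_cap) {
    stop("sequences exceed the exact-alignment size cap; use the seeded ",
         "fragment aligner (orthoani) for genome-scale comparisons")
  }
  if (alphabet == "dna") {
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                    mismatch = mismatch)
    pa <- Biostrings::pairwiseAlignment(
      a, b, type = "local", substitutionMatrix = mat,
      gapOpening = gap_open, gapExtension = gap_extend)
  } else {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
      substitutionMatrix = "BLOSUM62",
      gapOpening = gap_open, gapExtension = gap_extend)
  }
  sc <- Biostrings::score(pa)
  cols <- Biostrings::nchar(pa)
  if (sc <= 0 || cols == 0L) {
    return(list(score = 0, columns = 0L, identity = NA_real_,
                a_aligned = "", b_aligned = ""))
  }
  list(score = sc, columns = cols,
       identity = 100 * Biostrings::nmatch(pa) / cols,
       a_aligned = as.character(Biostrings::alignedPattern(pa)),
       b_aligned = as.character(Biostrings::alignedSubject(pa)))
}

# locate a fragment on a target genome by k-mer diagonal voting; returns
# NULL or list(strand, start) giving the approximate target start
seed_fragment <- function(frag, target_index, k, step = 29L) {
  flen <- nchar(frag)
  offs <- seq(1L, flen - k + 1L, by = step)
  words <- substring(frag, offs, offs + k - 1L)
  hit <- target_index$pos[match(words, target_index$kmer)]
  ok <- !is.na(hit)
  if (!any(ok)) return(NULL)
  strand <- target_index$strand[match(words, target_index$kmer)][ok]
  diag <- hit[ok] - offs[ok]
  key <- paste(strand, diag)
  tab <- sort(table(key), decreasing = TRUE)
  best <- strsplit(names(tab)[1], " ", fixed = TRUE)[[1]]
  list(strand = best[1], start = as.integer(best[2]))
}

build_kmer_index <- function(genome, k) {
  L <- nchar(genome)
  fwd <- substring(genome, 1:(L - k + 1L), k:L)
  rev <- substring(revcomp(genome), 1:(L - k + 1L), k:L)
  kmer <- c(fwd, rev)
  pos <- c(1:(L - k + 1L), 1:(L - k + 1L))
  strand <- rep(c("+", "-"), each = L - k + 1L)
  # keep only kmers unique within the index so the vote is unambiguous
  dup <- duplicated(kmer) | duplicated(kmer, fromLast = TRUE)
  list(kmer = kmer[!dup], pos = pos[!dup], strand = strand[!dup], len = L)
}

align_fragment <- function(frag, target, loc, margin = 200L) {
  L <- nchar(target)
  flen <- nchar(frag)
  if (loc$strand == "-") frag <- revcomp(frag)
  s <- max(1L, loc$start - margin)
  e <- min(L, loc$start + flen + margin)
  if (loc$strand == "-") {
    # index position was on the reverse-complement; convert to forward
    s <- max(1L, L - (loc$start + flen + margin) + 1L)
    e <- min(L, L - loc$start + 1L + margin)
  }
  win <- substr(target, s, e)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2)
  pa <- Biostrings::pairwiseAlignment(
    frag, win, type = "global-local", substitutionMatrix = mat,
    gapOpening = 4, gapExtension = 2)
  cols <- Biostrings::nchar(pa)
  ident <- if (cols > 0) 100 * Biostrings::nmatch(pa) / cols else 0
  tstart <- s + BiocGenerics::start(Biostrings::subject(pa)) - 1L
  tend <- s + BiocGenerics::end(Biostrings::subject(pa)) - 1L
  list(identity = ident, coverage = cols / flen,
       mid = (tstart + tend) / 2)
}

#' Fragment-based average nucleotide identity (OrthoANI scheme)
#'
#' Both genomes are cut into consecutive non-overlapping fragments of
#' `fragment_len` (tail fragments discarded). Each fragment is located on
#' the other genome by k-mer seeding and aligned by banded extension;
#' reciprocal best fragment pairs with at least `min_identity` percent
#' identity over at least `min_cov` of the fragment are retained, and the
#' ANI is the mean identity over retained pairs, symmetrized over both
#' directions.
#'
#' @param a,b Genome strings.
#' @param fragment_len Fragment size in bases (default 1020).
#' @param min_identity Minimum retained fragment identity, percent.
#' @param min_cov Minimum fragment coverage of the alignment.
#' @param k Seed k-mer length.
#' @return List with `ani` (percent, `NA` when undefined),
#'   `n_fragment_pairs`, `fragment_len`.
#' @export
orthoani <- function(a, b, fragment_len = 1020L, min_identity = 70,
                     min_cov = 0.5, k = 13L) {
  if (nchar(a) < fragment_len || nchar(b) < fragment_len) {
    return(list(ani = NA_real_, n_fragment_pairs = 0L,
                fragment_len = fragment_len))
  }
  frags <- function(g) {
    n <- nchar(g) %/% fragment_len
    substring(g, (0:(n - 1L)) * fragment_len + 1L,
              (1:n) * fragment_len)
  }
  fa <- frags(a); fb <- frags(b)
  direction <- function(frs, target, n_target_frags) {
    idx <- build_kmer_index(target, k)
    t(vapply(seq_along(frs), function(i) {
      loc <- seed_fragment(frs[i], idx, k)
      if (is.null(loc)) return(c(NA_real_, NA_real_, NA_real_))
      alr <- align_fragment(frs[i], target, loc)
      tf <- floor((alr$mid - 1) / fragment_len)
      if (tf < 0 || tf >= n_target_frags) return(c(NA_real_, NA_real_, NA_real_))
      c(alr$identity, alr$coverage, tf)
    }, numeric(3)))
  }
  ab <- direction(fa, b, length(fb))
  ba <- direction(fb, a, length(fa))
  ok_ab <- !is.na(ab[, 1]) & ab[, 1] >= min_identity & ab[, 2] >= min_cov
  ok_ba <- !is.na(ba[, 1]) & ba[, 1] >= min_identity & ba[, 2] >= min_cov
  # reciprocal best fragment pairs: i -> j in A->B and j -> i in B->A
  pairs_id <- numeric(0)
  n_pairs <- 0L
  for (i in which(ok_ab)) {
    j <- ab[i, 3] + 1L
    if (j >= 1 && j <= nrow(ba) && ok_ba[j] && ba[j, 3] + 1L == i) {
      pairs_id <- c(pairs_id, ab[i, 1], ba[j, 1])
      n_pairs <- n_pairs + 1L
    }
  }
  if (n_pairs == 0L) {
    return(list(ani = NA_real_, n_fragment_pairs = 0L,
                fragment_len = fragment_len))
  }
  list(ani = mean(pairs_id), n_fragment_pairs = n_pairs,
       fragment_len = fragment_len)
}

#' Read a 12-column tabular hit table (BLAST outfmt 6)
#'
#' Columns: query, subject, percent identity, alignment length,
#' mismatches, gap opens, qstart, qend, sstart, send, evalue, bitscore.
#' Query/subject lengths are not part of the format; supply them (e.g.
#' from the FASTA the search ran on) so query coverage can be computed.
#'
#' @param path Hit table path.
#' @param query_lengths,subject_lengths Optional named vectors of sequence
#'   lengths.
#' @return Hit data.frame with columns `query_id`, `subject_id`,
#'   `identity`, `aln_len`, `query_len`, `subject_len`, `evalue`,
#'   `bitscore`.
#' @export
read_hits <- function(path, query_lengths = NULL, subject_lengths = NULL) {
  raw <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 12L) stop("hit table parse error: expected 12 columns")
  out <- data.frame(query_id = as.character(raw[[1]]),
                    subject_id = as.character(raw[[2]]),
                    identity = as.numeric(raw[[3]]),
                    aln_len = as.integer(raw[[4]]),
                    query_len = NA_integer_, subject_len = NA_integer_,
                    evalue = as.numeric(raw[[11]]),
                    bitscore = as.numeric(raw[[12]]),
                    stringsAsFactors = FALSE)
  if (!is.null(query_lengths)) {
    out$query_len <- unname(query_lengths[out$query_id])
  }
  if (!is.null(subject_lengths)) {
    out$subject_len <- unname(subject_lengths[out$subject_id])
  }
  out
}

#' Generate a hit table by all-against-all exact local alignment
#'
#' Desk-scale hit generator for small gene sets (the heavy lifting for
#' real proteomes belongs to an external search engine whose 12-column
#' output [read_hits()] consumes).
#'
#' @param queries,subjects Named character vectors of sequences.
#' @param alphabet,... Passed to [local_align()].
#' @param min_score Hits below this alignment score are dropped.
#' @return Hit data.frame as in [read_hits()].
#' @export
align_all_pairs <- function(queries, subjects, alphabet = "dna",
                            min_score = 1, ...) {
  rows <- list()
  for (q in names(queries)) {
    for (s in names(subjects)) {
      al <- local_align(queries[[q]], subjects[[s]], alphabet = alphabet, ...)
      if (al$score < min_score || al$columns == 0L) next
      rows[[length(rows) + 1L]] <- data.frame(
        query_id = q, subject_id = s, identity = al$identity,
        aln_len = al$columns,
        query_len = nchar(queries[[q]]), subject_len = nchar(subjects[[s]]),
        evalue = NA_real_, bitscore = al$score,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(query_id = character(0), subject_id = character(0),
                      identity = numeric(0), aln_len = integer(0),
                      query_len = integer(0), subject_len = integer(0),
                      evalue = numeric(0), bitscore = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Filter pairwise hits on identity and query coverage
#'
#' Keeps hits with identity at or above `min_identity` whose query
#' coverage (`aln_len / query_len`, which can exceed 1 through gap
#' columns) lies strictly between the exclusion bounds — hits covering
#' `<= 75%` or `>= 120%` of the query are removed under the defaults.
#'
#' @param hits Hit data.frame ([read_hits()]).
#' @param min_identity Minimum percent identity (default 90).
#' @param qcov_low,qcov_high Exclusion bounds on query coverage.
#' @return Filtered hit data.frame.
#' @export
filter_hits <- function(hits, min_identity = 90, qcov_low = 0.75,
                        qcov_high = 1.20) {
  qcov <- hits$aln_len / hits$query_len
  keep <- hits$identity >= min_identity & qcov > qcov_low & qcov < qcov_high
  hits[keep, , drop = FALSE]
}

best_hit_per_query <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  ev <- ifelse(is.na(hits$evalue), Inf, hits$evalue)
  ord <- order(hits$query_id, -hits$bitscore, ev, hits$subject_id)
  h <- hits[ord, , drop = FALSE]
  h[!duplicated(h$query_id), , drop = FALSE]
}

#' Best bidirectional hits between two gene sets
#'
#' `(a, b)` is reported when `b` is `a`'s best subject in the A-to-B hit
#' table and `a` is `b`'s best subject in the B-to-A table, both at
#' identity at or above `min_identity`. "Best" is the maximum bitscore,
#' ties broken by minimum evalue then lexicographic subject id. The
#' identity filter is applied before choosing the best hit
#' (`filter_first = TRUE`, default) or after.
#'
#' @param hits_ab,hits_ba Hit data.frames for the two directions.
#' @param min_identity Minimum percent identity (default 90).
#' @param filter_first Apply the identity filter before picking best hits.
#' @return data.frame with columns `a` and `b`, one row per BBH pair.
#' @export
best_bidirectional_hits <- function(hits_ab, hits_ba, min_identity = 90,
                                    filter_first = TRUE) {
  if (filter_first) {
    hits_ab <- hits_ab[hits_ab$identity >= min_identity, , drop = FALSE]
    hits_ba <- hits_ba[hits_ba$identity >= min_identity, , drop = FALSE]
  }
  best_ab <- best_hit_per_query(hits_ab)
  best_ba <- best_hit_per_query(hits_ba)
  if (!filter_first) {
    best_ab <- best_ab[best_ab$identity >= min_identity, , drop = FALSE]
    best_ba <- best_ba[best_ba$identity >= min_identity, , drop = FALSE]
  }
  if (nrow(best_ab) == 0L || nrow(best_ba) == 0L) {
    return(data.frame(a = character(0), b = character(0),
                      stringsAsFactors = FALSE))
  }
  back <- setNames(best_ba$subject_id, best_ba$query_id)
  keep <- !is.na(back[best_ab$subject_id]) &
    back[best_ab$subject_id] == best_ab$query_id
  out <- data.frame(a = best_ab$query_id[keep],
                    b = best_ab$subject_id[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Genes without a surviving hit
#'
#' @param gene_ids Character vector: the full gene universe.
#' @param filtered_hits Hit data.frame after [filter_hits()].
#' @return Character vector of gene ids with zero surviving hits.
#' @export
unique_genes <- function(gene_ids, filtered_hits) {
  setdiff(gene_ids, unique(filtered_hits$query_id))
}

#' Fraction of a query genome covered by qualifying alignments
#'
#' Union length of the query intervals of alignments at or above
#' `min_identity` percent identity (overlaps merged), divided by the
#' query genome length. Alignments follow PAF semantics with the query on
#' the read axis (`read_start`/`read_end`).
#'
#' @param aln Alignment data.frame.
#' @param query_len Query genome length; defaults to `read_len` of the
#'   first record.
#' @param min_identity Minimum percent identity (default 95).
#' @return Fraction in \[0, 1\].
#' @export
aligned_fraction <- function(aln, query_len = NULL, min_identity = 95) {
  if (is.null(query_len)) {
    if (nrow(aln) == 0L) stop("query_len required for an empty alignment set")
    query_len <- aln$read_len[1]
  }
  if (nrow(aln) == 0L) return(0)
  ident <- 100 * aln$matches / aln$block_len
  keep <- ident >= min_identity
  if (!any(keep)) return(0)
  rng <- IRanges::reduce(IRanges::IRanges(aln$read_start[keep] + 1L,
                                          aln$read_end[keep]))
  sum(IRanges::width(rng)) / query_len
}

#' Classify gene presence from read coverage
#'
#' A gene base is covered when at least one read alignment overlaps it.
#' Status is `absent` when nothing is covered, `partial` when the
#' uncovered fraction exceeds `partial_uncovered_fraction`, else
#' `present`.
#'
#' @param genes Gene data.frame ([read_annotation()]).
#' @param aln Read alignments to the genome carrying the genes.
#' @param partial_uncovered_fraction Partial-call cutoff (default 0.25).
#' @return data.frame with `gene_id`, `covered_fraction`, `status`.
#' @export
gene_presence <- function(genes, aln, partial_uncovered_fraction = 0.25) {
  status <- character(nrow(genes))
  covered <- numeric(nrow(genes))
  for (ct in unique(genes$contig)) {
    gsub_ <- which(genes$contig == ct)
    asub <- aln[aln$target_id == ct, , drop = FALSE]
    cov_rng <- IRanges::reduce(IRanges::IRanges(asub$target_start + 1L,
                                                asub$target_end))
    gene_rng <- IRanges::IRanges(genes$start[gsub_] + 1L, genes$end[gsub_])
    covbases <- vapply(seq_along(gsub_), function(i) {
      ov <- IRanges::pintersect(
        IRanges::findOverlapPairs(gene_rng[i], cov_rng))
      sum(IRanges::width(ov))
    }, numeric(1))
    covered[gsub_] <- covbases / IRanges::width(gene_rng)
  }
  status[covered == 0] <- "absent"
  uncov <- 1 - covered
  status[covered > 0 & uncov > partial_uncovered_fraction] <- "partial"
  status[covered > 0 & uncov <= partial_uncovered_fraction] <- "present"
  data.frame(gene_id = genes$gene_id, covered_fraction = covered,
             status = status, stringsAsFactors = FALSE)
}
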