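#' Circularize a linear assembly by terminal-overlap trimming
#'
#' A closed chromosome assembled from long reads typically carries a
#' duplicated terminal overlap: the start of the contig reappears at its
#' end. `circularize()` finds the longest prefix that matches a terminal
#' suffix (allowing up to `max_mismatch_frac` mismatching bases), trims
#' one copy, and reports the circular sequence in canonical form (its
#' lexicographically smallest rotation) so the same chromosome linearized
#' at different cut points yields an identical result.
#'
#' Candidate overlaps are located by matching the first bases of the
#' sequence against its terminal region, then verified base by base. The
#' longest qualifying overlap wins; when more than one overlap length
#' qualifies the result is flagged ambiguous (degenerate sequence such as
#' a terminal homopolymer), but the longest is still returned.
#'
#' @param seq Linear sequence (single character string).
#' @param min_overlap Minimum acceptable overlap length in bases.
#' @param max_mismatch_frac Allowed fraction of mismatching bases within
#'   the overlap.
#' @param max_overlap Longest overlap considered (default half the
#'   sequence).
#' @return List with `circular` (logical), `sequence` (canonical circular
#'   sequence, or the input when not circularizable), `overlap` (trimmed
#'   overlap length) and `ambiguous` (logical).
#' @export
circularize <- function(seq, min_overlap = 50, max_mismatch_frac = 0,
                        max_overlap = NULL) {
  L <- nchar(seq)
  if (is.null(max_overlap)) max_overlap <- max(min_overlap, L %/% 2L)
  max_overlap <- min(max_overlap, L - 1L)
  if (min_overlap > max_overlap) {
    return(list(circular = FALSE, sequence = seq, overlap = 0L,
                ambiguous = FALSE))
  }
  seed_len <- min(min_overlap, 20L)
  seed <- substr(seq, 1L, seed_len)
  tail_start <- L - max_overlap + 1L
  tail_seq <- substr(seq, tail_start, L)
  hits <- Biostrings::matchPattern(
    seed, Biostrings::DNAString(tail_seq),
    max.mismatch = floor(max_mismatch_frac * seed_len))
  # overlap length implied by a seed match at tail position p
  ks <- L - (tail_start + BiocGenerics::start(hits) - 1L) + 1L
  ks <- sort(unique(ks[ks >= min_overlap & ks <= max_overlap]),
             decreasing = TRUE)
  qualifying <- integer(0)
  sv <- charToRaw(seq)
  for (k in ks) {
    mism <- sum(sv[seq_len(k)] != sv[(L - k + 1L):L])
    if (mism <= floor(max_mismatch_frac * k)) qualifying <- c(qualifying, k)
  }
  if (length(qualifying) == 0L) {
    return(list(circular = FALSE, sequence = seq, overlap = 0L,
                ambiguous = FALSE))
  }
  k <- max(qualifying)
  circ <- substr(seq, 1L, L - k)
  list(circular = TRUE,
       sequence = canonical_rotation(circ),
       overlap = k,
       ambiguous = length(qualifying) > 1L)
}

#' Lexicographically smallest rotation of a sequence
#'
#' Canonical form for circular sequences: two linearizations of the same
#' circle map to the same string.
#'
#' @param seq Single character string.
#' @return The smallest rotation of `seq`.
#' @export
canonical_rotation <- function(seq) {
  L <- nchar(seq)
  if (L <= 1L) return(seq)
  v <- as.integer(charToRaw(seq))
  doubled <- c(v, v)
  cand <- which(v == min(v))
  d <- 1L
  while (length(cand) > 1L && d < L) {
    ch <- doubled[cand + d]
    cand <- cand[ch == min(ch)]
    d <- d + 1L
  }
  start <- cand[1L]
  rawToChar(as.raw(doubled[start:(start + L - 1L)]))
}

#' Linearize a circular sequence with a duplicated terminal overlap
#'
#' Test helper and inverse of [circularize()]: cut a circular sequence at
#' `cut` and append a duplicated copy of the first `overlap` bases, the
#' structure a long-read assembler leaves at the ends of a closed
#' chromosome.
#'
#' @param seq Circular sequence (single character string).
#' @param cut Cut point (0-based) at which to open the circle.
#' @param overlap Length of the duplicated terminal overlap.
#' @return Linear character string of length `nchar(seq) + overlap`.
#' @export
linearize <- function(seq, cut = 0L, overlap = 0L) {
  L <- nchar(seq)
  stopifnot(cut >= 0L, cut < L, overlap >= 0L, overlap <= L)
  rotated <- if (cut == 0L) seq else {
    paste0(substr(seq, cut + 1L, L), substr(seq, 1L, cut))
  }
  paste0(rotated, substr(rotated, 1L, overlap))
}
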