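#' Read read-to-target alignments (PAF or minimal SAM)
#'
#' Coordinates are normalized to 0-based half-open intervals on the forward
#' target strand (PAF native convention). When several records share a
#' `read_id`, only the single best alignment is retained, mirroring the
#' "one best alignment per read" mapping contract used throughout the
#' pipeline: highest `matches`, ties broken by longest `block_len`, then by
#' input order.
#'
#' SAM support is deliberately minimal: unmapped records are skipped, the
#' reference span is taken from the CIGAR string, and identity comes from
#' the `NM` tag when present (otherwise `matches = block_len`).
#'
#' @param path Alignment file.
#' @param format `"paf"` or `"sam"`; guessed from the extension by default.
#' @param keep_best Apply the best-alignment-per-read rule (default `TRUE`).
#' @return An alignment data.frame with columns `read_id`, `read_len`,
#'   `read_start`, `read_end`, `strand`, `target_id`, `target_len`,
#'   `target_start`, `target_end`, `matches`, `block_len`, `mapq`.
#' @export
read_alignments <- function(path, format = c("auto", "paf", "sam"),
                            keep_best = TRUE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.sam$", path, ignore.case = TRUE)) "sam" else "paf"
  }
  aln <- if (format == "paf") parse_paf(path) else parse_sam_minimal(path)
  validate_alignments(aln, context = path)
  if (keep_best) aln <- best_alignments(aln)
  aln
}

parse_paf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_alignments())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, integer(1)) < 12L
  if (any(short)) {
    stop("PAF parse error in '", path, "' line ", which(short)[1],
         ": fewer than 12 columns", call. = FALSE)
  }
  col <- function(i) vapply(fields, `[[`, character(1), i)
  data.frame(
    read_id = col(1), read_len = as.integer(col(2)),
    read_start = as.integer(col(3)), read_end = as.integer(col(4)),
    strand = col(5),
    target_id = col(6), target_len = as.integer(col(7)),
    target_start = as.integer(col(8)), target_end = as.integer(col(9)),
    matches = as.integer(col(10)), block_len = as.integer(col(11)),
    mapq = as.integer(col(12)),
    stringsAsFactors = FALSE)
}

parse_sam_minimal <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^@", lines)
  sq <- lines[grepl("^@SQ", lines)]
  tlen <- integer(0)
  if (length(sq)) {
    nm <- sub(".*SN:([^\t]+).*", "\\1", sq)
    ln <- as.integer(sub(".*LN:([0-9]+).*", "\\1", sq))
    tlen <- setNames(ln, nm)
  }
  body <- lines[!hdr & nzchar(lines)]
  if (length(body) == 0L) return(empty_alignments())
  fields <- strsplit(body, "\t", fixed = TRUE)
  flag <- vapply(fields, function(f) as.integer(f[[2]]), integer(1))
  mapped <- bitwAnd(flag, 4L) == 0L
  fields <- fields[mapped]
  flag <- flag[mapped]
  if (length(fields) == 0L) return(empty_alignments())
  rows <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    cig <- cigar_lengths(f[[6]])
    nm <- grep("^NM:i:", f, value = TRUE)
    block <- cig$block
    matches <- if (length(nm)) block - as.integer(sub("^NM:i:", "", nm[1])) else block
    tid <- f[[3]]
    data.frame(
      read_id = f[[1]],
      read_len = cig$clip_left + cig$read + cig$clip_right,
      read_start = cig$clip_left,
      read_end = cig$clip_left + cig$read,
      strand = if (bitwAnd(flag[i], 16L)) "-" else "+",
      target_id = tid,
      target_len = if (tid %in% names(tlen)) unname(tlen[tid]) else NA_integer_,
      target_start = as.integer(f[[4]]) - 1L,
      target_end = as.integer(f[[4]]) - 1L + cig$ref,
      matches = matches, block_len = block,
      mapq = as.integer(f[[5]]),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

cigar_lengths <- function(cigar) {
  if (cigar == "*") stop("minimal SAM reader requires a CIGAR string")
  n <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  op <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  ref <- sum(n[op %in% c("M", "D", "N", "=", "X")])
  readc <- sum(n[op %in% c("M", "I", "=", "X")])
  block <- sum(n[op %in% c("M", "I", "D", "=", "X")])
  clip <- op %in% c("S", "H")
  clip_left <- if (length(op) && clip[1]) n[1] else 0L
  last <- length(op)
  clip_right <- if (last > 1 && clip[last]) n[last] else 0L
  list(ref = ref, read = readc, block = block,
       clip_left = clip_left, clip_right = clip_right)
}

empty_alignments <- function() {
  data.frame(read_id = character(0), read_len = integer(0),
             read_start = integer(0), read_end = integer(0),
             strand = character(0), target_id = character(0),
             target_len = integer(0), target_start = integer(0),
             target_end = integer(0), matches = integer(0),
             block_len = integer(0), mapq = integer(0),
             stringsAsFactors = FALSE)
}

validate_alignments <- function(aln, context = "alignments") {
  if (nrow(aln) == 0L) return(invisible(aln))
  bad <- aln$read_start < 0 | aln$target_start < 0 |
    aln$read_start >= aln$read_end | aln$target_start >= aln$target_end |
    aln$read_end > aln$read_len |
    (!is.na(aln$target_len) & aln$target_end > aln$target_len) |
    aln$matches > aln$block_len
  if (any(bad)) {
    stop("alignment parse error in '", context, "': negative, inverted or ",
         "out-of-bounds coordinates at record ", which(bad)[1], call. = FALSE)
  }
  invisible(aln)
}

#' Retain the single best alignment per read
#'
#' Implements the one-best-alignment contract: per `read_id` keep the record
#' with the most matching bases; ties are broken by the longest alignment
#' block, then by input order.
#'
#' @param aln Alignment data.frame (see [read_alignments()]).
#' @return Alignment data.frame with exactly one row per `read_id`, in
#'   first-seen read order.
#' @export
best_alignments <- function(aln) {
  if (nrow(aln) <= 1L) return(aln)
  ord <- order(aln$read_id, -aln$matches, -aln$block_len,
               seq_len(nrow(aln)))
  top <- aln[ord, , drop = FALSE]
  top <- top[!duplicated(top$read_id), , drop = FALSE]
  # restore first-seen order of reads
  top <- top[match(unique(aln$read_id), top$read_id), , drop = FALSE]
  rownames(top) <- NULL
  top
}

#' Alignment identity
#'
#' Fraction of matching bases over alignment block columns.
#'
#' @param aln Alignment data.frame.
#' @return Numeric vector in (0, 1].
#' @export
alignment_identity <- function(aln) {
  aln$matches / aln$block_len
}

#' Write alignments as PAF
#'
#' @param aln Alignment data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignments <- function(aln, path) {
  cols <- c("read_id", "read_len", "read_start", "read_end", "strand",
            "target_id", "target_len", "target_start", "target_end",
            "matches", "block_len", "mapq")
  m <- as.matrix(format(aln[, cols], scientific = FALSE, trim = TRUE))
  writeLines(apply(m, 1L, paste, collapse = "\t"), path)
  invisible(path)
}
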