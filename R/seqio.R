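#' Read sequences from FASTA or FASTQ
#'
#' Records are returned in file order with residues uppercased. FASTQ
#' qualities are kept as Phred strings; a per-read predicted accuracy is
#' derived from the mean base error probability when qualities are present.
#'
#' @param path Path to the sequence file.
#' @param format `"fasta"` or `"fastq"`. Guessed from the file extension
#'   when missing.
#' @return A data.frame with columns `id`, `seq`, and (FASTQ only) `qual`
#'   and `predicted_accuracy`.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "ACGT"), fa)
#' read_sequences(fa)
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_seq_format(path)
  if (!file.exists(path)) stop("sequence file not found: ", path)
  if (format == "fasta") {
    set <- tryCatch(
      Biostrings::readBStringSet(path, format = "fasta"),
      error = function(e) stop("FASTA parse error in '", path, "': ",
                               conditionMessage(e), call. = FALSE))
    df <- data.frame(id = names(set),
                     seq = toupper(as.character(set)),
                     stringsAsFactors = FALSE)
  } else {
    validate_fastq_lines(path)
    set <- tryCatch(
      Biostrings::readBStringSet(path, format = "fastq", with.qualities = TRUE),
      error = function(e) stop("FASTQ parse error in '", path, "': ",
                               conditionMessage(e), call. = FALSE))
    qual <- as.character(S4Vectors::mcols(set)$qualities)
    df <- data.frame(id = names(set),
                     seq = toupper(as.character(set)),
                     qual = qual,
                     stringsAsFactors = FALSE)
    err <- vapply(df$qual, function(q) {
      mean(10^(-(as.integer(charToRaw(q)) - 33L) / 10))
    }, numeric(1), USE.NAMES = FALSE)
    df$predicted_accuracy <- 1 - err
  }
  if (any(nchar(df$seq) < 1L)) {
    stop("parse error in '", path, "': zero-length record", call. = FALSE)
  }
  rownames(df) <- NULL
  df
}

#' Write sequences to FASTA or FASTQ
#'
#' Inverse of [read_sequences()]: writing then reading yields the same
#' records.
#'
#' @param records data.frame with columns `id`, `seq`, and `qual` for FASTQ.
#' @param path Output path.
#' @param format `"fasta"` or `"fastq"`.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(records, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  if (format == "fasta") {
    lines <- as.vector(rbind(paste0(">", records$id), records$seq))
  } else {
    if (!"qual" %in% names(records)) {
      stop("FASTQ output requires a 'qual' column")
    }
    lines <- as.vector(rbind(paste0("@", records$id), records$seq,
                             "+", records$qual))
  }
  writeLines(lines, path)
  invisible(path)
}

# structural pre-check of a 4-line-per-record FASTQ: record markers in
# place and per-record quality length equal to sequence length
validate_fastq_lines <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) return(invisible(TRUE))
  if (length(lines) %% 4L != 0L) {
    stop("FASTQ parse error in '", path, "': truncated record near line ",
         length(lines), call. = FALSE)
  }
  ids <- lines[seq(1L, length(lines), by = 4L)]
  seps <- lines[seq(3L, length(lines), by = 4L)]
  if (!all(startsWith(ids, "@")) || !all(startsWith(seps, "+"))) {
    stop("FASTQ parse error in '", path, "': malformed record markers",
         call. = FALSE)
  }
  seqs <- lines[seq(2L, length(lines), by = 4L)]
  quals <- lines[seq(4L, length(lines), by = 4L)]
  bad <- nchar(quals) != nchar(seqs)
  if (any(bad)) {
    stop("FASTQ parse error in '", path, "' line ", which(bad)[1] * 4L,
         ": quality length differs from sequence length", call. = FALSE)
  }
  invisible(TRUE)
}

guess_seq_format <- function(path) {
  if (grepl("\\.(fq|fastq)$", path, ignore.case = TRUE)) "fastq" else "fasta"
}

#' Load a genome from FASTA
#'
#' Convenience wrapper returning one uppercase sequence string per record,
#' named by record id.
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_genome <- function(path) {
  df <- read_sequences(path, "fasta")
  setNames(df$seq, df$id)
}

#' Reverse complement of DNA strings
#'
#' IUPAC ambiguity codes are complemented correctly (e.g. `revcomp("GGNCC")`
#' is `"GGNCC"`).
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Random DNA sequence
#'
#' Uniform i.i.d. draws over A, C, G, T; used by the community simulator.
#'
#' @param n Length in bases.
#' @return A single DNA string of length `n`.
#' @export
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
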