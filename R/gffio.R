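#' Read gene models from GFF3
#'
#' Only rows of the requested feature types are consumed. GFF3 1-based
#' inclusive coordinates are converted to the package's internal 0-based
#' half-open convention; strand is preserved.
#'
#' @param path GFF3 file.
#' @param types Feature types to keep (default CDS and gene).
#' @return data.frame with columns `gene_id`, `contig`, `start`, `end`
#'   (0-based half-open), `strand`, `product`.
#' @export
read_annotation <- function(path, types = c("CDS", "gene")) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop("GFF3 parse error in '", path,
                                          "': ", conditionMessage(e),
                                          call. = FALSE))
  gr <- gr[as.character(gr$type) %in% types]
  if (length(gr) == 0L) {
    return(data.frame(gene_id = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), product = character(0),
                      stringsAsFactors = FALSE))
  }
  meta <- S4Vectors::mcols(gr)
  id <- if ("ID" %in% names(meta)) as.character(meta$ID) else NA_character_
  if (all(is.na(id))) id <- paste0("gene_", seq_along(gr))
  product <- if ("product" %in% names(meta)) {
    as.character(meta$product)
  } else {
    rep(NA_character_, length(gr))
  }
  strand <- as.character(BiocGenerics::strand(gr))
  strand[!strand %in% c("+", "-")] <- "+"
  out <- data.frame(
    gene_id = id,
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = strand,
    product = product,
    stringsAsFactors = FALSE)
  if (any(out$end <= out$start)) {
    stop("GFF3 parse error in '", path, "': empty or inverted gene interval",
         call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Write gene models as GFF3
#'
#' Converts internal 0-based half-open coordinates back to GFF3 1-based
#' inclusive exactly (`start + 1`, `end`).
#'
#' @param genes Gene data.frame (see [read_annotation()]).
#' @param path Output path.
#' @param source Value for the GFF3 source column.
#' @param type Feature type to emit.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(genes, path, source = "strainsieve",
                             type = "CDS") {
  attrs <- paste0("ID=", genes$gene_id)
  has_prod <- !is.na(genes$product) & nzchar(genes$product)
  attrs[has_prod] <- paste0(attrs[has_prod], ";product=",
                            genes$product[has_prod])
  lines <- paste(genes$contig, source, type,
                 genes$start + 1L, genes$end, ".", genes$strand, "0",
                 attrs, sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}
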