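#' Coverage bin specification
#'
#' A named set of depth intervals. A read is routed to the bin when the
#' depth summary of its alignment footprint falls inside any interval.
#' Bounds may be open or closed on each side, so published cutoffs such as
#' strict `>110x` and inclusive `25-120x` are represented exactly.
#'
#' @param name Bin name.
#' @param intervals data.frame with columns `lo`, `hi` (may be `Inf`),
#'   `lo_incl`, `hi_incl`.
#' @return A `coverage_bin` object.
#' @export
coverage_bin <- function(name, intervals) {
  stopifnot(is.character(name), length(name) == 1L,
            is.data.frame(intervals),
            all(c("lo", "hi", "lo_incl", "hi_incl") %in% names(intervals)),
            nrow(intervals) >= 1L, all(intervals$lo < intervals$hi))
  structure(list(name = name, intervals = intervals),
            class = "coverage_bin")
}

format_bin_spec <- function(spec) {
  iv <- spec$intervals
  paste(paste0(ifelse(iv$lo_incl, "[", "("), iv$lo, ", ", iv$hi,
               ifelse(iv$hi_incl, "]", ")")), collapse = " U ")
}

#' @export
print.coverage_bin <- function(x, ...) {
  cat("coverage bin '", x$name, "': ", format_bin_spec(x), "\n", sep = "")
  invisible(x)
}

#' Default strain-separation bin specifications
#'
#' The two-bin scheme used to deconvolve a dominant and a minor strain:
#' the high-coverage bin collects reads on regions deeper than 110x
#' (strict), the low-coverage bin reads on regions of 25-120x (inclusive)
#' or deeper than 225x (strict). Regions above 225x are shared conserved
#' backbone and deliberately enter both bins so that both strains can be
#' assembled across them.
#'
#' @return List of two `coverage_bin` objects named `high` and `low`.
#' @export
default_bin_specs <- function() {
  list(
    coverage_bin("high", data.frame(lo = 110, hi = Inf,
                                    lo_incl = FALSE, hi_incl = FALSE)),
    coverage_bin("low", data.frame(lo = c(25, 225), hi = c(120, Inf),
                                   lo_incl = c(TRUE, FALSE),
                                   hi_incl = c(TRUE, FALSE))))
}

#' Rescale bin specifications to a different community depth
#'
#' The default cutoffs assume a community whose shared-backbone depth is
#' about 300x. `scale_bin_specs()` multiplies every interval bound by
#' `factor` so the same bin geometry applies to communities sequenced at a
#' different overall depth (`factor = observed_median / calibration`).
#'
#' @param specs List of `coverage_bin` objects.
#' @param factor Positive scale factor.
#' @return Rescaled list of `coverage_bin` objects.
#' @export
scale_bin_specs <- function(specs, factor) {
  stopifnot(is.numeric(factor), factor > 0)
  lapply(specs, function(spec) {
    iv <- spec$intervals
    iv$lo <- iv$lo * factor
    iv$hi <- iv$hi * factor
    coverage_bin(spec$name, iv)
  })
}

#' Per-base depth profile from alignments
#'
#' `d(i)` counts the alignments whose target interval contains position
#' `i` (0-based). The sum of the profile equals the total aligned
#' footprint, `sum(target_end - target_start)`.
#'
#' @param aln Alignment data.frame (one target).
#' @param target_id Target to profile; defaults to the single target
#'   present in `aln`.
#' @param target_len Target length; defaults to the `target_len` recorded
#'   in the alignments.
#' @return Integer depth vector of length `target_len` with attribute
#'   `target_id`.
#' @export
compute_depth <- function(aln, target_id = NULL, target_len = NULL) {
  if (is.null(target_id)) {
    ids <- unique(aln$target_id)
    if (length(ids) > 1L) {
      stop("alignments span several targets; pass target_id explicitly")
    }
    target_id <- if (length(ids)) ids else NA_character_
  }
  sub <- aln[aln$target_id %in% target_id, , drop = FALSE]
  if (is.null(target_len)) {
    if (nrow(sub) == 0L) stop("target_len required when no alignments match")
    target_len <- sub$target_len[1]
  }
  if (nrow(sub) && any(sub$target_end > target_len)) {
    stop("alignment exceeds target bounds on '", target_id, "'")
  }
  depth <- if (nrow(sub) == 0L) {
    integer(target_len)
  } else {
    cov <- IRanges::coverage(
      IRanges::IRanges(start = sub$target_start + 1L, end = sub$target_end),
      width = target_len)
    as.integer(cov)
  }
  structure(depth, target_id = target_id)
}

#' Depth profiles for every target in an alignment set
#'
#' @param aln Alignment data.frame.
#' @param target_lens Optional named vector of target lengths.
#' @return Named list of depth vectors, one per target.
#' @export
compute_depth_all <- function(aln, target_lens = NULL) {
  ids <- unique(aln$target_id)
  if (!is.null(target_lens)) ids <- union(ids, names(target_lens))
  setNames(lapply(ids, function(id) {
    len <- if (!is.null(target_lens) && id %in% names(target_lens)) {
      target_lens[[id]]
    } else NULL
    compute_depth(aln, target_id = id, target_len = len)
  }), ids)
}

#' Depth summary over alignment footprints
#'
#' Summarizes the depth profile over each alignment's target interval.
#' The median (default) is robust to footprint edges that dip into
#' flanking regions.
#'
#' @param aln Alignment data.frame.
#' @param profiles Named list of depth vectors (see [compute_depth_all()]),
#'   or a single depth vector when all alignments share one target.
#' @param statistic `"median"` or `"mean"`.
#' @return Numeric vector of footprint depth summaries, one per alignment.
#' @export
footprint_stat <- function(aln, profiles, statistic = c("median", "mean")) {
  statistic <- match.arg(statistic)
  fun <- if (statistic == "median") stats::median else mean
  if (!is.list(profiles)) {
    profiles <- setNames(list(profiles), attr(profiles, "target_id"))
  }
  vapply(seq_len(nrow(aln)), function(i) {
    d <- profiles[[aln$target_id[i]]]
    if (is.null(d)) stop("no depth profile for target '", aln$target_id[i], "'")
    fun(d[(aln$target_start[i] + 1L):aln$target_end[i]])
  }, numeric(1))
}

stat_in_spec <- function(stat, spec) {
  iv <- spec$intervals
  hit <- rep(FALSE, length(stat))
  for (k in seq_len(nrow(iv))) {
    lo_ok <- if (iv$lo_incl[k]) stat >= iv$lo[k] else stat > iv$lo[k]
    hi_ok <- if (iv$hi_incl[k]) stat <= iv$hi[k] else stat < iv$hi[k]
    hit <- hit | (lo_ok & hi_ok)
  }
  hit
}

#' Assign reads to coverage bins
#'
#' Each read enters every bin whose depth intervals contain its footprint
#' summary; a read may land in zero, one, or several bins. With
#' `relative = TRUE` the bin cutoffs are rescaled by
#' `median(depth)/calibration_depth` so the default bin geometry carries
#' over to communities sequenced at other depths.
#'
#' @param aln Alignment data.frame (best alignment per read).
#' @param profiles Depth profile(s), as for [footprint_stat()].
#' @param specs List of `coverage_bin` objects.
#' @param statistic Footprint summary statistic.
#' @param relative Interpret cutoffs relative to the observed depth.
#' @param calibration_depth Community depth the cutoffs were calibrated
#'   for (default 300x shared-backbone depth).
#' @return data.frame with columns `read_id`, `footprint_stat`, and one
#'   logical column per bin, plus a `bins` list-column of bin names.
#' @export
assign_bins <- function(aln, profiles, specs = default_bin_specs(),
                        statistic = c("median", "mean"),
                        relative = FALSE, calibration_depth = 300) {
  statistic <- match.arg(statistic)
  stat <- footprint_stat(aln, profiles, statistic)
  if (relative) {
    if (!is.list(profiles)) {
      profiles <- setNames(list(profiles), attr(profiles, "target_id"))
    }
    observed <- stats::median(unlist(lapply(profiles, as.numeric)))
    specs <- scale_bin_specs(specs, observed / calibration_depth)
  }
  out <- data.frame(read_id = aln$read_id, footprint_stat = stat,
                    stringsAsFactors = FALSE)
  names_ <- vapply(specs, `[[`, character(1), "name")
  member <- matrix(FALSE, nrow(out), length(specs),
                   dimnames = list(NULL, names_))
  for (j in seq_along(specs)) member[, j] <- stat_in_spec(stat, specs[[j]])
  for (nm in names_) out[[nm]] <- member[, nm]
  out$bins <- lapply(seq_len(nrow(out)), function(i) names_[member[i, ]])
  out
}

#' Precision and recall of strain binning against simulator truth
#'
#' Scores coverage-bin assignments for reads known (from simulator truth)
#' to originate wholly inside strain-unique regions. Recall is the
#' fraction of a strain's unique-region reads present in that strain's
#' bin. Because the binning scheme deliberately routes reads on deeply
#' covered shared regions into both bins, dual membership is the
#' conservative shared-sequence fallback, not a routing error; precision
#' is therefore computed over exclusively routed reads: among
#' unique-region reads assigned to exactly one bin, the fraction whose
#' truth strain matches that bin.
#'
#' @param assignments Output of [assign_bins()].
#' @param truth List mapping bin name to the character vector of read ids
#'   truly unique to that bin's strain, e.g.
#'   `list(high = dominant_ids, low = minor_ids)`.
#' @return data.frame with one row per bin: `bin`, `n_truth`,
#'   `precision`, `recall`.
#' @export
binning_performance <- function(assignments, truth) {
  bins <- names(truth)
  all_truth <- unlist(truth, use.names = FALSE)
  a <- assignments[assignments$read_id %in% all_truth, , drop = FALSE]
  n_bins <- rowSums(as.matrix(a[, bins, drop = FALSE]))
  rows <- lapply(bins, function(bn) {
    in_bin <- a$read_id[a[[bn]]]
    exclusive <- a$read_id[a[[bn]] & n_bins == 1L]
    data.frame(bin = bn, n_truth = length(truth[[bn]]),
               precision = if (length(exclusive)) {
                 mean(exclusive %in% truth[[bn]])
               } else NA_real_,
               recall = mean(truth[[bn]] %in% in_bin),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Refine a bin by excluding reads on shallow regions
#'
#' Reads whose footprint depth summary falls below `min_depth` are moved
#' to the excluded set; the kept and excluded sets partition the input.
#'
#' @param assignments Output of [assign_bins()] (or any data.frame with
#'   `read_id` and `footprint_stat`).
#' @param min_depth Depth cutoff (default 100).
#' @return List with `kept` and `excluded` read-id vectors.
#' @export
refine_bin <- function(assignments, min_depth = 100) {
  drop <- assignments$footprint_stat < min_depth
  list(kept = assignments$read_id[!drop],
       excluded = assignments$read_id[drop])
}

#' Select contigs by mean depth
#'
#' @param contig_mean_depths Named numeric vector (or data.frame with
#'   columns `contig` and `mean_depth`) of per-contig mean depths.
#' @param threshold Keep contigs with depth strictly greater (default 190).
#' @return Character vector of contig ids.
#' @export
select_contigs_by_depth <- function(contig_mean_depths, threshold = 190) {
  if (is.data.frame(contig_mean_depths)) {
    contig_mean_depths <- setNames(contig_mean_depths$mean_depth,
                                   contig_mean_depths$contig)
  }
  names(contig_mean_depths)[contig_mean_depths > threshold]
}

#' Low-coverage regions of a depth profile
#'
#' Maximal runs of positions with depth strictly below `threshold`,
#' filtered by length.
#'
#' @param depth Depth vector (see [compute_depth()]).
#' @param threshold Depth cutoff (default 25).
#' @param min_len,max_len Region size filter (defaults 50 and `Inf`).
#' @return data.frame with 0-based half-open `start`, `end` and `length`.
#' @export
low_coverage_regions <- function(depth, threshold = 25, min_len = 50,
                                 max_len = Inf) {
  r <- rle(as.numeric(depth) < threshold)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values & r$lengths >= min_len & r$lengths <= max_len
  data.frame(start = starts[keep], end = ends[keep],
             length = r$lengths[keep])
}

#' Count reads spanning the circularization junction
#'
#' Alignments are expected on the doubled representation of a circular
#' genome (the genome concatenated with its own leading bases), so the
#' junction is an internal position. A read counts when its single best
#' alignment covers the closed interval `[junction - flank,
#' junction + flank]` contiguously.
#'
#' @param aln Alignment data.frame on the doubled representation.
#' @param junction Junction position (0-based).
#' @param flank Required flank on both sides, in bases.
#' @return Number of spanning reads.
#' @export
spanning_reads <- function(aln, junction, flank) {
  sum(aln$target_start <= junction - flank &
        aln$target_end >= junction + flank)
}
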