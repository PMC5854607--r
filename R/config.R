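#' Pipeline configuration
#'
#' Collects every tunable threshold of the pipeline in one validated
#' object. Defaults are the published operating points of the workflow the
#' package implements: coverage bins `>110x` (high) and `25-120x` plus
#' `>225x` (low), bin refinement at `100x`, deep-contig selection at
#' `>190x`, modification QV threshold `100`, BBH identity `90%`, query
#' coverage exclusion at `<=75%` / `>=120%`, ANI fragments of `1020` bp,
#' GC windows of `1000` bp with a `5` percentage-point deviation cutoff,
#' low-coverage regions below `25x`, and gene presence calling with a
#' `25%` uncovered-fraction tolerance.
#'
#' @param rng_seed Integer seed; all pipeline randomness flows from it.
#' @param bin_specs Coverage bin definitions, see [default_bin_specs()].
#' @param bin_statistic Depth summary over a read's alignment footprint.
#' @param refine_min_depth Bin refinement cutoff (reads below are dropped).
#' @param contig_depth_threshold Deep-contig selection cutoff.
#' @param qv_threshold Modification QV call threshold.
#' @param qv_cap Upper cap on modification QV.
#' @param bbh_min_identity Minimum percent identity for BBH detection.
#' @param qcov_exclude_low,qcov_exclude_high Query-coverage exclusion
#'   bounds (hits with coverage `<= low` or `>= high` are removed).
#' @param ani_fragment ANI fragment length in bases.
#' @param gc_window GC scan window in bases.
#' @param gc_deviation GC deviation cutoff in percentage points.
#' @param lowcov_threshold Low-coverage region depth cutoff.
#' @param lowcov_min_len,lowcov_max_len Size filter for low-coverage regions.
#' @param partial_uncovered_fraction Gene presence partial-call cutoff.
#' @param circ_min_overlap Minimum terminal overlap for circularization.
#' @param circ_max_mismatch_frac Mismatch tolerance in the terminal overlap.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(rng_seed = 1L,
                            bin_specs = default_bin_specs(),
                            bin_statistic = c("median", "mean"),
                            refine_min_depth = 100,
                            contig_depth_threshold = 190,
                            qv_threshold = 100,
                            qv_cap = 1000,
                            bbh_min_identity = 90,
                            qcov_exclude_low = 0.75,
                            qcov_exclude_high = 1.20,
                            ani_fragment = 1020,
                            gc_window = 1000,
                            gc_deviation = 5,
                            lowcov_threshold = 25,
                            lowcov_min_len = 50,
                            lowcov_max_len = Inf,
                            partial_uncovered_fraction = 0.25,
                            circ_min_overlap = 50,
                            circ_max_mismatch_frac = 0) {
  cfg <- list(rng_seed = as.integer(rng_seed),
              bin_specs = bin_specs,
              bin_statistic = match.arg(bin_statistic),
              refine_min_depth = refine_min_depth,
              contig_depth_threshold = contig_depth_threshold,
              qv_threshold = qv_threshold,
              qv_cap = qv_cap,
              bbh_min_identity = bbh_min_identity,
              qcov_exclude_low = qcov_exclude_low,
              qcov_exclude_high = qcov_exclude_high,
              ani_fragment = ani_fragment,
              gc_window = gc_window,
              gc_deviation = gc_deviation,
              lowcov_threshold = lowcov_threshold,
              lowcov_min_len = lowcov_min_len,
              lowcov_max_len = lowcov_max_len,
              partial_uncovered_fraction = partial_uncovered_fraction,
              circ_min_overlap = circ_min_overlap,
              circ_max_mismatch_frac = circ_max_mismatch_frac)
  validate_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

validate_config <- function(cfg) {
  num <- c("refine_min_depth", "contig_depth_threshold", "qv_threshold",
           "qv_cap", "bbh_min_identity", "qcov_exclude_low",
           "qcov_exclude_high", "ani_fragment", "gc_window", "gc_deviation",
           "lowcov_threshold", "lowcov_min_len",
           "partial_uncovered_fraction", "circ_min_overlap")
  for (f in num) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] <= 0) {
      stop("config field '", f, "' must be a single positive number")
    }
  }
  if (cfg$qcov_exclude_low >= cfg$qcov_exclude_high) {
    stop("qcov_exclude_low must be below qcov_exclude_high")
  }
  if (cfg$circ_max_mismatch_frac < 0 || cfg$circ_max_mismatch_frac >= 1) {
    stop("circ_max_mismatch_frac must be in [0, 1)")
  }
  invisible(cfg)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("strainsieve pipeline configuration\n")
  cat("  rng_seed:", x$rng_seed, "\n")
  for (spec in x$bin_specs) {
    cat("  bin '", spec$name, "': ", format_bin_spec(spec), "\n", sep = "")
  }
  scalars <- setdiff(names(x), c("rng_seed", "bin_specs"))
  for (f in scalars) cat("  ", f, ": ", format(x[[f]]), "\n", sep = "")
  invisible(x)
}

#' Read a flat key=value configuration file
#'
#' Keys mirror the [pipeline_config()] argument names. Bin specifications
#' use `bin.<name> = lo,hi,lo_incl,hi_incl;...` with one `lo,hi` clause per
#' depth interval and `inf` allowed for open upper bounds.
#'
#' @param path Configuration file.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, integer(1)) != 2L
  if (any(bad)) stop("config parse error at line: ", lines[which(bad)[1]])
  keys <- trimws(vapply(kv, `[[`, character(1), 1))
  vals <- trimws(vapply(kv, `[[`, character(1), 2))
  is_bin <- startsWith(keys, "bin.")
  args <- list()
  for (i in which(!is_bin)) {
    v <- vals[i]
    args[[keys[i]]] <- if (keys[i] == "bin_statistic") v else as.numeric(v)
  }
  if (any(is_bin)) {
    specs <- lapply(which(is_bin), function(i) {
      clauses <- strsplit(vals[i], ";", fixed = TRUE)[[1]]
      iv <- do.call(rbind, lapply(clauses, function(cl) {
        p <- trimws(strsplit(cl, ",", fixed = TRUE)[[1]])
        if (length(p) != 4L) stop("bin interval needs lo,hi,lo_incl,hi_incl")
        data.frame(lo = as.numeric(sub("^inf$", "Inf", p[1], ignore.case = TRUE)),
                   hi = as.numeric(sub("^inf$", "Inf", p[2], ignore.case = TRUE)),
                   lo_incl = as.logical(p[3]), hi_incl = as.logical(p[4]))
      }))
      coverage_bin(sub("^bin\\.", "", keys[i]), iv)
    })
    args$bin_specs <- specs
  }
  do.call(pipeline_config, args)
}

#' Write a configuration file
#'
#' Inverse of [read_config()].
#'
#' @param cfg A `pipeline_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  scalars <- setdiff(names(cfg), "bin_specs")
  lines <- vapply(scalars, function(f) {
    paste0(f, " = ", format(cfg[[f]], scientific = FALSE))
  }, character(1))
  for (spec in cfg$bin_specs) {
    iv <- spec$intervals
    clauses <- paste(iv$lo, iv$hi, iv$lo_incl, iv$hi_incl, sep = ",")
    lines <- c(lines, paste0("bin.", spec$name, " = ",
                             paste(clauses, collapse = ";")))
  }
  writeLines(lines, path)
  invisible(path)
}
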