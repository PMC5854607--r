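#' Write a BED file of intervals
#'
#' @param intervals data.frame with `start`, `end` (0-based half-open) and
#'   optionally `name`.
#' @param path Output path.
#' @param chrom Chromosome/contig name (recycled).
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path, chrom = "genome") {
  name <- if ("name" %in% names(intervals)) intervals$name else "."
  lines <- paste(rep_len(chrom, nrow(intervals)),
                 intervals$start, intervals$end, name, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Write a depth profile as bedGraph-style text
#'
#' Consecutive equal-depth positions are collapsed into one row
#' (`target`, `start`, `end`, `depth`; 0-based half-open).
#'
#' @param depth Depth vector (see [compute_depth()]).
#' @param path Output path.
#' @param target Target name; defaults to the profile's `target_id`.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(depth, path, target = NULL) {
  if (is.null(target)) target <- attr(depth, "target_id")
  if (is.null(target)) target <- "genome"
  r <- rle(as.numeric(depth))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  writeLines(paste(target, starts, ends, r$values, sep = "\t"), path)
  invisible(path)
}

#' Run the pipeline stages on a set of inputs
#'
#' Orchestrates the stages on whatever inputs are supplied: coverage
#' binning (reads/alignments + genome), circularization (genome),
#' methylome (kinetics + genome), and comparative genomics (two genomes
#' and/or hit tables). Results are returned as a report bundle and,
#' when `outdir` is given, written as tabular outputs together with a
#' run log recording the configuration and seed. Given the same config
#' and inputs the run is deterministic.
#'
#' @param config A [pipeline_config()].
#' @param alignments Alignment data.frame (or PAF path) for binning.
#' @param genome Genome string (or FASTA path with one record).
#' @param kinetics Kinetics data.frame (or path) for the methylome stage.
#' @param genes Gene data.frame (or GFF3 path).
#' @param genome_b Second genome for comparative statistics.
#' @param hits_ab,hits_ba Hit data.frames (or paths) for BBH analysis.
#' @param stages Stages to run (subset of `"bin"`, `"circularize"`,
#'   `"methylome"`, `"compare"`); defaults to every stage whose inputs
#'   are present.
#' @param outdir Optional output directory.
#' @return A `pipeline_report` list with one element per executed stage.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         alignments = NULL, genome = NULL, kinetics = NULL,
                         genes = NULL, genome_b = NULL,
                         hits_ab = NULL, hits_ba = NULL,
                         stages = NULL, outdir = NULL) {
  set.seed(config$rng_seed)
  as_genome <- function(x) {
    # a path points at a FASTA on disk; anything else is the sequence
    if (is.character(x) && length(x) == 1L && file.exists(x)) {
      unname(read_genome(x)[1])
    } else x
  }
  if (is.character(alignments)) alignments <- read_alignments(alignments)
  genome <- as_genome(genome)
  if (is.character(kinetics)) kinetics <- read_kinetics(kinetics)
  if (is.character(genes)) genes <- read_annotation(genes)
  genome_b <- as_genome(genome_b)
  if (is.character(hits_ab)) hits_ab <- read_hits(hits_ab)
  if (is.character(hits_ba)) hits_ba <- read_hits(hits_ba)

  available <- c(
    bin = !is.null(alignments),
    circularize = !is.null(genome),
    methylome = !is.null(kinetics) && !is.null(genome),
    compare = !is.null(genome) &&
      (!is.null(genome_b) || (!is.null(hits_ab) && !is.null(hits_ba))))
  if (is.null(stages)) {
    stages <- names(available)[available]
  } else {
    stages <- match.arg(stages, names(available), several.ok = TRUE)
    missing_in <- stages[!available[stages]]
    if (length(missing_in)) {
      stop("configuration error: inputs missing for requested stage(s): ",
           paste(missing_in, collapse = ", "))
    }
  }
  if (!length(stages)) stop("configuration error: no stage has inputs")
  report <- list(config = config, stages = stages)

  if ("bin" %in% stages) {
    profiles <- compute_depth_all(alignments)
    assignments <- assign_bins(alignments, profiles,
                               specs = config$bin_specs,
                               statistic = config$bin_statistic)
    refined <- refine_bin(assignments, config$refine_min_depth)
    lowcov <- do.call(rbind, lapply(names(profiles), function(id) {
      lc <- low_coverage_regions(profiles[[id]], config$lowcov_threshold,
                                 config$lowcov_min_len, config$lowcov_max_len)
      if (nrow(lc)) cbind(target_id = id, lc) else NULL
    }))
    report$bin <- list(profiles = profiles, assignments = assignments,
                       refined = refined, low_coverage = lowcov)
  }
  if ("circularize" %in% stages) {
    report$circularize <- circularize(genome, config$circ_min_overlap,
                                      config$circ_max_mismatch_frac)
  }
  if ("methylome" %in% stages) {
    scored <- score_sites(kinetics, config$qv_cap, config$qv_threshold)
    called <- call_sites(scored, config$qv_threshold)
    motifs <- discover_motifs(genome, called)
    report$methylome <- list(
      called = called, motifs = motifs,
      summary = motif_summary(genome, motifs, called, genes))
  }
  if ("compare" %in% stages) {
    cmp <- list(stats_a = genome_stats(genome, config$gc_window),
                deviant = gc_deviant_windows(genome, config$gc_window,
                                             config$gc_deviation))
    if (!is.null(genome_b)) {
      cmp$ani <- orthoani(genome, genome_b, config$ani_fragment)
    }
    if (!is.null(hits_ab) && !is.null(hits_ba)) {
      filtered <- filter_hits(hits_ab, config$bbh_min_identity,
                              config$qcov_exclude_low,
                              config$qcov_exclude_high)
      cmp$bbh <- best_bidirectional_hits(hits_ab, hits_ba,
                                         config$bbh_min_identity)
      cmp$unique_a <- unique_genes(unique(hits_ab$query_id), filtered)
    }
    report$compare <- cmp
  }
  class(report) <- "pipeline_report"
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("strainsieve pipeline report; stages:",
      paste(x$stages, collapse = ", "), "\n")
  if (!is.null(x$bin)) {
    cat("  bin: ", nrow(x$bin$assignments), " reads, ",
        length(x$bin$refined$excluded), " excluded by refinement\n", sep = "")
  }
  if (!is.null(x$circularize)) {
    cat("  circularize: ", if (x$circularize$circular) "overlap " else
      "not circularizable", if (x$circularize$circular)
        x$circularize$overlap, "\n", sep = " ")
  }
  if (!is.null(x$methylome)) {
    cat("  methylome: ", nrow(x$methylome$called), " retained calls, ",
        length(x$methylome$motifs), " motifs\n", sep = "")
  }
  if (!is.null(x$compare) && !is.null(x$compare$ani)) {
    cat("  compare: ANI ", format(x$compare$ani$ani), "\n", sep = "")
  }
  invisible(x)
}

write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg <- report$config
  log_lines <- c(
    paste0("strainsieve ", as.character(packageVersion("strainsieve"))),
    paste0("R: ", R.version.string),
    paste0("stages: ", paste(report$stages, collapse = ",")),
    paste0("rng_seed: ", cfg$rng_seed))
  writeLines(log_lines, file.path(outdir, "run_log.txt"))
  write_config(cfg, file.path(outdir, "config.txt"))
  if (!is.null(report$bin)) {
    asg <- report$bin$assignments
    bin_names <- vapply(cfg$bin_specs, `[[`, character(1), "name")
    for (bn in bin_names) {
      writeLines(asg$read_id[asg[[bn]]],
                 file.path(outdir, paste0("bin_", bn, "_reads.txt")))
    }
    for (id in names(report$bin$profiles)) {
      write_bedgraph(report$bin$profiles[[id]],
                     file.path(outdir, paste0("depth_", id, ".bedgraph")), id)
    }
    lc <- report$bin$low_coverage
    if (!is.null(lc) && nrow(lc)) {
      write_bed(lc[, c("start", "end")],
                file.path(outdir, "low_coverage.bed"), lc$target_id)
    }
    writeLines(report$bin$refined$excluded,
               file.path(outdir, "bin_refinement_excluded.txt"))
  }
  if (!is.null(report$methylome)) {
    write_modifications(report$methylome$called,
                        file.path(outdir, "modifications.gff"))
    write.csv(report$methylome$summary,
              file.path(outdir, "motif_summary.csv"), row.names = FALSE)
  }
  if (!is.null(report$compare)) {
    dv <- report$compare$deviant$intervals
    write_bed(dv, file.path(outdir, "gc_deviant_windows.bed"))
    if (!is.null(report$compare$ani)) {
      writeLines(paste0("ANI\t", format(report$compare$ani$ani),
                        "\tfragments\t", report$compare$ani$n_fragment_pairs),
                 file.path(outdir, "ani.txt"))
    }
    if (!is.null(report$compare$bbh)) {
      write.csv(report$compare$bbh, file.path(outdir, "bbh_pairs.csv"),
                row.names = FALSE)
      writeLines(report$compare$unique_a,
                 file.path(outdir, "unique_genes_a.txt"))
    }
  }
  invisible(outdir)
}
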