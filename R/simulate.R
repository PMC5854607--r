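#' Configuration for the two-strain community simulator
#'
#' The generator emulates the statistical structure that coverage-based
#' strain deconvolution assumes: two near-identical strain genomes sharing
#' a conserved backbone, each carrying strain-unique insertions and
#' rearrangements, sequenced together at unequal abundance with long reads
#' whose length distribution is log-normal (median 2,558 bp, clipped to
#' 500 bp - 27 kb, the admission window of the uncorrected read set the
#' pipeline was built for).
#'
#' `total_depth` is the combined sequencing depth over the shared
#' backbone; with `abundance_ratio` r the dominant strain contributes
#' `total_depth * r / (r + 1)` and the minor strain `total_depth / (r + 1)`.
#' The defaults (300x combined at ratio 2) put strain-unique regions of
#' the dominant strain at ~200x, minor-unique regions at ~100x and the
#' shared backbone at ~300x, which is the geometry the default coverage
#' bins separate.
#'
#' @param backbone_len Shared backbone length in bases.
#' @param n_unique_regions_per_strain Strain-unique insertions per strain.
#' @param unique_region_len Mean unique-region length in bases.
#' @param n_inversions,n_relocations Rearrangements per strain.
#' @param sv_len Mean rearranged-segment length in bases.
#' @param substitution_rate_backbone Per-base substitution rate applied to
#'   each strain's backbone copy (0.006 yields two strains at ~98.8%
#'   identity to each other, i.e. ANI in the intra-species range).
#' @param abundance_ratio Dominant:minor strain depth ratio (> 1).
#' @param total_depth Combined depth over the shared backbone.
#' @param read_len_median,read_len_min,read_len_max Read-length model.
#' @param read_len_sdlog Log-normal shape parameter.
#' @param read_error_rate Total per-base error rate, split equally between
#'   substitutions, insertions and deletions.
#' @param seed Integer seed for the generators.
#' @return A `strain_sim_config` list.
#' @export
strain_sim_config <- function(backbone_len = 300000,
                              n_unique_regions_per_strain = 3,
                              unique_region_len = 15000,
                              n_inversions = 2,
                              n_relocations = 2,
                              sv_len = 5000,
                              substitution_rate_backbone = 0.006,
                              abundance_ratio = 2,
                              total_depth = 300,
                              read_len_median = 2558,
                              read_len_min = 500,
                              read_len_max = 27000,
                              read_len_sdlog = 0.55,
                              read_error_rate = 0.10,
                              seed = 1L) {
  cfg <- as.list(environment())
  if (backbone_len <= 10 * unique_region_len) {
    stop("backbone_len must exceed 10 * unique_region_len")
  }
  if (abundance_ratio <= 1) stop("abundance_ratio must be > 1")
  if (!(read_len_min <= read_len_median && read_len_median <= read_len_max)) {
    stop("read lengths must satisfy min <= median <= max")
  }
  if (read_error_rate < 0 || read_error_rate >= 1) {
    stop("read_error_rate must be in [0, 1)")
  }
  class(cfg) <- "strain_sim_config"
  cfg
}

#' Per-strain sequencing depths implied by a simulator configuration
#'
#' @param config A `strain_sim_config`.
#' @return Named numeric vector with elements `dominant` and `minor`.
#' @export
strain_depths <- function(config) {
  r <- config$abundance_ratio
  c(dominant = config$total_depth * r / (r + 1),
    minor = config$total_depth / (r + 1))
}

# place n non-overlapping intervals of the given lengths on [0, L),
# avoiding the intervals in `occupied` (data.frame start/end); errors
# after `attempts` rejections
place_intervals <- function(n, lens, L, occupied = NULL, attempts = 1000L) {
  out <- occupied
  placed <- data.frame(start = integer(0), end = integer(0))
  for (i in seq_len(n)) {
    len <- lens[i]
    ok <- FALSE
    for (a in seq_len(attempts)) {
      s <- sample.int(L - len, 1L) - 1L
      e <- s + len
      clash <- !is.null(out) && nrow(out) > 0 &&
        any(s < out$end & out$start < e)
      if (!clash) { ok <- TRUE; break }
    }
    if (!ok) stop("could not place a non-overlapping interval after ",
                  attempts, " attempts")
    placed <- rbind(placed, data.frame(start = s, end = e))
    out <- rbind(out, data.frame(start = s, end = e))
  }
  placed
}

mutate_backbone <- function(backbone, rate) {
  if (rate <= 0) return(backbone)
  L <- nchar(backbone)
  n <- rbinom(1L, L, rate)
  if (n == 0L) return(backbone)
  pos <- sample.int(L, n)
  chars <- strsplit(backbone, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  chars[pos] <- vapply(chars[pos], function(b) {
    sample(setdiff(bases, b), 1L)
  }, character(1), USE.NAMES = FALSE)
  paste(chars, collapse = "")
}

# one strain genome: mutated backbone copy + inversions + relocations +
# unique-region insertions, planned on backbone coordinates so that a
# piecewise map from the final genome back to the backbone is exact
build_strain <- function(backbone, strain, config) {
  L <- config$backbone_len
  bb <- mutate_backbone(backbone, config$substitution_rate_backbone)
  n_inv <- config$n_inversions
  n_rel <- config$n_relocations
  n_uni <- config$n_unique_regions_per_strain
  sv_lens <- as.integer(pmax(200, round(rlnorm(n_inv + n_rel,
                                               log(config$sv_len), 0.3))))
  segs <- place_intervals(n_inv + n_rel, sv_lens, L)
  inv <- segs[seq_len(n_inv), , drop = FALSE]
  rel <- segs[n_inv + seq_len(n_rel), , drop = FALSE]
  # destination points for relocations and insertion points for unique
  # regions: outside every rearranged segment
  pick_points <- function(n) {
    pts <- integer(0)
    for (i in seq_len(n)) {
      for (a in seq_len(1000L)) {
        p <- sample.int(L - 1L, 1L)
        inside <- any(p > segs$start & p < segs$end)
        if (!inside && !(p %in% pts)) { pts <- c(pts, p); break }
        if (a == 1000L) stop("could not place point after 1000 attempts")
      }
    }
    pts
  }
  rel_dest <- pick_points(n_rel)
  uni_pts <- pick_points(n_uni)
  uni_lens <- as.integer(pmax(500, round(rlnorm(n_uni,
                                                log(config$unique_region_len),
                                                0.2))))
  uni_seqs <- vapply(uni_lens, random_dna, character(1))

  # walk the backbone left to right, splicing in events at their positions
  cuts <- sort(unique(c(0L, L, inv$start, inv$end, rel$start, rel$end,
                        rel_dest, uni_pts)))
  pieces <- list()
  add <- function(type, src_start, src_end, strand, seq, uniq_id) {
    pieces[[length(pieces) + 1L]] <<- list(type = type,
                                           src_start = as.integer(src_start),
                                           src_end = as.integer(src_end),
                                           strand = strand, seq = seq,
                                           uniq_id = as.integer(uniq_id))
  }
  emit_insertions_at <- function(p) {
    for (j in which(rel_dest == p)) {
      add("bb", rel$start[j], rel$end[j], "+",
          substr(bb, rel$start[j] + 1L, rel$end[j]), NA_integer_)
    }
    for (j in which(uni_pts == p)) {
      add("uni", 0L, uni_lens[j], "+", uni_seqs[j], j)
    }
  }
  for (i in seq_len(length(cuts) - 1L)) {
    a <- cuts[i]; b <- cuts[i + 1L]
    emit_insertions_at(a)
    is_rel_src <- any(a >= rel$start & b <= rel$end)
    if (is_rel_src) next
    inv_idx <- which(a >= inv$start & b <= inv$end)
    if (length(inv_idx)) {
      add("bb", a, b, "-", revcomp(substr(bb, a + 1L, b)), NA_integer_)
    } else {
      add("bb", a, b, "+", substr(bb, a + 1L, b), NA_integer_)
    }
  }
  emit_insertions_at(L)

  lens <- vapply(pieces, function(p) nchar(p$seq), integer(1))
  ends <- cumsum(lens)
  starts <- ends - lens
  piece_df <- data.frame(
    type = vapply(pieces, `[[`, character(1), "type"),
    src_start = vapply(pieces, `[[`, integer(1), "src_start"),
    src_end = vapply(pieces, `[[`, integer(1), "src_end"),
    strand = vapply(pieces, `[[`, character(1), "strand"),
    uniq_id = vapply(pieces, `[[`, integer(1), "uniq_id"),
    start = starts, end = ends,
    stringsAsFactors = FALSE)
  genome <- paste(vapply(pieces, `[[`, character(1), "seq"), collapse = "")
  uni_rows <- piece_df[piece_df$type == "uni", , drop = FALSE]
  unique_intervals <- data.frame(
    uniq_id = uni_rows$uniq_id,
    contig = if (nrow(uni_rows)) {
      paste0("uniq_", strain, "_", uni_rows$uniq_id)
    } else character(0),
    start = uni_rows$start, end = uni_rows$end,
    stringsAsFactors = FALSE)
  sv_list <- rbind(
    if (nrow(inv)) data.frame(type = "inversion", start = inv$start,
                              end = inv$end, dest = NA_integer_),
    if (nrow(rel)) data.frame(type = "relocation", start = rel$start,
                              end = rel$end, dest = rel_dest))
  list(genome = genome, pieces = piece_df,
       unique_intervals = unique_intervals,
       unique_seqs = uni_seqs, unique_lens = uni_lens,
       sv_list = sv_list)
}

#' Simulate a pair of near-identical strain genomes
#'
#' Both strains derive from one random shared backbone; each receives its
#' own backbone substitutions, inversions, relocations and novel
#' strain-unique insertions. Ground truth (unique-region intervals in each
#' strain's own coordinates, the rearrangement list, and an exact
#' piecewise map from each strain genome back to the backbone) is recorded
#' for downstream validation.
#'
#' @param config A [strain_sim_config()].
#' @return A `strain_pair` list with elements `genomes` (named character
#'   vector `dominant`/`minor`), `truth` (`unique_intervals`, `sv_list`),
#'   `pieces` (coordinate maps), and `config`.
#' @export
simulate_strain_pair <- function(config = strain_sim_config()) {
  set.seed(config$seed)
  backbone <- random_dna(config$backbone_len)
  dom <- build_strain(backbone, "dominant", config)
  min_ <- build_strain(backbone, "minor", config)
  structure(list(
    genomes = c(dominant = dom$genome, minor = min_$genome),
    backbone = backbone,
    truth = list(
      unique_intervals = list(dominant = dom$unique_intervals,
                              minor = min_$unique_intervals),
      sv_list = rbind(
        if (!is.null(dom$sv_list)) cbind(strain = "dominant", dom$sv_list),
        if (!is.null(min_$sv_list)) cbind(strain = "minor", min_$sv_list))),
    pieces = list(dominant = dom$pieces, minor = min_$pieces),
    unique_lens = list(dominant = dom$unique_lens, minor = min_$unique_lens),
    config = config),
    class = "strain_pair")
}

#' @export
print.strain_pair <- function(x, ...) {
  cat("simulated strain pair\n")
  cat("  dominant:", nchar(x$genomes[["dominant"]]), "bp,",
      nrow(x$truth$unique_intervals$dominant), "unique regions\n")
  cat("  minor:   ", nchar(x$genomes[["minor"]]), "bp,",
      nrow(x$truth$unique_intervals$minor), "unique regions\n")
  invisible(x)
}

draw_read_lengths <- function(target_bases, config) {
  lens <- integer(0)
  total <- 0
  while (total < target_bases) {
    need <- max(100L, ceiling((target_bases - total) / config$read_len_median))
    batch <- round(rlnorm(need, log(config$read_len_median),
                          config$read_len_sdlog))
    batch <- pmin(pmax(batch, config$read_len_min), config$read_len_max)
    keep <- cumsum(batch) <= (target_bases - total) | seq_along(batch) == 1L
    batch <- batch[keep]
    lens <- c(lens, batch)
    total <- total + sum(batch)
  }
  as.integer(lens)
}

mutate_read <- function(src, nsub, nins, ndel) {
  chars <- strsplit(src, "", fixed = TRUE)[[1]]
  len <- length(chars)
  bases <- c("A", "C", "G", "T")
  if (nsub > 0) {
    pos <- sample.int(len, min(nsub, len))
    chars[pos] <- vapply(chars[pos], function(b) {
      sample(setdiff(bases, b), 1L)
    }, character(1), USE.NAMES = FALSE)
  }
  if (ndel > 0) {
    pos <- sample.int(len, min(ndel, len - 1L))
    chars <- chars[-pos]
  }
  if (nins > 0) {
    pos <- sample.int(length(chars) + 1L, min(nins, length(chars) + 1L),
                      replace = FALSE)
    ins <- sample(bases, length(pos), replace = TRUE)
    out <- character(length(chars) + length(pos))
    idx <- sort(pos)
    take <- rep(TRUE, length(out))
    spots <- idx + seq_along(idx) - 1L
    take[spots] <- FALSE
    out[!take] <- ins
    out[take] <- chars
    chars <- out
  }
  paste(chars, collapse = "")
}

#' Simulate long reads from one or more genomes
#'
#' Read lengths are log-normal (parameterized by the configured median and
#' shape), clipped to the admission window; reads shorter than
#' `read_len_min` are never emitted. Errors are uniform substitutions,
#' insertions and deletions at equal rates. Every read carries a truth
#' alignment (its origin interval on the source genome, with identity
#' `1 - realized error`).
#'
#' @param genomes Named character vector of genome sequences.
#' @param depths Named numeric vector of per-genome sequencing depths
#'   (names matching `genomes`).
#' @param config A [strain_sim_config()] providing the read model.
#' @param circular Logical (recycled): sample reads across the origin,
#'   reporting truth coordinates on the doubled representation.
#' @param emit_sequences Generate the actual read sequences (`TRUE`), or
#'   only coordinates and truth alignments (`FALSE`, much faster for
#'   depth-only experiments at genome scale).
#' @param seed Optional seed; defaults to `config$seed + 1`.
#' @return List with `reads` (data.frame `id`, `seq`), `alignments`
#'   (truth alignment data.frame, PAF semantics) and `origins`
#'   (data.frame `read_id`, `genome`).
#' @export
simulate_reads <- function(genomes, depths, config = strain_sim_config(),
                           circular = FALSE, emit_sequences = TRUE,
                           seed = NULL) {
  stopifnot(length(genomes) >= 1L, !is.null(names(genomes)),
            all(names(genomes) %in% names(depths) |
                  names(depths) %in% names(genomes)))
  if (any(depths[names(genomes)] <= 0)) stop("requested depth must be > 0")
  set.seed(if (is.null(seed)) config$seed + 1L else seed)
  circular <- rep_len(circular, length(genomes))
  all_reads <- list(); all_aln <- list(); all_orig <- list()
  for (g in seq_along(genomes)) {
    gname <- names(genomes)[g]
    gseq <- genomes[[g]]
    L <- nchar(gseq)
    depth <- depths[[gname]]
    lens <- draw_read_lengths(depth * L, config)
    lens <- pmin(lens, L)
    n <- length(lens)
    start <- if (circular[g]) {
      sample.int(L, n, replace = TRUE) - 1L
    } else {
      vapply(lens, function(l) sample.int(L - l + 1L, 1L) - 1L, integer(1))
    }
    strand <- sample(c("+", "-"), n, replace = TRUE)
    e <- config$read_error_rate / 3
    nsub <- rbinom(n, lens, e)
    nins <- rbinom(n, lens, e)
    ndel <- rbinom(n, lens, e)
    read_len <- lens - ndel + nins
    block <- lens + nins
    matches <- lens - nsub - ndel
    id <- sprintf("%s_r%05d", gname, seq_len(n))
    target_id <- if (circular[g]) paste0(gname, "_doubled") else gname
    tlen <- if (circular[g]) 2L * L else L
    aln <- data.frame(read_id = id, read_len = read_len,
                      read_start = 0L, read_end = read_len,
                      strand = strand,
                      target_id = target_id, target_len = tlen,
                      target_start = start, target_end = start + lens,
                      matches = matches, block_len = block, mapq = 60L,
                      stringsAsFactors = FALSE)
    seqs <- NULL
    if (emit_sequences) {
      src_genome <- if (circular[g]) paste0(gseq, gseq) else gseq
      seqs <- vapply(seq_len(n), function(i) {
        src <- substr(src_genome, start[i] + 1L, start[i] + lens[i])
        if (strand[i] == "-") src <- revcomp(src)
        if (nsub[i] + nins[i] + ndel[i] == 0L) return(src)
        mutate_read(src, nsub[i], nins[i], ndel[i])
      }, character(1))
    }
    all_reads[[g]] <- data.frame(id = id,
                                 seq = if (is.null(seqs)) NA_character_ else seqs,
                                 stringsAsFactors = FALSE)
    all_aln[[g]] <- aln
    all_orig[[g]] <- data.frame(read_id = id, genome = gname,
                                stringsAsFactors = FALSE)
  }
  list(reads = do.call(rbind, all_reads),
       alignments = do.call(rbind, all_aln),
       origins = do.call(rbind, all_orig))
}

#' Project truth alignments onto the draft-assembly representation
#'
#' A mixed-strain assembly represents the community as a shared backbone
#' contig plus one contig per strain-unique region. This helper maps each
#' read's truth alignment from its source strain's coordinates onto that
#' draft contig set, assigning the read to the contig holding the largest
#' part of its footprint (the single-best-alignment contract). Combined
#' over both strains, the projected alignments reproduce the composite
#' depth structure that coverage binning operates on: shared backbone at
#' the summed depth, unique-region contigs at their strain's own depth.
#'
#' @param aln Truth alignments from [simulate_reads()] (targets are strain
#'   names).
#' @param pair The [simulate_strain_pair()] result.
#' @return Alignment data.frame with targets `backbone` and
#'   `uniq_<strain>_<k>`.
#' @export
project_alignments <- function(aln, pair) {
  L_bb <- pair$config$backbone_len
  rows <- vector("list", length(pair$genomes))
  for (strain in names(pair$genomes)) {
    sub <- aln[aln$target_id == strain, , drop = FALSE]
    if (nrow(sub) == 0L) next
    pieces <- pair$pieces[[strain]]
    ulen <- pair$unique_lens[[strain]]
    # piece index covering each footprint's midpoint-dominant overlap:
    # find the piece with the largest overlap per read
    pidx <- integer(nrow(sub)); o1 <- integer(nrow(sub)); o2 <- integer(nrow(sub))
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(sub$target_start + 1L, sub$target_end),
      IRanges::IRanges(pieces$start + 1L, pieces$end))
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    width <- pmin(sub$target_end[qh], pieces$end[sh]) -
      pmax(sub$target_start[qh], pieces$start[sh])
    best <- tapply(seq_along(qh), qh, function(ix) ix[which.max(width[ix])])
    bi <- unlist(best)
    qb <- qh[bi]; sb <- sh[bi]
    o1[qb] <- pmax(sub$target_start[qb], pieces$start[sb]) - pieces$start[sb]
    o2[qb] <- pmin(sub$target_end[qb], pieces$end[sb]) - pieces$start[sb]
    pidx[qb] <- sb
    keep <- pidx > 0L
    sub <- sub[keep, , drop = FALSE]
    pi_ <- pieces[pidx[keep], , drop = FALSE]
    o1 <- o1[keep]; o2 <- o2[keep]
    is_uni <- pi_$type == "uni"
    tid <- ifelse(is_uni, paste0("uniq_", strain, "_", pi_$uniq_id),
                  "backbone")
    tlen <- ifelse(is_uni, pi_$src_end, L_bb)
    ts <- ifelse(is_uni, o1,
                 ifelse(pi_$strand == "+", pi_$src_start + o1,
                        pi_$src_end - o2))
    te <- ifelse(is_uni, o2,
                 ifelse(pi_$strand == "+", pi_$src_start + o2,
                        pi_$src_end - o1))
    frac <- (o2 - o1) / (sub$target_end - sub$target_start)
    rows[[strain]] <- data.frame(
      read_id = sub$read_id, read_len = sub$read_len,
      read_start = 0L, read_end = as.integer(round(sub$read_len * frac)),
      strand = sub$strand, target_id = tid, target_len = as.integer(tlen),
      target_start = as.integer(ts), target_end = as.integer(te),
      matches = as.integer(round(sub$matches * frac)),
      block_len = as.integer(round(sub$block_len * frac)),
      mapq = sub$mapq, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate per-site polymerase kinetics with planted methylation
#'
#' Emits one kinetics summary per (position, strand): the observed
#' log-transformed interpulse-duration mean/sd over `per_strand_depth`
#' passes, and the matching unmethylated control summary. Methylated
#' sites (occurrences of the planted motifs, methylated independently
#' with the given fraction) draw their observed mean from
#' `control + delta`; unmethylated sites from the control itself, so the
#' downstream Welch t-test is exactly calibrated under the null.
#'
#' @param genome Single genome string.
#' @param motifs data.frame with columns `pattern` (IUPAC), `methyl_index`
#'   (0-based offset of the methylated base) and `fraction` (methylated
#'   fraction of occurrences); may be empty for an unmethylated genome.
#' @param per_strand_depth Mean per-strand coverage (observed n).
#' @param delta Kinetic shift at methylated sites, log-IPD units.
#' @param sigma Per-pass log-IPD standard deviation.
#' @param ctrl_n Control model sample size per site.
#' @param target_id Name recorded in the output.
#' @param seed Optional seed.
#' @return List with `kinetics` (data.frame of per-site summaries) and
#'   `truth` (data.frame of planted methylated sites: `position`,
#'   `strand`, `motif`, `mod_type`).
#' @export
simulate_kinetics <- function(genome, motifs = NULL, per_strand_depth = 200,
                              delta = 1.0, sigma = 0.5, ctrl_n = 500L,
                              target_id = "genome", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- nchar(genome)
  fwd <- strsplit(genome, "", fixed = TRUE)[[1]]
  comp <- chartr("ACGT", "TGCA", fwd)
  N <- 2L * L
  pos <- rep(0:(L - 1L), 2L)
  strand <- rep(c("+", "-"), each = L)
  base <- c(fwd, comp)
  meth <- rep(FALSE, N)
  truth <- list()
  if (!is.null(motifs) && nrow(motifs) > 0) {
    for (k in seq_len(nrow(motifs))) {
      occ <- motif_occurrences_stranded(genome, motifs$pattern[k],
                                        motifs$methyl_index[k])
      if (nrow(occ) == 0L) next
      planted <- runif(nrow(occ)) < motifs$fraction[k]
      occ <- occ[planted, , drop = FALSE]
      idx <- occ$methyl_pos + 1L + ifelse(occ$strand == "-", L, 0L)
      meth[idx] <- TRUE
      if (nrow(occ)) {
        truth[[k]] <- data.frame(
          position = occ$methyl_pos, strand = occ$strand,
          motif = motifs$pattern[k],
          mod_type = ifelse(base[idx] == "A", "6mA",
                            ifelse(base[idx] == "C", "4mC", "unknown")),
          stringsAsFactors = FALSE)
      }
    }
  }
  mu0 <- rnorm(N, 0, 0.3)
  obs_n <- pmax(2L, rpois(N, per_strand_depth))
  obs_sd <- sigma * sqrt(rchisq(N, obs_n - 1L) / (obs_n - 1L))
  obs_mean <- rnorm(N, mu0 + delta * meth, sigma / sqrt(obs_n))
  ctrl_sd <- sigma * sqrt(rchisq(N, ctrl_n - 1L) / (ctrl_n - 1L))
  ctrl_mean <- rnorm(N, mu0, sigma / sqrt(ctrl_n))
  kinetics <- data.frame(
    target_id = target_id, position = pos, strand = strand, base = base,
    obs_mean = obs_mean, obs_sd = obs_sd, obs_n = obs_n,
    ctrl_mean = ctrl_mean, ctrl_sd = ctrl_sd, ctrl_n = ctrl_n,
    stringsAsFactors = FALSE)
  truth <- if (length(truth)) do.call(rbind, truth) else {
    data.frame(position = integer(0), strand = character(0),
               motif = character(0), mod_type = character(0),
               stringsAsFactors = FALSE)
  }
  list(kinetics = kinetics, truth = truth)
}

#' Write a kinetics table
#'
#' Tab-separated, columns exactly as produced by [simulate_kinetics()].
#'
#' @param kinetics Kinetics data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_kinetics <- function(kinetics, path) {
  utils::write.table(kinetics, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a kinetics table written by [write_kinetics()]
#'
#' @param path Kinetics file.
#' @return Kinetics data.frame.
#' @export
read_kinetics <- function(path) {
  read.delim(path, stringsAsFactors = FALSE,
             colClasses = c(target_id = "character", strand = "character",
                            base = "character"))
}
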