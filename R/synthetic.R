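#' @title Simulation of strand-specific end-enriched datasets
#' @name synthetic
#' @description Generates fully self-contained fixtures — a random genome,
#'   a tiling annotation, per-library SAM alignments whose 3' termini pile
#'   up at planted positions with negative-binomial counts and
#'   condition-specific log2 effects, background reads, and untemplated
#'   G-rich 3' tails emitted as soft clips — plus a truth table for
#'   recovery scoring. Reads are emitted as already-aligned SAM: the
#'   pipeline's contract starts at alignments, which keeps tests hermetic.
NULL

#' Plant differential ends on a simulated genome
#'
#' Positions are drawn without replacement from a grid with spacing
#' `min_gap`, keeping `read_length` nt clear of both replicon boundaries
#' so every read fits.
#'
#' @param n number of ends.
#' @param replicon_lengths named integer vector.
#' @param base_mean expected terminus count in the reference condition
#'   (recycled; default 50, the study's basemean filter floor).
#' @param log2_effect condition effect (recycled; default +5, the modal
#'   enriched fold change).
#' @param kind end taxonomy label: `termination`, `cleavage` or
#'   `exo_stall` (recycled; bookkeeping only).
#' @param jitter_sd positional smear of read termini in nt (default 0.5).
#' @param min_gap minimal spacing between planted positions (default 200).
#' @param read_length read length the dataset will use (default 75).
#' @param seed optional seed for reproducible placement.
#' @return Data frame with columns `replicon`, `position` (0-based),
#'   `strand`, `kind`, `base_mean`, `log2_effect`, `jitter_sd`.
#' @export
plant_ends <- function(n, replicon_lengths, base_mean = 50,
                       log2_effect = 5, kind = "cleavage",
                       jitter_sd = 0.5, min_gap = 200L,
                       read_length = 75L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  grid <- do.call(rbind, lapply(names(replicon_lengths), function(rn) {
    len <- replicon_lengths[[rn]]
    # leave a full min_gap of tail room so jitter and user-applied shifts
    # below min_gap/2 can never leave the replicon
    pos <- seq.int(read_length + 1L, len - read_length - min_gap,
                   by = min_gap)
    data.frame(replicon = rn, position = pos, stringsAsFactors = FALSE)
  }))
  if (n > nrow(grid)) stop("config error: too many ends for the genome")
  pick <- sort(sample.int(nrow(grid), n))
  out <- grid[pick, , drop = FALSE]
  out$position <- out$position + sample(0:(min_gap %/% 4L), n, replace = TRUE)
  out$strand <- sample(c("+", "-"), n, replace = TRUE)
  out$kind <- rep_len(kind, n)
  out$base_mean <- rep_len(base_mean, n)
  out$log2_effect <- rep_len(log2_effect, n)
  out$jitter_sd <- rep_len(jitter_sd, n)
  rownames(out) <- NULL
  out
}

#' Simulation configuration
#'
#' Defaults emulate the study design at desk scale: a 100 kb replicon,
#' three replicates per condition, 75 nt strand-specific single-end
#' reads, NB dispersion 0.1, and 10% of reads carrying an untemplated
#' G-rich 3' tail (70% G over the first 20 tail positions, lengths
#' 1 + Geometric so that ~95% are shorter than 39 nt).
#'
#' @param replicon_lengths named integer vector (default `c(chr = 1e5)`).
#' @param n_replicates replicates per condition (default 3).
#' @param read_length read length in nt (default 75, >= 20).
#' @param depth per-library depth scale; named by library id or a single
#'   value recycled (default 1).
#' @param dispersion NB dispersion of planted end counts (default 0.1).
#' @param planted data frame from [plant_ends()]; `NULL` plants nothing.
#' @param background_reads background reads per library with uniform random
#'   3' ends (default 5000).
#' @param tail_fraction fraction of reads carrying a 3' tail (default 0.1).
#' @param tail_g_prob probability of G at early tail positions (default 0.7).
#' @param tail_g_positions number of G-enriched leading tail positions
#'   (default 20).
#' @param tail_mean_length mean of the geometric tail-length excess
#'   (default 11, giving tails `1 + Geom`, ~95% below 39 nt).
#' @param seed integer seed; a fixed seed makes every output byte-identical.
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(replicon_lengths = c(chr = 100000L),
                       n_replicates = 3L, read_length = 75L, depth = 1,
                       dispersion = 0.1, planted = NULL,
                       background_reads = 5000L, tail_fraction = 0.1,
                       tail_g_prob = 0.7, tail_g_positions = 20L,
                       tail_mean_length = 11, seed = 1L) {
  stopifnot(read_length >= 20L, n_replicates >= 1L, dispersion >= 0)
  if (!is.null(planted)) {
    bad <- planted$position < 0 |
      planted$position >= replicon_lengths[planted$replicon]
    if (any(bad)) stop("config error: planted end outside replicon")
  }
  structure(list(replicon_lengths = replicon_lengths,
                 n_replicates = as.integer(n_replicates),
                 read_length = as.integer(read_length), depth = depth,
                 dispersion = dispersion, planted = planted,
                 background_reads = as.integer(background_reads),
                 tail_fraction = tail_fraction, tail_g_prob = tail_g_prob,
                 tail_g_positions = as.integer(tail_g_positions),
                 tail_mean_length = tail_mean_length,
                 seed = as.integer(seed)),
            class = "sim_config")
}

.random_genome <- function(replicon_lengths) {
  g <- vapply(replicon_lengths, function(len) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
  stats::setNames(g, names(replicon_lengths))
}

.sim_annotation <- function(replicon_lengths) {
  # deterministic tiling: a gene every 2 kb, mostly CDS with stable RNAs
  # and ncRNAs sprinkled in, alternating strands
  types <- c("CDS", "CDS", "CDS", "tRNA", "CDS", "ncRNA", "CDS", "CDS",
             "rRNA", "CDS")
  rows <- character(0)
  feats <- list()
  i <- 0L
  for (rn in names(replicon_lengths)) {
    len <- replicon_lengths[[rn]]
    starts <- seq.int(500L, len - 1500L, by = 2000L)
    for (s in starts) {
      i <- i + 1L
      type <- types[(i - 1L) %% length(types) + 1L]
      w <- if (type == "tRNA") 80L else if (type == "rRNA") 1400L else 900L
      e <- min(s + w, len - 10L)
      st <- if (i %% 2L == 0L) "-" else "+"
      id <- sprintf("gene_%04d", i)
      rows <- c(rows, sprintf(
        "%s\tsim\t%s\t%d\t%d\t.\t%s\t.\tID=%s;locus_tag=%s",
        rn, type, s + 1L, e, st, id, id))
    }
  }
  c("##gff-version 3", rows)
}

.revcomp_chr <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

.sim_tail_seqs <- function(n_tails, tail_lens, g_prob, g_positions) {
  if (n_tails == 0L) return(character(0))
  pos <- sequence(tail_lens)
  nb <- length(pos)
  u <- stats::runif(nb)
  base <- character(nb)
  early <- pos <= g_positions
  if (any(early)) {
    ue <- u[early]
    be <- rep("G", sum(early))
    ng <- ue >= g_prob
    alt_idx <- pmin(3L, pmax(1L, ceiling((ue[ng] - g_prob) /
                                           (1 - g_prob) * 3)))
    be[ng] <- c("A", "C", "T")[alt_idx]
    base[early] <- be
  }
  if (any(!early)) {
    base[!early] <- c("A", "C", "G", "T")[
      pmin(4L, pmax(1L, ceiling(u[!early] * 4)))]
  }
  unname(vapply(split(base, rep(seq_len(n_tails), tail_lens)),
                paste, character(1), collapse = ""))
}

.sim_library_reads <- function(cfg, genome, condition, depth_j, lib) {
  L <- cfg$read_length
  reads <- list()
  pl <- cfg$planted
  # planted reads
  if (!is.null(pl) && nrow(pl) > 0L) {
    mu <- depth_j * pl$base_mean *
      2^(pl$log2_effect * (condition == "test"))
    counts <- if (cfg$dispersion > 0) {
      stats::rnbinom(nrow(pl), mu = mu, size = 1 / cfg$dispersion)
    } else {
      stats::rpois(nrow(pl), mu)
    }
    idx <- rep(seq_len(nrow(pl)), counts)
    if (length(idx) > 0L) {
      jit <- as.integer(round(stats::rnorm(length(idx), 0,
                                           pl$jitter_sd[idx])))
      end_pos <- pl$position[idx] + jit
      rlen <- cfg$replicon_lengths[pl$replicon[idx]]
      end_pos <- pmin(pmax(end_pos, L), rlen - L - 1L)
      reads[[1L]] <- data.frame(replicon = pl$replicon[idx],
                                strand = pl$strand[idx],
                                end_pos = end_pos,
                                origin = "planted",
                                stringsAsFactors = FALSE)
    }
  }
  # background reads: one read each, uniform positions and strands
  if (cfg$background_reads > 0L) {
    rn <- sample(names(cfg$replicon_lengths), cfg$background_reads,
                 replace = TRUE,
                 prob = cfg$replicon_lengths / sum(cfg$replicon_lengths))
    lo <- L
    hi <- cfg$replicon_lengths[rn] - L - 1L
    pos <- lo + floor(stats::runif(cfg$background_reads) * (hi - lo + 1L))
    reads[[length(reads) + 1L]] <- data.frame(
      replicon = rn, strand = sample(c("+", "-"), cfg$background_reads,
                                     replace = TRUE),
      end_pos = as.integer(pos), origin = "background",
      stringsAsFactors = FALSE)
  }
  rd <- do.call(rbind, c(reads, list(make.row.names = FALSE)))
  if (is.null(rd) || nrow(rd) == 0L) {
    return(list(sam_body = character(0), n_planted = 0L, n_background = 0L))
  }
  n <- nrow(rd)
  has_tail <- stats::runif(n) < cfg$tail_fraction
  tail_len <- integer(n)
  tail_len[has_tail] <- pmin(
    1L + stats::rgeom(sum(has_tail), 1 / cfg$tail_mean_length),
    L - 20L)
  tail_seq <- rep("", n)
  tail_seq[has_tail] <- .sim_tail_seqs(sum(has_tail), tail_len[has_tail],
                                       cfg$tail_g_prob,
                                       cfg$tail_g_positions)
  la <- L - tail_len  # aligned span; 3'-terminal aligned base = end_pos
  plus <- rd$strand == "+"
  astart <- ifelse(plus, rd$end_pos - la + 1L, rd$end_pos)  # 0-based
  aend <- astart + la - 1L
  slice <- substring(genome[rd$replicon], astart + 1L, aend + 1L)
  seq <- character(n)
  cigar <- character(n)
  seq[plus] <- paste0(slice[plus], tail_seq[plus])
  cigar[plus] <- ifelse(tail_len[plus] > 0L,
                        sprintf("%dM%dS", la[plus], tail_len[plus]),
                        sprintf("%dM", la[plus]))
  if (any(!plus)) {
    rc_tail <- rep("", sum(!plus))
    ht <- has_tail[!plus]
    rc_tail[ht] <- .revcomp_chr(tail_seq[!plus][ht])
    seq[!plus] <- paste0(rc_tail, slice[!plus])
    cigar[!plus] <- ifelse(tail_len[!plus] > 0L,
                           sprintf("%dS%dM", tail_len[!plus], la[!plus]),
                           sprintf("%dM", la[!plus]))
  }
  pos1 <- astart + 1L  # SAM POS is 1-based leftmost aligned base
  flag <- ifelse(plus, 0L, 16L)
  qname <- sprintf("%s_read_%07d", lib, seq_len(n))
  sam_body <- sprintf("%s\t%d\t%s\t%d\t255\t%s\t*\t0\t0\t%s\t*",
                      qname, flag, rd$replicon, pos1, cigar, seq)
  list(sam_body = sam_body,
       n_planted = sum(rd$origin == "planted"),
       n_background = sum(rd$origin == "background"))
}

#' Simulate a complete two-condition dataset
#'
#' One global RNG stream (seeded from `cfg$seed`) drives genome,
#' annotation and per-library reads in a fixed order, so identical
#' configurations yield byte-identical outputs.
#'
#' @param cfg a [sim_config()].
#' @param out_dir optional directory; when given, `genome.fa`,
#'   `annotation.gff3`, `<library>.sam`, `truth.tsv` and `design.tsv` are
#'   written there.
#' @return List of class `"sim_dataset"`: `genome` (named character),
#'   `genome_fasta` / `gff3` / `sam` (character vectors of file lines,
#'   `sam` named by library), `truth` (data frame), `design` (data
#'   frame), `read_counts` (per-library planted/background tallies),
#'   `paths` (when written), `config`.
#' @export
simulate_dataset <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  genome <- .random_genome(cfg$replicon_lengths)
  gff3 <- .sim_annotation(cfg$replicon_lengths)
  conditions <- rep(c("reference", "test"), each = cfg$n_replicates)
  lib_ids <- sprintf("%s_%d", ifelse(conditions == "reference", "ref", "test"),
                     rep(seq_len(cfg$n_replicates), 2L))
  depth <- if (length(cfg$depth) == 1L) {
    stats::setNames(rep(cfg$depth, length(lib_ids)), lib_ids)
  } else {
    cfg$depth[lib_ids]
  }
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(cfg$replicon_lengths),
                      cfg$replicon_lengths))
  sams <- vector("list", length(lib_ids))
  names(sams) <- lib_ids
  read_counts <- data.frame(library_id = lib_ids, n_planted = 0L,
                            n_background = 0L, stringsAsFactors = FALSE)
  for (j in seq_along(lib_ids)) {
    r <- .sim_library_reads(cfg, genome, conditions[j], depth[[j]],
                            lib_ids[j])
    sams[[j]] <- c(header, r$sam_body)
    read_counts$n_planted[j] <- r$n_planted
    read_counts$n_background[j] <- r$n_background
  }
  truth <- if (is.null(cfg$planted)) {
    data.frame(replicon = character(), position = integer(),
               strand = character(), kind = character(),
               base_mean = numeric(), log2_effect = numeric(),
               jitter_sd = numeric(), stringsAsFactors = FALSE)
  } else {
    cfg$planted
  }
  design <- data.frame(library_id = lib_ids, condition = conditions,
                       replicate_index = rep(seq_len(cfg$n_replicates), 2L),
                       stringsAsFactors = FALSE)
  fasta <- as.character(rbind(paste0(">", names(genome)), unname(genome)))
  out <- list(genome = genome, genome_fasta = fasta, gff3 = gff3,
              sam = sams, truth = truth, design = design,
              read_counts = read_counts, config = cfg)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      genome = file.path(out_dir, "genome.fa"),
      gff3 = file.path(out_dir, "annotation.gff3"),
      truth = file.path(out_dir, "truth.tsv"),
      design = file.path(out_dir, "design.tsv"),
      sam = stats::setNames(file.path(out_dir, paste0(lib_ids, ".sam")),
                            lib_ids))
    writeLines(fasta, paths$genome)
    writeLines(gff3, paths$gff3)
    utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(design, paths$design, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    for (j in seq_along(lib_ids)) writeLines(sams[[j]], paths$sam[[j]])
    out$paths <- paths
  }
  class(out) <- "sim_dataset"
  out
}

#' Score recovery of planted ends by called differential ends
#'
#' A called end matches a truth end when both lie on the same replicon and
#' strand and the truth position is within `tolerance` nt of the called
#' interval; each called end matches at most one truth end (nearest wins,
#' leftmost truth on tie). Sensitivity counts truth ends with nonzero
#' effect recovered with the correct effect sign; precision counts called
#' ends matching a truth end with the correct sign. With nothing called,
#' precision is reported as 1.0 with `zero_called = TRUE`.
#'
#' @param called a `differential_ends` data frame.
#' @param truth truth data frame (as in a `sim_dataset`).
#' @param tolerance matching tolerance in nt (default 3).
#' @return List: `sensitivity`, `precision`, `sign_accuracy` (among
#'   position-matched calls; `NA` when none), `n_called`, `n_truth`,
#'   `recovered`, `zero_called`.
#' @export
score_recovery <- function(called, truth, tolerance = 3L) {
  if (tolerance < 0) stop("input error: tolerance must be non-negative")
  truth_nz <- truth[truth$log2_effect != 0, , drop = FALSE]
  n_called <- nrow(called)
  if (n_called == 0L) {
    return(list(sensitivity = 0, precision = 1.0, sign_accuracy = NA_real_,
                n_called = 0L, n_truth = nrow(truth_nz), recovered = 0L,
                zero_called = TRUE))
  }
  match_truth <- integer(n_called)  # 0 = unmatched
  sign_ok <- logical(n_called)
  for (i in seq_len(n_called)) {
    cand <- which(truth$replicon == called$replicon[i] &
                    truth$strand == called$strand[i])
    if (length(cand) == 0L) next
    tp <- truth$position[cand]
    d <- pmax(0L, pmax(called$start[i] - tp, tp - (called$end[i] - 1L)))
    ok <- d <= tolerance
    if (!any(ok)) next
    cand <- cand[ok]; d <- d[ok]
    best <- cand[order(d, truth$position[cand])][1L]
    match_truth[i] <- best
    sign_ok[i] <- sign(truth$log2_effect[best]) ==
      sign(called$mean_log2fc[i])
  }
  matched <- match_truth > 0L
  good <- matched & sign_ok
  recovered <- intersect(unique(match_truth[good]),
                         which(truth$log2_effect != 0))
  list(
    sensitivity = if (nrow(truth_nz)) length(recovered) / nrow(truth_nz) else NA_real_,
    precision = sum(good) / n_called,
    sign_accuracy = if (any(matched)) mean(sign_ok[matched]) else NA_real_,
    n_called = n_called, n_truth = nrow(truth_nz),
    recovered = length(recovered), zero_called = FALSE
  )
}
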