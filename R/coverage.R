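#' @title Per-nucleotide coverage tracks and the end-count matrix
#' @name coverage
#' @description Full-read coverage counts every aligned read base (CIGAR
#'   M/=/X); reference gaps (D/N) and clips (S/H) do not contribute.
#'   Read-terminus coverage counts exactly one position per read: the
#'   3'-terminal aligned base (`end3`; rightmost aligned base on `+`,
#'   leftmost on `-`) or its 5' mirror (`end5`). Soft-clipped tails never
#'   shift the counted terminus.
NULL

.check_strand <- function(strand) {
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
}

#' Compute per-strand coverage tracks
#'
#' @param alignments an `alignments` data frame from [read_alignments()].
#' @param replicon_lengths named integer vector of replicon lengths; when
#'   `NULL`, taken from the `replicon_lengths` attribute of `alignments`.
#' @param kind `"full"` (aligned read bases), `"end3"` or `"end5"`
#'   (one count per read at the respective terminal aligned base).
#' @return A list of class `"coverage_tracks"`: one element per replicon,
#'   each a list with integer vectors `+` and `-` of the replicon length.
#'   Attributes `kind` and `replicon_lengths` are set.
#' @examples
#' sam <- c("@SQ\tSN:chr\tLN:300",
#'          "r1\t0\tchr\t101\t255\t75M\t*\t0\t0\t*\t*")
#' tr <- compute_coverage(read_alignments(sam), kind = "end3")
#' which(tr$chr$`+` > 0) - 1  # 174: rightmost aligned base, 0-based
#' @export
compute_coverage <- function(alignments, replicon_lengths = NULL,
                             kind = c("full", "end3", "end5")) {
  kind <- match.arg(kind)
  if (is.null(replicon_lengths)) {
    replicon_lengths <- attr(alignments, "replicon_lengths")
  }
  if (is.null(replicon_lengths)) {
    stop("configuration error: replicon_lengths not supplied")
  }
  .check_strand(alignments$strand)
  tracks <- lapply(replicon_lengths, function(len) {
    list(`+` = integer(len), `-` = integer(len))
  })
  names(tracks) <- names(replicon_lengths)

  n <- nrow(alignments)
  if (n > 0L) {
    ref_w <- GenomicAlignments::cigarWidthAlongReferenceSpace(alignments$cigar)
    aln_end <- alignments$start + ref_w - 1L  # 0-based last ref position
    over <- aln_end >= replicon_lengths[alignments$replicon] |
      alignments$start < 0L
    if (any(over)) {
      i <- which(over)[1L]
      stop(sprintf("bounds error: read '%s' extends past replicon '%s'",
                   alignments$read_id[i], alignments$replicon[i]))
    }
    if (kind == "full") {
      irl <- GenomicAlignments::cigarRangesAlongReferenceSpace(
        alignments$cigar, ops = c("M", "=", "X"),
        pos = alignments$start + 1L)
      nblk <- S4Vectors::elementNROWS(irl)
      blocks <- unlist(irl, use.names = FALSE)
      rep_rep <- rep(alignments$replicon, nblk)
      rep_str <- rep(alignments$strand, nblk)
      bs <- BiocGenerics::start(blocks)  # 1-based
      bw <- BiocGenerics::width(blocks)
      for (rn in names(tracks)) {
        for (st in c("+", "-")) {
          sel <- rep_rep == rn & rep_str == st
          if (!any(sel)) next
          cov <- IRanges::coverage(
            IRanges::IRanges(start = bs[sel], width = bw[sel]),
            width = replicon_lengths[[rn]])
          tracks[[rn]][[st]] <- as.integer(cov)
        }
      }
    } else {
      is_plus <- alignments$strand == "+"
      if (kind == "end3") {
        pos <- ifelse(is_plus, aln_end, alignments$start)
      } else {
        pos <- ifelse(is_plus, alignments$start, aln_end)
      }
      for (rn in names(tracks)) {
        for (st in c("+", "-")) {
          sel <- alignments$replicon == rn & alignments$strand == st
          if (!any(sel)) next
          tracks[[rn]][[st]] <- tabulate(pos[sel] + 1L,
                                         nbins = replicon_lengths[[rn]])
        }
      }
    }
  }
  attr(tracks, "kind") <- kind
  attr(tracks, "replicon_lengths") <- replicon_lengths
  class(tracks) <- "coverage_tracks"
  tracks
}

.track_positions <- function(tracks) {
  # nonzero positions of a coverage_tracks object as a keyed data frame
  out <- list()
  for (rn in names(tracks)) {
    for (st in c("+", "-")) {
      v <- tracks[[rn]][[st]]
      p <- which(v > 0L) - 1L
      if (length(p)) {
        out[[length(out) + 1L]] <- data.frame(
          replicon = rn, pos = p, strand = st, count = v[p + 1L],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(replicon = character(), pos = integer(),
                      strand = character(), count = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

.pos_key <- function(replicon, pos, strand) {
  paste(replicon, pos, strand, sep = ":")
}

#' Assemble the cross-library end-count matrix
#'
#' Plus- and minus-strand tracks of all libraries are integrated into one
#' matrix keyed by (replicon, position, strand): the union of positions
#' with a nonzero terminus count in at least one library, zero-filled
#' elsewhere. Integration is concatenation of strand-keyed rows, never
#' summation across strands.
#'
#' @param tracks_by_library named list, library id -> `coverage_tracks`
#'   of kind `end3` or `end5`. All libraries must share the replicon set.
#' @return A list of class `"end_count_matrix"` with elements `positions`
#'   (data frame `replicon`, `pos`, `strand`, ordered by key), `counts`
#'   (integer matrix positions x libraries) and `library_ids`.
#' @export
build_end_count_matrix <- function(tracks_by_library) {
  libs <- names(tracks_by_library)
  if (is.null(libs) || any(!nzchar(libs)) || anyDuplicated(libs)) {
    stop("configuration error: tracks_by_library must have unique names")
  }
  repl_sets <- lapply(tracks_by_library, names)
  if (length(unique(vapply(repl_sets, paste, "", collapse = "\r"))) != 1L) {
    stop("configuration error: libraries have mismatched replicon sets")
  }
  per_lib <- lapply(tracks_by_library, .track_positions)
  all_pos <- do.call(rbind, c(per_lib, list(make.row.names = FALSE)))
  if (nrow(all_pos) == 0L) {
    positions <- data.frame(replicon = character(), pos = integer(),
                            strand = character(), stringsAsFactors = FALSE)
    counts <- matrix(0L, nrow = 0L, ncol = length(libs),
                     dimnames = list(NULL, libs))
    out <- list(positions = positions, counts = counts, library_ids = libs)
    class(out) <- "end_count_matrix"
    return(out)
  }
  key <- .pos_key(all_pos$replicon, all_pos$pos, all_pos$strand)
  positions <- all_pos[!duplicated(key), c("replicon", "pos", "strand")]
  positions <- positions[order(positions$replicon, positions$pos,
                               positions$strand), , drop = FALSE]
  rownames(positions) <- NULL
  pkey <- .pos_key(positions$replicon, positions$pos, positions$strand)
  counts <- matrix(0L, nrow = nrow(positions), ncol = length(libs),
                   dimnames = list(NULL, libs))
  for (j in seq_along(libs)) {
    d <- per_lib[[j]]
    if (nrow(d) == 0L) next
    counts[match(.pos_key(d$replicon, d$pos, d$strand), pkey), j] <-
      d$count
  }
  out <- list(positions = positions, counts = counts, library_ids = libs)
  class(out) <- "end_count_matrix"
  out
}

#' Look up per-library coverage values at matrix positions
#'
#' @param matrix an `end_count_matrix`.
#' @param tracks_by_library named list, library id -> `coverage_tracks`
#'   (typically kind `full`).
#' @return Numeric matrix, positions x libraries.
#' @export
coverage_at_positions <- function(matrix, tracks_by_library) {
  libs <- matrix$library_ids
  miss <- setdiff(libs, names(tracks_by_library))
  if (length(miss)) {
    stop("configuration error: missing coverage tracks for library ",
         paste(miss, collapse = ", "))
  }
  out <- vapply(libs, function(lib) {
    tr <- tracks_by_library[[lib]]
    v <- numeric(nrow(matrix$positions))
    for (rn in unique(matrix$positions$replicon)) {
      for (st in c("+", "-")) {
        sel <- matrix$positions$replicon == rn & matrix$positions$strand == st
        if (!any(sel)) next
        v[sel] <- tr[[rn]][[st]][matrix$positions$pos[sel] + 1L]
      }
    }
    v
  }, numeric(nrow(matrix$positions)))
  if (nrow(matrix$positions) == 1L) out <- t(as.matrix(out)) # vapply drops dim
  dimnames(out) <- list(NULL, libs)
  out
}
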