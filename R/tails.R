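#' @title Untemplated 3' tail extraction and profiling
#' @name tails
#' @description Reads that only align in local mode can carry untemplated
#'   3' additions as soft-clipped bases. A tail is trusted only when the
#'   read is anchored by a contiguous aligned block of at least 10 nt at
#'   its 5' end and carries no 5' soft clip; the 3'-side soft clip then
#'   becomes the tail, stored 5'->3' in read orientation.
NULL

.lead_run <- function(ops, lens, match_ops = c("M", "=", "X")) {
  # length of the leading contiguous aligned block (read bases)
  r <- 0L
  for (k in seq_along(ops)) {
    if (ops[k] %in% match_ops) {
      r <- r + lens[k]
    } else if (ops[k] == "D" || ops[k] == "N") {
      break  # reference gap interrupts the block but consumes no read base
    } else {
      break
    }
  }
  r
}

#' Extract soft-clipped 3' tails from local alignments
#'
#' In read orientation, the aligned block adjacent to the read's 5' end
#' must span at least `min_anchor` read bases and no 5' soft clip may be
#' present; the 3'-side soft clip (length >= 1) becomes the tail. For `-`
#' strand alignments the read's 3' tail is the *leading* soft clip in
#' reference orientation and is reverse-complemented into read
#' orientation for storage.
#'
#' @param alignments an `alignments` data frame; sequences must be present
#'   (`SEQ != "*"`).
#' @param min_anchor minimal 5' aligned block length in nt (default 10).
#' @return Data frame of class `"tail_records"`: `read_id`, `replicon`,
#'   `strand`, `last_matched_position` (0-based reference position of the
#'   read's 3'-terminal aligned base), `anchor_length`, `tail_sequence`.
#' @export
extract_tails <- function(alignments, min_anchor = 10L) {
  no_seq <- alignments$seq == "*"
  if (any(no_seq)) {
    stop("input error: read without sequence: ",
         alignments$read_id[which(no_seq)[1L]])
  }
  n <- nrow(alignments)
  if (n == 0L) {
    return(structure(data.frame(read_id = character(),
                                replicon = character(), strand = character(),
                                last_matched_position = integer(),
                                anchor_length = integer(),
                                tail_sequence = character(),
                                stringsAsFactors = FALSE),
                     class = c("tail_records", "data.frame")))
  }
  ops <- GenomicAlignments::explodeCigarOps(alignments$cigar)
  lens <- GenomicAlignments::explodeCigarOpLengths(alignments$cigar)
  ref_w <- GenomicAlignments::cigarWidthAlongReferenceSpace(alignments$cigar)
  plus <- alignments$strand == "+"

  lead_S <- vapply(seq_len(n), function(i) {
    o <- ops[[i]]; l <- lens[[i]]
    keep <- o != "H"
    o <- o[keep]; l <- l[keep]
    if (length(o) && o[1L] == "S") l[1L] else 0L
  }, integer(1))
  trail_S <- vapply(seq_len(n), function(i) {
    o <- ops[[i]]; l <- lens[[i]]
    keep <- o != "H"
    o <- o[keep]; l <- l[keep]
    if (length(o) && o[length(o)] == "S") l[length(l)] else 0L
  }, integer(1))
  anchor <- vapply(seq_len(n), function(i) {
    o <- ops[[i]]; l <- lens[[i]]
    keep <- o != "H" & o != "S"
    if (plus[i]) {
      .lead_run(o[keep], l[keep])
    } else {
      .lead_run(rev(o[keep]), rev(l[keep]))
    }
  }, integer(1))

  five_clip <- ifelse(plus, lead_S, trail_S)
  tail_len <- ifelse(plus, trail_S, lead_S)
  keep <- five_clip == 0L & anchor >= min_anchor & tail_len >= 1L
  if (!any(keep)) {
    return(extract_tails(alignments[0L, , drop = FALSE], min_anchor))
  }
  a <- alignments[keep, , drop = FALSE]
  plus <- plus[keep]
  tail_len <- tail_len[keep]
  nc <- nchar(a$seq)
  tail_seq <- ifelse(plus,
                     substring(a$seq, nc - tail_len + 1L, nc),
                     substring(a$seq, 1L, tail_len))
  if (any(!plus)) tail_seq[!plus] <- .revcomp(tail_seq[!plus])
  out <- data.frame(
    read_id = a$read_id,
    replicon = a$replicon,
    strand = a$strand,
    last_matched_position = ifelse(plus, a$start + ref_w[keep] - 1L, a$start),
    anchor_length = anchor[keep],
    tail_sequence = tail_seq,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("tail_records", "data.frame")
  out
}

#' Summarize tail lengths and positional base composition
#'
#' @param records a `tail_records` data frame (nonempty).
#' @param max_positions number of tail positions profiled for base
#'   frequencies (default 50).
#' @return List of class `"tail_summary"`: `lengths` (integer vector),
#'   `length_counts` (table), `quantiles` (25/50/75/95%, type-7),
#'   `base_freq` (matrix `max_positions` x `A,C,G,T`; rows sum to 1 where
#'   observed, `NA` beyond the longest tail; N bases are excluded from
#'   the denominators) and `n_records`.
#' @export
summarize_tails <- function(records, max_positions = 50L) {
  if (nrow(records) == 0L) stop("input error: no tail records")
  lens <- nchar(records$tail_sequence)
  bases <- c("A", "C", "G", "T")
  bf <- matrix(NA_real_, nrow = max_positions, ncol = 4L,
               dimnames = list(NULL, bases))
  for (p in seq_len(min(max_positions, max(lens)))) {
    ch <- substring(records$tail_sequence[lens >= p], p, p)
    cnt <- vapply(bases, function(b) sum(ch == b), numeric(1))
    tot <- sum(cnt)  # N excluded
    if (tot > 0) bf[p, ] <- cnt / tot
  }
  structure(list(
    lengths = lens,
    length_counts = table(lens),
    quantiles = stats::quantile(lens, c(0.25, 0.5, 0.75, 0.95), type = 7),
    base_freq = bf,
    n_records = nrow(records)
  ), class = "tail_summary")
}

#' Fraction of tails at most L nucleotides long
#'
#' @param summary a `tail_summary`.
#' @param L length threshold in nt.
#' @return Fraction of tails with length `<= L`.
#' @export
tail_fraction_le <- function(summary, L) {
  mean(summary$lengths <= L)
}
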