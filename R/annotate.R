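#' @title Feature assignment, class summaries and flanking windows
#' @name annotate
#' @description Differential ends are assigned strand-specifically to
#'   annotated features; ends overlapping no feature fall into the
#'   residual class `UTR`. Summaries count ends per (class, direction)
#'   and per gene, and flanking sequence windows are extracted for
#'   external motif and secondary-structure analyses.
NULL

.class_priority <- c(tRNA = 1L, rRNA = 2L, ncRNA = 3L, CDS = 4L, other = 5L)

#' Assign differential ends to features
#'
#' Overlap means nonempty interval intersection on the same strand. All
#' overlapping features are recorded; when several classes overlap, the
#' assigned class follows the priority tRNA > rRNA > ncRNA > CDS > other
#' (stable-RNA genes are short and often nested in mRNA context). Ends
#' with no overlap are classified `UTR`.
#'
#' @param ends a `differential_ends` data frame.
#' @param features a `features` data frame from [read_features()].
#' @return `ends` of class `"annotated_ends"` with added columns
#'   `assigned_class`, `feature_ids` (comma-separated, `""` for UTR) and
#'   list column `assigned_features` (integer indices into `features`).
#' @export
assign_features <- function(ends, features) {
  n <- nrow(ends)
  assigned <- rep(list(integer(0)), n)
  cls <- rep("UTR", n)
  fid <- rep("", n)
  if (n > 0L && nrow(features) > 0L) {
    ge <- GenomicRanges::GRanges(
      ends$replicon,
      IRanges::IRanges(start = ends$start + 1L, end = ends$end),
      strand = ends$strand)
    gf <- GenomicRanges::GRanges(
      features$replicon,
      IRanges::IRanges(start = features$start + 1L, end = features$end),
      strand = features$strand)
    hits <- suppressWarnings(GenomicRanges::findOverlaps(ge, gf))
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    for (i in unique(qh)) {
      f <- sh[qh == i]
      assigned[[i]] <- f
      pr <- .class_priority[features$feature_class[f]]
      cls[i] <- features$feature_class[f][which.min(pr)]
      fid[i] <- paste(features$feature_id[f], collapse = ",")
    }
  }
  out <- ends
  out$assigned_class <- cls
  out$feature_ids <- fid
  out$assigned_features <- assigned
  class(out) <- c("annotated_ends", class(ends))
  out
}

#' Summarize annotated ends by class, direction and gene
#'
#' @param annotated an `annotated_ends` data frame.
#' @param features the `features` data frame used for assignment (supplies
#'   feature lengths for per-kb normalization).
#' @return List of class `"class_summary"`: `class_direction` (integer
#'   matrix, classes x {enriched, depleted}), `per_gene` (data frame
#'   `feature_id`, `n_ends` of enriched ends, `length_nt`,
#'   `ends_per_kb = n_ends * 1000 / length_nt`), `n_ends` total.
#' @export
summarize_classes <- function(annotated, features) {
  classes <- c(names(.class_priority), "UTR")
  cd <- matrix(0L, nrow = length(classes), ncol = 2L,
               dimnames = list(classes, c("enriched", "depleted")))
  for (cl in classes) {
    for (d in c("enriched", "depleted")) {
      cd[cl, d] <- sum(annotated$assigned_class == cl &
                         annotated$direction == d)
    }
  }
  enr <- annotated[annotated$direction == "enriched" &
                     annotated$assigned_class != "UTR", , drop = FALSE]
  per_gene <- data.frame(feature_id = character(), n_ends = integer(),
                         length_nt = integer(), ends_per_kb = numeric(),
                         stringsAsFactors = FALSE)
  if (nrow(enr) > 0L) {
    # each enriched end counts toward one gene: the first feature of its
    # assigned class
    gene <- vapply(seq_len(nrow(enr)), function(i) {
      f <- enr$assigned_features[[i]]
      f <- f[features$feature_class[f] == enr$assigned_class[i]]
      features$feature_id[f[1L]]
    }, character(1))
    tab <- table(gene)
    len <- features$end - features$start
    names(len) <- features$feature_id
    per_gene <- data.frame(
      feature_id = names(tab),
      n_ends = as.integer(tab),
      length_nt = as.integer(len[names(tab)]),
      stringsAsFactors = FALSE)
    per_gene$ends_per_kb <- per_gene$n_ends * 1000 / per_gene$length_nt
    rownames(per_gene) <- NULL
  }
  structure(list(class_direction = cd, per_gene = per_gene,
                 n_ends = nrow(annotated)),
            class = "class_summary")
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Extract flanking sequence windows around differential ends
#'
#' For each end the 3'-terminal position `t` is the 3'-most base of its
#' interval (rightmost on `+`, leftmost on `-`). On `+`, the upstream
#' window of length L is `genome[t-L+1 .. t]` (terminal base included) and
#' the downstream window is `genome[t+1 .. t+L]`, both reported 5'->3'.
#' On `-` the windows are mirrored and reverse-complemented. Windows
#' truncated by a replicon boundary are dropped with a warning.
#'
#' @param ends a `differential_ends` data frame.
#' @param genome FASTA path or `DNAStringSet` named by replicon.
#' @param length window length in nt (>= 1).
#' @param side `"upstream"` or `"downstream"` of the 3' terminus.
#' @param dedupe drop ends whose intervals overlap another end on the same
#'   replicon and strand before extraction (keeps only non-overlapping
#'   ends).
#' @return A `DNAStringSet` named `"<replicon>:<pos>:<strand>:<side><length>"`
#'   where `pos` is the 0-based terminal position.
#' @export
extract_flanks <- function(ends, genome, length,
                           side = c("upstream", "downstream"),
                           dedupe = FALSE) {
  side <- match.arg(side)
  stopifnot(length >= 1)
  length <- as.integer(length)
  genome <- read_genome(genome)
  miss <- setdiff(unique(ends$replicon), names(genome))
  if (base::length(miss) > 0L) {
    stop("reference error: replicon(s) absent from FASTA: ",
         paste(miss, collapse = ", "))
  }
  if (dedupe && nrow(ends) > 1L) {
    gr <- GenomicRanges::GRanges(
      ends$replicon,
      IRanges::IRanges(start = ends$start + 1L, end = ends$end),
      strand = ends$strand)
    ov <- GenomicRanges::countOverlaps(gr, gr)
    ends <- ends[ov == 1L, , drop = FALSE]
  }
  if (nrow(ends) == 0L) return(Biostrings::DNAStringSet())
  plus <- ends$strand == "+"
  t <- ifelse(plus, ends$end - 1L, ends$start)
  if (side == "upstream") {
    ws <- ifelse(plus, t - length + 1L, t)
  } else {
    ws <- ifelse(plus, t + 1L, t - length)
  }
  we <- ws + length  # 0-based half-open
  rlen <- Biostrings::width(genome)[match(ends$replicon, names(genome))]
  ok <- ws >= 0L & we <= rlen
  if (any(!ok)) {
    warning(sum(!ok), " window(s) truncated at replicon boundaries dropped")
  }
  ends <- ends[ok, , drop = FALSE]
  ws <- ws[ok]; we <- we[ok]; t <- t[ok]; plus <- plus[ok]
  if (nrow(ends) == 0L) return(Biostrings::DNAStringSet())
  seqs <- as.character(Biostrings::subseq(
    genome[ends$replicon], start = ws + 1L, end = we))
  seqs[!plus] <- .revcomp(seqs[!plus])
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- sprintf("%s:%d:%s:%s%d", ends$replicon, t, ends$strand,
                        side, length)
  out
}

#' Fraction of unstructured sequences among folding energies
#'
#' Given minimum free energies (kcal/mol) computed by an external folding
#' step, returns the fraction equal to 0.0 within tolerance `1e-9` — the
#' "unstructured" sequences with no predicted base pairing.
#'
#' @param mfe_values numeric vector of MFE values.
#' @return Fraction in `[0, 1]`.
#' @export
unstructured_fraction <- function(mfe_values) {
  if (length(mfe_values) == 0L) stop("input error: empty MFE list")
  mean(abs(mfe_values) <= 1e-9)
}
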