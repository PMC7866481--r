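#' @title SAM, GFF3 and BED input/output
#' @name formats
#' @description Readers and writers bridging the standard flat-file formats
#'   of the pipeline (SAM alignments, GFF3 annotation, BED6 ends, bedGraph
#'   coverage) and the internal data model. All internal coordinates are
#'   0-based half-open; SAM and GFF3 are converted on read, BED is written
#'   natively.
NULL

.as_lines <- function(x) {
  if (length(x) == 1L && !grepl("\n", x, fixed = TRUE) && file.exists(x)) {
    readLines(x)
  } else if (length(x) == 1L && grepl("\n", x, fixed = TRUE)) {
    strsplit(x, "\n", fixed = TRUE)[[1L]]
  } else {
    as.character(x)
  }
}

.field_col <- function(fields, i) vapply(fields, `[[`, character(1L), i)

.field_cols <- function(fields, idx) {
  # fast path for rectangular bodies (constant field count)
  nf <- lengths(fields)
  if (length(fields) > 0L && all(nf == nf[1L])) {
    m <- matrix(unlist(fields, use.names = FALSE), nrow = nf[1L])
    lapply(idx, function(i) m[i, ])
  } else {
    lapply(idx, function(i) .field_col(fields, i))
  }
}

#' Read mapped primary alignments from SAM text
#'
#' Parses SAM (a file path, a single string, or a character vector of
#' lines), keeping only mapped primary alignments. File coordinates are
#' 1-based; the returned `start` is the 0-based leftmost reference position.
#' FLAG bit 0x10 maps to strand `-`. Reference names are validated against
#' the `@SQ` header lines.
#'
#' @param sam SAM input: path, single string with embedded newlines, or
#'   character vector of lines. Must carry a header with `@SQ` lines.
#' @param unique_only drop reads flagged as multi-mappers (an `NH:i:` tag
#'   greater than 1, or MAPQ below `mapq_min` when MAPQ is informative).
#'   Default `TRUE`: the analysis is defined on uniquely aligned reads.
#' @param mapq_min minimal MAPQ for `unique_only`; MAPQ 255 ("unavailable")
#'   is never used to drop a read.
#' @return A `data.frame` of class `"alignments"` with columns `read_id`,
#'   `replicon`, `strand` (`+`/`-`), `start` (0-based), `mapq`, `cigar`,
#'   `seq`, `flag`, plus attribute `replicon_lengths` (named integer from
#'   `@SQ`).
#' @examples
#' sam <- c("@HD\tVN:1.6", "@SQ\tSN:chr\tLN:1000",
#'          "r1\t0\tchr\t101\t60\t75M\t*\t0\t0\t*\t*")
#' aln <- read_alignments(sam)
#' aln$start   # 100: 0-based
#' @export
read_alignments <- function(sam, unique_only = TRUE, mapq_min = 1L) {
  lines <- .as_lines(sam)
  header <- startsWith(lines, "@")
  sq <- lines[startsWith(lines, "@SQ")]
  if (length(sq) == 0L) stop("SAM parse error: no @SQ header lines")
  sn <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
  ln <- suppressWarnings(as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sq)))
  if (anyNA(ln) || any(sn == sq)) stop("SAM parse error: malformed @SQ line")
  replicon_lengths <- stats::setNames(ln, sn)

  body_idx <- which(!header & nzchar(lines))
  if (length(body_idx) == 0L) {
    out <- data.frame(read_id = character(), replicon = character(),
                      strand = character(), start = integer(),
                      mapq = integer(), cigar = character(),
                      seq = character(), flag = integer(),
                      stringsAsFactors = FALSE)
    attr(out, "replicon_lengths") <- replicon_lengths
    class(out) <- c("alignments", "data.frame")
    return(out)
  }
  fields <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11L)) {
    bad <- body_idx[which(nf < 11L)[1L]]
    stop(sprintf("SAM parse error at line %d: fewer than 11 fields", bad))
  }
  cols <- .field_cols(fields, c(1L, 2L, 3L, 4L, 5L, 6L, 10L))
  flag <- suppressWarnings(as.integer(cols[[2L]]))
  pos <- suppressWarnings(as.integer(cols[[4L]]))
  if (anyNA(flag) || anyNA(pos)) {
    bad <- body_idx[which(is.na(flag) | is.na(pos))[1L]]
    stop(sprintf("SAM parse error at line %d: non-numeric FLAG or POS", bad))
  }
  mapq <- suppressWarnings(as.integer(cols[[5L]]))
  aln <- data.frame(
    read_id = cols[[1L]],
    replicon = cols[[3L]],
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    start = pos - 1L,
    mapq = mapq,
    cigar = cols[[6L]],
    seq = cols[[7L]],
    flag = flag,
    stringsAsFactors = FALSE
  )
  line_no <- body_idx

  mapped <- bitwAnd(flag, 4L) == 0L
  primary <- bitwAnd(flag, 256L) == 0L & bitwAnd(flag, 2048L) == 0L
  keep <- mapped & primary
  if (unique_only) {
    nh_hit <- grepl("\tNH:i:", lines[body_idx], fixed = TRUE)
    nh <- rep(NA_integer_, length(body_idx))
    nh[nh_hit] <- as.integer(sub(".*\tNH:i:([0-9]+).*", "\\1",
                                 lines[body_idx][nh_hit]))
    multi <- (!is.na(nh) & nh > 1L) |
      (!is.na(aln$mapq) & aln$mapq != 255L & aln$mapq < mapq_min)
    keep <- keep & !multi
  }
  aln <- aln[keep, , drop = FALSE]
  line_no <- line_no[keep]

  unknown <- !(aln$replicon %in% sn)
  if (any(unknown)) {
    i <- which(unknown)[1L]
    stop(sprintf("SAM reference error at line %d: replicon '%s' not in @SQ",
                 line_no[i], aln$replicon[i]))
  }
  # query-consumption invariant: M/=/X/I/S lengths must sum to SEQ length
  has_seq <- aln$seq != "*"
  if (any(has_seq)) {
    qw <- GenomicAlignments::cigarWidthAlongQuerySpace(aln$cigar[has_seq])
    bad <- qw != nchar(aln$seq[has_seq])
    if (any(bad)) {
      i <- which(has_seq)[which(bad)[1L]]
      stop(sprintf(
        "SAM parse error at line %d: CIGAR query length != SEQ length (%s)",
        line_no[i], aln$read_id[i]))
    }
  }
  rownames(aln) <- NULL
  attr(aln, "replicon_lengths") <- replicon_lengths
  class(aln) <- c("alignments", "data.frame")
  aln
}

#' Default mapping from GFF3 feature types to feature classes
#'
#' GFF3 types absent from the map are classified as `other`.
#' @return Named character vector mapping GFF3 `type` to one of
#'   `CDS`, `tRNA`, `rRNA`, `ncRNA`, `other`.
#' @export
default_class_map <- function() {
  c(CDS = "CDS", tRNA = "tRNA", rRNA = "rRNA",
    ncRNA = "ncRNA", sRNA = "ncRNA", tmRNA = "ncRNA",
    antisense_RNA = "ncRNA", SRP_RNA = "ncRNA", RNase_P_RNA = "ncRNA")
}

#' Read genomic features from GFF3
#'
#' Imports GFF3 (1-based inclusive coordinates) and converts to the
#' internal 0-based half-open convention. Feature types are mapped to the
#' closed class set `{CDS, tRNA, rRNA, ncRNA, other}`; unmapped types
#' become `other`. Features without a strand are a format error, since
#' end assignment is strand-specific.
#'
#' @param gff3 path to a GFF3 file, or a character vector of GFF3 lines.
#' @param class_map named character vector, GFF3 type -> feature class.
#' @return `data.frame` of class `"features"` with columns `feature_id`,
#'   `replicon`, `strand`, `start`, `end` (0-based half-open),
#'   `feature_class`.
#' @export
read_features <- function(gff3, class_map = default_class_map()) {
  path <- if (length(gff3) == 1L && !grepl("\n", gff3, fixed = TRUE) &&
              file.exists(gff3)) {
    gff3
  } else {
    tf <- tempfile(fileext = ".gff3")
    writeLines(.as_lines(gff3), tf)
    tf
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) stop("GFF3 format error: ", conditionMessage(e))
  )
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(strand == "*")) {
    stop("GFF3 format error: feature without strand at line(s) ",
         paste(utils::head(which(strand == "*"), 3L), collapse = ", "))
  }
  type <- as.character(gr$type)
  cls <- unname(class_map[type])
  cls[is.na(cls)] <- "other"
  id <- if (!is.null(gr$ID)) as.character(gr$ID) else rep(NA_character_, length(gr))
  if (!is.null(gr$locus_tag)) {
    lt <- as.character(gr$locus_tag)
    id[is.na(id)] <- lt[is.na(id)]
  }
  miss <- is.na(id) | !nzchar(id)
  id[miss] <- paste0(type[miss], "_", which(miss))
  out <- data.frame(
    feature_id = id,
    replicon = as.character(GenomicRanges::seqnames(gr)),
    strand = strand,
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    feature_class = cls,
    stringsAsFactors = FALSE
  )
  class(out) <- c("features", "data.frame")
  out
}

#' Write differential ends as BED6
#'
#' One line per end: chrom, 0-based start, half-open end, `end_<i>` name,
#' score = mean log2 fold change rendered with 4 decimals, strand. Lines
#' are sorted by (chrom, start).
#'
#' @param ends a `differential_ends` data frame (see [select_and_merge()]).
#' @param path optional output file; when `NULL` the lines are returned.
#' @return Invisibly, the character vector of BED lines.
#' @export
write_ends_bed <- function(ends, path = NULL) {
  if (nrow(ends) == 0L) {
    lines <- character(0)
  } else {
    o <- order(ends$replicon, ends$start)
    e <- ends[o, , drop = FALSE]
    lines <- sprintf("%s\t%d\t%d\tend_%d\t%.4f\t%s",
                     e$replicon, e$start, e$end, seq_len(nrow(e)),
                     e$mean_log2fc, e$strand)
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Re-read a BED6 file of differential ends
#'
#' Round-trip companion of [write_ends_bed()]; only the interval, strand
#' and score columns are recovered.
#' @param bed path or character vector of BED6 lines.
#' @return `data.frame` with `replicon`, `start`, `end`, `name`,
#'   `mean_log2fc`, `strand`.
#' @export
read_ends_bed <- function(bed) {
  lines <- .as_lines(bed)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(replicon = character(), start = integer(),
                      end = integer(), name = character(),
                      mean_log2fc = numeric(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 6L)) stop("BED format error: fewer than 6 fields")
  data.frame(
    replicon = .field_col(f, 1L),
    start = as.integer(.field_col(f, 2L)),
    end = as.integer(.field_col(f, 3L)),
    name = .field_col(f, 4L),
    mean_log2fc = as.numeric(.field_col(f, 5L)),
    strand = .field_col(f, 6L),
    stringsAsFactors = FALSE
  )
}

#' Write a coverage vector as bedGraph
#'
#' Nonzero runs of the per-nucleotide vector are emitted as 0-based
#' half-open intervals.
#' @param values integer vector of per-position coverage.
#' @param replicon replicon name for column 1.
#' @param path optional output file.
#' @return Invisibly, the bedGraph lines.
#' @export
write_bedgraph <- function(values, replicon, path = NULL) {
  r <- rle(as.integer(values))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values != 0L
  lines <- sprintf("%s\t%d\t%d\t%d", replicon, starts[keep], ends[keep],
                   r$values[keep])
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Read genome sequences from FASTA
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] that trims FASTA
#' headers to their first whitespace-delimited token so names match SAM
#' and GFF3 replicon names.
#' @param fasta path to a FASTA file or a `DNAStringSet`.
#' @return A `DNAStringSet` named by replicon.
#' @export
read_genome <- function(fasta) {
  if (methods::is(fasta, "DNAStringSet")) return(fasta)
  g <- Biostrings::readDNAStringSet(fasta)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}
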