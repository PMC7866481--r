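#' @title End-to-end differential end pipeline
#' @name pipeline
#' @description Deterministic composition of the stages: coverage ->
#'   end-count matrix -> count/ratio filtering -> size factors -> NB Wald
#'   test with BH adjustment -> selection and merging -> feature
#'   assignment. Identical inputs yield byte-identical outputs; a run
#'   manifest records inputs, configuration and per-stage row counts.
NULL

.read_sam_input <- function(x, unique_only = TRUE) {
  read_alignments(x, unique_only = unique_only)
}

#' Run the full differential-end pipeline
#'
#' @param sams named list (by library id) of SAM inputs: file paths or
#'   character vectors of SAM lines.
#' @param design data frame with `library_id`, `condition`
#'   (`reference`/`test`), `replicate_index`.
#' @param gff3 GFF3 annotation (path or lines); `NULL` skips annotation.
#' @param fasta genome FASTA (path or `DNAStringSet`); `NULL` takes
#'   replicon lengths from the SAM headers.
#' @param cfg a [filter_config()].
#' @param end_kind `"end3"` (default) or `"end5"` for the mirrored 5'
#'   analysis.
#' @param out_dir optional output directory: writes `ends.bed`,
#'   `positions.tsv` (per-position statistics), `ends_annotated.tsv` and
#'   `manifest.json`.
#' @param unique_only passed to [read_alignments()].
#' @return List of class `"end_pipeline_result"`: `matrix`, `filtered`,
#'   `size_factors`, `results`, `ends`, `annotated` (when `gff3` given),
#'   `manifest`.
#' @examples
#' \donttest{
#' sim <- simulate_dataset(sim_config(
#'   planted = plant_ends(5, c(chr = 20000L), seed = 7),
#'   replicon_lengths = c(chr = 20000L), background_reads = 500L))
#' res <- run_end_pipeline(sim$sam, sim$design)
#' res$ends
#' }
#' @export
run_end_pipeline <- function(sams, design, gff3 = NULL, fasta = NULL,
                             cfg = filter_config(),
                             end_kind = c("end3", "end5"),
                             out_dir = NULL, unique_only = TRUE) {
  end_kind <- match.arg(end_kind)
  if (!setequal(names(sams), design$library_id)) {
    stop("configuration error: SAM names do not match design library ids")
  }
  sams <- sams[design$library_id]
  replicon_lengths <- NULL
  if (!is.null(fasta)) {
    genome <- read_genome(fasta)
    replicon_lengths <- stats::setNames(Biostrings::width(genome),
                                        names(genome))
  }
  full_tracks <- list()
  end_tracks <- list()
  n_reads <- stats::setNames(integer(length(sams)), names(sams))
  for (lib in names(sams)) {
    aln <- .read_sam_input(sams[[lib]], unique_only = unique_only)
    rl <- if (is.null(replicon_lengths)) {
      attr(aln, "replicon_lengths")
    } else {
      replicon_lengths
    }
    full_tracks[[lib]] <- compute_coverage(aln, rl, "full")
    end_tracks[[lib]] <- compute_coverage(aln, rl, end_kind)
    n_reads[lib] <- nrow(aln)
  }
  mat <- build_end_count_matrix(end_tracks)
  filt <- filter_positions(mat, full_tracks, cfg)
  sf <- if (nrow(filt$positions) > 0L) {
    estimate_size_factors(filt)
  } else {
    stats::setNames(rep(1, length(sams)), names(sams))
  }
  res <- test_positions(filt, design, sf)
  ends <- select_and_merge(res, cfg)
  annotated <- NULL
  if (!is.null(gff3)) {
    feats <- read_features(gff3)
    annotated <- assign_features(ends, feats)
  }
  manifest <- list(
    tool = "rnaends",
    version = as.character(utils::packageVersion("rnaends")),
    end_kind = end_kind,
    config = unclass(cfg),
    libraries = as.list(n_reads),
    inputs = if (is.character(sams[[1]]) && length(sams[[1]]) == 1L &&
                 file.exists(sams[[1]][1])) {
      lapply(sams, function(p) list(path = p,
                                    md5 = unname(tools::md5sum(p))))
    } else {
      NULL
    },
    counts = list(
      positions_in = attr(filt, "n_input"),
      after_count_filter = attr(filt, "n_count_pass"),
      after_ratio_filter = nrow(filt$positions),
      significant = sum(abs(res$log2fc) >= cfg$lfc_cutoff &
                          res$padj <= cfg$alpha, na.rm = TRUE),
      merged_ends = nrow(ends)
    )
  )
  out <- list(matrix = mat, filtered = filt, size_factors = sf,
              results = res, ends = ends, annotated = annotated,
              manifest = manifest)
  class(out) <- "end_pipeline_result"
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_ends_bed(ends, file.path(out_dir, "ends.bed"))
    utils::write.table(res, file.path(out_dir, "positions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(annotated)) {
      a <- annotated
      a$assigned_features <- NULL
      utils::write.table(a, file.path(out_dir, "ends_annotated.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out
}

#' @export
print.end_pipeline_result <- function(x, ...) {
  cat("rnaends pipeline result\n")
  cat("  positions in matrix: ", x$manifest$counts$positions_in, "\n")
  cat("  after count filter:  ", x$manifest$counts$after_count_filter, "\n")
  cat("  after ratio filter:  ", x$manifest$counts$after_ratio_filter, "\n")
  cat("  significant:         ", x$manifest$counts$significant, "\n")
  cat("  differential ends:   ", x$manifest$counts$merged_ends, "\n")
  invisible(x)
}
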