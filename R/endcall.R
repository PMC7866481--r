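#' @title Differential end calling: filtering, normalization, testing, merging
#' @name endcall
#' @description The statistical core. Candidate terminus positions are
#'   filtered on minimal end coverage and on the end/full signal ratio,
#'   libraries are normalized with median-of-ratios size factors, each
#'   position is tested for differential terminus abundance with a
#'   two-group negative-binomial Wald test under Benjamini-Hochberg FDR
#'   control, and significant positions are merged into differential ends.
NULL

#' Filtering and calling thresholds
#'
#' Defaults are the study cutoffs: minimal end coverage 10 in at least one
#' library, end/full signal ratio above 0.05 in that same library,
#' |log2 fold change| >= 1, BH-adjusted p <= 0.05, and merging of
#' significant positions within 3 nt of each other.
#'
#' @param min_end_count minimal read-terminus count (default 10).
#' @param min_ratio minimal end/full coverage ratio, exclusive (default 0.05).
#' @param lfc_cutoff minimal |log2 fold change| (default 1).
#' @param alpha BH-adjusted p-value threshold, inclusive (default 0.05).
#' @param merge_distance maximal nucleotide gap between merged significant
#'   positions (default 3).
#' @return A list of class `"filter_config"`.
#' @export
filter_config <- function(min_end_count = 10L, min_ratio = 0.05,
                          lfc_cutoff = 1.0, alpha = 0.05,
                          merge_distance = 3L) {
  stopifnot(min_end_count >= 0, min_ratio >= 0, lfc_cutoff >= 0,
            alpha > 0, alpha < 1, merge_distance >= 0)
  structure(list(min_end_count = as.integer(min_end_count),
                 min_ratio = min_ratio, lfc_cutoff = lfc_cutoff,
                 alpha = alpha, merge_distance = as.integer(merge_distance)),
            class = "filter_config")
}

#' Filter candidate positions on end coverage and signal ratio
#'
#' A position is retained iff there exists a library in which the terminus
#' count is at least `min_end_count` AND the ratio of terminus to full
#' coverage exceeds `min_ratio` (both in that same library). A zero full
#' coverage makes the ratio undefined and fails that library. Row order is
#' preserved.
#'
#' @param matrix an `end_count_matrix`.
#' @param full_tracks named list, library id -> full `coverage_tracks`.
#' @param cfg a [filter_config()].
#' @return The filtered `end_count_matrix`; attributes `n_input` and
#'   `n_count_pass` record the row counts before filtering and after the
#'   count criterion alone (for run manifests).
#' @export
filter_positions <- function(matrix, full_tracks, cfg = filter_config()) {
  full <- coverage_at_positions(matrix, full_tracks)
  cnt <- matrix$counts
  count_ok <- cnt >= cfg$min_end_count
  # full = 0 makes the ratio undefined and fails that library
  ratio_ok <- full > 0 & (cnt / ifelse(full > 0, full, Inf)) > cfg$min_ratio
  keep_count <- rowSums(count_ok) > 0
  keep <- rowSums(count_ok & ratio_ok) > 0
  out <- list(positions = matrix$positions[keep, , drop = FALSE],
              counts = matrix$counts[keep, , drop = FALSE],
              library_ids = matrix$library_ids)
  rownames(out$positions) <- NULL
  attr(out, "n_input") <- nrow(matrix$positions)
  attr(out, "n_count_pass") <- sum(keep_count)
  class(out) <- "end_count_matrix"
  out
}

#' Median-of-ratios size factors
#'
#' For each library j, `s_j` is the median over positions i (restricted to
#' rows where every library has a positive count, so the geometric mean is
#' positive) of `counts[i,j] / geomean_i`. When no such row exists the
#' estimate falls back, with a warning, to library totals scaled to unit
#' geometric mean.
#'
#' @param matrix an `end_count_matrix` or a bare counts matrix.
#' @return Named numeric vector of positive size factors, one per library.
#' @export
estimate_size_factors <- function(matrix) {
  counts <- if (inherits(matrix, "end_count_matrix")) matrix$counts else matrix
  counts <- as.matrix(counts)
  if (ncol(counts) < 1L) stop("input error: no libraries")
  pos_rows <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos_rows)) {
    warning("no position with all-positive counts; ",
            "falling back to library-total normalization")
    tot <- colSums(counts)
    if (any(tot == 0)) stop("input error: library with zero total count")
    s <- tot / exp(mean(log(tot)))
    return(stats::setNames(s, colnames(counts)))
  }
  sub <- counts[pos_rows, , drop = FALSE]
  geo <- exp(rowMeans(log(sub)))
  s <- apply(sub / geo, 2L, stats::median)
  stats::setNames(s, colnames(counts))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up procedure with enforced monotonicity; input order is
#' preserved.
#'
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values in input order.
#' @export
adjust_bh <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("input error: p-values must lie in [0, 1]")
  }
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

#' Position-wise negative-binomial Wald test
#'
#' Counts are normalized by size factors; per position, condition means
#' `mu_ref` and `mu_test` give `log2fc = log2((mu_test + 0.5)/(mu_ref + 0.5))`.
#' The NB dispersion is estimated per position by method of moments on the
#' normalized counts pooled across conditions (deviations from the
#' condition means, pooled variance with `n - 2` degrees of freedom),
#' floored at `1e-8`. The Wald statistic `z = log2fc / SE`, with the SE
#' from the delta method on the NB variance `mu + dispersion * mu^2`, is
#' referred to a t distribution with `n_ref + n_test - 2` degrees of
#' freedom — a small-sample correction over the asymptotic normal tail
#' that restores type-I calibration at 3-vs-3 replication (see the
#' methods vignette). BH adjustment is applied across all tested
#' positions.
#'
#' @param matrix an `end_count_matrix` (typically filtered).
#' @param design data frame with columns `library_id`,
#'   `condition` (`"reference"`/`"test"`), `replicate_index`; at least two
#'   replicates per condition.
#' @param factors size factors named by library; `NULL` estimates them
#'   from `matrix` via [estimate_size_factors()].
#' @param dispersion optional fixed NB dispersion used for every position
#'   instead of the moment estimate (e.g. `1e-8` for a Poisson limit).
#' @return Data frame of class `"position_tests"`: position key columns
#'   plus `basemean`, `log2fc`, `p`, `padj`, in input row order.
#' @export
test_positions <- function(matrix, design, factors = NULL,
                           dispersion = NULL) {
  stopifnot(inherits(matrix, "end_count_matrix"))
  if (!all(c("library_id", "condition") %in% names(design))) {
    stop("design error: need library_id and condition columns")
  }
  if (!all(design$condition %in% c("reference", "test"))) {
    stop("design error: condition must be 'reference' or 'test'")
  }
  if (anyDuplicated(design$library_id)) {
    stop("design error: duplicate library ids")
  }
  if (!setequal(design$library_id, matrix$library_ids)) {
    stop("design error: design libraries do not match matrix columns")
  }
  nA <- sum(design$condition == "reference")
  nB <- sum(design$condition == "test")
  if (nA < 2L || nB < 2L) {
    stop("design error: need at least two replicates per condition")
  }
  counts <- matrix$counts[, design$library_id, drop = FALSE]
  if (any(counts != round(counts))) {
    stop("input error: counts must be integers")
  }
  if (is.null(factors)) factors <- estimate_size_factors(matrix)
  factors <- factors[design$library_id]
  if (anyNA(factors) || any(factors <= 0)) {
    stop("input error: size factors must be positive and cover all libraries")
  }
  res <- cbind(matrix$positions,
               data.frame(basemean = numeric(nrow(counts)),
                          log2fc = numeric(nrow(counts)),
                          p = numeric(nrow(counts)),
                          padj = numeric(nrow(counts))))
  if (nrow(counts) == 0L) {
    class(res) <- c("position_tests", "data.frame")
    return(res)
  }
  norm <- sweep(counts, 2L, factors, "/")
  idxA <- which(design$condition == "reference")
  idxB <- which(design$condition == "test")
  muA <- rowMeans(norm[, idxA, drop = FALSE])
  muB <- rowMeans(norm[, idxB, drop = FALSE])
  cc <- 0.5
  log2fc <- log2((muB + cc) / (muA + cc))
  if (is.null(dispersion)) {
    ssq <- rowSums((norm[, idxA, drop = FALSE] - muA)^2) +
      rowSums((norm[, idxB, drop = FALSE] - muB)^2)
    s2 <- ssq / (nA + nB - 2)
    mbar <- rowMeans(norm)
    disp <- pmax((s2 - mbar) / mbar^2, 1e-8)
    disp[!is.finite(disp)] <- 1e-8
  } else {
    disp <- rep(dispersion, nrow(norm))
  }
  vA <- (muA + disp * muA^2) / nA
  vB <- (muB + disp * muB^2) / nB
  se <- sqrt(vA / (muA + cc)^2 + vB / (muB + cc)^2) / log(2)
  z <- ifelse(se > 0, log2fc / se, 0)
  p <- 2 * stats::pt(-abs(z), df = nA + nB - 2)
  res$basemean <- rowMeans(norm)
  res$log2fc <- log2fc
  res$p <- p
  res$padj <- adjust_bh(p)
  class(res) <- c("position_tests", "data.frame")
  res
}

#' Select significant positions and merge them into differential ends
#'
#' Significance requires `|log2fc| >= lfc_cutoff` and `padj <= alpha`.
#' Per (replicon, strand), significant single-nucleotide positions `p < q`
#' merge transitively whenever `q - p - 1 <= merge_distance`. Each merged
#' end records its span (`distribution_size`), member count, arithmetic
#' mean log2 fold change, direction by the sign of that mean, and a
#' `mixed_sign` flag when members disagree in sign. Positions with
#' undefined `padj` are dropped with a warning.
#'
#' @param results a `position_tests` data frame.
#' @param cfg a [filter_config()].
#' @return Data frame of class `"differential_ends"` with columns
#'   `replicon`, `start`, `end` (0-based half-open), `strand`,
#'   `distribution_size`, `n_positions`, `mean_log2fc`, `direction`,
#'   `mixed_sign`, sorted by (replicon, start, strand).
#' @export
select_and_merge <- function(results, cfg = filter_config()) {
  empty <- data.frame(replicon = character(), start = integer(),
                      end = integer(), strand = character(),
                      distribution_size = integer(), n_positions = integer(),
                      mean_log2fc = numeric(), direction = character(),
                      mixed_sign = logical(), stringsAsFactors = FALSE)
  class(empty) <- c("differential_ends", "data.frame")
  if (nrow(results) == 0L) return(empty)
  bad <- !is.finite(results$padj) | !is.finite(results$log2fc)
  if (any(bad)) {
    warning(sum(bad), " position(s) with undefined statistics dropped")
    results <- results[!bad, , drop = FALSE]
  }
  sig <- abs(results$log2fc) >= cfg$lfc_cutoff & results$padj <= cfg$alpha
  results <- results[sig, , drop = FALSE]
  if (nrow(results) == 0L) return(empty)
  gr <- GenomicRanges::GRanges(
    seqnames = results$replicon,
    ranges = IRanges::IRanges(start = results$pos + 1L, width = 1L),
    strand = results$strand)
  red <- GenomicRanges::reduce(gr, min.gapwidth = cfg$merge_distance + 1L,
                               with.revmap = TRUE)
  revmap <- S4Vectors::mcols(red)$revmap
  mean_lfc <- vapply(revmap, function(i) mean(results$log2fc[i]), numeric(1))
  n_pos <- S4Vectors::elementNROWS(revmap)
  mixed <- vapply(revmap, function(i) {
    s <- sign(results$log2fc[i])
    any(s > 0) && any(s < 0)
  }, logical(1))
  out <- data.frame(
    replicon = as.character(GenomicRanges::seqnames(red)),
    start = BiocGenerics::start(red) - 1L,
    end = BiocGenerics::end(red),
    strand = as.character(BiocGenerics::strand(red)),
    distribution_size = BiocGenerics::width(red),
    n_positions = n_pos,
    mean_log2fc = mean_lfc,
    direction = ifelse(mean_lfc >= 0, "enriched", "depleted"),
    mixed_sign = mixed,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$replicon, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("differential_ends", "data.frame")
  out
}
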