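#' @title Comparing end sets across mutants
#' @name intersect
#' @description Differential-end sets from two mutant-vs-wildtype analyses
#'   are matched with a symmetric window, matched pairs are classified into
#'   fold-change sign quadrants, and overlap enrichment is tested with a
#'   two-tailed Fisher's exact test against the number of possible ends
#'   the genome could host.
NULL

.quadrant <- function(lfc_A, lfc_B) {
  paste0("A", ifelse(lfc_A >= 0, "+", "-"),
         "B", ifelse(lfc_B >= 0, "+", "-"))
}

#' Windowed matching of two end sets
#'
#' Intervals of set A are extended by `window` nt on both sides; a match
#' is any same-strand overlap (half-open semantics) with a set-B interval.
#' All pairs are reported together with distinct-end counts, supporting
#' both "total" and "unique" overlap reporting.
#'
#' @param set_A,set_B `differential_ends` data frames.
#' @param window symmetric extension of A in nt (default 1).
#' @return List of class `"end_matches"`: `matches` (data frame `idx_A`,
#'   `idx_B`, `lfc_A`, `lfc_B`, `quadrant`), `n_pairs`, `unique_A`,
#'   `unique_B`, `n_A`, `n_B`, `window`.
#' @export
window_match <- function(set_A, set_B, window = 1L) {
  if (window < 0) stop("input error: window must be non-negative")
  window <- as.integer(window)
  matches <- data.frame(idx_A = integer(), idx_B = integer(),
                        lfc_A = numeric(), lfc_B = numeric(),
                        quadrant = character(), stringsAsFactors = FALSE)
  if (nrow(set_A) > 0L && nrow(set_B) > 0L) {
    ga <- GenomicRanges::GRanges(
      set_A$replicon,
      IRanges::IRanges(start = pmax(set_A$start + 1L - window, 1L),
                       end = set_A$end + window),
      strand = set_A$strand)
    gb <- GenomicRanges::GRanges(
      set_B$replicon,
      IRanges::IRanges(start = set_B$start + 1L, end = set_B$end),
      strand = set_B$strand)
    hits <- suppressWarnings(GenomicRanges::findOverlaps(ga, gb))
    ia <- S4Vectors::queryHits(hits)
    ib <- S4Vectors::subjectHits(hits)
    matches <- data.frame(
      idx_A = ia, idx_B = ib,
      lfc_A = set_A$mean_log2fc[ia], lfc_B = set_B$mean_log2fc[ib],
      quadrant = character(length(ia)), stringsAsFactors = FALSE)
    if (nrow(matches) > 0L) {
      matches$quadrant <- .quadrant(matches$lfc_A, matches$lfc_B)
    }
  }
  structure(list(matches = matches,
                 n_pairs = nrow(matches),
                 unique_A = length(unique(matches$idx_A)),
                 unique_B = length(unique(matches$idx_B)),
                 n_A = nrow(set_A), n_B = nrow(set_B), window = window),
            class = "end_matches")
}

#' Quadrant counts and percentages of matched pairs
#'
#' Quadrants partition matched pairs by the signs of the two fold changes
#' (`A+B+`, `A+B-`, `A-B+`, `A-B-`). Percentages divide each quadrant's
#' distinct-B count by the total number of set-B ends of that direction
#' (taken from `set_B` when given, else from the matched B ends).
#'
#' @param matches an `end_matches` object.
#' @param set_B optional `differential_ends` frame supplying total B
#'   direction counts.
#' @return List with `counts` (named integer, pairs per quadrant) and
#'   `percent` (named numeric, distinct-B percentage per quadrant).
#' @export
quadrant_counts <- function(matches, set_B = NULL) {
  quads <- c("A+B+", "A+B-", "A-B+", "A-B-")
  m <- matches$matches
  counts <- vapply(quads, function(q) sum(m$quadrant == q), integer(1))
  if (!is.null(set_B)) {
    tot_plus <- sum(set_B$mean_log2fc >= 0)
    tot_minus <- sum(set_B$mean_log2fc < 0)
  } else {
    bsign <- tapply(m$lfc_B >= 0, m$idx_B, any)
    tot_plus <- sum(bsign)
    tot_minus <- sum(!bsign)
  }
  pct <- vapply(quads, function(q) {
    nb <- length(unique(m$idx_B[m$quadrant == q]))
    tot <- if (endsWith(q, "B+")) tot_plus else tot_minus
    if (tot == 0L) return(NA_real_)
    100 * nb / tot
  }, numeric(1))
  list(counts = counts, percent = pct)
}

#' Number of possible ends the genome could host
#'
#' `floor(genome_length / (mean_width_A + mean_width_B))` with widths the
#' distribution sizes of the two sets and `genome_length` the summed
#' single-strand replicon lengths — mirroring how interval-overlap
#' enrichment tools size their sampling universe.
#'
#' @param genome_length total replicon length in nt (single strand).
#' @param set_A,set_B nonempty `differential_ends` data frames.
#' @return Integer universe size.
#' @export
estimate_universe <- function(genome_length, set_A, set_B) {
  if (nrow(set_A) == 0L || nrow(set_B) == 0L) {
    stop("input error: both end sets must be nonempty")
  }
  mw_A <- mean(set_A$end - set_A$start)
  mw_B <- mean(set_B$end - set_B$start)
  as.integer(floor(genome_length / (mw_A + mw_B)))
}

.n_components <- function(ia, ib) {
  # connected components of the bipartite match graph (union-find)
  if (length(ia) == 0L) return(0L)
  a_id <- match(ia, unique(ia))
  b_id <- max(a_id) + match(ib, unique(ib))
  parent <- seq_len(max(b_id))
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (k in seq_along(a_id)) {
    ra <- find(a_id[k]); rb <- find(b_id[k])
    if (ra != rb) parent[rb] <- ra
  }
  roots <- vapply(c(unique(a_id), unique(b_id)), find, integer(1))
  length(unique(roots))
}

#' Build the 2x2 overlap table for Fisher's exact test
#'
#' Matched pairs are collapsed to distinct overlap events (connected
#' components of the bipartite match graph, so one event never exceeds
#' `min(n_A, n_B)`). The table is `(overlap, A-only, B-only, neither)`
#' with `neither = universe - overlap - A_only - B_only`, summing to the
#' universe.
#'
#' @param matches an `end_matches` object.
#' @param universe integer from [estimate_universe()].
#' @return 2x2 integer matrix `rbind(c(overlap, A_only), c(B_only, neither))`.
#' @export
overlap_table <- function(matches, universe) {
  n_overlap <- .n_components(matches$matches$idx_A, matches$matches$idx_B)
  a_only <- matches$n_A - matches$unique_A
  b_only <- matches$n_B - matches$unique_B
  neither <- universe - n_overlap - a_only - b_only
  if (neither < 0L) stop("input error: universe smaller than the end sets")
  matrix(as.integer(c(n_overlap, a_only, b_only, neither)),
         nrow = 2L, byrow = TRUE,
         dimnames = list(c("in_A", "not_A"), c("in_B", "not_B")))
}

#' Two-tailed Fisher's exact test on a 2x2 table
#'
#' The two-tailed p-value sums, over the hypergeometric support, the
#' probabilities of all tables at most as probable as the observed one
#' (relative tolerance `1e-7` on the comparison). The sum is accumulated
#' in log space, so the log10 p-value stays exact even when `p` itself
#' underflows below ~1e-300.
#'
#' @param table 2x2 matrix of non-negative integers, or a length-4 vector
#'   read row-wise.
#' @return List of class `"fisher_result"` with `p` (0 when underflowed)
#'   and `log10_p`.
#' @export
fisher_two_tail <- function(table) {
  x <- as.vector(t(as.matrix(table)))
  if (length(x) != 4L || any(x < 0) || any(x != round(x))) {
    stop("input error: table must be four non-negative integers")
  }
  a <- x[1]; b <- x[2]; cc <- x[3]; d <- x[4]
  m1 <- a + b   # row-1 margin ("white")
  m2 <- cc + d  # row-2 margin ("black")
  k <- a + cc   # column-1 margin (drawn)
  support <- max(0, k - m2):min(k, m1)
  lp <- stats::dhyper(support, m1, m2, k, log = TRUE)
  lobs <- stats::dhyper(a, m1, m2, k, log = TRUE)
  keep <- lp <= lobs + log1p(1e-7)
  lk <- lp[keep]
  mx <- max(lk)
  log_p <- mx + log(sum(exp(lk - mx)))
  log_p <- min(log_p, 0)
  structure(list(p = exp(log_p), log10_p = log_p / log(10)),
            class = "fisher_result")
}

#' Full intersection summary of two end sets
#'
#' Convenience wrapper running [window_match()], [quadrant_counts()],
#' [estimate_universe()], [overlap_table()] and [fisher_two_tail()].
#'
#' @param set_A,set_B `differential_ends` data frames.
#' @param genome_length summed replicon length in nt.
#' @param window matching window in nt (default 1).
#' @return List of class `"intersection_summary"` with elements `matches`,
#'   `quadrants`, `universe`, `table`, `fisher` and the scalar counts
#'   `n_A`, `n_B`, `pairs`, `unique_A`, `unique_B`.
#' @export
intersect_end_sets <- function(set_A, set_B, genome_length, window = 1L) {
  m <- window_match(set_A, set_B, window)
  q <- quadrant_counts(m, set_B)
  u <- estimate_universe(genome_length, set_A, set_B)
  tab <- overlap_table(m, u)
  f <- fisher_two_tail(tab)
  structure(list(matches = m, quadrants = q, universe = u, table = tab,
                 fisher = f, n_A = m$n_A, n_B = m$n_B, pairs = m$n_pairs,
                 unique_A = m$unique_A, unique_B = m$unique_B),
            class = "intersection_summary")
}
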