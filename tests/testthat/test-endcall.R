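make_full_tracks <- function(full_mat, positions, glen = 10000L) {
  # build per-library full coverage_tracks holding the given values at the
  # matrix positions
  libs <- colnames(full_mat)
  out <- lapply(seq_along(libs), function(j) {
    tr <- list(chr = list(`+` = integer(glen), `-` = integer(glen)))
    for (i in seq_len(nrow(positions))) {
      tr[[positions$replicon[i]]][[positions$strand[i]]][positions$pos[i] + 1L] <-
        full_mat[i, j]
    }
    attr(tr, "kind") <- "full"
    class(tr) <- "coverage_tracks"
    tr
  })
  names(out) <- libs
  out
}

test_that("count and ratio filters implement the there-exists semantics", {
  cnt <- rbind(c(9L, 9L),      # below min count everywhere -> rejected
               c(12L, 5L),     # count passes lib1 only; ratio 0.04 -> rejected
               c(12L, 5L),     # count passes lib1, ratio 0.12 -> retained
               c(5L, 40L),     # joint pass in lib2 -> retained
               c(15L, 0L))     # full = 0 in lib1; lib2 below count -> rejected
  colnames(cnt) <- c("L1", "L2")
  full <- rbind(c(100L, 100L),
                c(300L, 100L),
                c(100L, 100L),
                c(100L, 100L),
                c(0L, 100L))
  colnames(full) <- colnames(cnt)
  m <- make_matrix(cnt)
  ft <- make_full_tracks(full, m$positions)
  out <- filter_positions(m, ft)
  expect_equal(out$positions$pos, m$positions$pos[c(3, 4)])
  expect_equal(attr(out, "n_input"), 5L)
  expect_equal(attr(out, "n_count_pass"), 4L)
})

test_that("count/ratio criteria must pass jointly in a single library", {
  # count passes only in lib1, ratio passes only in lib2 -> rejected
  cnt <- matrix(c(12L, 4L), nrow = 1L,
                dimnames = list(NULL, c("L1", "L2")))
  full <- matrix(c(1000L, 10L), nrow = 1L,
                 dimnames = list(NULL, c("L1", "L2")))
  m <- make_matrix(cnt)
  out <- filter_positions(m, make_full_tracks(full, m$positions))
  expect_equal(nrow(out$positions), 0L)
})

test_that("filtering is monotone in both thresholds", {
  set.seed(301)
  cnt <- matrix(rnbinom(600L, mu = 15, size = 2), ncol = 6L,
                dimnames = list(NULL, paste0("L", 1:6)))
  full <- cnt + matrix(rpois(600L, 150), ncol = 6L)
  m <- make_matrix(cnt)
  ft <- make_full_tracks(full, m$positions)
  kept <- function(cfg) {
    filter_positions(m, ft, cfg)$positions$pos
  }
  base <- kept(filter_config())
  expect_true(all(kept(filter_config(min_end_count = 15)) %in% base))
  expect_true(all(kept(filter_config(min_ratio = 0.10)) %in% base))
})

test_that("size factors follow the median-of-ratios formula", {
  a <- c(10L, 20L, 40L, 80L)
  m <- cbind(L1 = a, L2 = 2L * a)
  expect_equal(unname(estimate_size_factors(m)), c(1 / sqrt(2), sqrt(2)))
  ident <- cbind(L1 = a, L2 = a, L3 = a)
  expect_equal(unname(estimate_size_factors(ident)), rep(1, 3))
})

test_that("size factors equal the direct oracle on a random NB matrix", {
  set.seed(302)
  m <- matrix(rnbinom(6L * 400L, mu = 80, size = 5), ncol = 6L,
              dimnames = list(NULL, paste0("L", 1:6)))
  expect_equal(unname(estimate_size_factors(m)),
               unname(size_factor_oracle(m)), tolerance = 1e-12)
})

test_that("size factors fall back to library totals with a warning", {
  m <- cbind(L1 = c(4L, 0L), L2 = c(0L, 16L))
  expect_warning(s <- estimate_size_factors(m), "falling back")
  expect_equal(unname(s), c(4, 16) / exp(mean(log(c(4, 16)))))
})

test_that("BH adjustment matches textbook step-up exactly", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(0.73), 0.73)
  set.seed(303)
  p <- runif(500L)
  expect_equal(adjust_bh(p), bh_oracle(p))
  expect_equal(adjust_bh(p), p.adjust(p, "BH"))
  expect_error(adjust_bh(c(0.5, 1.2)), "input error")
})

std_design <- function() {
  data.frame(library_id = paste0("L", 1:6),
             condition = rep(c("reference", "test"), each = 3L),
             replicate_index = rep(1:3, 2L), stringsAsFactors = FALSE)
}

test_that("identical conditions give log2fc 0 and p 1", {
  cnt <- matrix(rep(c(10L, 20L, 30L), 2L), nrow = 1L,
                dimnames = list(NULL, paste0("L", 1:6)))
  res <- test_positions(make_matrix(cnt), std_design(),
                        factors = setNames(rep(1, 6), paste0("L", 1:6)))
  expect_equal(res$log2fc, 0)
  expect_equal(res$p, 1)
})

test_that("the Poisson limit agrees with an independent Wald oracle", {
  set.seed(304)
  n <- 200L
  cnt <- matrix(rpois(n * 6L, 500), ncol = 6L,
                dimnames = list(NULL, paste0("L", 1:6)))
  sf <- setNames(rep(1, 6), paste0("L", 1:6))
  res <- test_positions(make_matrix(cnt), std_design(), factors = sf,
                        dispersion = 1e-12)
  # oracle: Poisson-variance Wald with the same t reference
  muA <- rowMeans(cnt[, 1:3]); muB <- rowMeans(cnt[, 4:6])
  lfc <- log2((muB + 0.5) / (muA + 0.5))
  se <- sqrt((muA / 3) / (muA + 0.5)^2 + (muB / 3) / (muB + 0.5)^2) / log(2)
  p_oracle <- 2 * pt(-abs(lfc / se), df = 4)
  expect_equal(res$log2fc, lfc, tolerance = 1e-12)
  expect_lt(max(abs(res$p - p_oracle)), 1e-6)
})

test_that("swapping condition labels negates log2fc and keeps p", {
  set.seed(305)
  cnt <- matrix(rnbinom(100L * 6L, mu = 60, size = 5), ncol = 6L,
                dimnames = list(NULL, paste0("L", 1:6)))
  sf <- setNames(rep(1, 6), paste0("L", 1:6))
  d1 <- std_design()
  d2 <- d1
  d2$condition <- rev(d1$condition)
  r1 <- test_positions(make_matrix(cnt), d1, factors = sf)
  r2 <- test_positions(make_matrix(cnt), d2, factors = sf)
  expect_equal(r1$log2fc, -r2$log2fc)
  expect_equal(r1$p, r2$p)
})

test_that("scaling one library's counts is absorbed by its size factor", {
  set.seed(306)
  cnt <- matrix(rnbinom(300L * 6L, mu = 500, size = 20), ncol = 6L,
                dimnames = list(NULL, paste0("L", 1:6)))
  m1 <- make_matrix(cnt)
  cnt2 <- cnt
  cnt2[, 1] <- cnt2[, 1] * 3L
  m2 <- make_matrix(cnt2)
  s1 <- estimate_size_factors(m1)
  s2 <- estimate_size_factors(m2)
  # scaling library 1 by 3 rescales every row's geometric mean by 3^(1/6),
  # so median-of-ratios moves its factor by 3^(5/6) and the others by
  # 3^(-1/6); normalized counts shift by a common 3^(1/6) and every
  # log2fc is invariant up to the continuity constant's second-order
  # effect at these large means
  expect_equal(s2[["L1"]] / s1[["L1"]], 3^(5 / 6), tolerance = 1e-9)
  expect_equal(unname(s2[-1] / s1[-1]), rep(3^(-1 / 6), 5),
               tolerance = 1e-9)
  r1 <- test_positions(m1, std_design(), factors = s1)
  r2 <- test_positions(m2, std_design(), factors = s2)
  expect_equal(r1$log2fc, r2$log2fc, tolerance = 1e-3)
})

test_that("design and input validation errors fire", {
  cnt <- matrix(1:8, nrow = 2L, dimnames = list(NULL, paste0("L", 1:4)))
  d <- data.frame(library_id = paste0("L", 1:4),
                  condition = c("reference", rep("test", 3L)),
                  replicate_index = c(1L, 1:3))
  expect_error(test_positions(make_matrix(cnt), d),
               "two replicates per condition")
  cnt2 <- matrix(c(1.5, rep(1, 11)), nrow = 2L,
                 dimnames = list(NULL, paste0("L", 1:6)))
  expect_error(test_positions(make_matrix(cnt2), std_design()),
               "counts must be integers")
})

res_frame <- function(pos, lfc, padj, strand = "+", replicon = "chr") {
  data.frame(replicon = replicon, pos = as.integer(pos), strand = strand,
             basemean = 100, log2fc = lfc, p = padj, padj = padj,
             stringsAsFactors = FALSE)
}

test_that("significant positions merge by the 3-nt gap rule", {
  res <- res_frame(c(100L, 102L, 106L), c(6, 4, 5), 1e-4)
  out <- select_and_merge(res)
  expect_equal(nrow(out), 1L)
  expect_equal(out$start, 100L)
  expect_equal(out$end, 107L)
  expect_equal(out$distribution_size, 7L)
  expect_equal(out$n_positions, 3L)
  expect_equal(out$mean_log2fc, 5)
  expect_equal(out$direction, "enriched")
  # gap of 4 nt does not merge
  out2 <- select_and_merge(res_frame(c(100L, 105L), c(3, 3), 1e-4))
  expect_equal(out2$distribution_size, c(1L, 1L))
  expect_equal(nrow(out2), 2L)
})

test_that("selection applies both the LFC and padj thresholds", {
  res <- res_frame(c(10L, 20L, 30L, 40L),
                   c(0.9, 1.0, -5, 2), c(0.01, 0.05, 0.06, 0.01))
  out <- select_and_merge(res)
  expect_equal(out$start, c(20L, 40L))  # |lfc|>=1 & padj<=0.05 only
})

test_that("1000 random significant positions match the union-find oracle", {
  set.seed(307)
  pos <- sort(sample.int(20000L, 1000L))
  lfc <- sample(c(-1, 1), 1000L, TRUE) * runif(1000L, 1, 8)  # all significant
  res <- res_frame(pos, lfc, 1e-6)
  out <- select_and_merge(res)
  oracle <- merge_oracle(pos, lfc, gap = 3L)
  expect_equal(out$start, oracle$start)
  expect_equal(out$end, oracle$end)
  expect_equal(out$n_positions, oracle$n)
  expect_equal(out$mean_log2fc, oracle$mean_lfc)
  # ends pairwise separated by gap > 3 and idempotent under re-merge
  expect_true(all(out$start[-1] - out$end[-nrow(out)] > 3L))
  gr <- GenomicRanges::GRanges("chr",
                               IRanges::IRanges(out$start + 1L, out$end),
                               strand = "+")
  red <- GenomicRanges::reduce(gr, min.gapwidth = 4L)
  expect_equal(length(red), nrow(out))
  expect_equal(BiocGenerics::start(red) - 1L, out$start)
})

test_that("merging is strand- and replicon-separated and flags mixed signs", {
  res <- rbind(res_frame(100L, 5, 1e-4, strand = "+"),
               res_frame(101L, 5, 1e-4, strand = "-"),
               res_frame(c(200L, 202L), c(4, -4), 1e-4, strand = "+"))
  out <- select_and_merge(res)
  expect_equal(nrow(out), 3L)  # +100, -101, +[200,203)
  mixed <- out[out$start == 200L, ]
  expect_true(mixed$mixed_sign)
  expect_equal(mixed$mean_log2fc, 0)
})

test_that("positions with undefined statistics are dropped with a warning", {
  res <- res_frame(c(100L, 200L), c(5, NaN), c(1e-4, NaN))
  expect_warning(out <- select_and_merge(res), "dropped")
  expect_equal(out$start, 100L)
})
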