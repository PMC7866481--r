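# Shared fixtures and independent oracles. Oracles deliberately use naive,
# direct computations so they stay independent of the code paths they check.

sam_rec <- function(qname, flag, rname, pos1, cigar, seq = "*",
                    mapq = 255L, tags = character(0)) {
  line <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
                  qname, flag, rname, pos1, mapq, cigar, seq)
  if (length(tags)) line <- paste(c(line, tags), collapse = "\t")
  line
}

make_sam <- function(records, sq = c(chr = 1000L)) {
  c("@HD\tVN:1.6",
    sprintf("@SQ\tSN:%s\tLN:%d", names(sq), sq),
    records)
}

rand_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

revcomp_oracle <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# minimal differential_ends constructor for annotate/intersect tests
make_ends <- function(replicon, start, end, strand, lfc) {
  out <- data.frame(replicon = replicon, start = as.integer(start),
                    end = as.integer(end), strand = strand,
                    distribution_size = as.integer(end - start),
                    n_positions = 1L, mean_log2fc = lfc,
                    direction = ifelse(lfc >= 0, "enriched", "depleted"),
                    mixed_sign = FALSE, stringsAsFactors = FALSE)
  class(out) <- c("differential_ends", "data.frame")
  out
}

# end_count_matrix constructor from a bare counts matrix
make_matrix <- function(counts, replicon = "chr", strand = "+") {
  counts <- as.matrix(counts)
  pos <- data.frame(replicon = replicon,
                    pos = seq_len(nrow(counts)) * 10L,
                    strand = strand, stringsAsFactors = FALSE)
  out <- list(positions = pos, counts = counts,
              library_ids = colnames(counts))
  class(out) <- "end_count_matrix"
  out
}

# textbook step-up BH: sort ascending, q_i = min_{j>=i} p_j * n / j
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) if (n > 1) q[i] <- min(q[i], q[i + 1])
  pmin(1, q)[order(o)]
}

# union-find merge of single-nt positions: p < q chain iff q - p - 1 <= gap
merge_oracle <- function(pos, lfc, gap = 3L) {
  o <- order(pos)
  pos <- pos[o]; lfc <- lfc[o]
  grp <- cumsum(c(1L, diff(pos) - 1L > gap))
  do.call(rbind, lapply(split(seq_along(pos), grp), function(i) {
    data.frame(start = min(pos[i]), end = max(pos[i]) + 1L,
               n = length(i), mean_lfc = mean(lfc[i]))
  }))
}

# full hypergeometric enumeration of the two-tailed Fisher p
fisher_oracle <- function(a, b, c_, d) {
  m1 <- a + b; m2 <- c_ + d; k <- a + c_
  support <- max(0, k - m2):min(k, m1)
  pr <- dhyper(support, m1, m2, k)
  obs <- dhyper(a, m1, m2, k)
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# direct median-of-ratios
size_factor_oracle <- function(counts) {
  geo <- apply(counts, 1, function(r) exp(mean(log(r))))
  keep <- geo > 0 & is.finite(geo)
  apply(counts, 2, function(cj) median(cj[keep] / geo[keep]))
}

# Small seeded end-to-end fixture: 8 differential and 16 unchanged planted
# ends on a 30 kb replicon. Unchanged termination ends anchor the
# median-of-ratios normalization, as in real end-enriched libraries.
pipeline_fixture <- function() {
  de <- plant_ends(8L, c(chr = 30000L), log2_effect = rep(c(5, -5), 4L),
                   seed = 81L)
  null <- plant_ends(16L, c(chr = 30000L), log2_effect = 0,
                     kind = "termination", seed = 82L)
  null$position <- null$position + 93L
  simulate_dataset(sim_config(replicon_lengths = c(chr = 30000L),
                              planted = rbind(de, null),
                              background_reads = 1000L, seed = 83L))
}
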