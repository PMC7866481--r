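make_features <- function(replicon, start, end, strand, cls,
                          id = NULL) {
  n <- length(start)
  if (is.null(id)) id <- sprintf("f%03d", seq_len(n))
  out <- data.frame(feature_id = id, replicon = replicon,
                    strand = strand, start = as.integer(start),
                    end = as.integer(end), feature_class = cls,
                    stringsAsFactors = FALSE)
  class(out) <- c("features", "data.frame")
  out
}

test_that("ends are assigned strand-specifically with UTR fallback", {
  feats <- make_features("chr", 400L, 900L, "+", "CDS")
  inside <- assign_features(make_ends("chr", 500L, 501L, "+", 3), feats)
  expect_equal(inside$assigned_class, "CDS")
  # same interval, feature on the other strand -> UTR
  wrong <- assign_features(make_ends("chr", 500L, 501L, "-", 3), feats)
  expect_equal(wrong$assigned_class, "UTR")
  expect_equal(wrong$feature_ids, "")
})

test_that("overlapping classes resolve by stable-RNA priority", {
  feats <- make_features("chr", c(100L, 380L), c(1000L, 460L),
                         c("+", "+"), c("CDS", "tRNA"))
  hit <- assign_features(make_ends("chr", 400L, 401L, "+", 2), feats)
  expect_equal(hit$assigned_class, "tRNA")
  expect_equal(length(hit$assigned_features[[1]]), 2L)
})

test_that("500 random ends match the all-pairs overlap oracle", {
  set.seed(401)
  nf <- 100L
  fs <- sort(sample.int(50000L, nf))
  feats <- make_features("chr", fs, fs + sample(50:500, nf, replace = TRUE),
                         sample(c("+", "-"), nf, replace = TRUE),
                         sample(c("CDS", "tRNA", "rRNA", "ncRNA", "other"),
                                nf, replace = TRUE))
  ne <- 500L
  es <- sample.int(52000L, ne)
  ends <- make_ends("chr", es, es + sample(1:5, ne, replace = TRUE),
                    sample(c("+", "-"), ne, replace = TRUE),
                    rnorm(ne, 2))
  got <- assign_features(ends, feats)
  prio <- c(tRNA = 1L, rRNA = 2L, ncRNA = 3L, CDS = 4L, other = 5L)
  for (i in seq_len(ne)) {
    ov <- which(feats$strand == ends$strand[i] &
                  feats$start < ends$end[i] & ends$start[i] < feats$end)
    expect_equal(sort(got$assigned_features[[i]]), sort(ov))
    want <- if (length(ov) == 0L) "UTR" else {
      names(prio)[min(prio[feats$feature_class[ov]])]
    }
    expect_identical(got$assigned_class[i], want)
  }
  # partition: every end gets exactly one class
  expect_equal(sum(table(got$assigned_class)), ne)
})

test_that("flipping feature strands sends every assigned end to UTR", {
  feats <- make_features("chr", c(100L, 300L), c(200L, 400L),
                         c("+", "-"), c("CDS", "ncRNA"))
  ends <- make_ends("chr", c(150L, 350L), c(151L, 351L), c("+", "-"),
                    c(2, -2))
  before <- assign_features(ends, feats)
  expect_true(all(before$assigned_class != "UTR"))
  flipped <- feats
  flipped$strand <- ifelse(feats$strand == "+", "-", "+")
  after <- assign_features(ends, flipped)
  expect_true(all(after$assigned_class == "UTR"))
})

test_that("class summaries tally counts and per-kb rates", {
  feats <- make_features("chr", 0L, 1500L, "+", "CDS", id = "geneA")
  ends <- make_ends("chr", c(100L, 200L, 300L), c(101L, 201L, 301L),
                    "+", c(5, 6, 7))
  s <- summarize_classes(assign_features(ends, feats), feats)
  expect_equal(s$class_direction["CDS", "enriched"], 3L)
  expect_equal(s$per_gene$n_ends, 3L)
  expect_equal(s$per_gene$ends_per_kb, 2.0)
  # empty input -> all-zero summary
  s0 <- summarize_classes(assign_features(ends[0, ], feats), feats)
  expect_true(all(s0$class_direction == 0L))
  expect_equal(nrow(s0$per_gene), 0L)
})

test_that("class/direction summary equals a hand tally on simulated ends", {
  set.seed(402)
  n <- 200L
  fs <- seq(0L, by = 1000L, length.out = 50L)
  feats <- make_features("chr", fs, fs + 800L, "+",
                         rep(c("CDS", "tRNA", "ncRNA", "rRNA", "other"), 10L))
  pos <- sample.int(50000L, n)
  ends <- make_ends("chr", pos, pos + 1L,
                    sample(c("+", "-"), n, replace = TRUE),
                    rnorm(n))
  ann <- assign_features(ends, feats)
  s <- summarize_classes(ann, feats)
  for (cl in rownames(s$class_direction)) {
    for (d in colnames(s$class_direction)) {
      expect_equal(s$class_direction[cl, d],
                   sum(ann$assigned_class == cl & ann$direction == d))
    }
  }
  expect_equal(sum(s$class_direction), n)
})

test_that("flank windows follow the terminal-base convention", {
  genome <- Biostrings::DNAStringSet(c(chr = "ACGTACGTAC"))
  plus <- make_ends("chr", 5L, 6L, "+", 2)
  up <- extract_flanks(plus, genome, 3L, "upstream")
  expect_equal(unname(as.character(up)), "TAC")  # positions 3..5 inclusive
  expect_equal(names(up), "chr:5:+:upstream3")
  down <- extract_flanks(plus, genome, 3L, "downstream")
  expect_equal(unname(as.character(down)), "GTA")  # positions 6..8
  minus <- make_ends("chr", 5L, 6L, "-", 2)
  upm <- extract_flanks(minus, genome, 3L, "upstream")
  # mirror rule: genomic 5..7 = "CGT", reverse complement = "ACG"
  expect_equal(unname(as.character(upm)), "ACG")
  downm <- extract_flanks(minus, genome, 3L, "downstream")
  # genomic 2..4 = "GTA", reverse complement = "TAC"
  expect_equal(unname(as.character(downm)), "TAC")
})

test_that("200 random flanks equal a slice-and-revcomp oracle", {
  set.seed(403)
  gstr <- rand_seq(5000L)
  genome <- Biostrings::DNAStringSet(setNames(gstr, "chr"))
  n <- 200L
  t0 <- sample(100:4900, n)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  ends <- make_ends("chr", t0, t0 + 1L, strand, rnorm(n))
  ends$start <- ifelse(strand == "+", t0, t0)
  L <- 15L
  up <- extract_flanks(ends, genome, L, "upstream")
  expect_equal(length(up), n)
  for (i in seq_len(n)) {
    want <- if (strand[i] == "+") {
      substring(gstr, t0[i] - L + 2L, t0[i] + 1L)
    } else {
      revcomp_oracle(substring(gstr, t0[i] + 1L, t0[i] + L))
    }
    expect_identical(unname(as.character(up[i])), want)
  }
  expect_true(all(nchar(as.character(up)) == L))
})

test_that("windows truncated at boundaries are dropped with a warning", {
  genome <- Biostrings::DNAStringSet(c(chr = "ACGTACGTAC"))
  ends <- make_ends("chr", c(1L, 5L), c(2L, 6L), "+", c(2, 2))
  expect_warning(fl <- extract_flanks(ends, genome, 4L, "upstream"),
                 "truncated")
  expect_equal(length(fl), 1L)
  expect_equal(names(fl), "chr:5:+:upstream4")
  expect_error(extract_flanks(make_ends("nope", 3L, 4L, "+", 1), genome, 2L),
               "reference error")
})

test_that("dedupe keeps only non-overlapping ends", {
  genome <- Biostrings::DNAStringSet(setNames(rand_seq(100L), "chr"))
  ends <- make_ends("chr", c(40L, 42L, 60L), c(45L, 44L, 61L), "+",
                    c(1, 2, 3))
  fl <- extract_flanks(ends, genome, 5L, "upstream", dedupe = TRUE)
  expect_equal(length(fl), 1L)
  expect_equal(names(fl), "chr:60:+:upstream5")
})

test_that("unstructured fraction counts zero-MFE sequences", {
  expect_equal(unstructured_fraction(c(-3.2, 0.0, -0.1, 0.0)), 0.5)
  expect_equal(unstructured_fraction(c(-1, -2, -0.5)), 0)
  set.seed(404)
  mfe <- -round(runif(1000L, 0.1, 20), 2)
  zero_idx <- sample.int(1000L, 137L)
  mfe[zero_idx] <- 0.0
  expect_equal(unstructured_fraction(mfe), 0.137)
  expect_error(unstructured_fraction(numeric(0)), "input error")
})
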