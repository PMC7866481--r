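# rnaends

Nucleotide-resolution detection of **differential RNA 3′ (or 5′) ends** in
strand-specific bacterial RNA-seq, written for people studying RNA decay
and processing — e.g. comparing a ribonuclease mutant (PNPase, RNase E,
RNase III, …) against its wild type to map where transcripts are cleaved,
where 3′→5′ degradation stalls, and which ends an exonuclease removes.

## What it computes

Starting from per-library single-end alignments (SAM), the pipeline:

1. builds per-nucleotide, per-strand **read-terminus coverage** (the
   3′-terminal aligned base of each read; soft-clipped tails never shift
   the terminus) and full read coverage;
2. integrates both strands of all libraries into one position × library
   count matrix, keeping a position when some library has terminus count
   ≥ 10 **and** a terminus/full coverage ratio > 0.05 in that same
   library;
3. normalizes libraries with **median-of-ratios size factors**
   s<sub>j</sub> = median<sub>i</sub>( k<sub>ij</sub> / (∏<sub>v</sub>
   k<sub>iv</sub>)<sup>1/m</sup> );
4. tests each position with a two-group **negative-binomial Wald test**:
   log2FC = log₂((μ̂_test + ½)/(μ̂_ref + ½)), per-position
   method-of-moments dispersion α in Var = μ + αμ², delta-method SE, and
   the Wald statistic referred to a t distribution with n−2 df (a
   small-sample calibration correction; see the vignette), under
   **Benjamini–Hochberg** FDR control;
5. keeps positions with |log2FC| ≥ 1 and adjusted p ≤ 0.05 and merges
   those within 3 nt into **differential ends** (the merged span is the
   end's *distribution size*), each carrying the arithmetic mean log2FC
   and an enriched/depleted direction;
6. assigns ends strand-specifically to annotated features (tRNA > rRNA >
   ncRNA > CDS priority, no overlap → UTR).

Companion modules compare two mutants' end sets (1-nt windowed matching,
fold-change sign quadrants, and a two-tailed Fisher's exact test on
overlap counts against the number of possible ends,
⌊G/(mean width A + mean width B)⌋, computed in log space so p-values far
below 1e-300 stay meaningful), profile **untemplated 3′ tails** from
soft-clipped local alignments (≥ 10 nt 5′ anchor required), extract
flanking sequence windows for motif/structure analyses, and simulate
complete datasets with planted ends for validation.

## Worked example

Simulate a 50 kb genome with 20 differential ends (|log2 effect| = 5),
40 unchanged termination ends and background reads, then run the chain:

```r
library(rnaends)
glen <- c(chr = 50000L)
de   <- plant_ends(20, glen, log2_effect = rep(c(5, -5), 10), seed = 11)
bg   <- plant_ends(40, glen, log2_effect = 0, kind = "termination", seed = 12)
bg$position <- bg$position + 97L
sim <- simulate_dataset(sim_config(replicon_lengths = glen,
                                   planted = rbind(de, bg),
                                   background_reads = 2000L, seed = 5))
res <- run_end_pipeline(sim$sam, sim$design, gff3 = sim$gff3)
print(res)
#> rnaends pipeline result
#>   positions in matrix:  11539
#>   after count filter:   166
#>   after ratio filter:   166
#>   significant:          50
#>   differential ends:    20
head(res$ends, 4)
#>   replicon start  end strand distribution_size mean_log2fc direction
#> 1      chr  6708 6711      -                 3    4.150488  enriched
#> 2      chr  7323 7326      +                 3   -4.111030  depleted
#> 3      chr  7705 7708      -                 3    4.578772  enriched
#> 4      chr  8915 8916      -                 1   -4.696165  depleted
score_recovery(res$ends, sim$truth)[c("sensitivity", "precision")]
#> $sensitivity [1] 1    $precision [1] 1
```

11,539 genomic positions carry at least one read 3′ end; 166 survive the
coverage and signal-ratio filters; 50 are significant and merge into the
20 planted differential ends (all recovered, none spurious — the planted
log2 effects of ±5 are attenuated to ≈ ±4.1–4.7 by the continuity
constant). Tail profiling on the same reads:

```r
tails <- extract_tails(read_alignments(sim$sam[["test_1"]]))
ts <- summarize_tails(tails)
c(ts$n_records, ts$quantiles[["95%"]], round(ts$base_freq[1, "G"], 2))
#> 2084   30   0.69
```

2,084 reads carry an untemplated tail behind a ≥10-nt anchor; 95% are
≤ 30 nt and the first tail position is 69% G — the planted G-rich
composition.

## Documentation

See the methods vignette (`vignettes/differential-rna-ends.Rmd`) for the
statistical model, its assumptions, every tunable threshold with its
default and rationale, what the simulator does and does not emulate, and
known limitations.
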