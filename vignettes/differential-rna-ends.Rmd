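---
title: "Detecting differential RNA ends: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting differential RNA ends: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnaends)
```

## The problem

In bacteria, RNA 3′ ends arise three ways: transcription termination,
endonucleolytic cleavage (RNase E, RNase III, …), and stalling of 3′→5′
exonucleolytic decay (PNPase, RNase II, RNase R) at obstacles such as
stable secondary structure. Comparing the per-nucleotide abundance of
read 3′ termini between a ribonuclease mutant and its wild type reveals
which ends that enzyme creates or removes: an end *enriched* in an
exonuclease mutant is normally degraded by that enzyme; an end
*depleted* in an endonuclease mutant is normally created by it. The same
machinery applied to 5′ termini maps processing 5′ ends.

`rnaends` implements this comparison for strand-specific single-end
bacterial RNA-seq, from SAM alignments to annotated differential ends,
plus cross-mutant intersection, untemplated 3′-tail profiling, and a
simulator that makes the whole chain testable without external data.

## The statistical model

### Counting

For every mapped primary alignment, exactly one genomic position is
counted: the 3′-terminal *aligned* base (rightmost on `+`, leftmost on
`-`). Soft-clipped bases are excluded deliberately — untemplated tails
would otherwise smear the terminus position; they are analyzed
separately by the tails module. Full coverage counts aligned read bases
only (CIGAR `M`/`=`/`X`); deletions and reference skips do not
contribute, because the signal-ratio filter compares read-supported
signal and counting reference gaps would inflate the denominator.

### Filtering

A candidate position survives when **some single library** has terminus
count ≥ `min_end_count` (default 10) *and* terminus/full ratio >
`min_ratio` (default 0.05) in that same library. The there-exists
reading keeps condition-specific ends (present only in the mutant or
only in the wild type) while the joint requirement stops a library with
high counts but terrible signal-to-noise from rescuing a position. A
position with zero full coverage in a library fails the ratio in that
library by definition.

### Normalization

Median-of-ratios size factors are computed on the filtered candidate
matrix: over rows where every library is positive,
\(s_j = \mathrm{median}_i\, k_{ij}/(\prod_v k_{iv})^{1/m}\). The
estimator needs a backbone of positions whose abundance does not change
between conditions; in real end-enriched data that backbone is provided
by the many unchanged termini (intrinsic terminators, constitutive
processing sites), which dominate any genome. When no row is
all-positive the code falls back, with a warning, to library totals
scaled to unit geometric mean.

### Testing

Counts are modelled as negative binomial with variance
\(\mu + \alpha\mu^2\). Per position, with normalized counts
\(n_{ij} = k_{ij}/s_j\) and condition means \(\hat\mu_A, \hat\mu_B\):

* \(\log_2\!\mathrm{FC} = \log_2\frac{\hat\mu_B + c}{\hat\mu_A + c}\)
  with continuity constant \(c = 0.5\) (finite for all-zero conditions;
  attenuates extreme effects at low counts, visible in the README
  example where planted ±5 effects report as ≈ ±4.1–4.7);
* dispersion \(\hat\alpha = \max\{(s^2 - \bar n)/\bar n^2,\,10^{-8}\}\),
  with \(s^2\) the pooled within-condition variance
  (\(n_A + n_B - 2\) df) of normalized counts — a per-position
  method-of-moments estimate, deliberately without any sharing of
  information across positions;
* Wald statistic \(z = \log_2\!\mathrm{FC}/\mathrm{SE}\), SE from the
  delta method:
  \(\mathrm{SE}^2 = \frac{1}{\ln^2 2}\left[
  \frac{(\hat\mu_A + \hat\alpha\hat\mu_A^2)/n_A}{(\hat\mu_A+c)^2} +
  \frac{(\hat\mu_B + \hat\alpha\hat\mu_B^2)/n_B}{(\hat\mu_B+c)^2}
  \right]\).

**Reference distribution.** \(z\) is referred to a *t* distribution with
\(n_A + n_B - 2\) degrees of freedom, not to the normal. This is the one
place the implementation departs from the asymptotic textbook form, and
it is a measured necessity: with 3 + 3 replicates the plug-in variance
has ~4 df, and the normal tail rejects 12% of null NB positions (mean
100, dispersion 0.1) at nominal 5%. The identical statistic under
\(t_4\) rejects 4.95% — the calibration the acceptance suite demands.
Tools that keep the normal tail get away with it by shrinking
dispersions across thousands of positions; this package's test is
defined per position, so the small-sample correction must live in the
reference distribution instead.

Raw p-values are Benjamini–Hochberg adjusted across all tested
positions. Significant positions (|log2FC| ≥ `lfc_cutoff`, padj ≤
`alpha`, both defaults matching the study design: 1 and 0.05) are merged
transitively whenever the gap between neighbours is ≤ `merge_distance`
(3 nt): positions \(p < q\) join iff \(q - p - 1 \le 3\). A merged end
records its span (*distribution size*), member count, arithmetic mean
log2FC, and direction by the sign of that mean; members with
disagreeing signs set a `mixed_sign` flag rather than being split,
mirroring a plain interval merge followed by averaging.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `min_end_count` | 10 | reads | minimal terminus evidence in one library |
| `min_ratio` | 0.05 | fraction | terminus/full signal-to-noise floor (exclusive) |
| `lfc_cutoff` | 1 | log2 | biologically meaningful two-fold change |
| `alpha` | 0.05 | fraction | BH-FDR level (inclusive: padj ≤ 0.05) |
| `merge_distance` | 3 | nt | one molecular end smears over a few nt |
| `window` (intersection) | 1 | nt | tolerated inaccuracy when matching two end sets |
| `min_anchor` (tails) | 10 | nt | aligned 5′ block required before trusting a clip |

## Intersection of two mutants

Set A intervals are extended by the window on both sides; any same-strand
overlap with a set B interval is a match (all pairs reported, plus
distinct-end counts, since both "total" and "unique" overlap numbers are
informative). Matched pairs fall into quadrants by fold-change signs —
`A+B−`, for example, collects ends enriched in mutant A and depleted in
mutant B, the signature of "B's enzyme creates the end, A's enzyme
removes it". Overlap enrichment uses a 2×2 table over a universe of
⌊G/(w̄_A + w̄_B)⌋ possible ends (G = single-strand genome length, w̄ the
mean distribution sizes); matched pairs collapse to connected components
of the bipartite match graph so one overlap event is never counted
twice. The two-tailed Fisher p sums hypergeometric probabilities ≤ the
observed table's (relative tolerance 1e-7), accumulated in log space:
`log10_p` stays informative when p underflows below ~1e-300, as it does
for realistically strong overlaps. The universe formula is
strand-unaware even though matching is strand-aware — inherited
deliberately from the interval-tool convention it mirrors, and
conservative (it halves the universe relative to stranded counting,
making reported p-values *larger*).

## Untemplated tails

Reads that only align in local mode may carry untemplated 3′ additions
as soft clips. A tail is trusted only when, in read orientation, the
contiguous aligned block at the 5′ end spans ≥ 10 nt and no 5′ soft clip
exists (the stricter reading of the anchor rule: a clipped 5′ end means
the anchor is not where it claims to be). On `-` strand alignments the
read's 3′ tail is the *leading* clip in reference orientation; stored
tails are always 5′→3′ in read orientation. Summaries report the length
distribution (type-7 quantiles) and a position × base frequency matrix;
`N` bases are kept in tails but excluded from frequency denominators.

## What the simulator emulates — and what it does not

`simulate_dataset()` emulates the *structure* of end-enriched bacterial
RNA-seq at desk scale: a uniform-random replicon (default 100 kb, a
stand-in for a several-Mb genome), 3 + 3 libraries of 75-nt
strand-specific single-end reads emitted as already-aligned SAM, planted
ends whose per-library terminus counts are NB(depth · base_mean ·
2^(effect·[test]), dispersion 0.1) via the gamma–Poisson mixture,
optional positional jitter (default sd 0.5 nt), uniform background
reads, and a fraction of reads (default 0.1) carrying G-rich soft-clip
tails (70% G over the first 20 positions; lengths 1 + Geometric with
mean 11, putting ~95% under 39 nt). Defaults follow the study design
the package targets: base_mean 50 (the basemean floor used there),
|log2 effect| 5 (the modal enriched fold change), and the G-rich tail
composition reported for PNPase-proficient cells.

Because median-of-ratios normalization needs non-differential backbone
positions, realistic fixtures must plant zero-effect termination ends
alongside differential ones; a world where *every* end changes leaves
the size factors unidentified and silently absorbs the effect — real
data never looks like that, and the recovery scorer treats calls at
zero-effect truth ends as false positives.

Not emulated: sequencing errors and quality strings, mapper behaviour
(reads are born aligned — a green test says nothing about alignment
artifacts), paired-end data, transcript-level covariance between nearby
ends, or compositional biases of real genomes. Recovery numbers from
simulation therefore certify the *statistical pipeline*, not the
upstream read processing.

## Numerical and degenerate-input choices

* Ties in BH are handled by the standard step-up with enforced
  monotonicity; order is preserved.
* Positions with undefined statistics (NaN padj) are dropped with a
  warning before merging.
* `SE = 0` (both condition means zero) maps to `z = 0`, `p = 1`.
* An empty significant set is a *valid* empty result everywhere
  downstream, including written outputs.
* With nothing called, recovery precision is reported as 1.0 together
  with a `zero_called` flag, so dashboards do not divide by zero.
* The threshold `alpha` is constrained to (0, 1); degenerate "call
  nothing" behaviour is reachable with any tiny positive value.
* All internal coordinates are 0-based half-open; SAM and GFF3 convert
  on read, BED is written natively. One convention, no off-by-one
  classes.

## Known limitations

* **End-level vs position-level FDR.** BH controls the FDR over
  *positions*. When true ends span several significant positions (e.g.
  under positional jitter) while false positives arrive as single
  positions, the FDR among *merged ends* is mechanically higher than
  among positions (measured: 5% position FDR became ~12–13% end-level
  false calls at 0.5-nt jitter). This is a property of every
  merge-after-test procedure, worth remembering when reading end
  counts.
* The per-position dispersion estimate is noisy at 3 + 3 replicates; the
  t reference fixes type-I calibration but costs power relative to
  information-sharing estimators. Effects of |log2FC| ≈ 5 at base mean
  ≥ 50 are recovered essentially completely; subtle effects near the
  cutoff are not the design point.
* The size-factor scale is conventional: rescaling one library by λ
  moves its factor by λ^((m−1)/m), not λ (the row geometric means absorb
  the rest); all fold changes are invariant, which is what matters.
* Multi-factor designs, shrunken LFC estimators, and nucleotide-level
  independent filtering are out of scope by design.
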