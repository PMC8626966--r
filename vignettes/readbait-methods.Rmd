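---
title: "Salvaging unmapped reads and estimating full-length transcript spans: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Salvaging unmapped reads and estimating full-length transcript spans: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(readbait)
```

## The problem

An RNA-seq aligner leaves a fraction of reads unmapped. Some of that
fraction is noise (contamination, low quality, orphaned mates), but some
comes from transcripts the annotation does not know, in particular reads
broken by an unannotated splice gap. Such transcripts are typically at low
coverage, below what assembly tools will reconstruct. `readbait` implements
the two computational pieces of a strategy for recovering them: a screening
cascade that isolates gap-bearing candidate reads, and a statistical model
that, given one candidate ("model read") and targeted resequencing fragments
mapped around it, estimates how far the underlying transcript extends on
each side.

## The screening cascade

`classify_reads()` assigns every sequencing template to the **first**
matching category of a fixed cascade:

| order | category        | rule                                                         |
|-------|-----------------|--------------------------------------------------------------|
| 1     | `unpaired`      | one mate missing from the input                              |
| 2     | `contaminant`   | id flagged by the rRNA/mitochondrial/microbial screen        |
| 3     | `low_quality`   | any mate fails `quality_filter()`                            |
| 4     | `annotated`     | id mapped to the reference annotation (union over aligners)  |
| 5     | `low_score`     | best alignment score `< minscore` (default 130)              |
| 6     | `new_annotated` | id matching a newly annotated transcript                     |
| 7     | `candidate`     | everything that survives                                     |

The external screens (rRNA filtering, annotation mapping, BLAT, BLAST) are
consumed as id sets and score tables — the cascade order and thresholds are
the contribution here, not the aligners. Accounting is per template: the two
mates of a pair are one unit, which is also how the planted truth tables of
the synthetic generator count. Reads absent from the score table are treated
as score $-\infty$ (a read without a reported high-scoring alignment cannot
clear `minscore`). Because "default arguments" of read-trimming tools drift
across versions, the quality rule is explicit and version-independent: mean
Phred ≥ 15 (inclusive) and length ≥ 36 bp, both configurable.

Candidates are then filtered by the gap rule, `gap_candidates()`: a read
qualifies when its CIGAR contains an `N` or `D` operation **strictly longer
than 20 bp** (`min_gap = 21`), the signature of a read straddling a putative
intron. Only reference-consuming operations move the gap coordinates;
insertions and clips never produce gaps. Gap intervals are reported 1-based
inclusive, so a 23 bp gap starting at position $p$ ends at $p + 22$.

## The power-law length model

The prior that links a fragment's distance to its probability of belonging
to the model read's transcript is the transcript-length distribution, which
is heavy-tailed and well described by a power law over the relevant range.
The fitting procedure (`fit_length_distribution()`) is:

1. one length per transcript from the GTF (sum of exon widths, else the
   transcript feature span);
2. drop lengths **strictly above the sample median** — long transcripts
   yield disproportionately many reads at equal molar expression, so the
   upper half is discarded to keep the fitted range representative. For
   even-sized samples the median is the lower central value by default
   (`tie = "mean"` gives the midpoint); the cutoff becomes the model's
   upper support bound `x_max`;
3. bin at 100 bp: bin $k$ covers $((k-1)w,\,kw]$, a boundary length belongs
   to the lower bin, counts are conserved by construction;
4. OLS of $\ln(\text{count})$ on $\ln(\text{rank }k)$ over non-empty bins
   (zero-count bins are dropped, not smoothed; at least three non-empty bins
   are required). Then $a = -\text{slope}$, $C = e^{\text{intercept}}$, with
   $R^2$, adjusted $R^2 = 1-(1-R^2)\frac{n-1}{n-2}$ and the two-sided slope
   $p$-value reported. The regression's x variable is the bin **rank
   index**, not the bin midpoint.

### Validity regime of the binned estimator

Binned log-log OLS is a popular but biased exponent estimator (Goldstein et
al. 2004, Eur. Phys. J. B 41:255; Clauset et al. 2009, SIAM Rev. 51:661).
Two regimes matter in practice:

* **Wide bins relative to `x_min`** (here $w = 100 \gg x_{\min} = 1$): the
  first bin integrates most of the density when $a \ge 1$ and sits far off
  the asymptotic line $\ln n_k \approx \text{const} - a \ln k$, dragging the
  slope. For shallow exponents ($a \approx 0.6$, the regime transcript
  lengths actually occupy) the deviation is small and recovery from $10^5$
  samples is within ±0.06 of truth.
* **Depopulated tail bins**: dropping zero-count bins keeps only the
  upwardly fluctuating survivors at large $k$, flattening the slope for
  steep exponents.

The package's parameter-recovery tests therefore check exponents
$a \in \{0.6, 1.5, 2.5\}$ on a support where the estimator is consistent
(bin width ≪ `x_min`, all bins populated: support $[2000, 20000]$, recovery
within ±0.15 and empirically within ±0.04), plus the shallow-exponent case
on $[1, 10^4]$. A truncated maximum-likelihood estimator on the raw samples
serves as the independent oracle in the tests (within ±0.05 of truth); it is
deliberately not part of the package surface — the binned regression *is*
the procedure being modelled.

## The co-membership probability

Let $x$ be the distance from the model-read center to a fragment's center
(floor midpoints of 1-based inclusive intervals; even-length intervals bias
the center by < 1 bp toward the start, which is negligible at the scale of
interest). The default **truncated** mode treats transcript length as a
power law with exponent $a$ on finite support $[x_{\min}, x_{\max}]$ and
returns the upper tail

$$P(X \ge x) \;=\; \frac{x_{\max}^{\,1-a} - x^{\,1-a}}
                        {x_{\max}^{\,1-a} - x_{\min}^{\,1-a}},
  \qquad a \ne 1,$$

with $\log(x_{\max}/x) / \log(x_{\max}/x_{\min})$ at $a = 1$. The
normalization constant $C$ cancels; the probability is 1 at $x_{\min}$, 0 at
$x_{\max}$, and monotone non-increasing in between. Distances below
$x_{\min}$ clamp to 1 (a fragment sitting on the anchor is certainly
co-local) and above $x_{\max}$ to 0. This is the only proper distribution
consistent with the procedure: the closed form
$F(x) = 1 - \frac{C}{a-1}x^{-(a-1)}$ is an improper CDF whenever $a < 1$ —
and fitted transcript-length exponents *are* below 1 — so the **literal**
mode that evaluates it with the stored $C$ exists purely for audit, clamped
into $[0,1]$ with a warning.

Fragments with probability **strictly greater** than the threshold (default
0.3) are retained. Equivalently there is a critical distance
(`critical_distance()`, the analytic inverse of the tail) inside which every
fragment is kept; at $a = 0.594$, support $[1, 6932]$, threshold 0.3 it is
about 2,964 bp.

Defaults and units: `x_min = 1` bp (distances are positive integers);
`x_max` = the median length cutoff carried from the filtering step;
`threshold` ∈ (0,1), default 0.3; scan `window` defaults to `x_max`, beyond
which the probability is 0 by construction.

## Span estimation

A "fragment" of paired-end data is the sequencing template: mates sharing a
read name are merged to their outermost coordinates when both map to the
anchor chromosome, and a lone mapped mate stands for its fragment
(secondary/supplementary alignments are excluded). The estimated span is the
interval union of the model span with all retained fragments; no chaining or
coverage continuity between fragments is required, because the target regime
is precisely sparse, low-coverage signal where isolated fragments are real.
Left/right extensions relabel to 5′/3′ by strand; with unknown strand the
estimate carries `strand_resolved = FALSE`. The span always contains the
model span, extensions are non-negative, and tightening the threshold can
only shrink the retained set and hence the span. `full_length` is the
reference-space span length; note that a gapped model alignment spans more
reference than its read length (a 149 bp read with a 23 bp `N` spans
172 bp), so with no retained fragments the full length equals the model
*alignment's* span, not the read length.

Coordinates are 1-based inclusive internally (SAM convention); BED I/O is
0-based half-open and the converters (`convert_coordinates()`) are exact
inverses.

## What the synthetic data emulates — and what it does not

`make_planted_locus()` plants one single-exon transcript (default 1,556 bp)
in a random uniform-composition chromosome with 3 kb flanks, places a model
read (149 bp, one 23 bp `N` gap after 60 matched bases) at an offset of
1,117 bp from the transcript start, and draws fragments as subintervals of
the transcript — uniform start, length $\mathcal{N}(200, 30^2)$ clipped at
20 bp, mimicking ~200 bp sonication at the default ~10× coverage
(`fragment_count = 80`). Fragments are emitted both as BED and as paired-end
SAM so the template-merging path is exercised. `decoy_count` adds
off-transcript fragments whose centers lie beyond the model support
(membership probability exactly 0) to test the rejection path. Because the
targeted resequencing step enriches the transcript itself, on-transcript
placement is the realistic default; fragments from unrelated nearby
transcripts inside the critical distance would be retained by construction —
the model has no way to distinguish them, which is a limitation of the
method, not of the simulator.

`sample_truncated_powerlaw()` draws lengths by inverse CDF and floors them
to integers; flooring (rather than rounding) keeps the empirical tail at
integer thresholds exactly equal to the continuous tail.
`make_screen_fixture()` plants per-category read counts — by default the
proportions observed in a real unmapped fraction, scaled to 1,000 reads —
together with the id sets, Phred strings and PSL scores that force
`classify_reads()` to reproduce them.

Not emulated: sequencing errors and quality decay along the read, splice
structure (the planted transcript is single-exon), multi-transcript loci,
microsatellite slippage, and library-preparation biases. Passing tests
therefore demonstrate the correctness of the decision rules and estimators
given faithful alignments, not robustness to alignment artefacts.

## Numerical choices and degenerate inputs

* OLS statistics are computed directly from the residuals so an exactly
  noiseless histogram yields $a$ and $C$ to machine precision, $R^2 = 1$ and
  slope $p = 0$ without spurious warnings.
* Fewer than three non-empty bins, or all counts in one bin, is an error —
  not a silent fit.
* `membership_probability()` rejects $x \le 0$; distance 0 from fragment
  collection is clamped to `x_min` *before* scoring.
* Retention is strict (`>` threshold), so a fragment sitting exactly at the
  critical distance is dropped.
* An empty retained set degenerates cleanly to the model span with zero
  extensions; an empty screening input yields an all-zero report.
* Test problem sizes: $10^5$ samples for recovery checks, 100-point oracle
  grids, $10^3$ random CIGARs, 3 seeds per stochastic claim — small enough
  to run in seconds while leaving sampling noise well inside the asserted
  tolerances.

## Design choices on genuinely open points

* **Direction of the probability.** The retention rule ("probability greater
  than 0.3") only makes sense for a quantity that *decreases* with distance,
  so the package scores the upper tail $P(X \ge x)$; the literal CDF form is
  kept as an audit mode rather than guessed into the default path.
* **Provenance of $C$.** The only constant computable from the stated
  regression is $e^{\text{intercept}}$, so that is the default; literal mode
  also accepts a user-supplied constant. In truncated mode $C$ cancels and
  probabilities are invariant to rescaling it (property-tested).
* **Median tie and bin boundary conventions** are stated above and
  configurable where ambiguity exists.
* **Gap coordinates.** Inclusive spans are reported; note that a 23 bp gap
  has an inclusive span of 23 positions; coordinate pairs produced under
  other conventions (half-open, or end-exclusive on both sides) subtend a
  different number of positions — the package documents its own convention
  and sticks to it.

## Known limitations

* The binned log-log exponent estimator is biased outside its validity
  regime (see above); for steep exponents use a narrower bin-to-`x_min`
  ratio or an external MLE.
* The co-membership model is isotropic and single-locus: it cannot separate
  fragments of an overlapping neighbouring transcript from fragments of the
  target, and it ignores strand and splice structure of the fragments.
* Extension estimates are bounded by `x_max`: a transcript longer than the
  median cutoff used to fit the model cannot be fully recovered, because
  fragments beyond `x_max` score 0. Choosing `x_max` from the length
  analysis of a *reference* annotation (rather than the filtered sample
  median, when that median is shorter than the expected target) is the
  practical remedy and is what the worked example does.
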