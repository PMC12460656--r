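---
title: "EEG complexity and dream reports under sedation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EEG complexity and dream reports under sedation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dreamcomplexity)
```

## The scientific question

Complexity measures of cortical dynamics — here single-channel Lempel-Ziv
complexity of spontaneous EEG (LZc) and the state-transition perturbational
complexity index of TMS-evoked EEG (PCIst) — are widely used as proxies for
the capacity for conscious experience. A serial-awakening design during deep
propofol sedation asks a sharper question than the usual wake-vs-anesthesia
contrast: *within* a fixed sedation depth, do these measures differ between
awakenings after which the participant reports a dream and awakenings after
which they report nothing?

This package implements the complete analysis stack for that question:

1. the two complexity measures,
2. the two-question report categorization and its three-class experience
   classification,
3. the statistical layer (random-intercept linear mixed models with Type-III
   tests and estimated marginal means; matched-pairs Wilcoxon signed-rank
   tests; Holm-Bonferroni correction over six tests; 1.5-IQR outlier
   screening), and
4. a synthetic-data generator so the full pipeline is exercised end-to-end
   without any EEG download.

## Single-channel Lempel-Ziv complexity

For each channel and each 5-second window, the signal $x(t)$ is mapped to its
analytic-signal envelope $a(t) = |x(t) + i\,\mathcal{H}[x](t)|$, computed by
the one-sided-spectrum FFT method. The envelope is binarized at its
within-window median; a value receives bit 1 only when it *strictly* exceeds
the median. The binary sequence is parsed into the Lempel-Ziv-1976 exhaustive
history (Kaspar-Schuster procedure; final incomplete word counted), giving a
word count $c$. The normalized value is

$$\mathrm{LZc} = \frac{c(\text{data})}{c(\text{single random shuffle of the
same bits})},$$

which preserves the 0/1 marginal distribution in the denominator. The
recording value averages window values over epochs within a channel, then
over channels.

Decisions worth pinning:

* **Tie policy.** Strict inequality at the median: a constant envelope
  binarizes to all zeros. Tests fix this behaviour.
* **Median scope.** The median is computed within each 5-second analysis
  window, not per recording, so each window is self-normalizing in amplitude.
* **Shuffle seeding.** Each window's shuffle permutation is drawn from a seed
  derived from the global seed *and the binarized window content*. This makes
  results bitwise reproducible, independent of the order windows are visited,
  and exactly invariant to relabeling channels or epochs — an index-based
  derivation would break the latter.
* **Edges.** No tapering before the Hilbert transform; windows (1250 samples
  at 250 Hz) are long relative to FFT edge artifacts.
* **Trailing data.** Partial windows at the end of an epoch are dropped;
  fixed-length windows keep the parser's length normalization comparable.
* **Parser.** The LZ76 counter is compiled (bit-packed longest-common-prefix
  matching); an independent brute-force exhaustive-history parser written in
  plain R is kept solely as a test oracle, and the two are compared on all
  8,188 binary sequences of lengths 2 through 12.

A note on a property the measure does **not** have: the per-pair transition
indicator used later in PCIst, and the LZ76 count here, are not monotone in
any single tuning quantity; what *is* guaranteed and tested are exact
invariances (amplitude rescaling leaves every bit, and hence the value,
unchanged) and distributional facts (shuffling an exchangeable sequence gives
ratios near 1).

## PCIst: state transitions of the TMS-evoked response

The trial set (trial x channel x sample, epoched -250 to +500 ms around the
pulse) is averaged across trials, baseline-corrected by the per-channel mean
over -250..-5 ms, and re-referenced to the channel average. The response
window 0..300 ms is decomposed by SVD; spatial singular vectors project the
full epoch onto component time courses carrying the singular-value amplitude.
Components are retained up to 99% of response-window variance (at most 10)
and dropped when their response/baseline RMS ratio falls below 1.1.

For one component with segments $y_b$ (baseline) and $y_r$ (response), the
pointwise distance matrix is $D_{ij} = |y_i - y_j|$, thresholded as
$T = \mathbf{1}[D > \varepsilon]$. The number of state transitions is the
mean over reference columns of $\sum_t |T_{t+1,t'} - T_{t,t'}|$. The
threshold $\varepsilon^\*$ maximizes the length-normalized weighted contrast

$$\frac{\mathrm{NST}_r(\varepsilon)}{L_r} - k \cdot
\frac{\mathrm{NST}_b(\varepsilon)}{L_b}, \qquad k = 1.2,$$

over 100 candidate thresholds placed at quantiles of the pooled distance
values (ties broken toward the smaller threshold). The component contributes
$\Delta\mathrm{NST} = L_r(\mathrm{NST}_r/L_r - \mathrm{NST}_b/L_b)$ at
$\varepsilon^\*$, clipped at zero, and PCIst is the sum over components.

Numerical notes:

* The grid evaluation uses the identity that a $(t, t+1)$ pair transitions at
  column $t'$ exactly when $\varepsilon$ lies in
  $[\min(D_{t,t'}, D_{t+1,t'}), \max(D_{t,t'}, D_{t+1,t'}))$, so all 100
  thresholds are evaluated with two sorted searches; a direct implementation
  of the definition is kept and the two are cross-checked in tests. The same
  identity shows NST is *not* monotone in $\varepsilon$ — raising the
  threshold can create transitions — so no monotonicity is assumed anywhere.
* Every stage is either scale-equivariant (averaging, SVD, distances) or
  quantile-based (the threshold grid), so a global gain change leaves the
  retained-component count identical and the value equal to within floating
  rounding; tests require 1e-9.
* Windows are half-open `[start, end)` in milliseconds, converted to samples
  by floor/ceil; time 0 is the stimulus sample.

**The noise floor.** On pure pink-noise trial sets the index does not go to
zero: the response-window SVD preferentially aligns components with whatever
slow post-stimulus noise structure exists, and baseline-mean anchoring makes
the response segment of such components systematically livelier than the
baseline. With the defaults above the pure-noise floor sits near a quarter of
the value of a strong 8-component evoked response — mirroring the empirical
behaviour of this index, which reports clearly nonzero values in unconscious
states. Contrast claims in tests are therefore framed as orderings and
bounded ratios, not as a vanishing null.

## Report classification

Q1 ("What did you experience?") is categorized by level of detail: `nothing`,
`no_info`, `white` (something was experienced but no content is remembered),
`vague` (isolated feelings/images), `vivid` (scenes and stories). Q2 ("Did
you experience anything?") is `no`, `no_info`, `maybe`, `yes`. The combined
experience classification applies, in order: positive detail on Q1 counts as
`experience` even over a conflicting Q2 `no`; otherwise Q2 `yes` counts as
`experience`; otherwise Q1 `nothing` or Q2 `no` counts as `no_experience`;
everything else (including `maybe` with an uninformative Q1) is
`no_information`. The rule lives in a plain 5x4 class matrix and can be
replaced wholesale.

The packaged marginals are Q1 = 1/28/2/9/12, Q2 = 8/22/4/18, classes =
24/23/5 over 52 awakenings (14 participants awoken three times, 4 twice, 2
once). The full Q1xQ2 joint table behind those marginals is not published as
numbers, so the package reconstructs one by deterministic backtracking
(lexicographic cell order, ascending counts, margin- and class-capacity
pruning): the result is a *consistent reconstruction*, unique as a search
output but not guaranteed to be the study's actual table. Its forced
arithmetic is still informative — e.g. exactly three detail-positive
awakenings must have answered `no` to Q2, and the conflict policy above is
the only one consistent with all printed totals.

## Statistical layer

For each measure, sedation values are modelled as
$y_{ij} = \beta_0 + \sum \beta_i\,\mathrm{class}_{ij} + u_j +
\varepsilon_{ij}$ with a per-participant random intercept, fitted by REML.
The class effect is reported as a Type-III F with Satterthwaite denominator
degrees of freedom (Kenward-Roger is available), and per-class estimated
marginal means are population-level predictions ($u = 0$); the reference
class is `no_experience`, to which the EMMs are invariant. Singular fits
(zero random-intercept variance) are flagged, not failed; in that limit the
F statistic collapses to the one-way ANOVA F, which is verified against
`aov` in the tests. A single observed class yields the intercept-only fit
with the class EMM and no F test.

The wake-sedation contrasts use the matched-pairs Wilcoxon signed-rank
statistic on per-participant sedation means (up to three recordings):
differences $d = y - x$ with zeros dropped, midranks for ties, and

$$Z = \frac{T^+ - n(n+1)/4}{\sqrt{n(n+1)(2n+1)/24 - \sum(t^3 - t)/48}}$$

with no continuity correction — for 20, 17 and 15 fully concordant untied
pairs this gives $Z = -3.92, -3.62, -3.41$. Note the tie correction matters:
20 concordant pairs with *identical* difference magnitudes would give
$-4.47$, so the closed-form reconstruction presumes distinct magnitudes.

Holm's step-down compares the $i$-th smallest of the six p-values against
$\alpha/(m - i + 1)$ and stops at the first failure; decisions are verified
against `p.adjust` on a thousand random p-vectors. One worked example:
p-values (0.001, 0.004, 0.02, 0.03, 0.2, 0.9) at $\alpha = 0.05$ reject only
the first two, because $0.02 \ge 0.05/4 = 0.0125$.

Outlier screening flags values beyond 1.5 IQR from the quartiles, with
quartiles by linear interpolation (type 7); the convention is pinned in tests
because flags can differ across quartile definitions. Missing pair members
are dropped (complete case) with a logged count, matching a cohort in which
only 17 of 20 participants have wake TMS recordings.

## The synthetic cohort

`gen_spontaneous()` builds each channel as an independent $1/f^\alpha$
background (spectrally limited to 0.5-45 Hz, emulating the 0.5-40 Hz
band-pass of cleaned recordings) plus amplitude-modulated band-limited
oscillators (two per band; carrier drawn uniformly within the band; slow
positive AM envelope from smoothed noise so envelopes are non-degenerate for
median binarization) mixed through smoothed random unit-norm topographies.
The three profiles share one broadband RMS (10 uV) and differ only
spectrally:

| profile | delta | theta | alpha | beta | slope $\alpha$ |
|---|---|---|---|---|---|
| `wake_eo` | 1.0 | 0.5 | 1.0 | 0.7 | 1.0 |
| `wake_ec` | 1.0 | 0.5 | 2.0 | 0.7 | 1.0 |
| `sedation` | 4.0 | 1.0 | 0.5 | 0.3 | 1.8 |

Eyes-closed doubles the alpha amplitude of eyes-open; sedation is dominated
by slow waves with a steeper background slope. These choices encode the
physiology the profiles emulate (posterior alpha enhancement with eye
closure; propofol slow-wave dominance) and produce the right measure
orderings as a *consequence*: regular, slowly modulated envelopes binarize
into more compressible sequences.

`gen_tep()` adds one identical deterministic evoked waveform — a sum of $k$
damped cosines with per-component frequency, damping, onset latency,
amplitude and smooth random unit-norm topography — to independent pink-noise
trials, strictly after time zero (the baseline of a noiseless trial set is
exactly zero). A `total_energy` option rescales amplitudes so trial sets with
different $k$ have matched evoked energy, isolating *spatiotemporal
differentiation* (what PCIst quantifies) from mere response strength. The
wake default is 8 components spread over 6-34 Hz and 15-220 ms; the sedation
default is a single slow (5 Hz), strongly damped component — a stereotyped,
spatially simple response.

`gen_reports()` expands the deterministic joint table into 52 (Q1, Q2) pairs,
permutes them uniformly under the seed, and deals them to participants; by
construction the classes are statistically unrelated to the EEG synthesized
for the same awakenings, which is exactly the null the within-sedation models
should not reject.

What the generator does *not* emulate: volume-conducted channel covariance
from real head geometry, artifacts (ocular, muscle, TMS pulse remnants),
nonstationary sedation depth, or any coupling between dream reports and EEG.
Passing tests therefore show that the pipeline measures what it claims on
signals with known structure — not that the measures would detect
experience-linked differences in real sedation EEG, which is precisely the
open scientific question.

## Problem sizes and runtime choices

Synthesis runs at 250 Hz (complexity values are computed on band-limited
signals, so nothing above 45 Hz is lost), 16 channels / 60 s for the
single-measure ordering checks, and a desk-scale cohort — 8 channels, 40-s
wake recordings, the protocol's 60-s sedation recordings, 60 trials per TMS
set — for the 50-seed end-to-end calibration. The cohort scale was chosen by
measuring detectability of the tightest contrast (eyes-open vs eyes-closed
LZc, per-pair effect about 4.7 residual standard deviations at this size)
against per-run cost before the calibration was run. The statistical-layer
calibration uses 500 null replicates (type-I error), 100 recovery replicates
at 200 participants, and 1,000 random Holm vectors.

## Known limitations

* The Q1xQ2 joint table is a reconstruction, not the published table; any
  analysis conditioning on joint cells (rather than margins or class totals)
  inherits that caveat.
* PCIst parameter defaults (component cap, $k$, SNR threshold, grid size) are
  pinned package defaults in the spirit of the method's reference
  implementation, not values asserted by the study they emulate; all are
  exposed in `pcist_params()`.
* The Wilcoxon p-values use the normal approximation throughout; exact
  permutation p-values are out of scope.
* The noise floor of PCIst (see above) means absolute values are comparable
  only within a fixed parameterization; between-condition orderings are the
  robust output.
* With ~50 observations, a 5-member smallest class and right-skewed PCIst
  values, the deep tail of the Satterthwaite Type-III F is only
  approximately calibrated; family-wise decisions at Holm-adjusted
  thresholds below 0.05 inherit that approximation. Kenward-Roger
  denominator df are available via `df_method` for sensitivity analyses.
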