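---
title: "Methods: posterior summarization and mixing diagnostics for MCMC traces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: posterior summarization and mixing diagnostics for MCMC traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tracekit)
```

`tracekit` processes the tab-delimited sample logs written by Bayesian
phylogenetic MCMC software and turns them into the summaries a
practitioner reports: mixing diagnostics, univariate and joint
posterior summaries, and demographic trajectories. This vignette is
the package's own account of the statistics it computes, the defaults
it chose where the field's conventions leave room, and what its test
suite does and does not demonstrate.

## Trace files, types and burn-in

A log file is a header row plus one row per sampled MCMC state; the
first column is the state (generation) counter and must be strictly
increasing and evenly spaced. Two dialects are recognized: BEAST-style
(`#` comment lines; state column named `state` or `Sample`) and
MrBayes `.p` (`[ID: ...]` banner; state column `Gen`). The banner is
an unambiguous sentinel, so auto-detection keys on it. If no
recognized state-column name is present the first column is used with
a warning rather than an error, since some programs use other labels
for the same counter.

Column types are inferred from the raw tokens: any unparseable token
makes a column categorical, all-whole numbers make it integer,
anything else real. The caller can override the inference per column;
this matters for indicator columns in stochastic-search output, which
are integer by construction even when a particular file happens to
contain only `0`s.

Burn-in defaults to 10% of the final state, rounded down to a multiple
of the sampling interval — the de-facto default of interactive trace
viewers. Samples at states at or beyond the burn-in point are
retained, so with states 0..10000 every 1000 a 10% burn-in keeps the
ten samples at states 1000..10000 and a zero burn-in keeps all eleven;
the full record is kept in the object so the choice is revisable. A
burn-in at or past the final state is an error (nothing would remain).

Replicate files with identical trace names and types can be combined;
samples are concatenated in file order. Combining files with different
sampling intervals is permitted: every permutation-invariant statistic
(mean, median, HPD, frequency tables) is unaffected, and the
autocorrelation machinery never crosses the concatenation boundary
(see below). This is one defensible choice for a situation the
conventions do not pin down.

## Effective sample size

For a trace $x_1,\dots,x_n$ sampled every $s$ states, let
$\gamma(k) = \tfrac1n \sum_i (x_i-\bar x)(x_{i+k}-\bar x)$ be the
empirical autocovariance. The truncated sum

$$ V = \gamma(0) + 2\sum_{\text{even } k \ge 2}
       \left[\gamma(k-1)+\gamma(k)\right] $$

accumulates consecutive lag pairs while each pairwise sum is positive
and stops at the first non-positive pair (the paired
initial-positive-sequence rule), capped at lag 2000 by default (the
cap is configurable via `max_lag`; it bounds work on pathologically
long-memory chains). Then

* ACT $= s\,V/\gamma(0)$ (state units),
* ESS $= n s / \text{ACT} = n\,\gamma(0)/V$, capped at $n$,
* SE$(\bar x) = \sqrt{V/n}$.

The pairwise truncation guarantees $V \ge \gamma(0)$, so ACT is never
below the sampling interval and ESS never exceeds $n$; the cap is kept
anyway as a belt-and-braces guard, because an ESS above $n$ only
confuses users. Zero-variance chains (common for indicator columns
fixed at one value) report ESS $= n$ with a `degenerate` flag rather
than `NaN`. Traces shorter than 4 samples have no autocorrelation
estimate; summaries fall back to the uncorrected $s/\sqrt n$ standard
error with ACT/ESS undetermined. Categorical traces have no ESS at
all and asking for one is an error, not a silent skip.

ESS values are flagged against the conventional cut-offs — `LOW`
below 100, `MEDIUM` in [100, 200), `OK` at 200 and above.

For a combined trace the ACT is estimated within each component chain
with its own sampling interval, and component ESS values are summed:
autocorrelation does not span independent chains, so estimating it
across the concatenation boundary would be meaningless.

The estimator is calibrated in the test suite against stationary AR(1)
chains, whose integrated autocorrelation time is $(1+\phi)/(1-\phi)$
sampling intervals in closed form, and checked for numerical
equivalence against a literal double-loop transcription of the
formulas above.

## Univariate summaries

**HPD interval.** The 95% highest posterior density interval is the
shortest contiguous window of the sorted samples containing
$m = \max(1, \mathrm{round}(0.95\,n))$ of them (half-up rounding);
ties between equally narrow windows are broken by the lowest start
index, making the result deterministic. The implementation is checked
against exhaustive enumeration of every window. Note the HPD of a
multimodal sample need not contain the median.

**Quantiles.** All quartiles/medians use linear interpolation between
order statistics (R's default type-7 rule), stated here because
boxplot hinges computed by other conventions differ visibly at small
$n$.

**KDE.** Gaussian kernel with Silverman's rule-of-thumb bandwidth
$h = 0.9\min(s, \text{IQR}/1.34)\,n^{-1/5}$, evaluated on 512 equally
spaced points spanning $[\min - 3h, \max + 3h]$. When one of $s$ and
IQR is zero (heavily tied samples) the positive one is used. There is
no boundary correction by default — the estimate of a strictly
positive parameter can leak mass below zero — but an optional
lower-bound reflection (`reflect_lower`) is available. These are
configuration defaults of this package, not claims about any
particular GUI's rule.

**Histograms.** Equal-width bins over the sample range; the automatic
bin count $\max(10, \lceil\sqrt n\rceil)$ capped at 100 is likewise
this package's own rule. The right-most bin is closed so counts always
sum to $n$.

**Violin data** is the KDE tagged for mirrored rendering; **frequency
tables** order integer levels numerically and categorical levels
lexically, stable across runs.

## Joint-marginal summaries

The joint table of two discrete traces is the empirical joint
probability matrix on aligned samples; its row and column sums
reproduce each trace's frequency table exactly, which the tests assert
to $10^{-12}$. The tile threshold (default 0.01, configurable) only
marks cells for background shading; it has no statistical meaning.

Correlation matrices use Pearson's $r$ with the standard correlogram
glyph: semi-axes $\sqrt{1+|r|}$ and $\sqrt{1-|r|}$ at $+45°$ for
positive and $-45°$ for negative correlation, so independence draws a
circle and perfect (anti)correlation a line.

Conditioning a continuous parameter on a discrete one slices the
continuous trace by level, by row index within one file — conditioning
across different files is refused, because matching samples between
independent chains has no meaning. Levels observed fewer than twice
report counts only and are flagged. The BSSVS rate summary is exactly
this conditioning at indicator level 1, plus the inclusion probability
$P(I=1)$; a rate whose indicator is never (or only once) 1 has no
support to summarize and errors.

## Demographic reconstruction

Time runs backwards: $t=0$ at the most recent sample, increasing into
the past, and a growth rate $r>0$ means growth toward the present —
hence $N(t) = N_0 e^{-rt}$ for the exponential model. The logistic
model uses the shape parameterization
$N(t) = N_0(1+c)/(1+c\,e^{rt})$, $c>0$; alternative $t_{50}$
parameterizations must be transformed by the caller. The skygrid is
piecewise constant, $N(t) = e^{\theta_j}$ on the $j$-th of $K$ equal
bins of $[0,T]$, extended beyond the cutoff $T$ at the last bin's
value. Skygrid columns are discovered by a configurable name prefix
and ordered by trailing integer index; the cutoff is supplied by the
user, as it is an analysis setting not reliably present in logs.

`reconstruct_trajectory()` evaluates $N(t)$ for every retained
posterior sample at every grid time and summarizes each time point by
the across-sample median and 95% HPD, computed with the same
`hpd_interval()` used everywhere else (asserted exactly in the tests).
The HPD is taken on the natural scale by default with a log-scale
option: HPD intervals are not transform-invariant and either
convention is defensible, so both are offered. Medians, by contrast,
commute with monotone maps, so the median trajectory is
scale-independent (exactly so for odd sample counts; for even counts
the mid-pair average introduces a negligible difference between the
scales).

## Synthetic fixtures and what the tests show

All test inputs are generated by the package's own seedable
generators: stationary AR(1) chains (the ESS calibration target),
i.i.d. normals, BSSVS indicator/rate pairs (Bernoulli indicator;
log-normal "on" distribution with CV 0.25 and a near-zero slab at
1/1000 of the on-mean), zero- or low-noise skygrid blocks, and
categorical columns. Every generator is a pure function of its seed
through `withr::with_seed`, so tests never depend on or disturb global
RNG state.

These fixtures emulate the statistical structure of real MCMC output —
autocorrelation, spike-and-slab mixtures, piecewise-constant
demographics — but not its pathologies: no within-chain
non-stationarity, no heavy-tailed likelihood spikes, no adaptive-phase
transients, no tree-topology component at all. A green suite therefore
demonstrates that the estimators compute what they claim on chains
with known truth, not that any particular real analysis has converged.
Problem sizes were chosen to make sampling noise small relative to the
tested tolerances while keeping the default suite fast: ESS
calibration uses chains of 50 000 samples over 20 seeds per
coefficient, HPD coverage 500 replicates of 2 000 draws, BSSVS
recovery 100 000 samples.

## Known limitations

* Bayesian skyline and skyride reconstructions need the sampled
  genealogies, which live in tree files, not parameter logs; only the
  log-file-based skygrid and the parametric models are implemented.
* No cross-chain convergence diagnostics (e.g. Gelman–Rubin); other
  packages cover these.
* Log-file dialects beyond the two implemented (LAMARC, Migrate,
  RevBayes quirks) are not special-cased; files following the generic
  header-plus-TSV shape still parse via the fallback state column.
* Streaming/partial logs are unsupported: a file is parsed whole, and
  a truncated final row is a parse error by design.
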