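# tracekit

Headless posterior summarization and convergence diagnostics for MCMC
trace files from Bayesian phylogenetic software.

Bayesian phylogenetic packages (BEAST, BEAST2, MrBayes, ...) write the
parameter values visited by their Markov chains to tab-delimited log
files. Everything a practitioner reports — posterior means, credible
intervals, demographic trajectories — is computed from these samples,
and every such report first needs a mixing diagnostic to show the chain
actually explored the posterior. `tracekit` provides that pipeline as a
scriptable R library plus a small command-line tool: no GUI, fully
reproducible, testable offline against its own synthetic-trace
generators.

## What it computes

**Trace I/O.** Parses BEAST-dialect logs (`#` comments, `state` column)
and MrBayes `.p` files (`[ID: ...]` banner, `Gen` column) with
automatic dialect detection; columns are typed as real, integer or
categorical. Burn-in defaults to 10% of the final state and is
revisable (`set_burnin()`). Replicate files exposing the same
parameters can be pooled (`combine_traces()`).

**Mixing diagnostics.** The effective sample size of a trace of `n`
samples taken every `s` states is

    ESS = n * s / ACT,   ACT = s * V / gamma(0),

where `gamma(k)` is the empirical autocovariance at lag `k` and `V`
truncates the sum `gamma(0) + 2 * sum_k gamma(k)` by the paired
initial-positive-sequence rule: consecutive lag pairs
`gamma(k-1) + gamma(k)` are accumulated while positive and the sum
stops at the first non-positive pair. ESS values are flagged with the
conventional cut-offs: `LOW` below 100, `MEDIUM` from 100 to 200, `OK`
above.

**Univariate summaries.** Mean, standard deviation,
autocorrelation-corrected standard error, median, min/max, and the
highest posterior density (HPD) interval — the shortest contiguous
window of the sorted samples containing the requested mass. Density
visualization data: Gaussian KDE with Silverman bandwidth
`0.9 * min(s, IQR/1.34) * n^(-1/5)`, equal-width histograms, boxplot
statistics (type-7 quartiles, 1.5 IQR whiskers) and mirrored-KDE
violin data, plus frequency tables for discrete traces.

**Joint-marginal summaries.** Joint probability tables of two discrete
traces (bubble-chart data with a nominal tile threshold), Pearson
correlation matrices with the standard correlogram ellipse glyph
(`sqrt(1 ± |r|)` semi-axes at ±45°), aligned scatter data, and
conditional posteriors of a continuous parameter given a discrete one.
For Bayesian stochastic search variable selection (BSSVS),
`bssvs_rate_summary()` summarizes a rate using only the samples where
its binary indicator equals one and reports the inclusion probability.

**Demographic reconstruction.** Constant, exponential
(`N(t) = N0 e^(-rt)`, `t` increasing into the past) and logistic
(`N(t) = N0 (1+c) / (1 + c e^(rt))`) coalescent models, and the
non-parametric skygrid (piecewise-constant `exp(theta_j)` on K equal
bins up to a cutoff T). `reconstruct_trajectory()` evaluates N(t) for
every posterior sample on a time grid and reports the pointwise median
and 95% HPD envelope.

**Synthetic fixtures.** Seedable generators (`gen_ar1()`,
`gen_bssvs_pair()`, `chain_spec()` + `write_log()`) produce
dialect-correct log files with known statistical structure, e.g. AR(1)
chains whose theoretical autocorrelation time `(1+phi)/(1-phi)` is the
calibration target for the ESS estimator.

## Worked example

```r
library(tracekit)

# a synthetic BEAST-dialect log: an autocorrelated likelihood trace, a
# well-mixed substitution parameter, and a BSSVS indicator/rate pair
spec <- chain_spec(n = 2000, step_size = 500, seed = 42, columns = list(
  col_ar1("treeLikelihood", phi = 0.6, mean = -4520, sd = 6),
  col_iid_normal("kappa", mean = 4.2, sd = 0.35),
  col_indicator("rateIndicator.AZ", p_on = 0.35,
                rate_name = "rate.AZ", rate_on_mean = 1.8)))
write_log(spec, "demo.log", dialect = "beast")

tf <- parse_log("demo.log")
tf
#> <trace_file 'demo.log'> dialect=beast states 0..999500 by 500, burn-in 99500
#>   4 traces, 1801 post-burn-in samples: treeLikelihood, kappa, rateIndicator.AZ, rate.AZ

summarize_trace(get_trace(tf, "kappa"), tf$step_size)
#> <trace_summary 'kappa'> n=1801
#>   mean 4.20296 (se 0.00833592), sd 0.35386, median 4.20297
#>   95% HPD [3.53779, 4.92764], ACT 500, ESS 1801 (OK)

s <- bssvs_rate_summary(get_trace(tf, "rate.AZ"),
                        get_trace(tf, "rateIndicator.AZ"), tf$step_size)
s
#> <trace_summary 'rate.AZ'> n=625
#>   mean 1.79072 (se 0.0184336), sd 0.461209, median 1.72757
#>   95% HPD [0.978729, 2.72187], ACT 500, ESS 625 (OK)
s$inclusion_prob
#> [1] 0.3470294
```

The `kappa` summary says: posterior mean 4.20 with a Monte Carlo
standard error of 0.008, 95% of the posterior mass in [3.54, 4.93],
and 1801 effectively independent draws — comfortably above the 200
cut-off, so the estimate is trustworthy. The BSSVS summary restricts
`rate.AZ` to the 625 samples (34.7% of states) where its indicator is
one: conditioning recovers the "on" mean 1.79 instead of the shrunken
unconditional average.

The same pipeline is available from a shell via the thin CLI wrapper:

```sh
TK=$(Rscript -e 'cat(system.file("cli", "tracekit.R", package = "tracekit"))')
Rscript "$TK" summary demo.log --burnin 0.1
Rscript "$TK" plot demo.log --which density --params kappa --out kappa_density
Rscript "$TK" synth --seed 7 --out synthetic
```

Subcommands: `summary`, `plot`, `combine`, `demographic`, `synth`.
Every plot writes its underlying numbers as TSV next to the image.
Exit codes: 0 success, 1 usage error, 2 parse error, 3 a `LOW`-flagged
trace under `--strict`.

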