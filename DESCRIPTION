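Package: tracekit
Title: Posterior Trace Exploration and Convergence Diagnostics for
    Bayesian Phylogenetic MCMC Output
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Headless toolkit for processing MCMC trace (log) files
    produced by Bayesian phylogenetic software such as BEAST and
    MrBayes. Parses tab-delimited sample logs with automatic dialect
    and parameter-type detection, estimates autocorrelation times and
    effective sample sizes with the conventional 100/200 mixing
    cut-offs, computes univariate posterior summaries (means, highest
    posterior density intervals, kernel density estimates, histograms,
    boxplot and violin data, frequency tables), joint-marginal
    summaries (joint probability tables for discrete pairs,
    correlation matrices with ellipse glyph parameters, conditional
    posteriors including indicator-conditioned rate summaries under
    Bayesian stochastic search variable selection), and demographic
    trajectory reconstruction (constant, exponential and logistic
    growth coalescent models and the non-parametric skygrid),
    summarized as median and HPD envelopes over time. Includes
    seedable synthetic log-file generators for fully offline testing
    and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
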