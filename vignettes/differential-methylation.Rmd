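---
title: "Detecting differential RNA methylation from MeRIP-seq with a Poisson random-effect model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting differential RNA methylation from MeRIP-seq with a Poisson random-effect model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A MeRIP-seq (m6A-seq) experiment produces two libraries per sample: an
INPUT library sequenced from the fragmented RNA pool before antibody
pull-down, which measures expression, and an IP library of fragments
captured by the anti-m6A antibody, which measures methylated RNA abundance.
Differential methylation (DM) between two groups of samples means a change
in methylated abundance *conditional on* expression, so a DM test has to
work with both measurements in pairs; differential-expression tools that
compare a single count per feature do not apply directly.

`meripdm` divides each gene's concatenated exons into fixed-width bins
(default 50 nt), counts INPUT and IP fragments per bin, normalizes the two
channels separately, adjusts IP counts for pre-IP expression, and tests
each bin with a Poisson random-effect regression that accepts covariates.

## Counting

Gene models are exon unions: all annotated exon records of a gene are
merged and concatenated in genome order into one transcript, which the bin
grid tiles ([0, 50), [50, 100), ...; the last bin of a gene may be shorter
and a gene shorter than one bin gets a single bin). Internally all
coordinates are 0-based half-open; GTF input is read as 1-based inclusive
and BED12 output is 0-based, so both ends match their conventions.

Each fragment — a single-end read, or a properly-paired mate pair collapsed
to its leftmost-start/rightmost-end span — is clipped to the gene's exon
union and assigned to the one bin containing the midpoint of its transcript
span. The midpoint rule is a deliberate choice where several conventions
exist: it guarantees each counted fragment contributes exactly once within
a gene (so gene-level sums equal fragment counts) and it places
junction-spanning reads sensibly. Counting is unstranded by default;
`strandness = "forward"/"reverse"` restricts by read orientation. Reads
below a mapping-quality floor and secondary/supplementary alignments are
dropped. At a bin size of 50 nt, libraries of 20 M mappable reads or more
give adequate per-bin coverage; for shallower libraries (< ~15 M) a 100-nt
bin is the better trade of resolution against sampling noise.

## Normalization and expression adjustment

The INPUT channel is an ordinary RNA-seq library, so sample depth is
estimated by median-of-ratios on *gene-level* INPUT counts (`geneSum`).
Gene-level rather than bin-level counts matter: a typical bin holds a few
reads, and Poisson noise at that scale leaks directly into the estimated
expression background; summing the ~10-fold larger gene total suppresses
it, at the cost of under-representing exon-specific expression changes
(see Limitations).

The IP channel depends on sequencing depth *and* antibody efficiency, so
its size factor is estimated from fold enrichment E = IP count / normalized
geneSum, averaged over the top 1% of bins ranked by mean raw IP count
across samples — background bins reflect non-specific binding and would
dilute the efficiency signal. Two details are choices the data cannot
settle and are exposed as arguments: ranking uses the *shared* top set by
mean across samples (keeping E comparable between samples), and the
summary over top bins is the mean, with factors then centred to geometric
mean 1 to fix the scale gauge. `summary = "median"` switches the summary.

Expression adjustment divides each bin's normalized IP count by a
gene-wise factor: the gene's normalized counts centred to mean 1 across
samples (arithmetic mean; the centred factors then average to exactly 1,
which the tests exploit). A sample where a gene has zero counts would give
an infinite adjustment, so factors are floored at 0.1 x the gene's mean
factor with a warning. Adjusted IP values stay real-valued through
normalization and are rounded half-to-even only at the model boundary,
because the likelihood below is a count likelihood.

One useful gauge identity, verified in the tests: multiplying one sample's
INPUT and IP libraries by the same constant changes the adjusted matrix
only by a common scalar (the geometric-mean centring re-distributes the
constant), and multiplying one sample's gene counts by k multiplies every
size-factor *ratio* involving that sample by exactly k. The factors
themselves shift by k^(1/n) through the geometric-mean reference, which is
why the equivariance statements are about ratios.

## Filtering

Two group-blind filters run before testing: bins whose mean raw IP count
across samples is below 15 (too noisy, and low IP coverage usually means
no methylation), and IP-depleted bins whose mean enrichment E is below 1
(signal attributable to non-specific binding). Both thresholds are
arguments (`min_ip`, `min_enrichment`). Because the filters ignore group
labels, applying BH only to retained bins does not bias the FDR.

## The model and test

For the processed IP count of one bin across samples,

$$Y_i \sim \mathrm{Poisson}(\lambda_i), \qquad
\log \lambda_i = \mu + X_0 \beta_0 + \textstyle\sum_j X_j \beta_j + e_i,$$

with a bin-specific intercept, the group indicator of interest, optional
covariates, and a random effect with mean-one log-gamma law,
$e^{e_i} = w_i \sim \Gamma(\psi, \psi)$. Integrating the random effect out
gives a negative binomial marginal with shape $\psi$ and mean
$e^{\mu + X\beta}$; the per-bin log-likelihood is

$$\ell = \sum_i \Big[ Y_i(\mu + X\beta) + \psi\log\psi
  + \log\Gamma(Y_i+\psi) - \log Y_i! - \log\Gamma(\psi)
  - (Y_i+\psi)\log(e^{\mu+X\beta}+\psi) \Big].$$

The free scale $\psi$ is what distinguishes this from RNA-seq-style NB
models with a global mean-variance trend: post-IP counts do not follow the
pre-IP trend, so each bin carries its own dispersion.

Estimation maximizes $\ell$ by gradient ascent with a backtracking
(Armijo, c = 1e-4, shrink 0.5) line search; $\psi$ is optimized as
$\log\psi$ so positivity needs no projection. The line-search starting
step is the Barzilai–Borwein spectral step, which cures the slow crawl a
unit-step gradient method suffers on this badly conditioned surface
(intercept and log-dispersion curvatures differ by orders of magnitude);
the Armijo condition still guarantees the objective never decreases.
Initial values are $\mu_0 = \log(\bar Y + 0.5)$, $\beta_0 = 0$, and a
method-of-moments $\psi_0 = \bar Y^2/\max(s^2 - \bar Y, 10^{-8})$ clipped
to [0.1, 1e4]. Convergence requires the log-likelihood increase to fall
below 1e-8 *and* a small gradient; fits that fail within 1000 iterations
are reported with a flag and excluded from BH by default
(`keep_nonconverged = TRUE` re-includes them). Against an independent NB
regression fit the MLEs agree to ~1e-5 in typical cases.

The Wald statistic is $\hat\beta_0/\mathrm{se}(\hat\beta_0)$ with the
standard error from observed Fisher information — the negative Hessian of
$\ell$ at the MLE, computed by central finite differences of the analytic
gradient with steps $10^{-5}(1+|\theta|)$. When the $\psi$ direction is
flat (underdispersed bins push $\psi$ to its bound) the regression block
is inverted instead; a fully singular information matrix yields p = 1 with
a diagnostic flag. Two-sided normal p-values are BH-adjusted across tested
bins.

A numerical footnote: swapping the group labels maps the optimum to
$(\mu+\beta_0, -\beta_0)$, so the mirrored solution is re-found by a fresh
optimization; with the 1e-8 stopping rule the sign-flip symmetry holds to
about 1e-4–1e-3 in the estimates rather than machine precision.

## Post-processing

Bins below the FDR cutoff with consecutive bin indices in the same gene
merge into peaks (bins of different genes never merge). A peak's effect
size is the inverse-variance-weighted mean of member estimates and its
score the minimum padj — both chosen for stability; the paper-level
convention leaves the peak summary open. Peaks map back through the gene
model to genome coordinates as BED12 records, with intron-spanning peaks
becoming multi-block entries and the BED score column set to
min(1000, round(-10 log10 padj)).

## The simulation generators

`simulate_pois_gamma()` draws, per bin, an intercept (per-bin mean count
log-normal, median 30 reads, log-sd 1) and a random-effect scale
($\psi$ log-uniform on [0.5, 20]), then per sample
$w \sim \Gamma(\psi,\psi)$ and $Y \sim \mathrm{Poisson}(e^{\eta} w)$.
Exactly $\lfloor 0.2 \, n_{\text{bins}} \rfloor$ bins are labelled true DM
and receive the effect $\beta_0$ in group 1. The default frame is 26,324
bins by 8 samples (4 vs 4). INPUT counts are negative binomial (shape 10,
biological CV ~0.3) around a log-normal gene depth (median 272 reads,
log-sd 1, 10 bins per gene), and raw IP counts are the simulated
enrichment rescaled to a mean IP/INPUT ratio of 1. The confounded-design
variant adds a binary covariate with effect 2 assigned 3:1 in one group
and 1:3 in the other — a moderately hard confounding, comparable to a
batch split that nearly tracks the phenotype. `simulate_qnb()` is the
alternative generating law: independent negative binomials for INPUT and
IP with the IP dispersion a configurable factor (default 10x) above the
INPUT dispersion, and the DM effect applied multiplicatively to the IP
mean.

What the generator emulates: per-bin overdispersion unrelated to the
expression mean-variance trend, realistic count magnitudes, exact truth
labels, confounded covariates. What it does not: correlated bins within a
peak, GC/mappability structure, expression changes coupled to methylation
changes, alternative splicing. Passing benchmarks here therefore speak to
the statistical engine, not to alignment- or annotation-level artefacts.

The distributions for the intercept and dispersion are synthetic
stand-ins, fully parameterized so the benchmark needs no external data.
This matters when comparing against published benchmark figures whose
generators drew these parameters from fits to a real islet dataset:
sensitivity and empirical FDR are strong functions of the $\psi$ law. With
the [0.5, 20] log-uniform law used here, a single full-size copy at BH 10%
gives roughly 41% sensitivity at effect 0.75, 59% at effect 1.0, with
empirical FDR around 38–50% — the pooled Fisher comparator on the same
data sits near 73% FDR and is always worse. Published figures derived from
empirically-drawn, less-overdispersed parameters are substantially higher
in sensitivity and near-nominal in FDR; matching them would need effective
$\psi$ in the 10–30 range.

## Calibration at small n

The Wald test is asymptotic, and with 4 + 4 samples and a per-bin
dispersion MLE it is anti-conservative — an inherent small-sample property
of per-feature NB Wald tests, not of this implementation (an independent
`MASS::glm.nb` oracle rejects 17.4% at nominal 5% under the null at
$\psi = 1$, n = 8). Consequences worth knowing: empirical FDR at BH 10%
exceeds the nominal level under heavy overdispersion; 20,000-bin KS tests
detect the non-uniformity of null p-values even where the BH rejection
fraction on a pure null stays well under 11%; and with 1 vs 1 samples the
per-bin model is saturated and makes no calls at all. Five or more
replicates per group is the practical recommendation, and the sample-size
sweep (`sample_size_sweep()`) reproduces the expected trends: sensitivity
rises monotonically with replicates, and FDR falls over 4 → 6 → 8 samples.

## Problem sizes used by the test suite

Unit tests run on 100–2,500-bin frames; benchmark-level tests run single
full-size copies (26,324 bins x 8 samples, ~10 s per dataset in the
compiled fitter), a 20,000-bin null calibration, and a sample-size sweep
at 8,000 bins x 2 copies. The acceptance script re-simulates four
full-size datasets and the Fisher comparator in under a minute.

## Limitations

Gene-level expression adjustment under-represents exon-specific expression
changes (alternative splicing can mimic DM); filtering DM calls that
coincide with annotated alternative exons is a sensible post-hoc guard.
The per-bin dispersion is estimated without information sharing across
bins, which is exactly what makes small-n calibration hard; empirical-Bayes
shrinkage of $\psi$ is out of scope here. Likelihood-ratio or score tests,
and interaction designs beyond additive covariates, are likewise not
implemented.
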