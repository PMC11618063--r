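---
title: "Estimating replication probabilities from meta-analytic z statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating replication probabilities from meta-analytic z statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(replimix)
library(dplyr)
```

## The model

Each observed effect size $\overline{ES}$ is assumed normal around its true
value with known sampling variance, $\overline{ES}\mid ES \sim N(ES, V)$.
Dividing by the standard error gives the z statistic
$z = \overline{ES}/SE$ and the signal-to-noise ratio $SNR = ES/SE$, so that

$$z \mid SNR \sim N(SNR, 1).$$

The marginal distribution of z is therefore the SNR distribution convolved
with standard normal noise. We model the marginal density of z as a
zero-mean Gaussian *scale* mixture,

$$f(z) = \sum_{k=1}^{K} w_k\, \varphi(z/\sigma_k)/\sigma_k,
  \qquad \sigma_k \ge 1,$$

with $K = 4$ by default. The zero-mean restriction encodes the prior
symmetry of effect directions across a whole research field; the floor
$\sigma_k \ge 1$ is forced by the unit noise variance. Deconvolution is then
exact and trivial: the SNR density is the same mixture with component scales
$\tau_k = \sqrt{\sigma_k^2 - 1}$. A component at the boundary
$\sigma_k = 1$ is a point mass of true nulls. We deliberately allow the
boundary: a strictly open constraint has no maximum-likelihood solution,
and a null spike is scientifically meaningful.

Effects cluster within studies and are correlated there. Rather than model
the dependence, estimation weights every effect inversely to its study's
effect count ($w_{ij} = 1/n_j$, each study totalling weight 1), so the
weighted log-likelihood behaves like a sample of $J$ independent studies.
This is also why the confidence construction below counts studies, not
effects.

### Fitting

`fit_z_mixture()` maximizes the weighted log-likelihood by EM. The M-step
for a scale is the weighted responsibility-average of $z^2$, clipped at 1;
clipping preserves EM's monotone ascent because the per-component objective
is unimodal in $\sigma_k^2$. Mixture likelihoods are multimodal, so the
best of 5 restarts is kept; scales start on a geometric ladder from 1.1
to 8 (spanning the SNR range seen in practice) and are jittered per
restart. Convergence is declared at a relative log-likelihood change below
1e-9 (cap 10,000 iterations). Components with weight below 1e-8 are pruned
and coincident scales merged, so the reported $K$ is effective, not
nominal. Fits are deterministic given the seed.

## Replication probability

A (hypothetical) exact replication of a study with statistic z succeeds
when it is significant in the same direction:
$z \cdot z_{repl} > 0$ and $|z_{repl}| > c$, with
$c = \Phi^{-1}(1-\alpha/2)$ at the two-sided level $\alpha = 0.05$. We use
the computed threshold 1.959964... rather than the rounded 1.96 for
internal consistency across $\alpha$; the difference is below $10^{-4}$ in
probability.

Given the fitted mixture, the posterior of SNR given z is again a normal
mixture with component probabilities
$\pi_k(z) \propto w_k\varphi(z/\sigma_k)/\sigma_k$, means
$\mu_k = z\,\tau_k^2/\sigma_k^2$ and variances $v_k = \tau_k^2/\sigma_k^2$
(`posterior_snr()`). If the replication sample is $m$ times larger its SNR
scales by $\sqrt m$, so $z_{repl}\mid z, k \sim N(\sqrt m\,\mu_k,\,
m v_k + 1)$ and, for $z > 0$,

$$P(\text{success}\mid z) = \sum_k \pi_k(z)\,
  \Phi\!\left(\frac{\sqrt m\,\mu_k - c}{\sqrt{m v_k + 1}}\right),$$

with the mirror image for $z < 0$. At exactly $z = 0$ the direction is
ill-posed; `replication_probability()` returns the significance-only
probability there and warns, so curves can be evaluated at a grid origin
without special-casing. As $m \to 0$ the probability tends to $\alpha/2$
(a lucky significant result in the right direction); under a pure-null
mixture it equals $\alpha/2$ for every $z$ and $m$ — two limits the test
suite pins exactly. The closed form is verified against a brute-force
Monte-Carlo oracle (sample the posterior, then $z_{repl}$) at $10^6$ draws.

`required_sample_factor()` inverts the curve in $m$ by bisection on
$\log m$ over $[10^{-6}, 10^4]$ to a probability tolerance of $10^{-4}$,
returning the continuous fold increase (callers may round up). When the
posterior leaves the supremum below the target — e.g. a dominant null spike
— the function refuses with the supremum estimate rather than returning the
cap.

Statistical power given the SNR is
$\Phi(-c - SNR) + 1 - \Phi(c - SNR)$, which includes wrong-direction
rejections and is strictly increasing in $|SNR|$; `power_distribution()`
exploits that monotonicity to turn the fitted SNR distribution into the
power distribution by numerical inversion (bisection on $|SNR| \in [0,50]$,
tolerance $10^{-10}$). Power cannot fall below $\alpha$, so requested CDF
points must exceed it.

## Simultaneous confidence bands (F-localization)

Point estimates say nothing about estimation uncertainty in the deconvolved
mixture, which is what dominates uncertainty in the replication curve. The
band construction avoids committing to $K = 4$: it considers *all*
zero-centred Gaussian scale mixtures on a dense geometric grid of SNR
scales, $\sigma_j = 10^{-5}\cdot 1.05^{j-1}$, 365 components up to
$\approx 516.3$ (`build_sigma_grid()`). The smallest scale is numerically a
null spike; the largest exceeds any plausible SNR.

The data constraint is an envelope around the study-weighted empirical CDF
of $|z|$ (a folded statistic, since the class is symmetric). Values of
$|z|$ below 2.3 and above 10 are censored into two interval cells: the
lower cut guards against mild p-hacking around the significance threshold
and misspecification near the origin, the upper against outliers. The
envelope half-width is the Dvoretzky–Kiefer–Wolfowitz bound
$\varepsilon = \sqrt{\log(2/\alpha_{band})/(2J)}$ with $J$ the number of
*studies*: each study contributes a weight-1 sub-ECDF through its $1/n_j$
effect weights, which makes the ECDF an average of $J$ independent
study-level CDFs and licenses the study-level DKW bound under arbitrary
within-study correlation. This study-level construction is our design
choice for handling dependence; it may be conservative relative to sharper
dependence-adjusted envelopes.

For a weight vector $\pi$ on the grid, the replication probability at
$z_0$ is the linear-fractional functional
$R(\pi) = \sum_j \pi_j f_j(z_0) r_j(z_0,m) \,/\, \sum_j \pi_j f_j(z_0)$,
with $f_j$ the component marginal density of z and $r_j$ the
single-component closed form above. `band_for_replication()` minimizes and
maximizes $R$ subject to $\pi$ lying in the simplex and the model CDF
matching the empirical CDF within $\varepsilon$ at every evaluation point
and both censored cells. Each extremum is a single linear program after the
Charnes–Cooper transform (normalize the denominator to 1); we solve the
pair per $z_0$ with `boot::simplex()` at feasibility tolerance $10^{-10}$
and clip values into $[0,1]$. Every $z_0$ shares one feasible set, so the
band is simultaneous at level $1-\alpha_{band}$. By default the envelope is
enforced at 200 equally spaced points in the censoring window — dense
enough that adding points moves bands by well under $10^{-3}$; validation
runs use 40 points, which leaves coverage conservative (fewer constraints
can only widen the band).

An infeasible localization (possible with very small $\varepsilon$ or an
empirical CDF inconsistent with the class) raises an error suggesting a
coarser censor window or larger $\alpha_{band}$ rather than returning an
empty band.

## The synthetic cohort generator

`generate_cohort()` exists so every stage can be tested against known
ground truth without any data download. It emulates the features the
estimator relies on:

- studies with zero-truncated Poisson effect counts, default mean
  $\approx 6.82$ effects/study (the scale of large ecology/evolution
  meta-analytic databases: roughly 88,000 effects from 13,000 studies);
- SNR drawn from a zero-centred scale mixture (default weights 0.6/0.4,
  z-scale spreads 1.5/4 — a mostly-modest-signal field with a heavy tail);
- within-study dependence through a shared latent study effect carrying a
  fraction $\rho$ (default 0.5) of the component's SNR variance — the
  simplest mechanism giving exchangeable within-study correlation exactly
  $\rho$;
- unit-variance estimation noise, $z = SNR + \epsilon$;
- log-normal standard errors (location $-0.5$, scale $0.6$; positive and
  right-skewed, otherwise arbitrary and cosmetic — they only split z into
  `es`/`se`) and effect-type labels at 45/36/15/4% for SMD/lnRR/Zr/other;
- optional significance-based thinning (`apply_selection()`): significant
  effects always survive, others with probability $s$ — a deliberately
  crude publication-bias caricature used to demonstrate that selection
  inflates fitted replicability.

It does **not** emulate heterogeneity between original and replication
study (the exact-replication idealization is kept), non-normal sampling
distributions, correlated standard errors and effect sizes, or realistic
p-hacking. Passing tests on these cohorts show the estimator recovers the
truth *under its own assumptions*; they cannot certify robustness to
selection bias, which biases real-data estimates upward.

All generation is vectorized under a single seed with the caller's RNG
state saved and restored; identical (config, seed) pairs give identical
tables.

## Validation problem sizes

The shipped tests recover a two-component truth from a 20,000-study cohort
(curve error below 0.02 at z = 1.96–3.89, planning fold within 10%), match
the Monte-Carlo oracle on 20 random mixtures at $10^6$ draws within three
binomial standard errors, and confirm band coverage on 200 cohorts of
2,000 studies (truth curve inside the simultaneous band at the nominal 95%
rate minus binomial slack). Band validation uses 40 envelope points and
four z values per cohort.

## Worked example

```{r example}
cohort <- generate_cohort(cohort_config(n_studies = 2000, seed = 1))
fit <- fit_z_mixture(cohort, K = 4, restarts = 3)
tidy(fit)
replication_probability(fit, c(1.96, 2.58, 3.29))
required_sample_factor(fit, 1.96, target = 0.75)
band <- replication_band(cohort, z_grid = c(1.96, 2.58, 3.29), n_eval = 60)
band
```

## Known limitations

- Replicability is defined for idealized exact replications; real
  replications add heterogeneity and will replicate less often.
- No selection adjustment: under publication bias the fitted SNR
  distribution is too optimistic and every reported probability is an
  upper bound.
- The study-level DKW extension is an approximation whose exact
  conservatism depends on the dependence structure.
- The EM point estimate fixes $K$; sensitivity should be checked by
  refitting with other $K$ (the band does not share this restriction).
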