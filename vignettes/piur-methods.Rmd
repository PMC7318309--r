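---
title: "Profile inter-unit reliability: model, calibration and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profile inter-unit reliability: model, calibration and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(piur)
```

## The model and the two reliability scales

Patient outcomes nest within providers under the one-way linear model
$$Y^*_{ij} = \mu + \alpha_i + X_{ij}'\beta + \epsilon_{ij}, \qquad
\alpha_i \sim N(0, \sigma_b^2), \quad \epsilon_{ij} \sim N(0, \sigma_w^2),$$
with $i = 1, \dots, m$ providers and $n_i$ patients in provider $i$. Large
outcomes are read as poor. Risk adjustment subtracts $\mu + X'\beta$; the
provider mean $\bar Y_i$ of the adjusted outcome estimates $\alpha_i$ with
variance $\sigma_b^2 + \sigma_w^2/n_i$.

The **inter-unit reliability** is the fraction of that variance that is
between-provider signal, $IUR_i = \sigma_b^2 / (\sigma_b^2 +
\sigma_w^2/n_i)$, and overall $IUR = \sigma_b^2 / (\sigma_b^2 +
\sigma_w^2/n')$ with $n'$ the effective size from the unbalanced one-way
ANOVA expectation of the between sums of squares. `piur` estimates the
components by method of moments from that decomposition
(`estimate_variance_components()`): the within mean square for
$\sigma_w^2$, and $(SSB/(m-1) - \hat\sigma_w^2)/n'$ for $\sigma_b^2$,
clamped at zero (the clamp is reported). REML would be marginally more
efficient but the moment estimator is the one whose expectation defines
$n'$, and it is exact to audit; we deliberately stay with it.

The IUR measures *average* separability. The **profile IUR** measures
*consistency of outlier identification*: split each provider's patients
into random halves, flag both halves, estimate the reflagging rate
$\hat\theta_{B|A}$, and report the IUR value $\tilde R$ that would produce
that rate under the null model, $G(\tilde R) = \hat\theta_{B|A}$. The two
scales agree when the model holds exactly; contamination by outlier
providers raises the PIUR above the IUR.

## Profiling methods and their calibration curves

Four flagging rules are implemented (`flag_config()`, `profile_panel()`),
all one-sided at level $p$ (default $0.025$, the conventional reporting
choice; `direction = "better"` mirrors to the lower tail):

* **FE**: $Z_{FE,i} = \bar Y_i / (\sigma_w/\sqrt{n_i})$, compared to $z_p$.
* **RE**: $Z_{RE,i} = \sqrt{IUR_i}\, Z_{FE,i}$, the BLUP-based score. Its
  null variance is $\rho/(1-\rho)$, not 1, and it is still compared to
  $z_p$ — that is the construction being calibrated, so no
  re-standardization is applied.
* **FERE**: $Z_{FERE,i} = \bar Y_i / \sqrt{\sigma_b^2 + \sigma_w^2/n_i} =
  \sqrt{1 - IUR_i}\, Z_{FE,i}$, marginally standard normal for every $n_i$.
* **EN**: the FE score judged against a normal fitted robustly to the
  central mass of all FE scores (below).

The displayed relations between the scores are implemented with square
roots, $\sqrt{IUR_i}$ and $\sqrt{1-IUR_i}$: these are the readings forced
by the stated variances ($\rho/(1-\rho)$ for RE, exactly 1 for FERE), and
the test suite checks both identities algebraically and the variances by
Monte Carlo.

Across random half-splits, the two half-sample Z-scores of a provider with
$IUR_i = R$ are bivariate normal with correlation $\rho = R/(2-R)$, and
each method's conditional reflagging probability is a ratio of bivariate to
univariate normal tails:
$$G_{FE}(R) = \frac{\Phi_{2,\rho}(s_1, s_1)}{\Phi(s_1)},\quad
s_1 = -z_p\sqrt{1-\rho}; \qquad
G_{RE}(R): s_2 = s_1/\sqrt{\rho}; \qquad
G_{FERE}(R): s_3 = -z_p.$$
$G_{FE}(0) = G_{FERE}(0) = p$; all three increase strictly in $R$ and
approach 1 as $R \to 1$ (slowly, at rate $\sqrt{1-\rho}$ — $G_{FERE}(0.999)
\approx 0.94$). The EN method is calibrated against $G_{FERE}$, to which it
is asymptotically equivalent under the null model.

Bivariate normal probabilities come from `mvtnorm`'s double-precision
TVPACK algorithm (absolute error far below the $10^{-8}$ we require),
cross-checked in tests against the closed-form orthant probability and a
Monte-Carlo oracle. Inversion of $G$ (`piur_from_theta()`) uses Brent
bracketed root finding on $[0, 1-10^{-9}]$, verified to
$|G(\tilde R) - \theta| \le 10^{-8}$; rates at or below $G(0)$ clamp to 0
and rates at 1 clamp to $1 - 10^{-9}$, with the clamp recorded. $G_{RE}$
underflows to $0/0$ below $R \approx 0.006$ (the RE flag probability itself
vanishes there), so its inversion brackets from $0.006$ and clamps below.

## The contamination model and the theoretical PIUR

Outlier providers are modelled by a two-component mixture: with probability
$\pi_1$ a provider's effect comes from an outlier distribution supported
above a bound $C$ instead of $N(0, \sigma_b^2)$. The analytic results use a
point mass at $\gamma\,\sigma_T$, where $\sigma_T = \sqrt{\sigma_b^2 +
\sigma_w^2/n'}$ is the total standard deviation of a provider mean; the
simulator also offers a half-normal alternative shifted to $C = 2\sigma_b$
and scaled so the mean outlier effect is $\gamma\sigma_T$
(`outlier_kind = "truncated_density"`), for model-faithful experiments.

For the point-mass mixture the FERE reflagging probability is
$$\theta(R) = \frac{\pi_0\,\Phi_{2,\rho}(-z_p,-z_p) + \pi_1\,\Phi(s)^2}
                   {\pi_0\,\Phi(-z_p) + \pi_1\,\Phi(s)}, \qquad
s = \frac{-z_p}{\sqrt{1-\rho}} + \frac{\gamma}{\sqrt{2-2R}}.$$
The squared tail $\Phi(s)^2$ is exact, not an approximation: given the
fixed outlier effect the two half-sample scores are independent, and $s$ is
the outlier mean $\gamma\sigma_T$ standardized by the half-sample noise
$\sigma_T\sqrt{2-2R}$, net of the threshold on the half-sample FERE scale
$\sigma_T\sqrt{2-R}$. Both the formula and this derivation are pinned by a
simulation oracle in the test suite. `theoretical_piur()` composes
$\theta(R)$ with the $G_{FERE}$ inversion; with $\pi_1 = 0$ the composition
returns $R$ (computed, not short-circuited).

Two genuine properties of this composition are worth noting. First, the
large-$\gamma$ limit of $\theta$ is $[\pi_0 \Phi_{2,\rho} + \pi_1] /
[\pi_0 p + \pi_1]$, which is below 1 whenever $\pi_0 p > 0$: null providers
flagged once and not reflagged keep the conditional rate down however
extreme the outliers are. Second, the PIUR exceeds the IUR only while the
outliers reflag *more* reliably than the null tail, i.e. while $\Phi(s) >
G_{FERE}(R)$; for large $R$ and modest $\gamma$ (roughly $R \gtrsim 0.85$
at $\gamma = 2$) the gap reverses. The property tests therefore assert
PIUR $\ge$ IUR on $R \le 0.7$, which covers the whole reported grid.

## The empirical null

`fit_empirical_null()` fits $N(\hat\mu_M, \hat\sigma_M^2)$ to the central
part of the FE Z-score distribution; flagging then uses the threshold
$\hat\mu_M + z_p \hat\sigma_M$. The default fit maximizes the
truncated-normal likelihood of the observations inside the sample-quantile
window $(0.10, 0.90)$, with truncation limits fixed at those quantiles; a
joint Huber location/scale M-estimate (tuning constant 1.345) is the
alternative. The window and tuning constant are this package's choices —
robust-fitting families are standard here but their parameters are not —
and both are configurable.

Numerical notes on the truncated fit:

* The likelihood degenerates when the windowed sample is at least as flat
  as a uniform on the window (the fitted normal then wants
  $\sigma \to \infty$). The optimizer is bounded, and a fit driven to the
  boundary falls back to the Huber estimate with a message
  (`fit_method = "huber_fallback"`). At the half-sample sizes used in
  split-reflagging of small panels this occurs at a low but non-negligible
  rate; at $m \ge 1000$ it is rare.
* The central 80% window carries weak information about scale: at
  $n \approx 300$ Z-scores the scale estimate has standard deviation
  $\approx 0.11$ and a small upward mean bias from its right-skewed
  sampling distribution. Quantities derived from it (notably the robust
  IUR `en_iur()` $= \max(0, 1 - 1/\hat\sigma_M^2)$) inherit that bias in
  small panels; at $m = 1000$ the estimator centres on the truth.
* When provider sizes vary strongly, the FE score variance
  $1 + n_i\sigma_b^2/\sigma_w^2$ varies with $n_i$ and a single global
  null is misspecified; `profile_panel(en_strata = K)` fits one null per
  size-quantile stratum.

## The split-reflagging engine

`estimate_theta()` performs the half-splitting: per provider a uniformly
random partition into halves of $\lceil n_i/2\rceil$ and
$\lfloor n_i/2\rfloor$ patients (a fair coin decides which half is larger
when $n_i$ is odd), Z-scores computed with the *actual* half sizes, flags
pooled over providers and splits. Design choices, each recorded in the
output:

* **Number of splits** defaults to 200 ("large" is the only guidance the
  construction gives); the pooled rate stabilizes well before that for
  $m \ge 1000$.
* **Symmetrization**: each split contributes both conditional directions
  (B given A and A given B) — they are exchangeable by construction and
  pooling them halves the Monte-Carlo variance. Consequently each split
  pair is counted twice, and binomial standard errors for the pooled rate
  should use half the flag-event count; the tests do.
* **Variance components** for FE/RE/FERE flagging inside splits are
  estimated once from the full panel by ANOVA (supplying known components
  is supported, and the simulator returns the generating truth). The EN
  null, whose scale differs between half and full samples, is refitted
  within each half.
* **Small providers** (below `min_split_size`, default 2) are excluded
  from splitting with a message; they still contribute to variance
  estimation on the full panel.
* $\hat\theta$ is a panel-level quantity: with few providers it is noisy
  *across panels* even when many splits make it precise *within* a panel,
  because the realized provider effects are fixed. The simulation table
  driver (`piur_sim_table()`) therefore pools reflagging counts across
  replicate panels before inverting $G$; per-panel inversion at small $m$
  is both noisy and biased toward the clamp at 0.

## The simulator

`simulate_panel()` generates the study conditions used throughout the
package's validation: $m = 1000$ providers with $n_i = 100$ (or $n_i \sim$
round $N(100, 50)$ floored at 10, emulating skewed real panel sizes),
$\sigma_w^2 = 1$, $\sigma_b^2$ solved from a target overall IUR through the
realized $n'$, outlier proportions $\pi_1 \in \{0, 0.01, 0.02, 0.05\}$ and
magnitudes $\gamma \in \{2, 3, 4\}$ times $\sigma_T$ (with $\sigma_T$
computed from $n'$ of the realized sizes — the equal-size case reduces to
the usual per-provider $\sigma_T$). Outliers are one-sided positive
(worse), matching the one-tailed flagging convention. An optional covariate
generator draws patient covariates whose provider-level means load on
$\alpha_i$, to exercise the within-provider (fixed-effects) estimator of
$\beta$ against the bias of a pooled fit.

What the generator does *not* emulate: real case-mix (covariate
distributions differing across providers in shape, not just location),
non-normal or heteroscedastic patient noise, within-provider correlation,
informative provider sizes, or drift over time. Passing tests demonstrate
the internal consistency of the estimators under the stated model, not
their behaviour on such data.

Reference values for the simulation study in the tests are reproduced at
reduced problem sizes chosen for precision per unit work: the equal-size
table at $m = 300$ with 50 splits and 16 replicate panels per
configuration, the variable-size table at $m = 1000$ with 100 splits and 6
replicates, and the acceptance script at $m = 1000$ with 20 replicates for
ANOVA quantities and 5 replicates of 100 splits for the empirical PIUR.
Outlier-driven cells reproduce tightly at any of these scales; the
no-outlier cells carry the panel-level noise and the small-sample biases
described above, and the robust-IUR column reproduces the generating truth
rather than the slightly lower reference values, a discrepancy documented
with measurements in the test output rather than absorbed into tolerances.

## Count measures

For standardized-ratio measures (observed events $O_i$ versus model-based
expected events $E_i$), the null "provider rate equals population rate"
makes $O_i$ approximately Poisson($E_i$). `count_z()` provides the
moment score $(O-E)/\sqrt{E}$ and an exact-tail alternative that maps the
mid-P Poisson tail through the normal quantile. The Poisson score's
skewness $\sim 1/\sqrt{E}$ fattens the upper tail enough to inflate
empirical-null flag rates (about 3.2% at a nominal 2.5% even at $E = 100$),
and since spurious flags do not persist across halves this inflates the
*null* PIUR; the exact score is calibrated at moderate expecteds
($E \gtrsim 50$ per provider) and is the recommended choice, though
discreteness still destabilizes it below $E \approx 25$. `piur_counts()`
runs the split algorithm on patient-level $(y, e)$ pairs — patients carry
their expecteds into the halves, so $O$ and $E$ split exactly — with the
empirical null refitted per half and calibration through $G_{FERE}$.
Providers with full-panel $E$ below `min_expected` (default 3, the usual
reporting exclusion) are dropped. Ratio-only data (provider totals without
patient rows) cannot be split and are refused with an explanatory error.

The two-stage survival and logistic models that produce real expecteds are
out of scope; `simulate_count_panel()` provides a synthetic stand-in with
Gamma patient expecteds and provider effects acting multiplicatively on the
rate, the contamination mixture living on the log-rate scale.

## Known limitations

* The closed-form curves assume halves of exactly $n_i/2$; odd sizes make
  the halves differ by one patient, which only the empirical route sees.
* $\mu$, $\beta$ and the variance components are treated as known once
  estimated from the full panel; their sampling error is not propagated
  into $\hat\theta$.
* The individualized (size-smoothed) empirical null is not implemented;
  size heterogeneity is handled only by stratification.
* Two-sided or simultaneous better/worse calibration is not provided; the
  construction is one-tailed.
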