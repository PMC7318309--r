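# piur: Profile Inter-Unit Reliability for Provider Profiling

`piur` assesses the reliability of provider-level quality measures — the
kind used to profile hospitals or dialysis facilities — with an emphasis on
how consistently a measure identifies *extreme* providers, not just how well
it separates average ones.

## The problem

For patient outcomes following the one-way linear model

    Y*_ij = mu + alpha_i + X_ij' beta + eps_ij,
    alpha_i ~ N(0, sigma_b^2),  eps_ij ~ N(0, sigma_w^2),

the classical **inter-unit reliability** (IUR) is the intraclass-type ratio

    IUR_i = sigma_b^2 / (sigma_b^2 + sigma_w^2 / n_i),

estimated overall from the one-way ANOVA decomposition with the effective
provider size `n' = (sum n_i - sum n_i^2 / sum n_i) / (m - 1)`. The IUR
measures the *average* signal-to-noise of a measure, but a small IUR does
not preclude — and a large IUR does not guarantee — reliable identification
of outlier providers.

The **profile IUR** (PIUR) targets that question directly:

1. randomly split each provider's patients into two near-equal halves;
2. flag extreme providers in each half (one-sided level *p*, by the FE, RE,
   FERE or empirical-null method);
3. over many random splits, estimate the reflagging rate
   `theta = Pr(flagged in B | flagged in A)`;
4. report the IUR value `R~` that would produce this reflagging rate under
   the null model: `G(R~) = theta`.

The calibration curves `G(R)` have closed forms in bivariate-normal
orthant probabilities with correlation `rho = R / (2 - R)`; for the FERE
method, `G_FERE(R) = Phi2_rho(-z_p, -z_p) / p`. A PIUR well above the IUR
signals outlier contamination: under a mixture in which a fraction `pi1` of
providers carry a fixed effect `gamma * sigma_T`, the reflagging probability

    theta(R) = [pi0 Phi2_rho(-z_p, -z_p) + pi1 Phi(s)^2] /
               [pi0 Phi(-z_p)            + pi1 Phi(s)],
    s = -z_p / sqrt(1 - rho) + gamma / sqrt(2 - 2R),

is available analytically (`mixture_theta()`, `theoretical_piur()`).

The package also applies the machinery to standardized-ratio count measures
(observed/expected events per provider, SMR/SRR style) through Poisson
Z-scores and the empirical null (`piur_counts()`), on synthetic data.

## Worked example

Simulate 1000 providers of 100 patients with true IUR 0.25 and 2% outlier
providers at four total standard deviations, then compare the estimators:

```r
library(piur)
sim   <- simulate_panel(m = 1000, sm = size_model("fixed", 100),
                        target_iur = 0.25, pi1 = 0.02, gamma = 4, seed = 42)
panel <- risk_adjust(sim$panel, variance_components())

estimate_variance_components(panel)
#> IUR estimate (one-way ANOVA):
#>   sigma_b2 = 0.00923977  sigma_w2 = 1.00685  n' = 100.00
#>   overall IUR = 0.4785  (m = 1000 providers)

z    <- z_fe(provider_means(panel), 1.00685, provider_sizes(panel))
null <- fit_empirical_null(z)
en_iur(null)
#> [1] 0.287

empirical_piur(panel, flag_config("FERE", p = 0.025),
               n_splits = 100, seed = 7)
#> PIUR (FERE, one-sided p = 0.025): 0.9348
#>   reflagging rate theta = 0.5520
#>   flag events conditioned on: 6830
```

Read the three numbers together: the ANOVA IUR (0.48) is badly inflated by
the 2% contaminated providers relative to the generating value 0.25; the
robust empirical-null IUR (0.29) is not. The PIUR (0.93, against an analytic
value `theoretical_piur(0.25, mixture_spec(0.02, 4)) = 0.865` at these
conditions) sits far above both: the measure re-identifies the same extreme
providers in over half of the split pairs, which is exactly the signature
of genuine outliers rather than diffuse between-provider spread.

The analytic contamination grid and the simulation summary table are
available as `piur_table1()` and `piur_sim_table()`, or from the shell:

```sh
exec/piur theory-table --p 0.025 --iur 0,0.25,0.5 --pi1 0.01,0.02,0.05 --gamma 2,3,4
exec/piur piur --method fere --p 0.025 --splits 200 --seed 1 --input panel.csv
```

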