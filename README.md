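# cryptdrift

Quantitative analysis of pulse-chase lineage tracing in intestinal crypts
and tumour glands: neutral-drift theory of clone sizes, Bayesian inference
of stem-cell dynamics from eighths-scored clone counts, and a spatial
pipeline that tests whether clones near tumours still behave like wild-type
tissue.

## The science

After a pulse of a heritable label marks single intestinal stem cells, each
labelled clone drifts in size as `N` equipotent stem cells per crypt
stochastically replace one another at a daily rate `λ`. Clone size is a
symmetric random walk on `0..N` with absorbing boundaries — extinction at 0,
monoclonal conversion at `N` — whose master equation has a closed-form
eigen-expansion solution `P_n(t)` (implemented here, and cross-checked
against a matrix-exponential oracle). Scored data add three wrinkles: only
surviving clones are observed (`P'_n = P_n/(1−P_0)`), sizes are recorded in
eighths of the crypt circumference (interval-overlap binning, with
monoclonals pinned to bin 8), and the label accrues only after a delay `τ`
(effective time `max(t−τ, 0)`).

On top of the model the package provides:

* **Exact simulation** of clone fates and full synthetic study datasets,
  including a spatial tumour-field scenario with distance-dependent rates
  and an intra-tumour monoclonal-excess mixture.
* **MCMC inference** of `(N, λ, τ)` from binned counts: multinomial
  likelihood, uninformative priors, Metropolis-within-Gibbs with 2 × 40,000
  iterations (burn-in 5,000, thinning 20); any parameter subset can be
  fixed, e.g. rate-only fits with `N = 5`, `τ = 2.45`.
* **Spatial divergence pipeline**: rolling 100-clone bins by distance from
  the tumour edge, per-bin Monte-Carlo null distributions of the wild-type
  likelihood, record-level divergent/consistent splitting with an implied
  distance cutoff, subset rate inference, monoclonal-proportion summaries
  and monoclonal rescaling.

## Worked example

Wild-type small-intestine drift (`N = 5`, `λ = 0.1`/day, `τ = 2.45` d)
predicts the fraction of surviving clones that have monoclonally converged:

```r
library(cryptdrift)
wt <- wt_drift_params()
round(100 * monoclonal_fraction(wt, c(13, 17, 19)), 1)
#> [1] 2.2 5.5 7.7
```

— about 2%, 6% and 8% of surviving clones own their whole crypt at 13, 17
and 19 days post induction; intra-tumour glands reporting 25–37% monoclonals
at the same times are therefore far off the wild-type trajectory.

Simulate the control pulse-chase study (692/595/592/457/302 surviving clones
at days 4/7/10/14/21) at ground truth `N = 6`, `λ = 0.15`, `τ = 2.45`, and
fit it back:

```r
set.seed(derive_seed(1, "tracing"))
cc  <- simulate_count_dataset(drift_params(6, 0.15, 2.45), simulation_schedule())
fit <- run_mcmc(cc, prior_spec(), mcmc_config(seed = derive_seed(1, "fit")))
summary(fit)
#> Posterior summary (3500 pooled draws)
#>   stem-cell number: posterior mode N = 6
#>   parameter median ci80_lo ci80_hi ci95_lo ci95_hi rhat
#> 1    n_stem 6.0000  6.0000  6.0000  6.0000  6.0000   NA
#> 2 repl_rate 0.1426  0.1356  0.1497  0.1325  0.1536    1
#> 3     delay 2.6200  2.4010  2.8220  2.2690  2.9160    1
```

The posterior mode recovers the true stem-cell number, the rate median sits
within the 95% interval of the truth, and the delay interval covers 2.45.

The numbered scripts under `analysis/` run the full workflow — wild-type
theory curves (`01`), study simulation (`02`), the production fit (`03`),
the synthetic tumour field with monoclonal summaries and rescaling (`04`),
and the spatial divergence pipeline with near/far rate inference (`05`) —
writing TSV tables under `results/`.

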