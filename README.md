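# atg13dyn

Kinetic modeling and analysis of ATG13 punctum dynamics in live-cell
imaging of autophagy initiation.

ATG13 is a subunit of the ULK kinase complex that nucleates autophagosome
formation. In starvation-induced (nonselective) autophagy, a GFP-ATG13
punctum brightens once and fades — a single accumulation/removal pulse. In
ivermectin-induced mitophagy, ATG13 translocates repeatedly to the same
mitochondrial fragment, giving oscillatory traces whose inter-peak delays
grow with every cycle until the fragment is engulfed by LC3-positive
membrane. `atg13dyn` is for modelers and quantitative cell biologists who
want to fit, compare and simulate these dynamics.

## Models

**Nonselective pulse.** Aggregated ATG13 follows
`dA/dt = kprod * A^m − krem * A` from a small seed, where the partial order
`m` captures cooperative recruitment onto the existing aggregate. Six
variants combine two structural hypotheses: an event at time `t` switching
accumulation to removal (variants 1–3) versus both reactions running
simultaneously (4–6), crossed with the target of wortmannin inhibition — a
multiplicative factor `kwrtm` on accumulation (1, 4), removal (2, 5) or
both (3, 6). All trajectories are evaluated from exact closed-form
solutions (the eventless model is a Bernoulli ODE).

**Mitophagy oscillations.** A hybrid stochastic model: each aggregation
cycle k runs the pulse kinetics with a random time-to-peak, deposits LC3 in
proportion to the ATG13 time integral, then waits `kpeak * k^p` seconds
(the fitted `p ≈ 2.79` makes delays grow almost cubically). The event
terminates once cumulative LC3 reaches `engulf_coeff * mt_diam`, so the
number of ATG13 translocations scales with the fragment diameter.

Around the models: a trace-processing pipeline (peak synchronization,
spline-assisted alignment, irregularity filtering, ≥3-repeat trimming,
bleaching regularization, peak/trough trains), normality/log-normality
analysis of peak times and diameters, multi-start global estimation with
AIC variant ranking and profile-likelihood identifiability, a two-stage
mitophagy calibration, and a synthetic-data generator with ground-truth
bundles for parameter-recovery validation.

## Worked example

Simulate a 17-event mitophagy population at the fitted kinetic parameters
and test the model's headline prediction — that the number of ATG13
aggregation peaks scales with the mitochondrial diameter:

```r
library(atg13dyn)

params <- default_mitophagy_params()
pop <- simulate_mitophagy_population(17, params, seed = 11)
counts <- vapply(pop, peaks_completed, integer(1), time = 910)
diams  <- vapply(pop, `[[`, numeric(1), "mt_diam")
correlate_counts_diameters(counts, diams)$r
#> [1] 0.8622493
```

A single deterministic event at the mean diameter (0.9 µm) completes six
aggregation cycles with visibly growing inter-peak delays:

```r
det <- simulate_mitophagy(default_mitophagy_params(t_sd = 0), mt_diam = 0.9)
length(det$peak_times)
#> [1] 6
round(det$peak_delay_obs, 1)
#> [1]  84.0  89.3 102.4 126.2 163.4
```

The delays climb from 84 s to 163 s across five intervals — the `k^2.79`
waiting law plus the constant active-cycle time. Fitting the nonselective
pulse model (variant 3, event-based, wortmannin on both reactions) to
synthetic two-condition data generated at the published parameters and
degraded with 5% noise recovers them:

```r
np <- default_nonselective_params()   # kprod 0.0082, krem 0.0029, m 1.01365
v3 <- model_variant(3)
set.seed(2)
times <- seq(0, 900, by = 10)
mk <- function(w) {
  A <- simulate_nonselective(np, v3, wortmannin = w)$intensity_au
  A <- A * exp(rnorm(length(A), 0, 0.05))
  data.frame(time_s = times - times[which.max(A)], intensity_au = A)
}
fit <- fit_multistart(v3, list(starvation = mk(FALSE), wortmannin = mk(TRUE)),
                      n_starts = 50, seed = 3)
round(fit$best_params, 5)
#> kprodATG13  kremATG13          m      kwrtm          t
#>    0.00809    0.00291    1.01618    0.40504  306.47178
```

`m` comes back at 1.016 (truth 1.014) and the event time at 306 s (truth
300); `kprodATG13` lands inside its published 95% interval — the kprod–m
pair is only weakly identified, which `profile_likelihood()` makes
explicit. Ranking all variants with `rank_variants()` puts the event-based
models far ahead of the eventless ones on pulse-shaped data, since a
one-dimensional autonomous ODE without an event cannot produce an interior
peak at all.

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/atg13dyn.R synth --outdir fixtures --seed 1
Rscript inst/cli/atg13dyn.R fit-nonselective --input fixtures/nonselective_traces.csv \
        --outdir fits --seed 1 --n-starts 50
Rscript inst/cli/atg13dyn.R simulate-mitophagy --n 17 --seed 1 --outdir sim
```

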