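# fatekinetics

Kinetic modelling of cell-fate adoption at the exit from pluripotency.

When mouse embryonic stem cells are released from self-renewal they first
exit pluripotency and then commit, rapidly and irreversibly, to one of two
primary fates: neuroectoderm (NECT, the Sox1::GFP+ readout) or Primitive
Streak (PS, the Brachyury/T::GFP+ readout). Pulse-chase experiments — a
single 1-day pulse of Activin + CHIR99021 ("AC") applied on successive days
of an otherwise neutral (N2B27) time course — show a transient competence
window for PS, peaking after about two days, with the NECT and PS endpoint
responses strongly anticorrelated.

`fatekinetics` implements the four-compartment kinetic model behind this
picture, for modellers and quantitative stem-cell biologists who want to
simulate, fit, and generate data for it:

$$
\dot P = -\lambda_D P,\quad
\dot D = \lambda_D P - (\lambda_N + \lambda_M) D,\quad
\dot N = \lambda_N D,\quad
\dot M = \lambda_M D,
$$

with $P$ pluripotent, $D$ differentiating, and absorbing committed states
$N$ (NECT) and $M$ (PS). Fractions are conserved (no death/division). A
population signal $s(t) = 1 - P(t)$ builds up as pluripotency is lost;
once $s \ge \theta$ the PS rate switches irreversibly from
$\lambda_{M,\mathrm{low}}$ (default 0) to
$\lambda_{M,\mathrm{high}} \gg \lambda_N$ — and only in PS-permissive
media (AC); in N2B27 the PS channel is closed. Because the rates are
piecewise constant, the model solves exactly by gluing closed-form segment
solutions at protocol boundaries and at the signal crossing.

The package provides:

* `simulate_fates()` — exact piecewise-glued solution along any culture
  protocol; `simulate_fates_ode()` — independent adaptive ODE
  cross-check (deSolve);
* `pulse_chase_design()`, `pulse_response()`, `fate_correlation()` — the
  competence-window experiment and its readouts;
* `fit_neutral()`, `fit_switch()` — bounded multi-start least-squares
  estimation of $(\lambda_D, \lambda_N)$ from neutral time courses and of
  $(\lambda_{M,\mathrm{high}}, \theta)$ from pulse-chase endpoints, with
  broom-style `tidy()`/`glance()` methods;
* `simulate_cells()` — a per-cell stochastic counterpart with exact
  exponential exit times;
* `generate_neutral_dataset()`, `generate_pulse_chase_dataset()`,
  `noise_model()` — synthetic flow-cytometry datasets with binomial
  sampling and misclassification noise;
* `run_config()` and a thin CLI (`inst/scripts/fatekinetics.R`) for
  reproducible, manifest-logged pipeline runs;
* `autoplot()` methods for trajectories, pulse responses and stochastic
  runs.

## Worked example

```r
library(fatekinetics)

prm <- paper_like_params()   # calibrated defaults, see the methods vignette
prm
#> <rate_params>
#>   lambda_D      0.8      /day  (exit from pluripotency)
#>   lambda_N      0.55     /day  (D -> NECT)
#>   lambda_M_low  0        /day  (D -> PS, below threshold)
#>   lambda_M_high 8        /day  (D -> PS, above threshold)
#>   theta         0.85           (signal threshold)
#>   signal_law    instantaneous

crossing_time(prm)
#> [1] 2.3714
```

A 1-day AC pulse on day 2 straddles the signal crossing (day 2.37), so PS
conversion switches on mid-pulse and captures ~41% of the population; m
stops growing the moment the pulse ends:

```r
simulate_fates(protocol(c("N2B27", "AC", "N2B27"), c(2, 1, 3)), prm, times = 0:6)
#> # A tibble: 7 × 8
#>    time       p      d     n     m signal condition regime_label
#>   <dbl>   <dbl>  <dbl> <dbl> <dbl>  <dbl> <chr>     <chr>
#> 1     0 1       0      0     0      0     N2B27     N2B27/pre-threshold
#> 2     1 0.449   0.408  0.142 0      0.551 N2B27     N2B27/pre-threshold
#> 3     2 0.202   0.419  0.379 0      0.798 AC        AC/pre-threshold
#> 4     3 0.0907  0.0111 0.490 0.408  0.909 N2B27     N2B27/post-threshold
#> 5     4 0.0408  0.0434 0.507 0.408  0.959 N2B27     N2B27/post-threshold
#> 6     5 0.0183  0.0417 0.531 0.408  0.982 N2B27     N2B27/post-threshold
#> 7     6 0.00823 0.0315 0.552 0.408  0.992 N2B27     N2B27/post-threshold
```

Sweeping the pulse day reproduces the competence window: pulses on days 0–1
end before the crossing and yield no PS; the response peaks at day 2 and
declines as NECT absorbs the pool, and the two fates anticorrelate:

```r
resp <- pulse_response(pulse_chase_design(), prm)
resp
#> # A tibble: 6 × 4
#>   pulse_start_day n_final m_final uncommitted_final
#>             <dbl>   <dbl>   <dbl>             <dbl>
#> 1               0   0.900   0               0.0999
#> 2               1   0.900   0               0.0999
#> 3               2   0.552   0.408           0.0398
#> 4               3   0.627   0.346           0.0267
#> 5               4   0.754   0.229           0.0168
#> 6               5   0.846   0.145           0.00911
fate_correlation(resp)
#> [1] -0.979

autoplot(resp)   # competence-window plot
```

Round-trip: generate a synthetic cytometry time course in N2B27 (10,000
cells/day, 1% misclassification) and recover the generating rates:

```r
ds <- generate_neutral_dataset(prm, days = 0:5, noise = noise_model(seed = 1))
fit_neutral(ds, seed = 1)
#> <fate_fit: neutral>  loss = 0.00064881  (20 starts, converged: TRUE)
#>   lambda_D       0.782929   [bounds 0.0001, 10]
#>   lambda_N       0.545444   [bounds 0.0001, 10]
```

Both estimates land within ~2% of the generating truth (0.8, 0.55) at this
noise level.

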