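# avburst

Agent-based simulation of anti-vaccination opinion dynamics, with the
ensemble and burst-statistics machinery needed to characterise its spiky
activity and its catastrophic "AV success" transition.

## The problem

Online anti-vaccination activity is bursty: long quiet stretches broken by
short, high spikes of apparently random size and spacing, and — the
disquieting part — an occasional spike that does not collapse but grows
into society-wide vaccination refusal.  `avburst` implements a
discrete-time agent-based model of this dynamic for researchers in
computational social science and infodemiology who want to study when the
pro-vaccination state is metastable, what the waiting-time distribution of
its collapse looks like, and which interventions (more institutional
messaging, message caps) change the odds.

A population of `NP` patients holds opinions on the scale $[-2, +2]$.
Opinions update on encounters as a convex combination,

$$O_i' = O_i (1 - \alpha f_{iS}) + O_S\, \alpha f_{iS},$$

where the filtering factor $f_{iS}$ encodes biased assimilation with one
crucial asymmetry: infosphere *messages* — written by a handful of
fixed-opinion initiators and by "activist" patients whose opinion fell
below the activism threshold AT — bypass filtering entirely for
non-activists, standing in for the emotional appeal that rational
pro-vaccination communication lacks.  Doctors (a fraction of whom go
uncommitted as refusal spreads) pull opinions up; messages pull them
down; and because encounter sources are drawn uniformly from the pooled
entities, message influence grows with the size of the message pool — a
nonlinear feedback that produces bursts, and occasionally an avalanche
that tips the whole population below the vaccination threshold ("AV
success").

On top of the engine the package provides deterministic ensemble sweeps
over (AT, PW) with logistic/Gompertz fits of the success-ratio curve,
peak detection over a rolling-median background, lognormal / bounded
power-law / log-Cauchy fitting (the bounded power law handles exponents
above $-1$, like the transition-time exponent near $-0.75$, which are not
normalisable on infinite support), time-rescaling matches between tick
and real-time separations, and a synthetic burst-fixture generator with
ground truth.

## Worked example

The spiky regime (AT = -1.8, PW = 0.45), one seeded run:

```r
library(avburst)
p <- model_params(activism_threshold = -1.8, writing_probability = 0.45)
sim <- run_simulation(p, seed = 404)
sim
#> <av_simulation> seed 404, 12401 ticks (cpp engine)
#>   final: NAV = 1988/2000, activists = 1890, active messages = 372545
#>   AV success at tick 12312 (ascent duration 10 ticks)
```

This run stayed in the fluctuating pro-vaccination background for over
12,000 ticks — antivaxxer counts (`sim$metrics$n_antivax`) hovering near
the ~2% tail of the initial opinion distribution, message bursts coming
and going — and then collapsed: within 10 ticks of crossing 50%
refusal it passed 95%, and by the end 1890 of 2000 patients are activists.
The burst statistics of the quiet phase (activist-written messages per
tick, 50-tick bins, transition ramp excluded):

```r
b <- analyze_message_bursts(sim)
b$n_peaks
#> [1] 11
b$fit
#> <av_fit> family = lognormal, n = 11
#>   parameters:
#>     meanlog      2.13717
#>     sdlog        0.57283
#>   gof ks         0.338116
#>   gof loglik     -32.9884
b$ks_p
#> [1] 0.1616252
```

Eleven bursts whose relative heights are consistent with a lognormal law
(KS p = 0.16) — the same family that describes empirical comment-activity
peaks.  Ensemble questions go through `ensemble_spec()` /
`run_ensemble()`:

```r
spec <- ensemble_spec(model_params(n_patients = 500),
                      grid = data.frame(writing_probability = seq(0.1, 0.7, 0.1)),
                      n_reps = 20, base_seed = 500)
ens <- run_ensemble(spec)
fit_success_sigmoid(ens$cells$writing_probability, ens$cells$success_ratio)
```

which yields the sigmoid success-ratio curve in PW whose location shifts
to higher PW as AT deepens from -1.7 to -1.8.

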