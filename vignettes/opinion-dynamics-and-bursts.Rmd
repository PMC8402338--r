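---
title: "Anti-vaccination opinion dynamics and burst statistics: the model behind avburst"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anti-vaccination opinion dynamics and burst statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avburst)
```

## The model

`avburst` simulates the dynamics of vaccination opinion in a society exposed
to an emotionally asymmetric information environment.  Four kinds of
entities interact in discrete time:

* **Patients** (`n_patients`, default 2000): the population taking
  vaccination decisions.  Each carries an opinion on the closed scale
  \[-2, +2\] (+2 strong support, -2 strong opposition) and an age;
  a patient leaving the system after `patient_lifetime` (90) ticks is
  replaced by a fresh agent whose opinion is drawn from a normal
  distribution centred at `opinion_center` (0) with standard deviation
  `opinion_sd` (0.5), truncated to the opinion bounds.  "Lifetime" here is
  the span of active interest in the vaccination question, not biological
  life.
* **Doctors** (`n_doctors`, default 100): the pro-vaccination
  institutional channel.  A fraction of doctors is *uncommitted* — it
  mirrors hesitancy in the population through
  `NDU = round(ND * k * NAV / NP)` with `k = doctor_hesitancy_factor`
  (0.5), where NAV is the current number of patients refusing vaccination.
  Committed doctors hold opinions uniform on \[1, 2\], uncommitted ones on
  \[-0.25, 0\]; membership of the uncommitted subset is redrawn every tick.
* **Initiators** (`n_initiators`, default 1): permanently committed
  anti-vaccination authors with a fixed opinion (`initiator_opinion`,
  default -1.83) who seed the message stream.
* **Messages**: infosphere items.  Every initiator, and every patient whose
  opinion lies below the activism threshold AT (`activism_threshold`),
  makes up to five (`max_messages_per_author_per_tick`) independent
  Bernoulli(`writing_probability`) writing attempts per tick; each success
  appends a message cloning the author's current opinion.  Messages age out
  after `message_lifetime` (90) ticks and are not replaced.

A patient whose opinion falls below the vaccination threshold VT
(`vaccination_threshold`, -1) refuses vaccination; below AT it becomes an
*activist* that both writes messages and filters incoming information most
aggressively.  Activists age at half the normal rate
(`activist_aging_factor` 0.5), modelling their longer engagement.

### The opinion update

An encounter between patient *i* (opinion $O_i$) and source *S* (opinion
$O_S$) updates

$$O_i' = O_i\,(1 - \alpha f_{iS}) + O_S\, \alpha f_{iS},$$

with acceptance rate $\alpha$ (0.66) and a filtering factor $f_{iS}$
encoding biased assimilation:

* undecided patients ($|O_i| \le \mathrm{FT}$, `filtering_threshold` 1) do
  not filter: $f = 1$;
* committed non-activists accept same-sign sources fully and discount
  opposing ones by $f = (2 - |O_i|)/(2 - \mathrm{FT})$, the constant 2
  being the opinion-bound magnitude;
* **messages are exempt** from non-activist filtering ($f = 1$ regardless
  of sign) — the formal stand-in for the emotional, narrative appeal of
  anti-vaccination content that rational institutional messaging lacks;
* activists discount even same-sign sources by the same ratio and totally
  reject opposing sources ($f = 0$), messages included.

The update is a convex combination, so opinions can never leave the
bounds; the engine asserts this instead of clamping.

### The tick

Each tick executes, in order: (0) the doctor-commitment refresh against
the previous tick's NAV; (1) ageing and replacement; (2) message writing;
(3) doctor visits — each patient independently visits a uniformly random
doctor with probability `doctor_visit_ratio` (PVD); a committed doctor
updates the patient directly, an uncommitted one deflects the patient to a
random message from the pool; (4) external exposure — every patient, in a
fresh random permutation, encounters one source drawn **uniformly over the
pooled entities**: all doctors, all other patients and all active
messages.  Updates within a tick are sequential, so earlier-updated
patients expose their new opinions to later ones.  Activist status for
ageing and writing is fixed once at tick start; filtering always uses the
current opinion.

The entity-uniform source choice in process (4) is the load-bearing design
decision: the probability of meeting a message grows with the size of the
message pool, which is the nonlinear feedback loop behind everything the
package studies.  More activists mean more messages, more messages mean
more message encounters, and since messages bypass filtering, more message
encounters mean more radicalisation.  We also examined the alternative
reading in which the *category* (doctor / patient / message) is chosen
uniformly first: it gives a handful of early messages the same aggregate
influence as the entire doctor pool from the first tick, the population
collapses deterministically into the anti-vaccination attractor within a
few dozen ticks, and none of the phenomena of interest (metastable
background, bursts, stochastic transitions) exist.  That reading was
discarded.

### AV success

A run ends in *AV success* when the antivaxxer fraction NAV/NP stays at or
above 0.95 for one patient lifetime (90 ticks, all three thresholds
configurable).  The paper-level description of this state is qualitative
("all patients adopting the activists' opinion", most doctors
uncommitted); the 0.5/0.95/lifetime criterion is this package's
operationalisation.  The `transition_time` is the first tick of the
confirmed window; the `transition_duration` counts ticks from the last
time the fraction was at or below 0.5 to the window start, so an
instantaneous jump has duration 0.  Runs stop early once success is
confirmed (the state is absorbing in practice: newcomers are overwhelmed
immediately); this can be disabled.

## Calibration of the unreported parameters

Three parameters of the published model are not recoverable from the
available text: the number of initiators, the doctor-visit ratio, and the
initiators' fixed opinion (only "below the activism threshold" is given).
They were calibrated **once**, at NP = 2000, against the qualitative phase
structure the original study reports, and are not revisited:

* at AT = -1.8, PW = 0.45 the system must sit in a metastable
  pro-vaccination state with spiky message activity and only occasional,
  late transitions;
* at AT = -1.7, PW = 0.45 and at AT = -1.8, PW = 0.70 success must be
  near-certain within 20,000 ticks, with transition times spread over
  orders of magnitude;
* the success-ratio curve in PW must be sigmoid, and lowering AT from
  -1.7 to -1.8 must shift it to higher PW.

The calibration outcome is `n_initiators = 1`, `doctor_visit_ratio = 1`,
`initiator_opinion = -1.83`, and the reasoning is worth recording:

* **The initiator message stock must be small.**  At steady state the
  initiators maintain about `NI * 5 * PW * message_lifetime` live
  messages.  Because messages bypass filtering and the source pool is
  entity-uniform, a stock of ~1000 messages (NI = 5 at PW = 0.45) is an
  irresistible force: no admissible doctor-visit ratio holds the
  population, and the pro-vaccination state collapses deterministically.
  A single initiator (~200 messages at PW = 0.45, an 8% share of the
  entity pool) is the largest stock compatible with metastability.
* **The doctor channel must saturate.**  Even against a single initiator,
  a per-tick contact probability near 1 is needed to hold the background
  state.  PVD here bundles personal doctor contact with all institutional
  pro-vaccination communication, so a guaranteed per-tick exposure is the
  natural reading of a society with an active public-health presence; the
  model's pessimistic message is precisely that even this maximal
  rational-channel pressure only just maintains metastability.
* **The initiator opinion anchors the threshold effect.**  A single
  message encounter moves a patient two-thirds of the way to the message
  opinion, so a message at -2 converts patients from a wide opinion band
  into activists regardless of AT, and the AT = -1.7 and AT = -1.8 systems
  behave almost identically — contradicting the reported boundary shift.
  With the initiator fixed at -1.83, just below the deeper threshold
  studied, one message hit can only convert patients already deep in the
  negative tail; how deep depends strongly on AT (the band reaches -1.74
  at AT = -1.8 but -1.45 at AT = -1.7, whose tail population is several
  times larger).  Activist genesis — and with it the position of the phase
  boundary — then inherits the threshold dependence.  This value is a
  fixed constant, deliberately *not* tied to AT: tying it to AT makes the
  dynamics nearly translation-invariant in AT and erases the shift.

## Randomness and reproducibility

A run is a pure function of `(params, seed)`.  All randomness flows
through R's generator in one stream with a fixed draw order (set by the
reference engine); the compiled engine consumes the identical sequence, so
the two produce bit-identical trajectories — a tested invariant, including
the per-tick mean opinion, which the compiled engine accumulates with the
same long-double two-pass algorithm R's `mean()` uses.  Ensembles assign
replicate `j` of cell `i` the seed `base_seed + i * n_reps + j`, so any
single run of an ensemble can be reproduced in isolation.  We considered
named per-process substreams but rejected them: base R has no cheap
substream facility, and a single documented stream keeps the
engine-equivalence contract exact.

## Burst statistics

The analysis side of the package treats any binned activity series:

* `normalize_series()` divides a raw count series by a centred moving
  average of a total-activity series (shrunken windows at the edges) — the
  standard correction when platform traffic grows over time.
* `detect_peaks()` flags bins exceeding `threshold_factor` (default 5)
  times the local background, a centred rolling median over
  `background_window` (21) bins floored at the series mean; candidates
  closer than `min_separation` (3) bins merge into one peak.  The mean
  floor is what makes the detector meaningful on series that are exactly
  zero between bursts, and it keeps the detector invariant under positive
  rescaling of the series.  The detection method is this package's own:
  the source study reports burst statistics without specifying a detector.
* `peak_statistics()` extracts relative heights and inter-peak
  separations, with an optional minimum-gap filter (the
  over-counting guard used for empirical data binned in days).
* `fit_lognormal()`, `fit_powerlaw_bounded()`, `fit_logcauchy()` fit the
  three families used across the analyses.  The bounded power law is fit
  either by exact truncated maximum likelihood (any real exponent is
  admissible on finite support — essential for exponents above -1, where
  the unbounded density is not normalisable) or by least squares on a
  log-binned histogram (15 bins per decade, density = count / (bin width
  x n), empty bins dropped; the bin count halves with a warning if over
  half the bins are empty).  A goodness measure (exact KS distance) is
  reported uniformly.
* `rescale_time_match()` grid-searches the factor mapping simulation ticks
  to real-world time by minimising the two-sample KS distance between
  separation samples.
* `generate_synthetic_bursts()` builds fixture series — Poisson background
  plus lognormal spike heights at lognormal gaps — with ground truth, so
  the detector and fitters are testable end to end without any corpus
  data.  Real activity series differ from these fixtures in ways the
  fixtures deliberately ignore (multi-bin peak shapes, background drift,
  weekly seasonality), so passing the recovery tests demonstrates the
  correctness of the machinery, not its field performance.

`analyze_message_bursts()` applies this machinery to a simulation: it
takes the per-tick count of newly written activist messages (initiator
messages excluded), truncates it to the fluctuating regime — ticks before
NAV/NP first exceeds 0.25, because the run-away transition ramp would
otherwise inflate the mean-floored threshold and mask the background
bursts — aggregates it into 50-tick bins (the discrete analogue of the
weekly binning used for empirical series), and reports detected peaks, the
lognormal fit of their relative heights and its KS p-value.

## Problem sizes used in the shipped checks

The test suite and the acceptance script re-run four paper-level analyses
at sizes chosen to keep a full check under a few minutes of CPU: 200 runs
for the transition-time exponent at (AT = -1.7, PW = 0.45) with the
bounded power-law fit on \[min observed, 20000\]; 100 runs for the fastest
transition at (AT = -1.8, PW = 0.70); two 7 x 20 ensembles at NP = 500 for
the sigmoid boundary and its AT shift; 20 runs for the burst statistics of
the spiky regime at full NP = 2000.  The NP = 500 profile is a genuine
reduction: the entity-pool balance depends on NP, so its sigmoid sits at
lower PW than the full-scale one — within the profile the monotonicity and
the direction of the AT shift are the meaningful observables, not the
absolute locations.  The original study's 1000-run ensembles are
reproduced in structure, not in count.

## Numerical choices and edge cases

* NDU rounding is half-up; the uncommitted subset is redrawn each refresh
  (the aggregate ratio is all the model specifies); only doctors whose
  commitment status changed redraw their opinion.
* Initial patient ages are staggered uniformly over one lifetime;
  synchronous ageing would otherwise replace the entire population in one
  tick every 90 ticks.
* The truncated normal is sampled by rejection; `opinion_sd = 0`
  degenerates to the centre point without consuming randomness.
* Opinion 0 counts as agreeing with either sign in the filtering rules
  (unreachable for filtering agents at the default FT = 1, but fixed for
  determinism).
* The activist same-sign discount is clamped at 1, reachable only for
  non-default thresholds with AT above -FT.
* Messages written in a tick are readable in the same tick's processes
  (3) and (4); message counts under an active `message_cap` include only
  messages admitted to the pool.
* Sigmoid fits cap the amplitude at 1 and report half-maximum locations;
  degenerate inputs (all ratios equal) return an explicit no-fit value
  rather than an error.

## Known limitations

The model has no social-network topology, no per-agent heterogeneity in
the acceptance rate, fixed (not distributed) lifetimes, and treats all
institutional communication through one visit probability — limitations
inherited from the modelling framework it implements.  The phase structure
is sensitive to the calibrated trio (NI, PVD, initiator opinion) in ways
the published account does not constrain further; the calibration above
should be read as one defensible operating point, not an identified
estimate.  Burst-statistic comparisons against empirical corpora (which
this package does not ship) additionally depend on the tick-to-day
rescaling factor, for which `rescale_time_match()` provides the machinery
but no data.
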