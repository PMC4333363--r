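---
title: "Modeling self-organized wait-time dynamics in regional surgical services"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling self-organized wait-time dynamics in regional surgical services}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`hospwait` simulates a regional surgical service system — patterned on
province-scale cardiac surgery — as a discrete-time agent-based model with
a one-day step. Three kinds of entities interact through a shared
information board (the *environment*):

* **Cities** generate patients: city $i$ produces a Poisson number of new
  patients per day with mean $pop_i \, m_i$, where $m_i$ is the per-person
  daily probability of becoming a surgical patient. In the warm months
  (May–October) $m_i$ is multiplied by 0.85, reflecting the roughly 15%
  seasonal reduction in arrivals observed in such systems. Each patient is
  *urgent* with probability 0.23, *non-urgent* otherwise.

* **Patients** (jointly with their general practitioners) choose a
  hospital by a gravity-style categorical rule. A fraction $P_r$ of
  patients is *wait-time sensitive* and weighs three factors — driving
  time, physician supply, and the last released wait time:
  $$a_{ij} \propto f(d_{ij})\, f(r_j)\, f(w_j), \qquad
    f(d_{ij}) = \frac{d'_{ij}}{\sum_k d'_{ik}},\quad
    d'_{ij} = \frac{\sum_k d_{ik}^{\alpha_d}}{d_{ij}^{\alpha_d}},\quad
    f(r_j) = \frac{r_j^{\alpha_r}}{\sum_k r_k^{\alpha_r}},$$
  with the wait factor $f(w_j)$ built inverse-proportionally to
  $w_j^{\alpha_w}$, symmetrically to the distance factor. The remaining
  $1 - P_r$ ignore the wait factor. The product of separately normalized
  factors is renormalized over hospitals into a proper categorical
  distribution, since each patient must choose exactly one hospital.

* **Hospitals** run priority queues (urgent patients ahead of non-urgent,
  first-in-first-out within class) served at a daily rate $\mu_j(t)$ that
  adapts every $\tilde\tau = 5$ days to recent demand:
  $$\mu_j(t) = \bar\mu_j \left(
      b_j \frac{\sum_{t'=t-\tilde\tau}^{t-1} \tilde A_j(t')}
               {\tilde\tau\, \bar A_j} + g_j \right),$$
  with $b_j = 0.57$, $g_j = 0.43$; at average load ($b+g = 1$) the rate
  equals the baseline $\bar\mu_j$. Every release round of
  $\hat\tau = 30$ days each hospital publishes the median realized wait
  of the round's completed patients, carrying the previous value forward
  if nobody completed.

Two feedback loops arise. Released waits steer wait-sensitive patients
away from congested hospitals (a negative arrivals–wait loop), while the
service-rate rule lets hospitals chase their own arrivals (a positive
arrivals–service–wait loop). The simulation examines when these coupled
loops produce heavy-tailed, self-organized fluctuations in the released
wait-time series.

## Within-step order of operations

The model description does not serialize events within a day, so the
package fixes the order: service-rate adjustment (on adjustment days),
patient generation, selection and enqueueing, service, then wait release
(on release days). Consequences: patients arriving on a given day can be
served the same day (wait 0), and a release reflects exactly the
completions of its own round.

Daily service uses a Poisson draw with mean $\mu_j(t)$, truncated at the
queue length — the one-day departure law of a busy exponential
single-server queue — instead of tracking residual exponential service
times across midnight. Under the near-saturated utilizations studied here
the two formulations are distributionally indistinguishable, and the
truncated-Poisson form needs no carry-over state.

## Calendar convention

Step $t$ (1-based) belongs to calendar month
$((\lceil t/30 \rceil - 1) \bmod 12) + 1$, starting in January. The
calendar is fixed at 30-day months *independently* of the release period
$\hat\tau$, so sweeping $\hat\tau$ (weekly to quarterly releases) does not
also move the warm season. At the default $\hat\tau = 30$ the release
rounds coincide with calendar months.

## Key parameters

| Parameter | Default | Meaning |
|---|---|---|
| $\alpha_d$ | 4 | distance sensitivity (steep distance decay) |
| $\alpha_r$ | 1 | physician-supply sensitivity |
| $\alpha_w$ | 1 | wait-time sensitivity |
| $P_r$ | 0.2 | share of wait-time-sensitive patients |
| urgent fraction | 0.23 | urgent : non-urgent mix 0.23 : 0.77 |
| warm multiplier | 0.85 | May–October arrival reduction |
| $b_j, g_j$ | 0.57, 0.43 | service-adjustment gain and floor |
| $\hat\tau$ | 30 d | wait-release round |
| $\tilde\tau$ | 5 d | service-adjustment window |
| $T$ | 720 d | horizon (two years, 24 monthly rounds) |
| $\varepsilon_w$ | 0.5 d | floor on released waits entering $f(w)$ |

$\varepsilon_w$ guards the inverse-power wait factor when a hospital
served everyone same-day; half a day is the smallest meaningful wait
below the one-day step. The service-rate update period follows the
tabulated weekly (5-step) schedule of the source system's operating
practice rather than a monthly one.

## The synthetic calibration

The real calibration of such a model — census populations, registry
service rates, road driving times — is proprietary, so
`generate_synthetic_ontario()` builds a structurally faithful stand-in:
47 cities (log-normal populations floored at 40,000) placed uniformly in
a plane, 11 hospitals hosted in the largest cities, driving times of
0.3–8 h proportional to planar distance, 5–30 physicians per hospital,
and generation probabilities scaled so the province generates 24 patients
per day in expectation in the cold season (roughly 8,800 surgeries a
year, the right order of magnitude for one province's cardiac surgery
volume).

Each hospital's reference arrivals $\bar A_j$ are its expected daily
cold-season arrivals under the distance + resourcefulness rule, and its
baseline capacity is $\bar\mu_j = 1.05 \times$ its *year-average*
expected arrivals. Two design choices deserve emphasis:

* **Capacity is proportional to expected arrivals, not to raw physician
  counts.** Physician supply enters through the selection rule's $f(r)$
  factor, so capacity still grows with $r_j$; but strict proportionality
  to $r_j$ alone would leave geographically favored hospitals permanently
  under-provisioned and their queues divergent.
* **The 1.05 ratio is applied to year-average demand** (warm months at
  0.85 of the cold rate). Backlogs then build through the cold season and
  drain through the warm one, keeping every hospital near unit
  utilization with wait times in the tens of days — the near-critical
  regime in which self-organized fluctuations can live. Anchoring the
  ratio to cold-season demand instead leaves ~10% slack year-round, and
  the system relaxes to trivial 1–3-day waits.

What the generator does *not* emulate: real geography and road networks
(driving times are clipped planar distances), demographic structure
(patients are exchangeable within a city), hospital case-mix, and any
secular trend in demand. Results on synthetic bundles demonstrate the
model's mechanisms, not province-specific magnitudes.

## Variation statistics

For a monthly (or weekly, or half-monthly) series $x_n$, the package uses
range-normalized variations
$$v_{n+1} = \frac{x_{n+1} - x_n}{x_{max} - x_{min}},$$
and their absolute values $v'_n = |v_n|$. The transform is invariant to
positive affine rescaling of the series, so hospitals with different wait
scales pool comparably. `pool_wait_variations()` re-aggregates each
hospital's realized waits into period medians (carrying empty periods
forward, as the release rule does), differences each hospital against its
*own* range, and concatenates across hospitals and replicates. Exact
zeros are dropped before power-law fitting (the fit works in the log
domain); the dropped count is reported. Distribution-level statistics are
always computed from per-replicate panels and pooled — never from the
replicate-mean panel, since averaging destroys distributional shape.

## Power-law fitting

`fit_power_law()` implements the standard continuous maximum-likelihood
fit $\hat\alpha = 1 + n_{tail}\left[\sum \ln(x_i/x_{min})\right]^{-1}$
with the cutoff $x_{min}$ chosen to minimize the Kolmogorov–Smirnov
distance, and a semiparametric bootstrap goodness of fit: each resample
draws tail values from the fitted model and body values from the observed
sub-cutoff data, is refit from scratch, and `gof_p` is the fraction of
resamples whose KS distance reaches the observed one. Under the standard
reading, **large** `gof_p` means the power law cannot be rejected.

Applied work in this literature sometimes prints the *inverted* decision
rule — treating $p \le 0.1$ as evidence *for* a power law — and quotes
the slope of an ordinary least-squares fit to the log–log binned density
as "the power". Both conventions are therefore returned side by side:
`plausible_clauset` (`gof_p >= 0.1`), `follows_inverted_convention`
(`gof_p <= 0.1`), and `ols_slope` with its significance. They are
different quantities and can disagree; the classification a user should
trust is the standard one.

Numerical choices: the cutoff scan examines up to 100 quantile-spaced
candidates among the unique values (keeping at least 5 tail points),
which bounds the cost of the 1000-resample bootstrap; ties and small
samples are handled by evaluating both one-sided empirical-CDF gaps. Two
known limitations are documented rather than patched: free cutoff
selection has limited power against light-tailed alternatives (it can
retreat into a small conforming tail — the reason likelihood-ratio
comparisons exist, which are out of scope here; fixing `xmin` restores
full power), and the bootstrap p-value is only approximately uniform
under the null.

The Lilliefors normality test uses the exact KS statistic against a
normal with sample-estimated moments and a Monte-Carlo null (default
2000 replicates) that repeats the estimation step, rather than tabulated
critical values. KL divergence between samples uses 20 shared
equal-width bins with one pseudo-count per bin, guaranteeing finiteness;
it is reported in nats and is not bounded by 1. Gini coefficients use
the sorted-form mean absolute difference.

## Replicates, seeds, determinism

A run is deterministic given (configuration, environment, seed).
Replicate $r$ of a set derives its seed from the master seed, and
distribution analyses pool replicates. The package default is 50
replicates; the headline analyses in the acceptance script use 20
replicates of the full 720-step, 47-city bundle, which keeps a complete
two-condition comparison (including the 1000-resample bootstrap) within
a few minutes on one core. Categorical draws use a single-uniform
inverse-CDF, so results are exactly reproducible across platforms with
the same RNG stream.

## What the feedback produces

With all patients wait-sensitive and service rates frozen, a hospital's
released wait and its next-round arrival share are negatively correlated
— the regulating loop in isolation. With no wait-sensitive patients and
frozen rates, round-to-round arrival-share differences are mean-zero
with variance consistent with multinomial sampling alone: nothing
self-organizes. Between the extremes, a minority of wait-sensitive
patients (the default $P_r = 0.2$) couples the hospitals' wait series
and stretches the tail of the pooled absolute variation distribution.

On default synthetic bundles the pooled monthly absolute wait variations
at $P_r = 0.2$ are typically *not rejected* as a power law by the
bootstrap test, while at $P_r = 0$ they typically *are* rejected —
feedback makes the difference between heavy-tailed self-organized
variation and plain sampling noise. Note the convention trap: expressed
in the inverted threshold convention described above, these same
p-values read oppositely. The package reports the computed `gof_p` and
both flags and leaves the semantics explicit. Exact p-values vary with
the master seed (they are Monte-Carlo functionals of a stochastic
simulation); the direction of the comparison is the robust finding.

## Known limitations

* The released statistic is the median wait of a round's completions; a
  "round-mean of daily medians" reading would smooth the series and
  slightly change variation magnitudes.
* Priority is an ordering rule only — an urgent arrival never preempts
  completions already drawn for the day.
* No within-day ordering of arrivals beyond urgency class, and no
  patient abandonment or transfers once enqueued.
* The initial backlog is seeded as non-urgent patients of age zero, so
  first-round waits understate steady-state waits slightly.
* The Gini-based release-period sweep measures dispersion of the
  released series only; it does not decompose seasonal from
  feedback-driven variation.
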