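---
title: "A coupled fish-dynamics and angler-demand model for the Texas bays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A coupled fish-dynamics and angler-demand model for the Texas bays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(baytrips)
```

## The model

`baytrips` couples two models of a recreational fishery on the seven major
Texas bays (Galveston, Matagorda, San Antonio, Aransas, Corpus Christi, and
the Upper and Lower Laguna Madre, always in this coastal order):

1. **A biological model** of the seasonal gillnet catch per unit effort
   (CPUE, fish per net-hour) of red drum and spotted seatrout — a
   second-order *periodic vector autoregression* fitted as a state-space
   model by Kalman-filter maximum likelihood.
2. **An angler-decision model** — a conditional-logit choice of which bay
   to fish, nested under a participation decision driven by the inclusive
   value of a trip, calibrated to observed base-season trips and landings.

The two are linked by assuming recreational catch per trip moves
proportionally with the monitoring CPUE, so simulated fish fluctuation
drives simulated trips per bay.

### The periodic state-space model

For bay $j = 1,\dots,7$ and half-year time steps $t$ (spring and fall of 35
years, 70 rows), the latent abundance index $x_{t,j}$ evolves as

$$x_{t,j} = b_{1,s}\,x_{t-\tfrac12,j} + b_{2,s}\,x_{t-1,j}
  + w_{1,s}\,\varepsilon_{t,j-2} + w_{2,s}\,\varepsilon_{t,j-1}
  + w_{3,s}\,\varepsilon_{t,j} + w_{4,s}\,\varepsilon_{t,j+1}
  + w_{5,s}\,\varepsilon_{t,j+2},$$

with i.i.d. standard-normal process shocks $\varepsilon$, and the
observation is $y_{t,j} = x_{t,j} + v_s e_{t,j}$ with standard-normal
$e_{t,j}$. Coefficients are indexed by the season $s$ of the *target* row
(1 = spring, 2 = fall). The five $w_{k,s}$ form a banded loading matrix
coupling each bay to its two coastal neighbours on each side; loadings that
would reach past the ends of the coast are structurally zero. The full
model has 16 coefficients. Candidate models keep $v_1, v_2, w_{4,1},
w_{4,2}$ always and exclude any proper, non-empty-complement subset of the
other 12, giving $2^{12}-1 = 4095$ nested candidates
(`enumerate_varm_specs()`); note the always-included process loadings are
literally the $j{+}1$-neighbour terms $w_{4,s}$, not the own-bay $w_{3,s}$,
which mirrors the published model space and is worth knowing before
interpreting sparse fits.

`pvarm()` maximizes the exact Gaussian likelihood (Kalman filter over the
stacked state $[x_t; x_{t-1/2}]$, implemented in compiled code) from five
randomized starts, `select_bic()` picks the candidate minimizing
$-2\ell + k\ln(490)$ with $490 = 70 \times 7$ scalar observations, and
`simulate()` draws new panels from the fitted dynamics started at the
stationary distribution.

Identifiability note: the loadings enter the likelihood only through
$W_sW_s^\top$, so their signs are not identified. The fitter constrains
$w \ge 0$ and $v > 0$, which makes reported coefficients unique and matches
the sign convention of published estimates.

### De-trending and standardization

The raw CPUE series (one per species, bay and season; 35 annual points
each) are non-stationary over the study period, so each is de-trended
separately before fitting: an ordinary-least-squares polynomial of degree
0–3 in the year index, the degree chosen by exact leave-one-out
cross-validation (`select_poly_order()`, ties to the smaller degree), and
the residuals re-centred on the series mean (`detrend_series()`), which
preserves the long-run level. Degree 0 is included so untrended series are
left alone. Stationarity of every series is screened with an augmented
Dickey–Fuller test (`adf_stationary()`): constant, no deterministic trend
(the series have just been de-trended), augmentation lag 0–3 chosen by AIC
on a common estimation sample, MacKinnon finite-sample critical values,
level $\alpha = 0.1$ by default.

The de-trended panel is then logged and z-scored per bay column
(`standardize_panel()`). Because residual-plus-mean de-trending can touch
zero, values are floored at $10^{-3}$ times the column mean before logging;
the floor is stored with the column means and standard deviations so
`unstandardize_panel()` inverts the transform exactly on the floored
domain. Simulated panels are mapped back to the CPUE scale with the same
transform.

### The angler-decision model

Conditional on taking a trip, the probability of choosing bay $j$ is the
logit

$$P_j = \frac{e^{\beta_d d_j + \beta_{cR} c_j^R + \beta_{cS} c_j^S}}
  {\sum_k e^{\beta_d d_k + \beta_{cR} c_k^R + \beta_{cS} c_k^S}},$$

with distance $d_j$ in one-way miles and expected catch per trip $c_j$ by
species. The default coefficients are the published Gulf-coast estimates
$\beta_d = -0.082$, $\beta_{cR} = 0.170$, $\beta_{cS} = 0.347$
(`choice_coefs()`); `fit_site_choice()` re-estimates them from choice
records by conditional-logit maximum likelihood (exercised on synthetic
records from `gen_choice_dataset()`).

Because the trip distribution of Texas anglers is observed but their
distances are not, the model is calibrated through a *representative
angler*: `calibrate_distances()` solves the share-matching system so the
logit reproduces the observed trip shares exactly, after anchoring
$\bar d_1 = 100$ miles at Galveston. Base catch rates come from
`base_catch_rates()` as landings/trips of the packaged base table
(`texas_base_tables()`). The calibrated vectors are not physical distances;
they are the distances a single hypothetical angler would have to face for
the observed shares to be utility-consistent.

Participation is logistic in the inclusive value
$IV = \ln \sum_k e^{u_k}$ with slope $\lambda$ (the nested-logit
dissimilarity coefficient), calibrated from willingness to pay:
$\lambda = -(\beta_d / \text{cost-per-mile}) \cdot WTP$ with $WTP = \$30$
per fishing day, so \$1, \$2 and \$0.5 per one-way mile give
$\lambda = 2.46$, $1.23$ and $4.92$. (A published narrative figure of 4.96
for the \$0.5 case is inconsistent with this formula; the package reports
the formula value.) Base seasonal participation spreads 20 fishing days per
year across a 189-day high (summer) and 176-day low (winter) season
proportionally to base trips (`base_participation()`, giving 0.0749 and
0.0332 per day), and scenario responses use the linearization
$\Delta P_T = \lambda(1-P_T)P_T\,\Delta IV$ by default
(`delta_trip_probability()`; an exact-logistic mode is available and used
as a robustness check, since the base intercept is never estimated — the
module carries base $P_T$ directly).

The catch elasticity of trips to bay $j$ decomposes into a participation
and a site-choice part (`trip_elasticity()`):

$$\varepsilon_j^T = \underbrace{\lambda (1-P_T)\,\beta_c P_j
c_j}_{\text{participation}} + \underbrace{\beta_c c_j (1 -
P_j)}_{\text{site choice}}.$$

Both components are validated against a central finite-difference
derivative of $\ln(P_T P_j)$ computed through the full logit. Published
elasticity tables for this system are *not* reproducible from the published
base inputs through this formula (the computed values are several-fold
smaller, inconsistently across species — the scale of $c_j$ used there is
ambiguous); `elasticity_table()` therefore reports the formula faithfully
and this discrepancy is documented rather than tuned away.

### Coupling

Spring monitoring CPUE informs the following high season, fall CPUE the
following low season of the same year (`map_seasons()`). Simulated CPUE is
rescaled so its long-run mean per bay/season equals the base catch rate
(`scale_to_recreational()`), which makes the base table a *fixed point*:
when simulated catch sits at its mean, `simulate_trips()` returns exactly
the base trips. Total trip occasions per season are backed out as
$N_s = \sum_j T_j / P_T^{base}$, and trips to bay $j$ in a given year are
$N_s P_T P_j$ with $P_T$ clamped to $[0,1]$ (clamping events are logged).
Expectation smoothing of catch across neighbouring sites and past waves
(`expected_catch()`, geometric distance decay $(1-r)^{miles}$, wave weight
$\omega^{wv}$ per lagged wave, year weight $\omega^{yr}$) is available but
off by default in the Texas simulation: no inter-bay distance matrix for
the representative angler exists, and the weighted form matters mostly when
site-level reports are sparse. `run_scenarios()` repeats the simulation for
cost-per-mile $\in \{0.5, 1, 2\}$ with the same catch draw, so trajectories
differ only through $\lambda$; cheaper travel (larger $\lambda$) amplifies
the variability of total trips.

## Tunable constants

| constant | default | units | role |
|---|---|---|---|
| `beta_d` | −0.082 | utility/mile | distance disutility |
| `beta_cR`, `beta_cS` | 0.170, 0.347 | utility/(fish/trip) | catch utility |
| `wtp` | 30 | $/fishing day | calibrates λ |
| `cost_per_mile` | 0.5, 1, 2 | $/one-way mile | scenario travel cost |
| `annual_days` | 20 | days/year | base participation |
| `days_high`, `days_low` | 189, 176 | days | season lengths |
| `d1` | 100 | miles | distance anchor, bay 1 |
| `alpha` | 0.1 | — | ADF screening level |
| `floor_frac` | 1e-3 | × column mean | log floor |
| `n_starts` | 5 | — | ML restarts per model |

## The synthetic generator

`gen_trended_cpue()` emits study-shaped raw data (35 years × 7 bays × 2
seasons × 2 species): per bay, $\text{CPUE} = \exp(\text{polynomial trend}
+ \text{stationary fluctuation})$. Its defaults are chosen once, on realism
grounds, and define the conditions under which the pipeline is tested:

* **Trends**: log-linear slopes of roughly ±0.05–0.08 per year on most
  bays (several-fold change over 35 years, one bay flat), emulating the
  pronounced multi-decade increases seen in the monitoring data, where most
  raw series fail a stationarity screen.
* **Fluctuation**: the stationary component is simulated from the
  published red-drum state-space estimates for *both* species and scaled by
  0.4 log-units. The red-drum dynamics (one-year autoregression 0.33/0.23)
  are used rather than the near-unit-root seatrout estimates (0.91) because
  the generator must produce fluctuation whose stationarity is *detectable*
  at 35 observations; 0.4 log-units matches typical seasonal gillnet CPUE
  variability (CV ≈ 0.4).
* **Streams**: every noise component draws from a named substream of the
  master seed, so adding a component does not shift the others, and equal
  seeds give byte-identical output.

What passing tests on these panels shows: the de-trend → screen →
standardize → fit → simulate → trips pipeline is internally consistent, and
the fitter recovers known dynamics at realistic scales. What it does not
show: behaviour under features the generator omits — observation gaps,
season-specific trends within a bay, non-Gaussian heavy tails in catch, and
effort feedback onto mortality (deliberately outside the model).

A note on the stationarity screen at study scale: with AIC lag selection
over 0–3 at $n = 35$, the ADF rejection rate under even the most favourable
stationary alternative is about 97%, so *some* of 28 screened series will
occasionally fail in any finite panel; the pipeline tests therefore assert
the per-series stationarity rate across seeds rather than an all-28 verdict
per panel.

## Numerical choices

* Kalman initialization: stationary covariance of the composite two-season
  map via the discrete Lyapunov equation; a diffuse prior (variance
  $10^7$) is selectable and suggested by the error raised for explosive
  dynamics. For complete panels the filter reuses the converged per-season
  gain (relative change < 1e-13 twice in a row), which leaves likelihoods
  identical to ~1e-10 while making long panels cheap.
* Multi-start optimization: L-BFGS-B with $b \sim U(-0.5, 0.5)$,
  $w, v \sim U(0.1, 1)$ starts; "not estimable" (all starts fail, or the
  observed information is singular away from a $w = 0$ boundary) is a
  returned state, not an error, so model sweeps can drop such candidates
  the way the published search did.
* Ties: LOOCV ties resolve to the lower polynomial degree; BIC ties to the
  smaller model, then the lexicographically earlier inclusion mask.
* Softmax and log-sum-exp are computed with a max shift everywhere
  utilities are exponentiated.
* Degenerate inputs error early and specifically: constant series (ADF),
  zero-variance log columns, non-positive trips, $\beta_d = 0$ in the
  calibration, explosive dynamics with stationary initialization.

## Problem sizes used by the test-suite experiments

Chosen to make the experiments' Monte-Carlo error small at desk scale: the
likelihood-identity property runs 200 random systems at $T \le 5$, $J \le
3$ against a brute-force joint-Gaussian density; parameter recovery fits
the published red-drum specification to one $T = 2000$, $J = 7$ panel;
model-space recovery runs 50 replicates of an 11-candidate sweep at
$T = 500$ on a 4-bay system (the banded edge structure is already present
at 4 bays); the travel-cost variance ordering averages 20 seeds of 35-year
simulations.

## Known limitations

* The choice model carries no site-specific constants (none are
  identifiable for the simulated bays), so all cross-bay preference comes
  through distance and catch.
* The coupling is one-directional: trips do not feed back into fish
  mortality.
* Calibrated distances and the representative angler are accounting
  devices that reproduce shares, not geography.
* Polynomial trends are removed, not extrapolated; the simulation explores
  stationary fluctuation around the historical mean only.
* The seatrout published estimates sit near the unit root; simulations from
  them are long-memory and slow to mix, which is why the generator defaults
  to the red-drum dynamics.
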