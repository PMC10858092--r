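---
title: "Modelling the power-duration relationship: hyperbolic vs power law"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the power-duration relationship: hyperbolic vs power law}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endurofit)
```

## The two models

The power-duration relationship gives the highest power $P(T)$ (for runners:
velocity $V(T)$, with distance standing in for work) that an athlete can
*sustain* for a duration $T$. `endurofit` implements the two classical
two-parameter forms:

* **Hyperbolic (critical-power) model**: $P(T) = W'/T + \mathrm{CP}$, with
  asymptote $\mathrm{CP} > 0$ (critical power; critical velocity CV in
  running) and curvature constant $W' > 0$ (distance analogue $D'$), read as
  a finite tank of work performable above CP. Equivalent forms:
  $W(T) = W' + \mathrm{CP}\,T$ and time to exhaustion
  $T(P) = W'/(P - \mathrm{CP})$ for $P > \mathrm{CP}$.
* **Power-law (Riegel) model**: $P(T) = S\,T^{E-1}$ with speed parameter
  $S > 0$ (the one-second power) and endurance exponent $E \in (0,1)$.
  Riegel's fatigue factor is the derived view $F = 1/E > 1$; internally only
  $E$ is stored, so the two presentations cannot drift apart. Equivalent
  forms: $W(T) = S\,T^{E}$, $T(P) = (S/P)^{1/(1-E)}$.

All inverses are closed forms and are implemented analytically; no root
finding is involved anywhere in the model layer. Units are SI throughout
(`s`, `m`, `J`, `J/s`); the `mode` field of a parameter object
(`"power"`/`"velocity"`) is a printing label only and never changes a
number. Conversions such as hh:mm:ss live exclusively at the I/O boundary
(`parse_hms()`, the effort CSV dialect).

A modelling assumption worth keeping in mind: both curves describe
*sustained* intensity and ignore the initial acceleration phase, so observed
maximal efforts over a few seconds fall below either curve.

### Which inputs count

The hyperbolic model is conventionally trusted only for efforts of about
2–15 minutes; `fit_hyperbolic()` therefore restricts itself to efforts
inside a closed `window = c(120, 900)` seconds (boundaries included — the
conventional reading of "between 2 and 15 min"). The physiological
severe-domain boundaries that motivate the window cannot be estimated from
race results alone, so the duration window is the operational stand-in, and
it is a parameter, not a constant: rowing-style analyses customarily widen
it to 2–20 min. The power law carries no such restriction and
`fit_powerlaw()` uses every effort by default.

## Estimation

Both fits are ordinary least squares on the models' linearising transforms:
intensity against $1/T$ (slope $W'$, intercept CP), and $\log$ intensity
against $\log T$ ($S = e^{\text{intercept}}$, $E = \text{slope} + 1$).
Weighted or non-linear refinements exist but change little in practice and
would obscure the comparison; the unweighted transforms are the deliberate
choice here. Two efforts tied on duration cannot both be maximal, so only
the higher-intensity one enters a fit. A fitted CP, $W'$, $S$ outside its
admissible range raises a classed `invalid-fit` error carrying the offending
values rather than returning an unusable object.

With a single previous race, both parameters cannot be estimated;
`calibrate_fixed_f()` implements the magazine-style predictor
$T = T_0 (D/D_0)^{F}$ with $F$ fixed at the road-running default 1.06,
which is exactly the power law with only $S$ estimated.

```{r}
fit_hyperbolic(kipchoge_prs())$params
fit_powerlaw(kipchoge_prs())$params
```

The package ships the career personal records of Eliud Kipchoge and Haile
Gebrselassie (World Athletics; road times to the second, track times to the
hundredth) as `kipchoge_prs()` / `gebrselassie_prs()` and as CSV fixtures
under `inst/extdata/`. Note what the fits above show: the two models agree
closely on 2–15 min efforts yet imply a 1-second velocity of roughly
660 km/h (hyperbolic) versus 34 km/h (power law) — the divergence outside
the window is the scientific point, and it is the property the test suite
checks on synthetic cohorts where the truth is known.

### Dataset hygiene

`filter_dataset()` applies three configurable screens before large-scale
fitting: (a) a minimum in-window effort count per athlete (default 3),
(b) maximality — the mean-maximal curve must be non-increasing, so an effort
whose mean intensity does not exceed that of every strictly longer effort is
dropped; (c) outliers whose log-residual exceeds `mad_multiplier` (default
5) times the MAD of residuals from a preliminary power-law line. The
preliminary line is a Theil–Sen fit rather than OLS: a 10× power-meter spike
at an extreme duration has enough leverage to drag an OLS line toward
itself and hide from its own residuals, whereas the median-of-pairwise-slopes
line ignores it (breakdown point ~29%). Rules that would exclude everything
return an empty table plus a per-rule report, never an error.

## Exertion, fatigue and fatigued curves

Inverting each model for $1/T$ gives an instantaneous *rate of exertion* at
power $P$ — hyperbolic $(P-\mathrm{CP})/W'$, power law $(P/S)^{1/(1-E)}$ —
whose integral over an intensity profile is accumulated fatigue; exhaustion
is the first time that integral reaches 1. The hyperbolic rate is linear in
$P$ (deplete the tank in any order), the power-law rate strictly convex —
the analytic seed of every pacing result below. Because profiles are
piecewise constant (`power_profile()`), `accumulate_fatigue()` sums exactly
and locates the exhaustion instant analytically inside the breaching
segment; `accumulate_fatigue_fn()` offers quadrature (tolerance `1e-10`)
for genuinely continuous profiles. Below CP the hyperbolic rate is an
*error*, not zero: a zero would silently imply recovery, and recovery
(intermittent-exercise extensions) is deliberately outside this package's
scope. Trajectories may report fatigue above 1 as a diagnostic, but the
exhaustion event itself is always located at exactly 1.

After exercising $t$ seconds at constant $P$ without exhausting, the
remaining curve stays in-family with one parameter reduced:
$W' \mapsto W' - t(P - \mathrm{CP})$ (CP untouched), and
$S \mapsto (S^{1/(1-E)} - t P^{1/(1-E)})^{1-E}$ ($E$ untouched). The
power-law update is computed in log space because $1/(1-E)$ reaches ~20 for
realistic $E$ and the naive powers overflow. The contrast is the point: the
fatigued hyperbolic athlete can still hold arbitrarily-close-to-CP forever,
while the fatigued power-law curve scales down wholesale, matching the
observed downward drift of the relationship during prolonged exercise.

```{r}
fatigued_params(hyperbolic_params(400, 25500), p = 407, t = 2700)
```

## Pacing

For a fixed amount of work, `even_pace()` gives the unique constant power
finishing exactly at exhaustion, and `two_phase_finish_time()` evaluates a
plan that holds $P_1$ for the first $W_1$ of work and then the best constant
salvage power. Under the hyperbolic model every feasible start at or above
CP finishes in exactly the even time (the order of depletion is irrelevant
to a linear rate), and only starting *below* CP costs time; under the power
law any $P_1$ other than the even pace is strictly slower, over-pacing
asymmetrically worse than under-pacing. Both statements are verified
numerically on 10,000 random plans in the test suite, and the closed forms
are cross-checked against the fatigue-integration oracle to $10^{-9}$.

Two boundary outcomes are structured results rather than exceptions, so that
`pacing_curve()` can tabulate a full "first-kilometre velocity" axis:
exhaustion before completing phase 1 (`dnf_phase1`, the over-pacing
catastrophe) and the hyperbolic degenerate case `degenerate_underpacing`
where the residual tank already covers the remaining work ($W_2 \le R$), so
no finite constant power exhausts at the line and the model assigns the
remainder zero time. The hyperbolic phase-1 bookkeeping below CP deserves a
note: with recovery out of scope, sub-CP riding consumes nothing and the
tank simply stays full ($R = W'$), which is precisely what makes slow starts
strictly costly.

## The synthetic cohort generator

`generate_population()` emulates the structure of large observational
effort datasets: per-athlete truth parameters drawn from stated
distributions, exact model-implied efforts over a race menu
(`generate_effort_grid()`, also the oracle kernel for tests), multiplicative
log-normal noise on recorded time, and optional labelled contamination.
Defaults, chosen once as a realistic club-runner cohort and not revisited:
$S \sim \mathrm{lognormal}(\log 8.5, 0.08)$ m/s,
$E \sim U(0.88, 0.96)$ (bracketing the elite estimate 0.94 and Riegel's
road-running $F = 1.06$, i.e. $E \approx 0.943$), the standard distance menu
800 m–marathon, and $\sigma = 0.02$ time noise (roughly a 1–2 min spread on
a marathon). Noise multiplies the *time* with work held fixed, matching the
log–log fitting geometry; for fixed-duration menu entries (rowing 30/60 min
efforts) the recorded duration wobbles around the nominal one the same way.
Contamination is either 10× intensity spikes (power-meter malfunction) or
times inflated by $U(1.10, 1.40)$ (non-maximal efforts), each row labelled,
so filter recall and precision are exactly computable. Everything is
reproducible from the spec's seed, and the global RNG state is left
untouched (`withr::with_seed`).

What the generator deliberately does *not* emulate: within-athlete
parameter drift across seasons, course/weather effects, correlated
event-specialisation (a 400 m specialist's flat short-end profile), or raw
second-by-second files. Passing tests on this cohort therefore show that
the *pipeline* recovers what it assumes, not that real athletes follow a
power law; the case-study fixtures are the only real data in the package.

## The model-comparison studies and their design choices

`binned_errors()` reproduces the duration-binned comparison: per athlete,
fit each model by *its own* protocol (hyperbolic on the window, power law on
all efforts), score every effort by the signed or absolute relative
intensity error, average within athlete per bin, then across athletes with
SE = SD/$\sqrt{n}$. Whether published figures of this kind average signed
or absolute errors per athlete is not something the main-text sources pin
down; both conventions are implemented (`absolute =`), absolute being the
default since error-magnitude curves are what the figures display. Bins are
half-open $[lo, hi)$ on observed duration with default edges at 0.5, 1, 2,
15, 20, 45, 90 and 360 min — fine near the window, coarse far from it —
and fully configurable. Athletes unfittable by either model are excluded
from *both* summaries (exact set equality is asserted in tests), empty bins
are omitted, and a one-athlete bin reports `NA` SE. The out-of-sample
protocol (`out_of_sample()`) draws the same six seeded training efforts for
both models, scores the held-out rest, and excludes an athlete from both
models if either fit fails on the draw.

Two study conditions used by the comparison and recovery experiments were
fixed a priori and are worth recording. The binned-comparison cohort (200
runners, $\sigma = 0.02$) races a menu that *includes 400 m*: the sub-2-min
bins the comparison must populate are populated in real race databases by
short track events, while a club runner's 800 m already takes over two
minutes. The parameter-recovery experiment instead uses 8 log-spaced best
efforts from 30 s to 2 h — a cycling mean-maximal-power ladder — because
$S$ is the curve's 1-second intercept and estimating it sensibly requires
short best efforts, which power files routinely contain; problem sizes (200
athletes; 500 replicates) keep each experiment comfortably within a minute
on one CPU.

## Numerical choices, degenerate inputs, limitations

* Closed forms everywhere the algebra allows; log-space evaluation wherever
  $1/(1-E)$ exponents appear (fatigued $S$, phase-2 power).
* Classed conditions (`endurofit_error_*`) for: domain violations; the
  hyperbolic "no exhaustion at $P \le$ CP" case (an inspectable condition,
  never a silent `Inf` — downstream code must distinguish "never exhausts"
  from overflow); sub-CP exertion rates; exhausted athletes in
  `fatigued_params()`; insufficient or invalid fits; malformed CSV rows
  (reported with line numbers).
* Round trips (`pd_tte` after `pd_power`, CSV write/read) are exact to
  machine precision and tested at `1e-12`.
* Limitations shared with the underlying models: both predict a dead stop
  at exhaustion rather than the gradual power decline seen in all-out
  tests, and neither models recovery below CP (the power law has no
  threshold below which to recover, by construction). The pacing results
  assume constant conditions and ignore start/finish kinetic-energy
  effects, so they apply to longer time trials, not sprints.
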