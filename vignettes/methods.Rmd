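---
title: "Models and methods behind wheatnr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind wheatnr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wheatnr)
library(dplyr)
```

`wheatnr` implements the trait derivations used to study why wheat
cultivars differ in nitrogen responsiveness: the slope of the yield
response to fertilizer N. This vignette documents the models, the
numerical choices, and what the synthetic data generator does and does
not emulate.

## The Richards grain-filling model

Grain dry weight after anthesis follows the asymmetric sigmoid

$$W(t) = A\,(1 + B e^{-kt})^{-1/N}$$

with $A$ the final grain weight (mg per grain, or g per 1000 grains —
any unit consistent within a dataset), $k$ (d$^{-1}$) the intrinsic
rate, $B$ a time-shift coefficient and $N$ the asymmetry exponent
($N = 1$ recovers the logistic). The assumptions are the usual ones for
grain-filling work: a single smooth sigmoid per plot, anthesis at
$t = 0$, and no late-season weight loss.

Grain filling is decomposed into three phases delimited by the zeros
$T_1 < T_2$ of the third time-derivative of $W$ — the inflection points
of the filling *rate* — and by $T_3$, the time the grain reaches 99% of
$A$. All have closed forms in the parameters; substituting
$u = B e^{-kt}$, the third derivative vanishes at
$u = \tfrac12\!\left(N^2 + 3N \pm N\sqrt{N^2+6N+5}\right)$ and
$W = 0.99A$ at $u = (100/99)^N - 1$, each converting to a time via
$t = \ln(B/u)/k$. Because every boundary is $\ln(B)/k$ plus a function
of $N$ and $k$ only, the durations $T_{fast} = T_2 - T_1$ and
$T_{slight} = T_3 - T_2$ are independent of $B$ — a property the test
suite asserts to $10^{-10}$ d, and which the synthetic generator
exploits to invert a target $T_{fast}$ into $k$ with $B$ free to set
the phase onset. The maximum rate is
$GFR_{max} = kA(N+1)^{-(N+1)/N}$ and the mean rate is taken as
$GFR_{mean} = Ak/(2(N+2))$, the closed form conventional in this trait
family; its averaging interval is not derivable from the curve alone and
it is implemented exactly as printed in the agronomic literature.

The closed forms are verified in the tests against oracles that know
nothing of the algebra: base R's symbolic differentiator applied to the
growth formula, with `uniroot()`/`optimize()` locating the zeros and the
rate maximum over 1,000 random parameter sets (log-uniform
$A \in [20,60]$, $B \in [1,50]$, $k \in [0.05,0.5]$, $N \in [0.2,5]$,
filtered by the phase-ordering condition $(100/99)^N - 1 < u_2$, which
fails only for large $N$ where the 99% point precedes the second rate
inflection; such fits are reported as an error naming the inequality).

### Fitting

`fit_richards()` minimises unweighted least squares with
Levenberg–Marquardt (`minpack.lm::nlsLM`). Richards fits are
init-sensitive, so initialisation follows a logistic approximation
($A_0 = 1.05\max W$; $k_0$ from the slope of $\mathrm{logit}(W/A_0)$
on $t$; $N_0 = 1$; $B_0$ through the first observation), with a
deterministic $3{\times}3{\times}3$ restart grid scaling
$(k_0, N_0, B_0)$ by $\{0.5, 1, 2\}$ whenever the first attempt fails
or leaves $r^2 < 0.98$. Bounds $A \in (0, 3\max W]$,
$B,k,N \in (10^{-6}, 10^3]$ keep the exponent sane. A series needs at
least 5 points (4 parameters + 1); the trial design provides 7
(0–36 d every 6 d). Non-convergence is reported, never silently
patched. A fitted curve already past its slow phase at anthesis
($T_1 \le 0$) is returned with a quality flag rather than clamped, and
flagged fits are excluded from downstream aggregation — this preserves
auditability over tidiness.

Fits are per replicate plot by default, with traits then averaged over
replicates; `analysis_config(fit_level = "mean")` fits the
replicate-mean series instead. Both are defensible; plot-level
preserves the error structure.

## Linear-plus-plateau yield response

$GY(N) = b_0 + N_r \min(N, N_{cs})$ is fitted by profiling the
breakpoint: at each candidate $N_{cs}$ the conditional fit is OLS on
$\min(N, c)$, solved in closed form, so the 1-D profile can be searched
exhaustively (observed rates plus a 1 kg N ha$^{-1}$ grid) and then
refined by golden section — a deterministic global optimum, no random
starts. Ties in RSS resolve to the smallest breakpoint, consistent with
defining the critical supply as a *minimum* rate. With only four N
rates the breakpoint is weakly identified; under the trial noise model
(yield SD 0.2 t ha$^{-1}$, 3 reps) the median breakpoint error is
about 6 kg N ha$^{-1}$, well inside the 25 kg tolerance the tests
assert over 500 simulations. A response still linear at the top rate is
flagged `plateau_observed = FALSE` rather than extrapolated.

## SPAD senescence and the degradation rate

SPAD readings at 7, 14, 21 and 28 d after anthesis are fitted with
$y = at^2 + bt + c$. The chlorophyll degradation rate is taken as
$|2a|$ — the absolute slope of the fitted derivative — which is a
curvature (SPAD d$^{-2}$), invariant to adding a constant or a linear
trend to the series. The field literature sometimes describes the same
quantity as the slope of a linear regression of SPAD on time (SPAD
d$^{-1}$); the two are not the same object and the ambiguity cannot be
resolved from definitions alone, so `fit_spad()` returns both (`cdr`
and `linear_decline_rate`) and `analysis_config(cdr_mode = )` selects
which feeds the sensitivity analysis (default: the quadratic $|2a|$).

## Nitrogen accounting

Organ N amounts (g m$^{-2}$) are biomass × concentration. With $N_{aa}$
the shoot N at anthesis, $N_{vtm}$ vegetative N at maturity and
$N_{gm}$ grain N: $NTA = N_{aa} - N_{vtm}$,
$NTE = 100\,NTA/N_{aa}$, $CNTA = 100\,NTA/N_{gm}$ (its complement is
the post-anthesis-uptake share of grain N). Efficiency indices convert
everything to kg ha$^{-1}$ first (g m$^{-2}$ ×10, t ha$^{-1}$ ×1000):
$NUtE = GY/N_{am}$, $NUpE = N_{am}/N_e$, $NUE = GY/N_e$, with
$N_e$ = fertilizer N + plant-available soil N. Soil N is rarely
reported per plot; the default constant is 60 kg ha$^{-1}$
(`analysis_config(soil_n = )`), a typical 0–30 cm mineral N level for
intensive winter-wheat systems. A plot gaining vegetative N after
anthesis yields a negative $NTA$ with a flag, not an error.

The nitrogen nutrition index is $NNI = NC_{act}/NC_{cri}$ with the
critical dilution curve $NC_{cri} = 4.59\,W_{shoot}^{-0.41}$ (% N).
Curves of this family are calibrated on biomass in t ha$^{-1}$;
evaluating the same coefficients on kg ha$^{-1}$ gives absurd
concentrations (at 8,000 kg ha$^{-1}$, $NC_{cri} \approx 0.11$%), so
the default unit is t ha$^{-1}$ with `unit = "kg_ha"` available for
anyone wanting the literal alternative. $NC_{act}$ uses total
above-ground N and biomass at anthesis.

## Sensitivity and path analysis

Trait sensitivity to N supply is the OLS slope of treatment means
(4 N rates) per cultivar × year — means rather than replicates because
the sensitivity narrative is about treatment response, though the
replicate-level table is available upstream. With 5 cultivars any
cross-cultivar correlation of sensitivities is low-powered; the
pipeline reports it without multiplicity adjustment.

Path analysis standardizes the yield components, solves the normal
equations $R\,p = r$ for the direct coefficients $p$ (identical to
standardized multiple-regression coefficients) and reports first-order
indirect contributions $r_{ij} p_j$, so each predictor's correlation
with yield decomposes exactly as $r_i = p_i + \sum_{j \ne i} r_{ij}
p_j$ and $R^2 = \sum_i p_i r_i$. A predictor correlation matrix with
condition number above $10^{10}$ is rejected with a diagnostic. Years
and N levels are pooled by default.

## The synthetic trial generator

`generate_trial()` emulates the statistical structure the pipeline
assumes: a 2-year × 5-cultivar × 4-N-rate (0/75/150/225 kg N
ha$^{-1}$) × 3-replicate design; grain series from Richards curves on
the 0–36 d, 6-d grid; SPAD as a concave quadratic whose curvature
equals the profile's CDR at that rate; yields exactly
linear-plus-plateau in N; and organ N pools built so the mass balances
$N_{am} = N_{vtm} + N_{gm}$ and $N_{gm} = NTA + \text{post-anthesis
uptake}$ hold exactly before noise. Gaussian noise defaults — grain
0.5 mg, SPAD 0.8 units, yield 0.2 t ha$^{-1}$, N-pool CV 5% — are
realistic plot-level magnitudes chosen so that recovery tests are
meaningful but not trivial. A single seed feeds per-table substreams,
so adding a table never perturbs the others, and identical seeds give
byte-identical CSVs.

The five default cultivar profiles encode a breeding-era gradient:
monotonically increasing yield slope (0.012–0.021 t ha$^{-1}$ per kg
N), critical supply (120–150 kg N ha$^{-1}$), fast-phase sensitivity
(0.006–0.024 d per kg N) and anthesis N accumulation, and decreasing
chlorophyll degradation and post-anthesis grain-N share (40% down to
24%). The values are invented but sized from typical North China Plain
winter-wheat agronomy (grain weights 34–42 mg, yields 3–7.5 t
ha$^{-1}$, anthesis N 8–20 g m$^{-2}$); a pleasant consequence is that
the most responsive profile reaches $NNI \approx 1$ near its critical
N supply, as an optimally fertilized modern cultivar should.

What the generator does **not** emulate: weather-driven year effects
beyond a small yield offset, spatial field heterogeneity and plot
autocorrelation, non-Gaussian measurement error, missing samples, or
any soil N dynamics. Passing recovery tests therefore demonstrates
correctness of the estimators under the assumed error model, not
robustness to everything field data can do.

## Problem sizes and determinism

The test suite checks the closed-form algebra on 1,000 random parameter
sets against symbolic-derivative oracles, parameter recovery on 200
seeded noisy grain series and 500 noisy yield responses, and runs the
full pipeline end-to-end on 20 seeded trials (120 plots each),
asserting rank correlation ≥ 0.9 between recovered and generating
cultivar orderings of fast-phase sensitivity and N responsiveness. All
randomness is seeded; `run_analysis()` is deterministic given its
inputs and config.

## Known limitations

* Four N rates identify the plateau breakpoint only coarsely; the
  reported `n_cs` should be read with that in mind.
* The mean-rate closed form $Ak/(2(N+2))$ is adopted as a convention,
  not derived; alternative definitions (e.g. $0.99A/T_3$) would differ.
* The CDR unit ambiguity (d$^{-2}$ vs d$^{-1}$) is surfaced, not
  resolved.
* Sensitivity slopes assume linearity of trait response in N over the
  tested range, which for plateauing traits understates the low-N
  response.
* No alternative growth models (Gompertz, Weibull), quadratic-plateau
  response, or economic-optimum N rate are provided.

```{r example}
trial <- generate_trial(cultivar_profiles(), trial_design(seed = 42))
res <- run_analysis(trial)
res$n_response |> group_by(cultivar) |> summarise(n_r = mean(n_r), n_cs = mean(n_cs))
```
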