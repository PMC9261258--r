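---
title: "Stepwise calibration of mechanistic models with heterogeneous constraints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stepwise calibration of mechanistic models with heterogeneous constraints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stepcal)
```

Mechanistic models of tumor growth rarely come with a single likelihood.
Their parameters are constrained by a patchwork of sources: a measured
time series here, a literature statement ("the viable rim is a few
hundred micrometers") there, and experiments performed at different
biological scales — spheroids in a dish, xenografts in a mouse. `stepcal`
implements a calibration workflow built for exactly this situation:
every constraint is translated into a score in $[0,1]$, the scores are
combined into one weighted objective, the objective is maximized with a
self-contained CMA-ES, and calibration proceeds in ordered steps that
freeze solved parameters and re-verify earlier behavior.

## The objective

Each constraint $k$ yields a sub-score $s_k(y(\theta)) \in [0,1]$ from
the simulated trajectory $y(\theta)$, and the calibration maximizes

$$ f(\theta) = \frac{\sum_k \omega_k\, s_k(y(\theta))}{\sum_k \omega_k}, $$

with user-chosen weights $\omega_k \ge 0$. Two constraint kinds exist.

**Binary knowledge rules** (`binary_constraint()`) score 1 when a model
output satisfies a strict comparator (`greater`, `less`, `between`) at
every sampled time of a window (or at the final time), 0 otherwise.
Strictness makes tie-breaking deterministic: boundary equality fails.

**Continuous data-fit rules** (`data_constraint()`) compare an output,
linearly interpolated onto the measurement times, with a series of
means and standard deviations. Each point contributes
$\varphi(r_t)$ with $r_t = |y(t)-m_t| / (2 s_t)$ and

$$ \varphi(r) = \begin{cases} 1 & r \le 1 \\ e^{1-r} & r > 1, \end{cases} $$

and the constraint score is the mean over points. The shape of
$\varphi$ is a design choice: staying *within two standard deviations*
of every measurement — the usual acceptance language for this kind of
fit — earns a perfect sub-score, and the exponential tail decays
smoothly so an optimizer still receives gradient information far from
the data. Any strictly monotone alternative would preserve the argmax.
Missing or zero SDs fall back to 10% of the mean (1 absolute when the
mean is zero), overridable per constraint.

Because $\varphi$ is flat inside the band, all-band-satisfying
parameter sets form a *plateau* of $f=1$: the data alone do not pin
down, say, a growth slope beyond what the band width implies. Where a
source states a quantitative behavior explicitly ("reaches 400 µm at
day 20"), the shipped plans therefore add `anchor_constraint()`s —
single-point continuous rules whose perfect-score band is a few percent
wide. They are knowledge constraints like the binary rules, but with a
smooth pull that an optimizer can follow.

## The optimizer

`cma_maximize()` is a from-scratch $(\mu/\mu_w,\lambda)$ CMA-ES in the
standard Hansen formulation: the best $\mu=\lfloor\lambda/2\rfloor$
candidates of each generation are recombined with logarithmic weights;
the mean, two evolution paths, the covariance (rank-one plus rank-$\mu$
updates) and the global step size (cumulative step-size adaptation)
evolve with the usual learning rates as functions of the dimension $d$
and the variance-effective selection mass $\mu_\mathrm{eff}$. The
default population size is $\lambda = 4 + \lfloor 3\ln d\rfloor$
(natural logarithm, floored — the rule of the reference library
implementations).

Choices worth knowing about:

* **Normalized coordinates.** Every parameter is mapped to $[0,1]$
  (logarithmically when `log_scale` is set) before sampling. Rates in
  day$^{-1}$ and rim widths in µm then share one scale and the
  covariance stays well conditioned.
* **Initialization.** The mean starts at the initial guesses; the
  covariance is diagonal with standard deviation equal to *half the
  search interval width* per coordinate (overridable per parameter via
  `init_sd`), the global step size at 1.
* **Bounds.** Out-of-bounds draws are resampled up to 100 times, then
  clipped to the boundary — simple and deterministic.
* **Stopping.** Threshold (best $f$ reaches `stop_threshold`),
  stagnation (generation-best improves by less than `stagnation_tol`,
  default $10^{-6}$, over `stagnation_window` generations, default 30),
  or the generation budget, whichever fires first.
* **Robustness.** A candidate whose evaluation errors or returns a
  non-finite value is scored 0 (the worst possible) and the run
  continues; covariance eigenvalues are floored at $10^{-12}$.
* **Determinism.** All sampling runs through R's RNG seeded from the
  spec, so a run is bit-reproducible.

The two-dimensional toy problem (`toy_demo()`) exercises the whole
scoring-plus-CMA-ES loop on a known landscape: a negated six-hump-camel
score rescaled to $[0,1]$ (division by the known optimum magnitude
1.0316, clipped) combined at equal weight with the binary half-plane
rule $x_2 \le x_1$. Only one of the two camel optima satisfies the
rule, so the global maximum of 1 is attained at $(0.0898, -0.7126)$
alone — a property verified independently by dense grid search in the
test suite.

## Stepwise plans

`run_plan()` executes an ordered list of `calibration_step()`s. Each
step maximizes its own constraint set over its free parameters, then
freezes the solutions (or narrows their intervals to best $\pm 3$ final
search standard deviations — `narrow_ranges()`), and re-evaluates the
constraints of *all earlier steps* under the merged parameter set,
aborting if any score drops below a floor (default 0.8, a package
default since the requirement is qualitative). Steps may re-free an
earlier parameter; the carry-over check — and, in the shipped plans,
keeping the earlier constraints inside the later objective — guards the
earlier behavior. Per-step seeds derive deterministically from one
master seed; `n_restarts` runs extra CMA-ES repeats (the last polishes
the incumbent best with a tightened spread; intermediate ones restart
wide) and keeps the best. Steps on multimodal landscapes can
additionally run a deterministic factorial `prescreen` over selected
parameters to place the first run in the best coarse-grid basin.

Step ordering follows advisory guidance (documented on each step as
`priority_notes`, not enforced): best-documented data first, lowest
granularity first, least connected first.

## The surrogate growth model

The worked example calibrates a compact rim-structured
(Greenspan-style) ODE for EGFR-mutant lung-adenocarcinoma growth. It
is a *declared surrogate*: it is the minimal model exposing the five
phenomena the calibration data speak to — proliferation, death,
neoangiogenesis, immune clearance, treatment — together with the exact
published geometry relations; it does not attempt to reproduce any
proprietary pathway model. States are proliferating ($nb_{pc}$),
quiescent ($nb_{qc}$) and necrotic ($nb_{nc}$) cell counts plus a
dimensionless vascular support $A$:

$$
\begin{aligned}
\dot{nb}_{pc} &= k_{div}(1-I)\,nb_{pc} - k_q\,g_q\,nb_{pc}
                - e_{imm}\,nb_{pc} - k_{apo}\,occ\,nb_{pc}\\
\dot{nb}_{qc} &= k_q\,g_q\,nb_{pc} - k_n\,g_n\,nb_{qc} - e_{imm}\,nb_{qc}\\
\dot{nb}_{nc} &= k_n\,g_n\,nb_{qc} + k_{apo}\,occ\,nb_{pc}
                - \frac{k_{lys}\,nb_{nc}}{1 + nb_{nc}/N_{lys}}\\
\dot{A} &= d_{ang}\left(A_{max}\,\frac{nb_{pc}}{N_{1/2}+nb_{pc}} - A\right)
          \quad\text{(xenograft; } A \equiv 0 \text{ in vitro)}
\end{aligned}
$$

with $g_q = ((R - L_p\,\xi)_+/R)^3$, $g_n = ((R - L_v\,\xi)_+/R)^3$,
$\xi = 1 + a_{ang} A$, and the sphere geometry
$V = (nb_{pc}+nb_{qc}+nb_{nc})/\rho$,
$R = (3V/4\pi)^{1/3}$ at constant density
$\rho = 2.8\times 10^8$ cells/cm³ (tumors assumed perfectly
spherical). Both rims are widened by vascularization: the same nutrient
limitation that necroses the core also drives quiescence, so relief
applies to both thresholds. In vitro, angiogenesis and immune
clearance are switched off entirely; in the xenograft they operate,
the immune term as a small constant rate (the mice are
immunosuppressed, so limited but not null).

**Treatment.** Gefitinib exposure is a constant effective
concentration $C$ during treatment (the 25 mg/kg oral dose maps to a
calibratable exposure; no PK compartment is modeled). Receptor
occupancy $occ = (1-b_{res})\,C/(C+K_i)$ acts twice: cytostatically,
$I = I_{max}\,occ$ reduces division; and cytotoxically, $k_{apo}\,occ$
kills proliferating cells. A purely cytostatic drug cannot shrink a
tumor by 80% in ten days, so the cytotoxic pathway is part of the
surrogate's minimal design. Three further choices shape the regression
kinetics the way treated xenografts actually shrink: killed cells join
the necrotic-debris pool rather than vanishing (dead mass is resorbed,
not teleported); debris clearance saturates at a fixed capacity
($k_{lys} N_{lys}$ cells/day — limited phagocytic throughput), which is
what produces an approximately *linear* volume decline while the pool
is loaded and a smooth stop when it empties; and quiescent cells are
insensitive to the drug (dormant persisters), which is what produces a
stable residual mass. Vascular support $A$ relaxes toward a saturating
function of the proliferating pool at turnover rate $d_{ang}$ — the
steady-state support level and the collapse timescale after treatment
are deliberately separate parameters, because the untreated arms
constrain only the former.

**Genotypes.** `apply_mutations()` maps mutation flags onto effective
parameters while storing the literature constants verbatim
(`mutation_literature()`): KRAS mutation (98% reduction of GTP
hydrolysis) becomes a sustained-activation proliferation multiplier
$1+0.98$; EGFR exon 19 deletion sets $K_i$ from 16.4 to 0.833 nM
(sensitivity) and engages a calibratable constitutive-activation drive
`egfr_prolif_mult`; PIK3CA mutation renders the PI3K node
constitutively active (2.7-fold) *independently of EGFR*, so
receptor-level inhibition no longer propagates — full downstream
resistance, $b_{res}=1$ — and selects the PIK3CA line's own
growth factor `pik3ca_prolif_mult` (the two xenograft lines are
different cell lines, not one line with an extra mutation).

**Allometry.** Rates are expressed at the in vitro reference mass of
2.63 g and transferred to the 23 g mouse inside the simulator by
$Z = a M^b$ with $b$ fixed by the physical dimension — the
quarter-power table (first-order rates $b=-1/4$, fluxes $b=3/4$
following the 3/4-power metabolic law, times $b=1/4$, dimensionless
$b=0$) — so in vivo biology runs slower than in vitro by
$(23/2.63)^{-1/4} \approx 0.58$ on every rate. All first-order rate
constants are flagged allometric; the table is config-extensible.

**Numerics.** `deSolve::lsoda` with `rtol = 1e-8`, `atol = 1e-3`
cells; state floored at zero inside the derivative; a non-finite state
aborts with the offending parameter set in the message (consumed by the
factorial screening). A fixed-step RK4 oracle in the test suite agrees
with the adaptive solution to better than 0.1%. Xenograft scenarios
start "equilibrated": the tumor is grown untreated from $n_0/8$ to
$n_0$ and the resulting compartment composition (and vascular support)
is the day-0 state — an established 200 mm³ tumor is not a fresh
inoculum, and the treated-arm dynamics depend on that composition.

## The synthetic datasets

No tabulated measurements exist for the emulated experiments, so
`generate_spheroid_series()` and `generate_xenograft_series()` generate
them from the *published growth descriptors*, which are the only
quantitative ground truth:

* spheroid radius: 12.5 µm/day over days 0–20 from 150 µm, reaching
  400 µm, then a saturating approach to a 480 µm plateau; sampled every
  2 days; SD 8% of the design mean;
* xenograft volume from 200 mm³, twice-weekly for 4 weeks: +20 mm³/day
  (EGFR placebo, days 0–20), −16 mm³/day to a 40 mm³ plateau (EGFR +
  gefitinib, days 0–10), +7.5 mm³/day for *both* PIK3CA arms
  (identical by design — no treatment effect); SD 10% of the mean.

Observed means add seeded Gaussian noise of SD/4; seeds change the
noise only, never the design. The initial radius (150 µm), initial
volume (200 mm³), sampling grids, plateau shapes and noise levels are
declared design constants (echoed into every dataset header): the
figures they emulate cannot be digitized, so everything beyond the
printed slopes and plateau onsets is a package choice. Passing tests
against these data therefore demonstrate that the machinery recovers
*the printed behaviors under the declared noise model* — not that the
surrogate reproduces the original laboratory measurements.

## The shipped three-step plan

`calibrate_surrogate()` runs the end-to-end example:

1. **In vitro spheroid** (KRAS line): frees `k_div`, `k_q`, `k_n`,
   `k_lys`, `L_p`, `L_v` against the radius series, a loose
   viable-fraction rule (placeholder thresholds — the rim literature
   prints none) and the radius anchors. The baseline (pre-calibration)
   parameters deliberately under-predict the slope by about a third.
2. **In vivo untreated growth**: frees the vascular, immune and
   cell-line parameters (plus the weakly in-vitro-identified `L_v`,
   `k_n`, `k_lys`) against both placebo arms, keeping the spheroid
   constraints inside the objective.
3. **Treatment response**: frees the cytotoxic rate `k_apo`, the
   exposure `gef_conc_nM`, the clearance capacity `N_lys`, and re-frees
   `d_ang`, `a_ang`, `k_n`, `k_lys` against all four arms (treated arms
   now active), again with the earlier constraints in the objective;
   carry-over verification then re-checks steps 1–2. The cytostatic cap
   `I_max` stays at its default 0.95: at saturating exposure it is not
   separable from `k_apo` on volume data alone.

Splitting the in vivo work into growth-then-treatment keeps each CMA-ES
search small (7 dimensions each) and follows the least-connected-first
ordering guidance. The treatment landscape is multimodal — the shrink /
plateau trade-off has distinct basins — so that step first runs a
deterministic factorial prescreen over its most influential parameters
(`k_apo`, `d_ang`, `k_lys`, `N_lys`; the step's `prescreen` option) and
starts CMA-ES from the best coarse-grid row with a reduced initial
spread (15–20% of the interval width); a final restart polishes the
incumbent. Problem sizes are kept modest throughout — 16 spheroid
points, 9 points per arm, generation budgets of 100–120 with
populations of 10–11 — so a full calibration completes in minutes on
one core.

## Factorial screening

`factorial_design()` + `screen_design()` implement the pre-calibration
sweep: a full grid of equally spaced (log-spaced where appropriate)
levels per parameter is simulated; rows are classified `ok`,
`numerical_error` or `aberrant` (violating literature-derived binary
rules); the surviving rows' per-parameter min–max defines the reduced
search space (`apply_screen()`). The axis-aligned reduction is
deliberately conservative; 3 levels per parameter is the default.
Classification involves no randomness.

## Known limitations

* The surrogate is a five-phenomenon caricature: no intracellular
  pathway kinetics, no PK, no spatial resolution, no inter-animal
  variability. It is built to be *calibratable against the printed
  behaviors*, and nothing more.
* The treated-arm data (linear shrink, then a hard plateau) lie at the
  edge of what smooth first-order loss cascades can produce; the
  calibrated fit tracks the shrink rate and plateau level with partial
  credit on the transition's sharpness.
* Parameter identifiability is out of scope: a calibration returns one
  good parameter set, not a unique or uncertainty-quantified one.
* Binary scores make $f$ piecewise-constant along some directions;
  CMA-ES copes (it only ranks candidates), but plans should pair binary
  rules with continuous constraints when possible.
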