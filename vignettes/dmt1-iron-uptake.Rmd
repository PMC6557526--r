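---
title: "Modelling DMT1 cycling and the mucosal block of intestinal iron uptake"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling DMT1 cycling and the mucosal block of intestinal iron uptake}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ferroflux)
library(dplyr)
```

## The biological problem

Enterocytes take up dietary ferrous iron across their apical membrane through
the divalent metal transporter DMT1. Iron feeding triggers rapid
internalisation of DMT1 into vesicles, and this relocation is believed to
drive the *mucosal block*: a first iron dose substantially reduces the uptake
of a second dose given minutes later. ferroflux implements two
phenomenological state-cycle models of this process for polarized Caco-2
monolayers grown on bicameral inserts, together with everything needed to
confront them with two-challenge uptake data: simulation, jackknife
parameter estimation, corrected-AIC model comparison, local sensitivity
analysis, and a synthetic-data generator.

## The transporter cycle

Both models describe DMT1 as fractions $P_1,\dots,P_6$ of a conserved
transporter pool ($\sum_i P_i = 1$):

* $P_1$ — empty transporter, outward (apical) facing;
* $P_2$ — iron-bound, after binding apical Fe$^{2+}$ at rate
  $k_{12} P_1\,\mathrm{FeOUT}$;
* $P_3$ — occluded, inward-facing conformation ($k_{23}$);
* $P_4$ — empty, inward-facing, after releasing iron to the cell ($k_{34}$);
  $P_4 \leftrightarrow P_1$ is the only reversible step
  ($k_{41}$, $k_{14}$);
* $P_5$ (and $P_6$, swing model only) — endocyted transporter in vesicles.

Iron accumulates in a pooled intracellular + basolateral compartment of
volume $V_{cb}$:

$$\frac{d\,\mathrm{FeIN}}{dt} = k_{34}\,\mathrm{DMT1}_E\,P_3 +
  \gamma\,k_{\mathrm{rel}}\,\mathrm{DMT1}_E\,P_{\mathrm{ves}}, \qquad
\frac{d\,\mathrm{FeOUT}}{dt} = -\frac{V_{cb}}{V_a}
  \frac{d\,\mathrm{FeIN}}{dt},$$

where $\mathrm{DMT1}_E$ is the *effective* transporter amount (the unknown
absolute amount divided by a model-specific cycle effectiveness $\Phi$; only
ratios of $\Phi$ between models are identifiable, see
`effectiveness_ratio()`), and $\gamma = V_V/V_{cb}$ scales release from the
small vesicular volume $V_V$ into the large pooled compartment. The second
source term is vesicular release: $k_{\rm rel} = k_{54}$ acting on $P_5$ in
the switch model, $k_{64}$ acting on $P_6$ in the swing model.

The *switch model* makes endocytosis ($P_4 \to P_5$, rate
$k_{45}\,\mathrm{FeOUT}\,P_4$) and exocytosis ($P_5 \to P_4$, rate
$k_{54} P_5$) mutually exclusive hysteretic modes: the endocytic mode runs
until the endocyted fraction reaches $\alpha_{E}$, the exocytic mode until
the membrane fraction $P_1{+}P_2{+}P_3{+}P_4$ reaches $\alpha_{M}$. The
*swing model* instead couples $P_4, P_5, P_6$ through three competitive
autocatalytic reactions (a minimal Ball oscillator:
$\rho k_{45}\mathrm{FeOUT}\,P_4P_5$, $k_{56}P_5P_6$, $\rho k_{64}P_6P_4$),
so endocytosis and exocytosis co-occur and the transporter distribution
oscillates; sustained oscillation requires $P_5(0), P_6(0) > 0$.

The swing model's kinetic correction factor
$$\rho(t, j) = 1 - 2.8\,
  \frac{\mathrm{FeIN}(t) - 1.67\,\mathrm{FeUP}(j-1)}{\mathrm{FeIN}(t)}
  \cdot \frac{\mathrm{FeCHG}(j-1)}{\mathrm{FeCHG}(j)}$$
damps both trafficking rates as a function of the challenge history,
encoding the empirical observation that cumulative uptake after a second
dose is about 1.67-fold the first-dose uptake (a ~33% reduction). With
histories defined as zero before the first challenge, $\rho \equiv 1$
throughout challenge 1; just after a second identical challenge, where
$\mathrm{FeIN} = \mathrm{FeUP}$, it evaluates to
$1 - 2.8(1 - 1.67) = 2.876$ and then falls as iron accumulates.

### Reading the history term

The source text indexes the previous-uptake term ambiguously ("evaluated
just after the $j$th challenge" for an index of $j-1$). We resolve it by
recording FeIN at the *start of each challenge*: the term used while
simulating challenge $j$ is the value frozen at the start of challenge $j$,
i.e. the iron accumulated through challenge $j-1$. This is the only reading
under which $\rho = 1$ during the first challenge and $\rho(t_2^+) = 2.876$
for equal 20 uM challenges, both of which the package asserts in its tests.

## Geometry and units

All times are minutes, concentrations uM, volumes uL (so uM x uL = pmol;
1 um^3 = 1e-9 uL). `cell_geometry()` derives the enterocyte surface area
from a cylindrical cell ($A_E = 2\pi r h + 2\pi r^2 \approx 636.93$ um$^2$
at the reference 29.6 um x 6.2 um dimensions), the iron-releasing vesicle
volume $V_V = f\,R_V\,A_E$ (with $f = 0.01$, the lower bound of the
plausible 1–5% release-competent range and the value consistent with the
reference $V_V = 2.5\times10^{-10}$ uL), and $\gamma = V_V / V_{cb}$.
The monolayer volume `V_m` is carried for completeness but appears in no
model equation.

## Numerical choices

* **Integration.** `deSolve::lsoda` with `rtol = 1e-8`, `atol = 1e-10`
  defaults; the $P_1$ relaxation ($k_{14} \approx 11$–$31$ min$^{-1}$
  against a 15-min horizon) makes the system mildly stiff. The right-hand
  sides are compiled (C, `src/`), as is usual for deSolve models that sit
  inside optimisation loops — a jackknife fit evaluates the solver tens of
  thousands of times. The exported `switch_rhs()`/`swing_rhs()` are
  independent R implementations of the same equations, which the tests
  difference against compiled trajectories as an oracle. The apical
  concentration is *not* integrated: it is recovered from the exact
  within-challenge mass balance $V_a\,\mathrm{FeOUT} + V_{cb}\,\mathrm{FeIN}
  = \text{const}$, so iron conservation holds to machine precision and the
  redundant equation cannot drift.
* **Mode switching.** Switch-model transitions are located by root-finding
  (`lsodar`) on $P_5 - \alpha_E$ and
  $P_1{+}P_2{+}P_3{+}P_4 - \alpha_M$, then integration restarts in the
  flipped mode. Detecting crossings on output samples instead would
  mis-time switches on coarse grids and corrupt the cycling curves.
  Ties at exact threshold equality resolve toward switching. Thresholds are
  interpreted as fractions of total DMT1 (the tabulated values 0.9890 and
  0.9780 are dimensionless and below 1), with "membrane" meaning
  $P_1{+}P_2{+}P_3{+}P_4$.
* **Cold wash.** The inter-challenge ice wash is instantaneous: fractions
  and FeIN freeze, FeOUT resets to the new challenge concentration, and the
  switch model re-enters the endocytic mode (configurable via
  `reset_mode`, since the initialisation rule is only stated for the start
  of a simulation).
* **$\rho$ evaluation.** $\rho$ is computed continuously inside the
  right-hand side from the instantaneous FeIN, not frozen per step. It is
  not clamped by default — the expression is implemented literally and can
  in principle go negative, though it does not within 15-min windows at the
  reference parameters; `clamp_rho = TRUE` floors it at zero for
  explorations far from that regime.
* **Degenerate inputs.** $\rho$ at $\mathrm{FeIN} = 0$ is defined as 1
  during challenge 1 (the zero-history convention resolves the 0/0);
  for later challenges a zero FeIN cannot follow a completed challenge and
  raises an error.

## The inverse problem

Fitting minimises the mean squared error between model-predicted and
observed cumulative uptake with the Nelder-Mead simplex, run on
transformed parameters: log scale for rates and $\mathrm{DMT1}_E$
(positivity), logit scale for the switch thresholds (confinement to
$(0,1)$ — a plain log scale could push them above 1). Because the log-scale
starting values span some 26 natural-log units, the optimiser normalises
step sizes via `parscale`; simplex collapse on the narrow, curved valleys
of this 9–10 parameter problem is countered by fresh-simplex restarts from
the incumbent. Integration failures during simplex excursions (e.g. apical
depletion regimes) are scored as a large penalty rather than raised.

One caveat matters for anyone refitting these models: the few-point
objective of an oscillatory model is *rugged*. Mis-phased oscillations
create genuine local minima — profiling the objective between a stalled
fit and the generating parameters shows ridges several pmol² high — and
any purely local search (simplex or quasi-Newton alike) can converge
cleanly to a solution a few percent off in curve space. `fit_parameters()`
therefore offers a deterministic multistart (`n_starts`): log-normally
jittered copies of the initial guess are screened and the best basin
polished. In our synthetic-recovery experiments roughly a third of
jittered starts land in the generating basin, so a handful of starts
suffices; the jitter is seeded, keeping fits bit-reproducible.

`jackknife_fit()` then runs the leave-one-out loop: one fold per
observation (per-time-point triplicate means by default — five folds for
the standard first-challenge training window), each fold warm-started from
the full-data fit, the left-out point predicted, and `MSE_jk` aggregated as
the mean of squared leave-one-out errors (a raw-sum option exists).
Confidence half-widths use the jackknife standard error with a
$t_{0.975,\,n-1}$ quantile; p-values test $H_0{:}\ \theta = 0$ two-sided —
the conventional reading, since the source does not state the null. Only
first-challenge data are fitted; second-challenge data are reserved for
validation, and the mucosal-block magnitude (the 1.67 factor inside
$\rho$) is treated as a fixed literature value, not re-estimated.

With five mean observations against 9–10 parameters the fit is
deliberately under-determined: parameter point estimates are sloppy and the
package asserts *curve* recovery, not parameter recovery, on synthetic
data.

### Model comparison

`aicc()` implements the least-squares form
$\mathrm{AICc} = n\ln(\mathrm{mse}) + 2K + 2K(K{+}1)/(n{-}K{-}1)$. At
$n = 5$ means and $K = 9$–$10$ the correction is undefined
($n \le K + 1$), so `aicc()` raises an explicit error there and
`compare_models()` defaults to the replicate-level count ($n = 15$), where
the correction exists. Consequently the package asserts only the *ordering*
of the two models (the swing model wins on two-challenge data), never
printed criterion values.

## Sensitivity analysis

`local_sensitivity()` implements the normalized coefficient
$r_i = \frac{\partial \mathrm{FeIN}/\mathrm{FeIN}}{\partial\theta_i/\theta_i}$
by one-at-a-time ±10% perturbations, each differenced against the nominal
trajectory (forward differences — the +10% and −10% coefficients are
reported separately), and `classify_influence()` applies the four-way
scheme: negligible $|r^*|\le0.25$; low $0.25<|r^*|\le0.5$; regular
$0.5<|r^*|\le1$; high $|r^*|>1$. The output functional is FeIN at the end
of the first 15-min challenge — the end of the training window, the most
defensible choice since no evaluation time is stated in the source — and is
exposed as `eval_time`.

Two structural facts are worth knowing when reading these tables. First,
coefficients for $k_{12}$ and $\mathrm{DMT1}_E$ sit at $\approx 1$ robustly:
uptake is near-linear in both (the tiny deviation from 1 comes from apical
depletion feedback; `freeze_feout = TRUE` removes it and recovers exactly 1,
which the tests use as an analytic check). Second, at the reference
parameters the intermediate states $P_2, P_3$ relax within about
$1/k_{23} \approx 1$ min, after which the transport flux is controlled by
the binding step alone ($P_3 \propto 1/k_{34}$, so $k_{34}P_3$ is
invariant); coefficients for $k_{23}$ and $k_{34}$ evaluated anywhere
beyond the first minutes are therefore necessarily small (~0.01–0.03).
Published tables for this system that show $k_{23}, k_{34}$ coefficients
near 1 cannot be reproduced from these equations by the stated formula at
any single evaluation time we scanned (0.5–30 min, including the end of
the second challenge); the package reports what the equations give and its
regression tests pin only the robust rows.

## The synthetic-data generator

`generate_uptake_dataset()` emulates the reference radiotracer experiments
and stands in for their raw data: two sequential 15-min challenges at 20 uM
apical iron, cumulative uptake sampled at 3, 6, 9, 12, 15 min, triplicates,
uptake in the 0–20 pmol/insert range, and a second challenge reduced most
strongly at early times. Measurement noise is multiplicative Gaussian with
cv = 0.20 by default — a free choice calibrated by eye to the published
error bars, since no noise law or numeric spread is reported; replicate
draws are floored at zero and all randomness flows from one explicit seed.
What the generator does *not* emulate: replicate correlation within an
insert, day effects between experiments, counting statistics of the
radiotracer, or any misspecification between the generating model and the
biology — so tests passing on synthetic data demonstrate internal
consistency of the pipeline (simulation → noise → fitting → selection), not
correctness of either model for real Caco-2 monolayers. Noisy replicates
are deliberately not forced monotone in time; only noise-free means are.

Cumulative uptake converts as
$(\mathrm{FeIN}(t) - \mathrm{FeIN}(t_{\rm start}))\,V_{cb}$ (uM x uL =
pmol), pooling cells + basolateral medium exactly as the radioactivity
measurement does, and each challenge is baseline-subtracted, mirroring the
subtraction of first-challenge counts from second-challenge totals. Both
baseline-subtracted and cumulative-from-zero views are available from the
trajectory, since published uptake figures are ambiguous between them.

## Worked example

```{r example, eval = FALSE}
geom <- cell_geometry()
prot <- challenge_protocol()            # two 15-min 20 uM challenges

# simulate the swing model and summarise the mucosal block
traj <- run_protocol(swing_params(), geom, prot)
data <- generate_uptake_dataset(swing_params(), geom, prot, seed = 42)
mucosal_block_summary(data)
autoplot(traj, "uptake", data = data)
autoplot(traj, "fractions")

# sensitivity of end-of-challenge FeIN to each parameter
sensitivity_table(swing_params(), geom,
                  challenge_protocol(FeCHG = 20, duration = 15))
```

## Problem sizes used by the test-suite

The shipped tests integrate trajectories on grids of 31–151 points per
challenge, fit on five per-time means of a single challenge, and run
jackknife loops of five folds with warm starts; these sizes reproduce every
asserted property while keeping the whole suite comfortably runnable on a
laptop. The fits in the tests use reduced simplex budgets (hundreds of
iterations per round rather than the 5000-iteration production default)
because warm starts make larger budgets redundant there.

## Known limitations

* Parameter point estimates are non-identifiable by design of the
  experiment (5 observations, 9–10 parameters); only predicted curves and
  the ratio of model effectivenesses are meaningful.
* No proton coupling, pH dependence, basolateral efflux (ferroportin),
  Dcytb reduction, or transferrin dynamics: the models assume these are
  silenced by the experimental design, and the package does not extend to
  conditions where they are not.
* The switch-model sensitivity coefficients for the trafficking parameters
  ($k_{45}, k_{54}$ and the thresholds) depend on mode-switch timing at the
  evaluation instant and are intrinsically less stable than the transport
  parameters' coefficients.
* $\rho$ is a phenomenological damping term; nothing mechanistic (e.g.
  lysosomal degradation) is modelled.
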