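# ferroflux

Kinetic modelling of DMT1-mediated intestinal iron absorption and of the
*mucosal block* — the fast regulatory phenomenon by which a first iron dose
suppresses the uptake of a second one — in polarized Caco-2 cell monolayers.

Dietary Fe²⁺ enters enterocytes through the apical transporter DMT1, which
is itself endocyted upon iron feeding. ferroflux implements two
phenomenological models of this transporter cycle for users who study
transepithelial iron transport in the standard two-challenge insert
experiment (two sequential 15-min challenges at 20 µM apical iron, cumulative
uptake sampled at 3–15 min in triplicate):

* **Switch model** — a five-state DMT1 cycle in which endocytosis
  (P4 → P5, rate k₄₅·FeOUT) and exocytosis (P5 → P4, rate k₅₄) are mutually
  exclusive modes with hysteresis: the endocytic mode runs until the
  endocyted fraction reaches α_E, the exocytic mode until the membrane
  fraction P1+P2+P3+P4 reaches α_M.
* **Swing model** — a six-state cycle in which endocytosis and exocytosis
  co-occur, coupled through three competitive autocatalytic reactions
  (a minimal Ball oscillator on P4, P5, P6:
  ρk₄₅·FeOUT·P4·P5, k₅₆·P5·P6, ρk₆₄·P6·P4). The history-dependent kinetic
  correction factor

      ρ(t, j) = 1 − 2.8 · (FeIN(t) − 1.67·FeUP(j−1))/FeIN(t)
                       · FeCHG(j−1)/FeCHG(j)

  damps both trafficking rates after repeated challenges and encodes the
  observed ~33% mucosal-block reduction (the 1.67 factor). ρ ≡ 1 during the
  first challenge.

In both models iron accumulates in a pooled intracellular + basolateral
compartment: dFeIN/dt = k₃₄·DMT1_E·P3 + γ·k_rel·DMT1_E·P_ves, with the
apical pool balancing it exactly (dFeOUT/dt = −(V_cb/V_a)·dFeIN/dt). Around
the models the package provides the full analysis pipeline: multi-challenge
simulation with event-located mode switching, conversion to pmol/insert
uptake observables, jackknife (leave-one-out) Nelder-Mead fitting with
confidence intervals and p-values, AICc model comparison, normalized local
sensitivity analysis (±10% perturbations, negligible/low/regular/high
classification), and a seeded synthetic-data generator emulating the
triplicate radiotracer experiments.

## Worked example

```r
library(ferroflux)

geom <- cell_geometry()        # Caco-2 insert culture geometry
geom$A_E                       # 636.9265  (enterocyte area, um^2)
geom$V_V                       # 2.547706e-10  (iron-releasing vesicle volume, uL)

effectiveness_ratio(switch_params(), swing_params())
# 81.53374  -> the switch-model transport cycle is ~80-fold more effective

# simulate the two-challenge experiment with the swing model
prot <- challenge_protocol()   # 2 x 15 min at 20 uM, sampled 3,6,9,12,15 min
traj <- run_protocol(swing_params(), geom, prot)
uptake_series(traj, geom, challenge = 1, times = c(3, 6, 9, 12, 15))$uptake_pmol
# 7.085394  7.789033 10.138397 15.730992 16.152938   (pmol/insert)

# mucosal block: the second challenge takes up less, most strongly early
d <- generate_uptake_dataset(swing_params(), geom, prot,
                             noise = noise_model(cv = 0), seed = 1)
mucosal_block_summary(d)[c("time_min", "reduction_pct")]
#   time_min reduction_pct
# 1        3          70.1
# 2        6          68.0
# 3        9          49.9
# 4       12          64.5
# 5       15          47.1

# sensitivity of end-of-challenge FeIN to the iron-binding constant
local_sensitivity(swing_params(), geom,
                  challenge_protocol(FeCHG = 20, duration = 15),
                  parameter = "k12")
#    r_plus   r_minus
# 0.9992788 0.9994060     -> "high"-influence, near-linear parameter
```

The uptake numbers are cumulative pmol per insert (µM × µL); the reduction
percentages compare mean uptake between the first and second challenges at
each sampling time; sensitivity coefficients are the relative change in
predicted intracellular iron per relative change in the parameter.

Fitting and model comparison:

```r
fit_sw <- jackknife_fit(switch_params(), d, geom, prot)
fit_sg <- jackknife_fit(swing_params(), d, geom, prot)
glance(fit_sg)                  # MSE, MSE_jk, R^2
tidy(fit_sg)                    # estimates, CI half-widths, p-values
compare_models(fit_sw, fit_sg)  # lower-AICc model selected
```

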