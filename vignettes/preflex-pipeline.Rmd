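---
title: "Muscle preflex analysis: models, synthetic experiments, and statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Muscle preflex analysis: models, synthetic experiments, and statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

When a leg hits the ground, neural feedback cannot act for the first
~30 ms — sensorimotor delays are longer than that. Whatever stabilizes the
body in that window is the *preflex*: the zero-delay mechanical response of
the activated muscle–tendon system itself. This package implements a
complete computational pipeline for quantifying preflex mechanics:

1. **`hopper_sim`** — a single-leg vertical hopper driven by a Hill-type
   muscle–tendon unit (MTU) as knee extensor, hopped to a stable limit cycle
   and then perturbed by a 5 cm step-up, no step, or 5 cm step-down. The
   contractile-element (CE) kinematics of its stance phase are
   physiologically realistic boundary conditions for fiber experiments.
2. **`boundary_conditions`** — extraction of the CE lengthening profiles
   (10 kHz) and their 80× time-expanded *quasistatic* counterparts (1 kHz),
   in which velocity-dependent force contributions become negligible.
3. **`isolated_ce`** — the same Hill-model CE + parallel elastic element,
   detached from the tendon, replayed open-loop along those kinematics at
   constant activity (u = a, as in a chemically activated skinned fiber).
4. **`synthetic_fiber`** — a generative model of skinned-fiber recordings
   with the phenomenology the Hill model lacks (short-range stiffness and
   velocity-dependent "give"), used to emulate the full in vitro session.
5. **`preflex_analysis`** — work-loop analysis of the preflex window:
   mechanical work, short-range stiffness, post-SRS work, speed-condition
   differences.
6. **`stats_report`** — the nonparametric statistics chain
   (Shapiro–Wilk, Friedman, pairwise sign tests with Bonferroni, Cohen's d).

The numbered scripts under `analysis/` run these stages in order and write
their tables under `results/`.

# The muscle–tendon model

The MTU has four elements: contractile element (CE), parallel elastic
element (PEE), serial elastic element (SEE) and serial damping element
(SDE). **Sign convention: lengthening CE velocity is positive.** Much of
the Hill-model literature uses the opposite sign; every eccentric formula
below assumes lengthening-positive.

* **Force–length**: `F_isom(l) = exp(-|(l - 1)/dW|^nu)` with independent
  width/exponent per limb (`dW_asc = 0.45`, `nu_asc = 1.5`,
  `dW_des = 0.32`, `nu_des = 1.54`). `fit_force_length_ascending()`
  recovers `(dW_asc, nu_asc)` from measured points of the ascending limb by
  least squares, the same way the model would be matched to fiber data.
* **Force–velocity, concentric**: the classic Hill hyperbola through the
  isometric point with normalized parameters `A_rel`, `B_rel`; their
  activity and length scalings `(1 + 3a)/4` and `(3 + 4a)/7` can be
  disabled (`fv_act_dependence = FALSE`) for unit testing.
* **Force–velocity, eccentric**: the branch
  `F = F_max[(a F_isom + A_rel,e)/(1 - v/B_rel,e) - A_rel,e]` with
  `A_rel,e`, `B_rel,e` (both negative) derived internally from three
  conditions — continuity at v = 0, slope ratio `S_e = 2.0` between the
  eccentric and concentric slope at v = 0, and the plateau
  `F_e = 1.5` times the isometric force. The plateau is reached within a
  fraction of an optimal length per second, so at the 3–5 l_opt/s stretch
  velocities of the perturbed hopping impacts the model's eccentric force
  is essentially velocity-insensitive. That deliberate *absence* of
  short-range stiffness in the model is part of what the pipeline
  quantifies; no SRS extension is (or should be) added here.
* **PEE**: power-law spring engaged above `0.9 l_opt` (exponent 2.5).
* **SEE**: power-law toe region up to 4.25% strain, linear above, value- and
  slope-continuous at the transition.
* **SDE**: linear damper whose coefficient scales with the load on the
  contractile side, `d = d_SE_max[(1 - R_SE) f/F_max + R_SE]`.
* **Activation dynamics**: first-order lag `da/dt = (u - a)/tau` with
  `tau = 10 ms` and floor `a_min = 0.005`. A nonlinear calcium-kinetics
  form was considered and rejected: the isolated-CE pathway bypasses
  activation entirely (u = a), and the hopper only needs a smooth monotone
  rise, so extra unconstrained parameters would buy nothing.

**Contraction dynamics.** The CE velocity follows from the instantaneous
balance `F_CE + F_PEE = F_SEE + F_SDE`. On either Hill branch this is a
quadratic in the transformed velocity, solved in closed form
(`ce_velocity_closed_form`); the result is verified against the residual at
every call (accepted only below `1e-10 F_max`) with a bracketing
root-finder as fallback, and tested against an independent bisection oracle
to `1e-6 l_opt/s` on 1 000 random states.

# The hopper and its reconstructed parameters

Two equal massless segments (0.5 m) joined by a knee; point mass 80 kg at
the hip; MTU length affine in the knee angle with constant moment arm,
`l_MTU = l_MTU_ref + r (phi_ref - phi)`. The ground reaction force follows
by virtual work, `GRF = F_MTU · r · dphi/dy`, and stance integrates
`m ÿ = GRF - m g` together with the MTU state. During flight the knee is
locked at `phi_flight` and the CE relaxes toward its CE/SEE equilibrium
under the constant flight stimulation `u0 = 0.15`. After touchdown the
stimulation stays at `u0` for the 30 ms preflex and then ramps with slope
`b = 10 s⁻¹`, saturating at 1.

The exact source-model constants are not tabulated in the main text we
reimplement, so the defaults here are **reconstructions**, chosen once so
that the simulation reproduces the printed boundary conditions and then
frozen: `F_max = 30 kN`, `B_rel0 = 3.0 s⁻¹`, `r = 0.07 m`,
`l_opt = 0.1 m`, `l_SEE0 = 0.4 m`, `phi_ref = phi_flight = 2.0 rad`.
`l_MTU_ref` is not free: `flight_equilibrium_l_mtu()` inverts the flight
CE/SEE equilibrium so that the CE sits at `0.56 l_opt` at touchdown, the
operating point the analysis expects. With these values the limit cycle
(apex return-map iteration to `1e-4 m`) settles at an apex 0.171 m above
contact, and the three scenarios give touchdown speeds 1.54/1.83/2.08 m/s
and peak preflex CE velocities 3.47/4.10/4.64 l_opt/s — inside the 3–5
l_opt/s band the in vitro protocol was designed around. These are model
properties verified by `analysis/01` and the test suite, not inputs.

Numerical choices: stiff-capable `lsodar` with `rtol 1e-8 / atol 1e-10`;
touchdown, toe-off (first downward GRF zero crossing) and apex located by
integrator root-finding; a work integral is carried in the stance state so
the work–energy audit `|Δ(KE+PE) - ∫GRF·ẏ dt| < 1e-6 J` is checked by
quadrature of the integrator itself rather than by post-hoc trapezoids.
Degenerate-case policy: stance shorter than 30 ms truncates the preflex
window with an explicit flag and warning.

# Quasistatic construction

`make_quasistatic()` expands the time base of a lengthening profile by 80
while keeping the *sequence of lengths identical*, so every path integral
(total stretch, force–length work at matched samples) is invariant and
velocities scale down exactly by the factor. With `fs = NULL` the mapping
is exact sample-for-sample (the dynamic/quasistatic peak-velocity ratio is
exactly 80, by construction); with `fs = 1000` the result is resampled at
the quasistatic recording rate through a cubic spline on length with
analytic differentiation for velocity. The expansion is applied to the
whole stance lengthening profile, not just the preflex, so the
matched-length analysis rule below can always find its endpoint.

# The synthetic fiber generator

The generator is deliberately **not** the Hill model — its purpose is to
emulate what real skinned fibers do and the model does not. Noiseless
force in units of the fiber's current maximal force:

    F = a·F_isom(l)                          isometric operating force
      + kappa·a·phi(v_pk)·min(s, delta)      short-range stiffness ramp
      + k_post·a·(s - delta)+                post-SRS elastic trend
      + c·a·v/(v_c + v)  for s > delta       post-SRS viscous adaptation

with `s = (l - 0.57)+` the stretch past force onset, `delta = 0.02 l_opt`
(the 0.57–0.59 window), and the trial-level velocity factor
`phi(v_pk) = 1 + beta·v_pk²/(v_sat² + v_pk²)`, `v_sat = 0.4 l_opt/s`. The
sigmoidal (quadratic) form keeps the SRS flat *within* the dynamic band
(3–5 l_opt/s) and *within* the quasistatic band (~0.04–0.06 l_opt/s) while
separating the two bands by nearly the full factor `1 + beta` — matching
reports that SRS varies between stretch speeds orders of magnitude apart
but not inside either regime. A linear saturation `v/(v_sat + v)` was
tried first and rejected: its low-speed slope turns the small systematic
velocity spread between perturbations into a spurious SRS effect that a
rank test detects.

Sessions emulate the in vitro protocol: 9 fibers; per fiber one *block*
per perturbation × speed condition holding the three activities in
randomized order; block order randomized; every block bracketed by
isometric reference contractions at optimal length and full activity
(adjacent blocks share the reference between them); every activation
advances a geometric degradation factor `rho = 0.995`. Reference traces
rise exponentially (`tau = 0.3 s`, 3 s duration) so the plateau criterion
— force rise below 1% within the final 1.5 s — holds at the trace end.

Heterogeneity and noise: per-fiber `F_max`, `l_opt` and gains are
log-normal with CV 15% (which is what makes fiber-blocked rank statistics
meaningful); per-trial multiplicative gain jitter CV 3%; white measurement
noise `sigma = 0.01 F_max`; and a per-trial baseline offset
`sigma_base = 0.043 F_max` representing transducer baseline drift between
activations. `sigma_base` is the one deliberately *calibrated* constant:
it was set by mapping the Friedman-test operating curve of the full
pipeline by simulation so that the perturbation effect on preflex work is
detected at activities 0.15 and 0.25 but not at 0.05 in the large majority
of seeds, then frozen. With n = 9 and effects proportional to activity
(1:3:5), those two requirements pull against each other; the chosen value
maximizes the joint margin (rejection rates near 0.18/0.88/1.0), which is
the attainable frontier of this design rather than a comfortable interior
point. What passing tests show, therefore, is that the *pattern* is
reproducible under the stated conditions — not that real recordings have
this noise structure. The generator also does not emulate: sarcomere-level
force transients, history dependence (residual force enhancement),
temperature effects, or pCa-to-activity chemistry.

# Analysis rules

* **Normalization** (`normalize_trial`): force divided by the
  degradation-corrected maximal force — linear interpolation between the
  bracketing reference plateaus at the trial's position in the block (the
  j-th of k trials sits at fraction j/(k+1)); length divided by the
  fiber's optimal length.
* **Window** (`preflex_window`): dynamic trials → first 30 ms; quasistatic
  trials → from start until the length first reaches the end-of-preflex
  length of the *matching dynamic condition* (same fiber, scenario,
  activity), with linear interpolation to the exact boundary so windows
  are bit-comparable across conditions.
* **Work** (`mechanical_work`): trapezoidal integral of normalized force
  over normalized length; positive when the fiber resists lengthening.
  Exact for piecewise-linear profiles (tested at 1e-12).
* **SRS** (`srs_stiffness`): OLS slope of force vs length restricted to
  0.57–0.59 l_opt. The window is fixed in absolute normalized length
  because the onset values are approximate in the source; an onset
  detector (`force_onset_length`, threshold 0.005 above baseline) is
  provided as the alternative.
* **Post-SRS work** (`post_srs_work`): trapezoidal work from 0.59 l_opt to
  a *common end length* — the step-up condition's end-of-preflex length —
  so stretch extent (and with it the elastic contribution) is equal across
  perturbations and only velocity-dependent differences remain.
* **Speed difference** (`work_difference`): dynamic minus quasistatic work
  on matched-length windows, with condition-label checking.

# Statistics

The chain mirrors the nonparametric decision flow: Shapiro–Wilk screen,
then a Friedman test (blocks = fibers) across the three perturbations
within each activity × speed condition for each metric; pairwise exact
sign tests as post hoc with Bonferroni correction over the three pairs
(Wilcoxon signed-rank available as an alternative); paired exact sign
tests for dynamic vs quasistatic; Cohen's d with the small/medium/large
cut-offs at 0.3 and 0.5. The Friedman statistic is implemented in-package
with midranks and the standard tie correction,
`chi² = (k-1)·SS_treatment/SS_total` on ranks; it is validated
exhaustively against `stats::friedman.test` over all 4×3 row-multisets
with entries in {1,2,3} and its type-I error is checked at 5% ± 2% over
2 000 null replicates. Sign-test p-values are exact binomial (two-sided,
ties dropped) for all n used here.

# Problem sizes and runtime

The default pipeline uses: limit cycle to `1e-4 m` apex tolerance
(~10 cycles), three scenario strides at 10 kHz output, 162 perturbation
trials + 63 references per session, and 20-seed replication for the
stochastic end-to-end checks. On one CPU the boundary-condition stage
takes well under a minute, a full session with analysis a few seconds, and
the entire test suite a few minutes.

# Known limitations

* The hopper is 1-DOF vertical with a constant moment arm and massless
  segments; no swing leg, no forward motion, no reflex feedback after the
  preflex window.
* All hopper constants are reconstructions constrained only by the printed
  boundary conditions; absolute forces and works are therefore in
  normalized units throughout the analysis, which is also why the analysis
  never needs the simulation and fiber scales to match.
* The generator's parameters are inventions tuned to a reported
  phenomenology; parameter recovery tests show the analysis recovers the
  generator's truth, which validates the analysis, not the generator.
* Because the generator's SRS ramp contribution persists additively after
  the SRS region, the dynamic preflex work exceeds the quasistatic work
  systematically; real fibers show nearly identical amounts. The speed-comparison sign tests therefore flag work differences
  the in vitro study did not, and conclusions about the dynamic-minus-
  quasistatic contrast should be read against the generator definition,
  not as a biological prediction.
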