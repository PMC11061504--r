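---
title: "Methods: muscle model, tracking OCP, and the feasibility campaign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: muscle model, tracking OCP, and the feasibility campaign}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`hillmc` asks a model-identification question: when a person deconditions
(bed rest, spaceflight), which parameters of a Hill-type muscle model must
be adjusted so that simulations can still reproduce the measured
post-unloading knee moments? The package answers it by tracking isokinetic
knee-extension moment profiles with an optimal control problem (OCP),
perturbing grouped muscle parameters by Monte Carlo, classifying each
perturbation as feasible or infeasible, and regressing feasibility on the
perturbations. This vignette documents the model, every tunable parameter,
and the numerical design choices, in enough detail to reproduce or
challenge them.

## 1. Muscle-tendon unit model

Each muscle-tendon unit (MTU) is a contractile element with parallel
elasticity, in series with a nonlinear tendon spring, oriented by a
pennation angle under the constant-thickness assumption
(`l_m sin α = l_opt sin α_opt`). States are the activation `a ∈ [0, 1]`
and the normalized tendon force `F̃_t = F_t / F_max`; their time
derivatives are the controls. Given the MTU length (from the joint
kinematics) and `F̃_t`, the tendon strain, tendon length, fiber length and
pennation follow algebraically, and the Hill equilibrium

```
F̃_t = ( a · f_act(l̃) · f_v(ṽ) + f_pas(l̃) ) · cos α
```

is enforced as a path constraint. The fiber velocity `ṽ` is obtained from
the tendon-force rate by the chain rule through the inverted tendon curve,
which is what makes `F̃_t` a well-behaved state for collocation.

**Characteristic curves.** The source analysis cites a published
tendon-force-state formulation without printing coefficients; we adopt the
De Groote et al. (2016) curves and surface all coefficients via
`hill_curve_constants()`:

* active force–length: sum of three Gaussians, maximum ≈ 1 at `l̃ = 1`,
  negligible outside roughly `[0.4, 1.8]`;
* passive force–length: exponential with shape 4, normalized to 1 at the
  strain limit 0.6 (i.e. `l̃ = 1.6`), slightly negative below `l̃ = 1`
  (|value| ≤ 0.02);
* force–velocity: arsinh (logarithmic) form, 1 at `ṽ = 0`, ~0.01 at
  maximal shortening `ṽ = −1`, eccentric plateau ≤ 1.8 on `[−1, 1]`;
* tendon: `f_t(ε) = e^{−0.04 k_t}(e^{k_t ε} − 1)`. This offset-exponential
  is calibrated so that force is exactly zero at zero strain and the slope
  at 4% strain equals `k_t` *identically* — the one curve constraint the
  source framework states (baseline `k_t = 35`). Perturbing `k_t`
  (tendon-compliance perturbation) automatically re-calibrates the offset,
  preserving both identities.

**Per-MTU parameters** (`mtu_parameters()`): maximum isometric force
`F_max` (N), optimal fiber length `l_opt` (m), pennation at optimal length
`α_opt` (rad), maximum shortening velocity `v_max` (m/s; baseline
`10·l_opt` per second), tendon stiffness shape `k_t` (dimensionless),
tendon slack length (m; never perturbed — no documented unloading
adaptation), and the MTU's fraction of total muscle volume `PV_j` (used to
weight the effort cost). `F_max` is scaled from volume as
`σ·V/l_opt` with specific tension `σ = 60 N/cm²` (deliberately high, as in
the source framework; it cancels out of the perturbation analysis).

**Activation dynamics** are first-order with activation and deactivation
time constants `t_a = 0.015 s`, `t_d = 0.06 s`, imposed as the two
inequality bounds `−a/t_d ≤ ȧ ≤ (1 − a)/t_a`.

## 2. The synthetic limb model

`build_default_model()` generates a deterministic-given-seed stand-in for
a scaled musculoskeletal model: 40 MTUs (4 knee extensors, 8 knee flexors,
28 hip/ankle muscles), three actuated coordinates (hip flexion fixed at
60°, knee flexion moving over 0–90°, ankle fixed neutral). MTU lengths are
additive polynomials of the joint angles; moment arms are their angle
gradients and MTU velocities follow by the chain rule.

**Sign convention.** The knee coordinate is the flexion angle; the
extension motion runs 90°→0° so the coordinate velocity is negative. Knee
moment arms are reported extension-positive: `r = ∂l/∂θ_flex`, so an
extensor (`r > 0`) *shortens* during the extension motion (concentric, as
in the real task) and contributes `r·F > 0` to the net extension moment.
Muscles with mean knee arm above +1 mm are classified extensors, below
−1 mm flexors, otherwise non-knee; grouping depends only on geometry.

The generator targets the operating ranges that make the physics of the
problem come out right and that are asserted by tests: extensor fibers on
the ascending limb/plateau over the motion (normalized length ~0.65 at
full extension to ~1.1 at 90° flexion, at slack tendon), flexors on the
plateau/descending limb (~1.1–1.2 at full extension), non-knee muscles
near optimal at the posture, all within `[0.4, 1.6]` at baseline.
Moment-arm magnitudes: extensors ~2–5 cm, flexors ~2–3.5 cm, non-knee
±2.5–5.5 cm with alternating signs and a mild systematic imbalance (so
uniform passive-force increases do not cancel out of the hip/ankle moment
balance). Volumes: extensors 380–520 cm³, flexors 150–260 cm³, non-knee
80–220 cm³; volume fractions normalized to sum to 1. These are *synthetic,
labelled* ranges chosen once to be physiologically plausible — not fitted
polynomials from any real model.

What the generator deliberately does *not* emulate: rigid-body dynamics,
patellofemoral mechanics, biarticular coupling (knee muscles span only the
knee), gravity-corrected dynamometry, EMG. A green test therefore
establishes that the *pipeline* behaves as specified on a world with the
stated structure; it does not reproduce the source study's numeric tables,
whose reference data and OpenSim model are not public.

## 3. Reference profiles and the recovery oracle

Reference knee moments are assembled the way the source data were: a
normative angle profile tabulated at 10° intervals is expressed as
fractions of its 30°-flexion value, multiplied by a measured anchor moment
at 30° flexion, and interpolated — here with a monotone (Fritsch–Carlson)
cubic so a moment profile never overshoots its knots. `default_scenario()`
provides synthetic anchors (pre ~190–230 N·m at 30°/s; post reduced by
32–42%; 180°/s anchors ~0.68–0.78 of the 30°/s ones) with a bell-shaped
profile peaking at 60–70° flexion.

Because the real anchors are unavailable, all quantitative acceptance
work uses `oracle_post_reference()`: apply a *known* perturbation `p*` to
the model, fix group activations (defaults: extensors 0.9, flexors 0.05,
non-knee 0.1), solve the quasi-static Hill equilibrium (zero tendon-force
rate) pointwise by scalar root-finding, and use the resulting net knee
moment as the reference. By construction this reference is attainable by
the perturbed model, so `p*` lies inside the feasible set — which converts
"does the campaign recover the truth?" into a testable property.

## 4. The tracking OCP

Legendre–Gauss–Radau collocation: the motion is split into equal mesh
intervals (production default 50; campaign runs use 5 and a refinement
test shows the tracking objective changes < 1% when the mesh doubles);
states are degree-3 interval polynomials through the interval start plus
three flipped-Radau points (the right endpoint included, which gives exact
interval continuity by construction in the solver and explicit continuity
constraints in the transcription). The cost is

```
J = Σ_j PV_j ∫ a_j² dt                (effort)
  + w_reserve Σ_i ∫ τ̃_i² dt          (reserves, scaled by the ±25 N m bound)
  + w_control Σ_j ∫ (scaled ȧ_j)² + (scaled dF̃_t,j/dt)² dt
```

subject to collocation dynamics, continuity, Hill equilibrium per MTU per
collocation point, moment balance per coordinate per collocation point
(the knee tracks the reference; hip and ankle balance zero, each with its
own bounded reserve), activation-rate inequalities, and variable bounds —
all variables affinely scaled to ±1. Tracking is a hard path constraint,
not a cost term.

**Weights.** `w_control = 0.01` on the scaled rates is pure
regularization. `w_reserve = 10` (not 1) is a deliberate choice: with
quadratic costs the marginal price of the first N·m of reserve is zero, so
a cheap reserve lets the optimizer shed a roughly constant ~2 N·m of knee
moment into the reserve everywhere. That constant is invisible at the
moment peak but is several percent of the reference near full extension —
exactly where the 9% feasibility rule is evaluated — so a low reserve
weight makes the classifier measure cost-shedding instead of muscular
capacity. With `w_reserve = 10` the ground-truth perturbation tracks its
own reference with a peak reserve well under 1% and the classifier
responds to capacity.

**Solver.** No interior-point NLP solver exists in the target environment,
so `solve_tracking_ocp()` works in a reduced space: the normalized tendon
forces on the state grid (plus initial activations) are the only free
variables. Controls follow from the differentiation matrix, activations
from the Hill identity, reserves from the moment-balance equality — so
every equality constraint holds to machine precision by construction
(verified independently by evaluating the full `transcribe()` constraint
vector on the packed solution). The remaining inequalities (activation
bounds, rate bounds, reserve bounds) are handled by an augmented
Lagrangian around L-BFGS-B with a hand-derived analytic gradient
(finite-difference-verified in the tests). Defaults: constraint tolerance
1e-3 on the scaled inequalities ("converged" status requires this; a 1e-3
violation of a scaled bound is physically immaterial, and 1e-6 is
attainable at ~4× the iteration budget), iteration cap 3000, up to 12
outer multiplier updates with a ×10 penalty ramp when violations stall.
The initial guess is a vectorized quasi-static warm start (bisection for
the tendon forces at fixed group activations, with a coarse line search
over the extensor activation level); a flat mid-range guess
(`a = 0.1`, `F̃_t = 0.2`) remains available via
`ocp_settings(init_method = "flat")`. Both are deterministic, so solves
are reproducible bit-for-bit.

**Degenerate inputs.** Solver failures (including an unattainable
reference, where the reserve is driven to/beyond its ±25 N·m bound) return
`status = "failed"` with full diagnostics — failures are data, because
infeasible draws are the object of study. The implied fiber length is
floored at a tiny positive value (with zero gradient) purely as an
arithmetic guard; the synthetic model's geometry keeps it inactive.

## 5. Feasibility rule and the Monte Carlo campaign

A draw is **feasible** iff the solve converged *and* at every collocation
time `|τ_res,knee(t)| ≤ 9% · |M_ref(t)|`, with a 1 N·m floor on `|M_ref|`
guarding the percentage where the reference approaches zero near full
extension. The 9% threshold mirrors dynamometer test-retest reliability;
the rule is applied to the knee reserve only, while all three coordinates
carry reserves in the cost (reconciling a six-term reserve cost with a
knee-specific feasibility text).

The campaign draws the 15 grouped percentages i.i.d. uniform within the
unloading bounds (MIF 40–100, OFL 60–100, OPA 75–100, MSV 50–200, TC
40–100, % of baseline), expands them so every MTU in a group gets the same
five percentages (15 inputs → 200 per-MTU slots at 40 MTUs), solves,
classifies, and appends one record per draw. Per-draw seeds derive from
the campaign seed by a counter-based scheme, so records are independent of
execution order. Convergence of a campaign is declared when, for each of
the 15 parameters among feasible records, the mean and coefficient of
variation of the final 10% of records are within 2% (relative) of the
overall values; population (not sample) moments are used so that a tail
replicating the overall distribution passes exactly regardless of window
size. Note the rule's sampling error: the CV of a 500-record window
fluctuates by about 2% on its own, so small campaigns legitimately report
"not converged".

## 6. Analysis stage

Perturbations are centred (`x = p − 100`) so regression coefficients are
log-odds per 1% perturbation. Descriptives per class and parameter:
median, IQR (linear-interpolation quartiles), percentile-bootstrap 95% CI
of the median (2000 resamples; the CI method is a package choice — the
source tables do not state one), min, max. Kernel densities are Gaussian
with Silverman's rule-of-thumb bandwidth and a bandwidth floor for
zero-variance input.

Stepwise logistic regression: forward selection over the 15 main effects
and all 105 pairwise interaction products (an interaction is admissible
only once both parents are selected; switchable), adding at each step the
candidate with the largest increase in McFadden's adjusted pseudo-R²
`1 − (ℓ − k)/ℓ₀` and stopping below an increase of 2.5 *percentage
points* (the "2.5%" threshold read as absolute, the interpretation under
which it is actually usable as a stopping rule). Ties break by candidate
order (mains first, in group-by-parameter order). Coefficients are
reported as odds ratios with Wald 99% CIs on the log scale; a term is
significant when its CI excludes 1. Possible separation is flagged, with
coefficients still reported under a warning.

## 7. Known limitations

* The solver is a first-order reduced-space method: accurate and fast at
  desk scale, but without second-order convergence guarantees; very tight
  feasibility margins (within ~1% of the 9% line) can classify either way
  at low iteration budgets.
* The feasibility floor for flexor OFL is scenario-dependent, and near it
  feasibility couples to flexor MIF (weaker flexors carry proportionally
  weaker passive moments). Tests therefore assert the *existence and
  direction* of the floor, not a specific percentage.
* Knee muscles are monoarticular in the synthetic model; biarticular
  load-sharing (rectus femoris, hamstrings at the hip) is absent, which
  likely makes the non-knee group less influential here than in the
  source study.
* The campaign convergence diagnostic needs large n (tens of thousands)
  before its 2% tolerance is inside sampling noise; treat it as a
  diagnostic, not a stopping rule, at desk scale.
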