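---
title: "Predictive haemodynamics of coronary bypass graft configurations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predictive haemodynamics of coronary bypass graft configurations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graftflow)
```

## The problem

When a surgeon revascularises triple-vessel coronary disease with arterial
conduits only (both internal mammary arteries and a radial artery), the
*configuration* of the grafts — separate aorto-coronary grafts versus
composite Y-grafts, sequential grafts with two coronary touchdowns, or a
jump graft off a native vessel — decides how the limited conduit inflow is
shared between the three coronary territories. A graft sewn onto a vessel
whose native stenosis is not flow-limiting competes with native flow and
tends to fail ("flow competition" or "steal"). `graftflow` simulates the
pressure and flow fields of a patient's coronary circulation under each of
twelve standard total-arterial configurations (A–L) and derives the
functional numbers used to judge them: the resting instantaneous wave-free
ratio (iFR) per stenosed vessel, an FFR equivalent, transit-time-flowmetry
indices per graft — mean graft flow (MGF), pulsatility index (PI),
diastolic filling (DF) and backward flow (BF) — and regional myocardial
perfusion. Each configuration is classified as *unsatisfactory*,
*satisfactory* or *ideal*, and the package also provides the
contingency-table statistics used to compare selection strategies across a
cohort.

## The model

### 1D vessels

Each vessel segment is a 1D compliant tube with linearly tapered reference
radius. The state is cross-sectional area $A(x,t)$ and volumetric flow
$Q(x,t)$:

$$\partial_t A + \partial_x Q = 0, \qquad
  \partial_t Q + \partial_x\!\left(\frac{Q^2}{A}\right)
  + \frac{A}{\rho}\,\partial_x p = -\,2(\zeta+2)\pi \frac{\mu}{\rho}\frac{Q}{A},$$

closed by the algebraic tube law

$$p = p_\mathrm{ref} + \frac{\beta}{A_0(x)}\left(\sqrt{A}-\sqrt{A_0(x)}\right)
      + p_\mathrm{ext}(t),$$

with wave speed $c^2 = \beta\sqrt{A}/(2\rho A_0)$. Segment stiffness
$\beta$ defaults to the value giving a 900 cm/s pulse-wave speed at the
mean radius for native coronaries (1100 cm/s for mammary conduits, 1300
cm/s for the stiffer radial artery). The reference pressure
$p_\mathrm{ref}$ defaults to the mean aortic pressure, so imaging-derived
radii are interpreted as radii at physiological distension.

The friction closure uses velocity-profile order $\zeta = 2$ (parabolic).
Coronary vessels are 2–4 mm in calibre with low Womersley number, so the
quasi-steady Poiseuille profile is the appropriate closure there — and it
makes the solver's low-Reynolds steady limit agree exactly with
Poiseuille's law, which the test suite exploits as an oracle. The flat-ish
profiles ($\zeta \approx 9$) used for large systemic arteries are
available through `solver_config(zeta = ...)`.

### Numerical scheme

The interior update is the Richtmyer two-step (predictor at cell
interfaces, corrector at nodes), second-order in space and time on smooth
solutions, with default mesh spacing 0.1 cm and time step $2.95\times
10^{-5}$ s (the largest stable step on these meshes with a safety margin).
Two discretisation choices matter and are deliberate:

* **Non-conservative pressure gradient.** The $({A}/{\rho})\partial_x p$
  term is discretised from nodal/half-step pressures rather than folded
  into a conservative flux. On a tapered vessel a spatially uniform
  pressure is then an *exact* discrete equilibrium. The conservative
  pressure-flux form is not exactly balanced on tapers; its residual
  scales with the (very large) absolute flux and rectifies into a
  spurious mean pressure gradient under pulsatile flow.
* **Conservative half-cell boundaries.** Each segment end owns a half
  cell whose mass balance links the boundary flux to the predictor flux
  at the first interior interface. The coupling conditions (below) are
  solved for the boundary fluxes themselves, so mass telescopes exactly
  from every inflow to every terminal: cyclic volume closure is at
  round-off, not at truncation, and a 1–1 junction of identical segments
  reduces algebraically to the interior corrector (it is transparent).

Couplings close the half-cell systems:

* **Inflows** prescribe the aortic pressure waveform (every inflow — the
  coronary ostia, the subclavian origins of in-situ mammary grafts, and
  aortic conduit origins — sees the same generic root waveform).
* **Junctions** of $N$ segment ends enforce static-pressure continuity
  and exact mass balance (Newton on the $N$ end fluxes). Static rather
  than total pressure: it is the standard simple choice, and junction
  losses are deliberately not modelled — the package studies flow
  competition, not anastomotic technique.
* **Lumped stenoses** are internal interfaces splitting their host
  segment, with flux continuity and the pressure jump
  $\Delta p = K_v \mu Q / D_0^3 + K_t \tfrac{\rho}{2A_0^2}(A_0/A_s-1)^2
  Q|Q| + K_u \rho \tfrac{L_s}{A_0}\dot Q$,
  where $A_s$ follows from the percent *diameter* reduction and the
  viscous coefficient defaults to the length-scaled
  $K_v = 32 (L_s/D_0)(A_0/A_s)^2$, with $K_t = 1.52$, $K_u = 1.2$.
  A 100% stenosis is rejected (model an occlusion instead).
* **Terminals** are three-element Windkessel (RCR) models advanced by
  backward Euler, with intramyocardial coupling
  $$C\,\frac{dP_c}{dt} = Q_\mathrm{in} - \frac{P_c - P_\mathrm{im}}{R_2}
    + C\,\frac{dP_\mathrm{im}}{dt}, \qquad
    p = P_c + Q_\mathrm{in} R_1,$$
  where $P_\mathrm{im} = \gamma_\mathrm{im} P_\mathrm{LV}(t)$. The
  $dP_\mathrm{im}/dt$ term expresses that the terminal stores volume
  against *transmural* pressure: ventricular contraction squeezes the
  intramural bed and produces the diastolic-dominant coronary inflow
  signature (diastolic filling fraction above 50% for left-territory
  terminals). The term averages to zero over a cycle, so it leaves the
  mean operating point — and hence calibration — untouched. Defaults
  $\gamma_\mathrm{im}$: 0.75 for LAD/CIRC terminals, 0.5 for
  RCA-territory terminals (the inferior wall sees less cavity pressure),
  0 for systemic ones.

Whole cardiac cycles are run until the cycle-to-cycle relative L2 change
of all terminal flows falls below $10^{-3}$ (at most 20 cycles; runs that
do not converge are flagged, never silently accepted).

### Boundary data

The aortic template is a sinusoidal systolic arc with an explicit
dicrotic-notch dip and an exponential diastolic decay, rescaled exactly to
the requested systolic/diastolic pressures (default 120/77 mmHg at 65
bpm). The default period is $60/65 = 0.9231$ s; a rounded 0.917 s can be
requested explicitly. The LV template is a squared half-sine synchronised
with aortic ejection over a 2 mmHg baseline. Both are plain sampled
waveforms, so measured curves can be substituted at any inflow.

### Calibration

Terminal resistances are calibrated on the healthy network: 4.5% of a 5
L/min cardiac output is assigned to the myocardium and split 40/30/30
between the LAD, CIRC and RCA territories. Within a territory, target
flow is allocated **uniformly per outlet**: side branches are evenly
spaced, so this approximates uniform perfusion per unit of supplied
myocardium. (Murray-type $r^3$ weighting was considered and rejected: the
stand-in tip radii are not meaningful calibres and it funnels about half
of a territory's flow through the single most distal outlet, which
produces unphysiologically large distal pressure drops.) $R_1$ is pinned
to the characteristic impedance of the attached segment, capped at 20% of
the total, to minimise non-physiological terminal reflection; $R_2$
absorbs the remainder. Compliances share the coronary fraction of the
1.15 ml/mmHg total arterial compliance in proportion to target flow.
Calibration iterates against the steady-state (0D Poiseuille network)
solver to 0.5%, then applies one linear trim against a periodic pulsatile
solve — the steady oracle cannot see the small convective (Bernoulli)
losses of pulsatile flow through tapers and branch take-offs, and the
single trim absorbs them. Re-running calibration changes resistances by
well under 0.5% (it is idempotent to tolerance).

## Graft configurations

`apply_configuration(net, "A")` … `"L"` performs explicit network
surgery: conduit segments are created with their default calibres (IMA
2.0 mm; radial 2.7 mm; LIMA 17 cm, RIMA 19 cm or 21 cm via the transverse
sinus), attached at their origin (subclavian inflow, aortic inflow, a
Y-origin 10 cm along a parent conduit, an end-to-end I-extension, or a
take-off from the distal LAD for the jump graft), and anastomosed
end-to-side or side-to-side at the LAD/OM/PDA target markers. Sequential
grafts produce a four-ended junction at the first touchdown. Native
stenoses are never altered — grafts bypass, never replace — and the
distal runoff of every target is preserved. Category (aortic/anaortic)
and inflow counts are *derived from the built graph*, not looked up:
`graft_category()` inspects conduit origins, `inflow_count()` counts
pressure sources feeding graft segments. MGF and PI are measured at the
distal end of each graft, i.e. on the conduit piece arriving at its
touchdown; for a sequential graft the reading at the first touchdown
therefore includes the flow continuing to the second target, exactly as a
transit-time probe on that conduit piece would read.

## Functional metrics and classification

The wave-free window runs from 25% into diastole (dicrotic notch to the
diastolic pressure minimum) until 5 ms before end-diastole; the notch is
detected as the first local pressure minimum after the systolic peak, so
the definition is independent of cycle phase. iFR is the ratio of
window-mean distal to aortic pressure, measured just distal to each
lesion; with serial lesions this yields per-lesion readings (the proximal
lesion is assessed between the lesions), as serial disease is reported
clinically. The FFR equivalent is the fixed affine conversion
$\mathrm{FFR} = 0.68\,\mathrm{iFR} + 0.18$.

A configuration is **unsatisfactory** if any graft has MGF < 15 ml/min or
PI > 5; otherwise **ideal** if every left-sided graft (LAD or OM target)
has PI < 3, right-sided grafts needing only PI < 5; otherwise
**satisfactory**. The side-specific ideal threshold reflects the higher
pulsatility tolerated in grafts to the right territory; applied to the
published 60-configuration grid shipped with the package it reproduces
the published 14/9/37 split exactly, which a side-blind PI < 3 rule does
not.

## Synthetic patients

`patient_archetype(1:5)` builds five triple-vessel-disease circulations
with the published lesion patterns (location class, percent diameter,
lesion length), including the patient-specific features: a ramus
intermedius for patients 1–2, additional milder lesions for 3–4, an
in-stent restenosis segment for 5, and OM1 versus OM2 grafting targets.
Epicardial dimensions are literature-typical stand-ins (LM 0.20 cm, LAD
0.16→0.10 cm over 10 cm, CIRC 0.15→0.10 cm, RCA 0.17→0.10 cm over 12 cm,
PDA 2.2 mm proximal calibre); side branches follow the deterministic rule
of one 1 cm branch of 0.4× local parent radius every 1.5 cm. Lesion
positions sit at the centres of the inter-branch intervals so stenosis
interfaces never create mesh pieces shorter than 0.75 cm, which keeps the
coarse profile inside its CFL margin. Because the real per-patient
geometries are not public, archetype simulations target *directional*
agreement (severity ordering of iFR, near-unity healthy iFR, the
single-inflow double-Y starving its LAD limb, reduced perfusion under
disease) — not the published per-graft flow values, which are instead
shipped verbatim as a fixture and drive the classification and statistics
layers.

What the generator does not emulate: real vessel tortuosity and calibre
variation, microvascular disease, autoregulation, hyperaemia, collateral
flow, and stent mechanics (the in-stent restenosis is an ordinary lumped
element). Passing tests therefore demonstrate correctness of the solver
and of the decision layers, and qualitative fidelity of the physiology —
not patient-level predictive accuracy.

## Statistics

The cohort statistics are standard tests behind an explicit 2×2
interface: the continuity-corrected (Yates) chi-squared — required to
reproduce the published selection p-values (0.015, 0.746, 0.743); the
uncorrected statistic gives e.g. 0.48 where 0.64 is printed — Fisher's
exact test, chosen automatically when any expected cell is below 5 (this
policy matches the rows the published table evidently computed exactly),
the exact-binomial McNemar test (well defined at zero discordant counts),
the paired t, and nonparametric fallbacks. Base R implementations are
used where they exist; the test suite cross-checks Fisher against a full
hypergeometric enumeration.

## Numerical choices and degenerate inputs

* Periodicity tolerance $10^{-3}$ (relative L2 over all terminal flows),
  maximum 20 cycles; non-periodic results carry their residual history.
* The coarse profile (`solver_config("fast")`: dx 0.5 cm, dt 2×10⁻⁴ s)
  exists for quick directional runs; its time step is chosen with a CFL
  margin over the shortest mesh pieces the configurator can create,
  slightly below a pure 10× coarsening of the standard step.
* Newton solves at junctions/stenoses/terminals iterate to a relative
  step of 10⁻¹⁰–10⁻¹¹ with a 1 ml/s flow scale in the denominator (the
  invariant residual floors at machine epsilon times the wave speed, so a
  purely relative criterion is unattainable at near-zero flow).
* Degenerate inputs fail loudly: 100% stenosis, empty metric tables,
  missing target markers, networks with unattached segment ends, CFL
  violations (naming the segment), zero-mean flow in PI.
* Problem sizes used by the shipped tests: archetypes have ~60 mesh
  segments / ~800 nodes at the standard grid; periodic runs take 3–5
  cycles (≈ 3 s standard, ≈ 0.3 s fast per network on one core).

## Known limitations

* The archetype severities use percent *diameter* with a uniform-lumen
  viscous term, which makes >85% lesions nearly occlusive; simulated
  diseased iFR values are therefore lower than the published ones (the
  ordering and thresholds survive; the printed values themselves are an
  explicit non-goal without the true geometries).
* One generic aortic waveform drives all inflows; no subclavian pressure
  loss is modelled for in-situ mammary origins.
* No hyperaemia: FFR comes only from the affine map, never from a
  simulated hyperaemic run.
* Junctions are lossless; anastomotic technique is out of scope.
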