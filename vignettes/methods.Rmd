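---
title: "Methods: from channel block to body-surface biomarkers"
author: "cardioscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from channel block to body-surface biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cardioscreen` is a desk-scale, fully deterministic multiscale simulator for
in-silico proarrhythmia screening.  Its pipeline follows the structure of
CiPA-style model-based safety assessment:

1. **Pharmacology** — free plasma concentration is converted into fractional
   block of four ionic currents (I~Na~, I~NaL~, I~CaL~, I~Kr~) through the
   Hill equation.
2. **Cell** — the blocked currents drive the O'Hara–Rudy dynamic (ORd) human
   ventricular myocyte model in its endocardial, mid-myocardial (M) and
   epicardial variants.
3. **Tissue** — a monodomain reaction–diffusion model propagates the action
   potential across a synthetic transmural geometry with a Purkinje-style
   activation scheduler.
4. **ECG** — a volume-conductor forward model maps the tissue sources to
   electrode potentials and lead voltages.
5. **Biomarkers** — APD~90~, transmural dispersion of repolarization (TDR),
   QTc, JT~peak~c, early-afterdepolarization (EAD) and ventricular-tachycardia
   (VT) flags summarize each drug × concentration condition.

This vignette records the modelling choices, the parameters that matter, and
the limits of what the synthetic test bed can show.

## Drug model

Fractional block of a channel at free concentration $C$ is
$$b = \frac{C^h}{C^h + \mathrm{IC}_{50}^h},$$
with the per-drug, per-channel $\mathrm{IC}_{50}$ and Hill coefficient $h$
from the bundled table of seven CiPA reference compounds (dofetilide,
bepridil, cisapride, verapamil, ranolazine, mexiletine, diltiazem).  All
concentrations are free (unbound) C~max~ multiples; the schema carries no
protein-binding field.  An infinite IC~50~ encodes "no measurable block" and
produces exactly zero.  The orientation of the formula (block, not
potentiation) is pinned by a mandatory unit test that reproduces every
finite printed block-at-C~max~ percentage of the source table to three
significant figures.  Scaling is purely static multiplicative conductance
scaling $g \mapsto (1-b)\,g$; dynamic (state-dependent) drug binding of
later CiPA hERG models is out of scope.

Extremely small blocks (down to $10^{-42}$) are computed on the log scale so
they retain relative accuracy instead of underflowing through the naive
power ratio.

## Myocyte model

The ORd equations (41 state variables) are implemented in compiled code with
endo/M/epi parameter variants and per-channel scaling hooks on
$G_{Na}$, $G_{NaL}$, $P_{Ca}$ and $G_{Kr}$.  Currents are expressed per unit
membrane capacitance (A/F), so the single-cell equations are independent of
the tissue capacitance value; the bundled tissue capacitance
(2.0&nbsp;µF/cm²) is metadata for conductivity-based workflows only.

**Integration.**  The default scheme is the hybrid used by the model's own
reference code: exponential (Rush–Larsen) updates for all relaxation-form
variables (gates, the Ca-dependent ICaL mode fraction, the SR release
flux) and forward Euler for the membrane potential, concentrations and CaMK,
at $\Delta t = 0.005$&nbsp;ms.  Pure forward Euler is available
(`method = "fe"`) and agrees with the hybrid scheme within 1&nbsp;mV over a
beat, but it is *not* the default because the fast-I~Na~ inactivation gate
has a sub-$\Delta t$ time constant at depolarized voltages: in long paced
M-cell runs the explicit update eventually diverges, which we observed
directly during development.  Step-halving changes a one-beat trace by
<&nbsp;0.2&nbsp;mV away from the upstroke and moves APD~90~ by
<&nbsp;0.1&nbsp;ms; the O($\Delta t$) phase shift of the ~300&nbsp;mV/ms
upstroke dominates the pointwise difference in the first milliseconds, which
is why convergence is judged outside that window.

**Validation.**  A second, independently typed plain-Python transcription of
the model ships under `inst/oracle/`.  Both implementations pace from the
published initial conditions; their APD~90~ values agree within
0.05&nbsp;ms at every horizon we compared (50 and 100 beats, all three cell
types), and the long-run steady-state APD~90~ values (≈268/333/229&nbsp;ms
endo/M/epi at CL&nbsp;1000&nbsp;ms) sit where the literature for this model
puts them.  The frozen oracle values asserted in the test suite were
produced by that script at the panel protocol below.

## Pacing protocol and single-cell biomarkers

The source study does not state its pacing protocol, so the package fixes
one and reports it everywhere: cycle length 1000&nbsp;ms, stimulus
−80&nbsp;A/F for 0.5&nbsp;ms, 100 paced beats, analysis on the final beat.
One hundred beats is a deliberate compromise: the model's slow
concentration drift continues for hundreds of beats, but the drug-induced
*differences* are stable at this depth — except for near-cancelling blocks
(verapamil in endocardial cells, where ICaL and IKr block offset to a
|Δ|&nbsp;<&nbsp;2&nbsp;ms effect whose sign only settles with deeper
pacing).  Because of the unstated protocol, millisecond values of the drug
panel are treated as approximate (±15%) wherever they are compared to the
printed study values; signs and orderings are treated as exact.

The `steady_tolerance` field of a protocol implements an optional early
stop when successive APD~90~ values differ by less than the tolerance.  It
defaults to 0 (disabled): successive-beat differences fall under any useful
tolerance within a handful of beats, long before the slow drift settles, so
an early stop systematically under-paces; the convergence flag is still
reported.

APD at level $\ell$ is measured from the time of maximum upstroke velocity
to the first fall below $V_{peak} - \ell\,(V_{peak} - V_{rest})$, with
$V_{rest}$ sampled immediately before the stimulus.  The amplitude-relative
reference is robust under drug-shifted plateaus, unlike a fixed voltage
threshold.  A beat that never reaches the 90% level before the next
stimulus returns the explicit failure marker (`NA`), which propagates
through ΔAPD~90~ and TDR rather than silently disappearing.

**EAD detection** looks for a depolarizing excursion
($dV/dt > 0.02$&nbsp;mV/ms sustained for ≥5&nbsp;ms) during repolarization.
Two guards matter: the threshold rejects numerical ripple at the default
step, and the excursion must take off from a voltage at least 30%
repolarized — epicardial cells physiologically rise again after their
phase-1 notch (spike-and-dome), and that dome must not be misread as an
EAD.  TDR is the max−min APD~90~ across the three cell types; in control it
is positive with the M cell longest.

## Tissue model

The monodomain equation
$$\partial_t V_m = \nabla\!\cdot\!(D \nabla V_m) - (I_{ion} + I_{stim})$$
is discretized with linear finite elements and mass lumping on simplicial
meshes (segments, triangles, tetrahedra), which on a uniform 1D grid reduces
exactly to the second-difference stencil $D/\Delta x^2\,(1,-2,1)$ — that
identity, constant-field conservation, and the analytic Neumann heat-decay
rate are all asserted in tests.  Because the reaction term is in A/F
(mV/ms), the capacitance does not appear separately; $D$ is the effective
diffusivity.

**The diffusion-coefficient unit switch.**  The source table prints the
ventricular diffusion coefficient as 0.00154&nbsp;cm²/s.  Taken literally
that value yields a conduction velocity around half a millimetre per
second — three orders of magnitude below physiology — while the same digits
read as cm²/ms give ≈57&nbsp;cm/s on the refined cable, squarely
physiological.  The package stores the printed number, defaults to the
per-millisecond reading, and exposes `d_time_unit` so the literal reading
remains available; it does not silently rescale a published constant.

Time stepping is explicit with a divergence guard and an a-priori
Gershgorin bound ($\Delta t \le 1/\max_i |L_{ii}|$) that refuses unsafe
configurations with a suggested step.  Default tissue step: 0.01&nbsp;ms at
$\Delta x = 0.01$&nbsp;cm.

**Geometry.**  The patient-specific ventricular mesh of the source study
(≈1.5M elements) is deliberately replaced by synthetic, deterministic
generators: a 165-node transmural cable (~1.65&nbsp;cm wall, equal
endo/M/epi thirds — the study assigns layers only "with reference to a
figure", so equal thirds is the package's configurable default), a 2D
sheet, a slab, and a closed ellipsoid shell (geodesic sphere extruded
radially into conforming tetrahedra; transmural layers run radially).  An
idealized closed torso surface (triangulated ellipsoid) stands in for the
study's torso geometry, which is not published in the text.  All default
diffusion is isotropic scalar — the study describes no fiber architecture —
though the type admits per-element values.

**Purkinje system.**  The conduction system is an activation-*time*
scheduler, not a membrane model: a tree of segments with per-segment
speeds delivers the His-bundle pacing time to each Purkinje–muscle junction
(PMJ) along the unique root-to-leaf path, strictly unidirectionally (no
retrograde coupling, matching the source's design).  Each PMJ node is held
at −80&nbsp;A/F from its scheduled time until its membrane potential first
exceeds −10&nbsp;mV, then latches off for the rest of the beat; the latch
resets at every pacing cycle.  Regional speeds are not printed in the
source, so the default 0.2&nbsp;cm/ms is an explicit placeholder,
configurable per segment.  A parametric binary tree with deterministic
terminal-length modulation stands in for the study's digitized 2D network,
which is not reproducible from the text.

## Forward ECG

Sources are per-element $J_c = -D\nabla V_m$ (constant on linear elements).
The default forward model is the homogeneous unbounded-medium reduction of
the surface-potential equation, evaluated by centroid quadrature:
$$\phi(\mathbf r) = \frac{1}{4\pi\sigma}\sum_e v_e\, \mathbf J_e \cdot
\frac{\mathbf r - \mathbf c_e}{|\mathbf r - \mathbf c_e|^3},$$
with body conductivity 2.0&nbsp;mS/cm.  The optional boundary-element model
solves the single-closed-surface collocation system with analytic triangle
solid angles; for the torso–air boundary the system is defined up to a
constant, removed by deflation (lead voltages are gauge-invariant).  A
centered dipole in a triangulated sphere with insulating exterior
reproduces the analytic bounded-sphere solution within ~0.5% at 1280
triangles, and the zero-jump limit reproduces the infinite-medium potential
exactly.

Electrode placement on the synthetic geometries is canonical and fixed:
for a cable along $x$, "LA" sits 2&nbsp;cm beyond the epicardial end and
"RA" 2&nbsp;cm beyond the endocardial end with a 0.5&nbsp;cm lateral
offset, and lead&nbsp;I = φ(LA) − φ(RA).  With endo-to-epi activation and
the epicardium repolarizing first, this yields the classic concordant
upright QRS and T wave.  Amplitudes are in units proportional to mV (a 1D
source assigns no absolute cross-section); every interval biomarker is
amplitude-invariant, so this affects plots, not numbers.

## ECG biomarkers

Fiducials per beat: QRS onset is the first time |dφ/dt| exceeds 5% of the
beat's peak slope after pacing; the J point is the return of the QRS
complex into a baseline band (15% of R amplitude); T~peak~ is the largest
absolute excursion at least 40&nbsp;ms past the J point; T~end~ uses the
tangent method (steepest post-peak tangent extrapolated to baseline), the
standard choice and well-behaved on smooth simulated T waves.  A flat or
T-less trace returns the failure marker.  Rate correction defaults to
Fridericia ($\mathrm{QTc} = \mathrm{QT}/(RR/1000)^{1/3}$, the CiPA
convention; the source does not state its formula), with Bazett and "none"
switchable and the method recorded in every report.

The VT flag combines two criteria: above-noise oscillatory deflections
persisting beyond control QT + 200&nbsp;ms guard, or continued tissue
activations after pacing stops.  ΔTDR is computed from the single-cell
panel by default (the source leaves ambiguous whether its values are
single-cell or in-tissue).

## What the synthetic test bed does and does not show

The generators emulate: transmural heterogeneity (three layers),
endocardial-first activation through PMJ-style stimulation, rate-dependent
repolarization, and source-to-surface forward mapping.  They do not
emulate: patient anatomy or fiber architecture, torso inhomogeneity (lungs,
bone — a limitation the source itself states), polymorphic arrhythmia
morphology, or absolute ECG amplitudes.  Consequently the package treats
the study's 3D-torso millisecond intervals and 3D VT occurrences as out of
desk-scale reach and verifies *properties* instead: the sign pattern and
ordering of the drug panel, repolarization failure of the high-risk
compound at 5–10× exposure with clean safe comparators, JT~peak~
decreasing with heart rate, JT~peak~ ≤ QT, and a scaled-tissue contrast in
which dofetilide at 5× flags VT while verapamil at 5× does not.

Problem sizes used by the automated checks, chosen once as this package's
panel conditions: 100-beat pacing per single-cell condition, the
165-node default cable with two tissue beats (the second analysed) for ECG
conditions, heart rates 60/80/100&nbsp;bpm for the rate sweep, and a
320-triangle sphere for the routine boundary-element check (1280 in the
full validation).

## Known limitations

* Conductance scaling is static; kinetic (state-dependent) block and
  metabolite pharmacology are out of scope.
* The Purkinje speeds and the transmural layer fractions are placeholders
  where the source prints none; both are configurable and recorded.
* The arrhythmia detector flags sustained activity; it does not classify
  morphology.
* One-dimensional sources make ECG amplitudes relative; studies of T-wave
  amplitude morphology need the 3D geometries and the BEM torso.
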