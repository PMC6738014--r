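# cardioscreen

Desk-scale multiscale simulation of drug-induced proarrhythmia risk, for
safety pharmacologists and cardiac-electrophysiology modellers who want a
fully deterministic, testable pipeline from patch-clamp potencies to
ECG-level biomarkers.

The pipeline:

1. **Hill-equation pharmacology.** Fractional block of I_Na, I_NaL, I_CaL
   and I_Kr at free concentration C: `block = C^h / (C^h + IC50^h)`.
   A table of seven CiPA reference drugs (dofetilide, bepridil, cisapride,
   verapamil, ranolazine, mexiletine, diltiazem) with per-channel Cmax,
   IC50 and Hill coefficients is bundled.
2. **Human ventricular myocyte model** (O'Hara–Rudy dynamic, endo/M/epi
   variants, 41 state variables, compiled core) with multiplicative
   conductance scaling `g -> (1 - block) g` per channel.
3. **Monodomain tissue**: `dVm/dt = div(D grad Vm) - (Iion + Istim)` with
   linear finite elements + mass lumping on synthetic geometries (1D
   transmural cable, 2D sheet, 3D slab and ellipsoid shell), plus a
   Purkinje-style activation scheduler implementing the
   stimulate-until-(-10 mV) latch rule at -80 A/F.
4. **Forward ECG**: infinite-medium volume-conductor potentials (default)
   or a single-closed-surface boundary-element torso; lead I = LA - RA.
5. **Biomarkers**: APD90, delta-APD90, transmural dispersion of
   repolarization (TDR), QTc and JTpeak_c (Fridericia by default), EAD /
   repolarization-failure flags, VT flag, JTpeak–heart-rate curves.

Everything is deterministic — there is no random number generation anywhere
in the pipeline, and identical configurations produce bit-identical
reports.

## Worked example

Dofetilide (high torsade risk) versus verapamil (QT-prolonging but safe) at
therapeutic exposure:

```r
library(cardioscreen)

drugs <- loadDrugTable()             # bundled 7-drug CiPA table
drugScalings(drugs$dofetilide, 1)    # fraction of each current left open
#>   INa  INaL  ICaL   IKr
#> 0.999 1.000 1.000 0.398           # 60.2% hERG block at free Cmax

prot <- pacingProtocol(cl = 1000, n_beats = 100)
ctrl <- paceToSteadyState("M", drugScalings(NULL), prot)
dof  <- paceToSteadyState("M", drugScalings(drugs$dofetilide, 1), prot)
tail(ctrl$apd90, 1); tail(dof$apd90, 1)
#> [1] 349.62
#> [1] 550.61                        # +201 ms in the M cell

# at 5x Cmax the M cell no longer repolarizes (torsade trigger):
dof5 <- paceToSteadyState("M", drugScalings(drugs$dofetilide, 5), prot)
dof5$repolarization_failure
#> [1] TRUE

# tissue-level: cable ECG and intervals
res <- cableEcgRun(buildCable(), drugScalings(drugs$verapamil, 1),
                   prepace_beats = 100)
res$intervals
#> <intervalSet> lead leadI: QRS onset 1000.0, J 1039.0, Tpeak 1302.0, Tend 1333.7 ms
#>   QT 333.7 ms, JTpeak 263.0 ms, Tpeak-Tend 31.7 ms
```

`runScreen(screenConfig())` runs the whole drug x {1x, 5x, 10x} panel and
writes a biomarker report (CSV/JSON) with a reproducibility manifest. A thin
CLI over the same functions ships in `inst/scripts/cardioscreen`.

The numbers above are what the code prints under the package's default
panel protocol (100 beats at CL 1000 ms, dt 0.005 ms); because the original
study's pacing protocol is unreported, millisecond values are
protocol-dependent while signs and orderings are robust.

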