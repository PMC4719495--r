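---
title: "Methods: a population-of-models study of repolarization alternans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a population-of-models study of repolarization alternans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## What this package computes

Repolarization alternans — stable beat-to-beat (period-2) oscillation of the
action potential duration (APD) — is a recognized arrhythmia risk marker.
This package studies how cell-to-cell variability in ionic conductances and
permeabilities shapes the *type* of APD alternans a human ventricular
epicardial myocyte can develop under steady pacing at cycle lengths (CLs)
from 600 down to 350 ms:

* **Eye-type** alternans: a *closed* restitution bifurcation. Alternans
  appear as rate increases and vanish again at the fastest rates.
* **Fork-type** alternans: an *open* bifurcation. Alternans persist at the
  fastest rates (and typically remain when pacing is pushed to CL 200 ms).
* **CaT-only** alternans: the calcium transient (CaT) alternates while APD
  alternans stay below the 5 ms classification threshold.

The package builds a population of models that share the equations of the
O'Hara–Rudy dynamic (ORd) human ventricular epicardial cell model but differ
in eleven maximal conductances/permeabilities, calibrates the population
against activation-recovery-interval (ARI) envelopes, classifies each
accepted model's restitution, traces the mechanism through per-beat calcium
balances, and runs two interventions: scaling of the L-type calcium current
(I~CaL~) kinetics time constants and partial block of the Na^+^/Ca^2+^
exchanger (I~NaCa~).

## The cell model

The electrophysiology is the epicardial variant of the ORd model: 41 state
variables (membrane potential, intracellular/subspace Na^+^, K^+^ and Ca^2+^
concentrations, network and junctional sarcoplasmic-reticulum (SR) Ca^2+^,
Hodgkin–Huxley gates, CaMKII-phosphorylated gate duplicates, the SR release
flux states and the CaMKII trap). Only the epicardial parameterization is
provided, because the study design compares against epicardial recordings.

Eleven parameters are varied multiplicatively in [0, 2] (±100 %):

| factor | quantity |
|---|---|
| `s_GNa` | fast Na^+^ conductance |
| `s_GNaL` | late Na^+^ conductance |
| `s_Gto` | transient outward K^+^ conductance |
| `s_GCaL` | L-type Ca^2+^ channel permeability |
| `s_GKr`, `s_GKs`, `s_GK1` | delayed/inward rectifier K^+^ conductances |
| `s_GNaCa` | Na^+^/Ca^2+^ exchanger conductance |
| `s_GNaK` | Na^+^/K^+^ pump activity |
| `s_PJrel` | RyR release permeability |
| `s_PJup` | SERCA uptake permeability |

`s_PJup` scales the SERCA pump term only, not the passive SR leak; `s_PJrel`
scales the release flux as a whole. Three further multipliers (`m_tau_d`,
`m_tau_f`, `m_tau_j`, each in [0.5, 1.5]) scale the I~CaL~ activation,
voltage-dependent inactivation, and recovery-from-Ca-dependent-inactivation
time constants pointwise, leaving every steady-state curve untouched.
`m_tau_f` acts on the fast and slow voltage-dependent inactivation gates (and
their phosphorylated counterparts, whose time constants are defined as fixed
multiples); `m_tau_j` acts on the 75 ms recovery gate of Ca-dependent
inactivation.

The package carries **two independent transcriptions** of the equations: a
plain-R derivative function (`ord_rhs()`), integrated with `deSolve::lsoda`,
and the compiled production engine. The test suite asserts pointwise
agreement of the two derivative evaluations (relative error < 1e-10) and
agreement of paced-beat biomarkers between the fixed-step engine and the
adaptive stiff solver (APD90 within 1 ms, CaT amplitude within 2 %). Since no
third-party reference implementation is available offline, this dual-route
check is the package's model-fidelity gate; baseline hallmarks (resting
potential near −88 mV, epicardial APD90 in the physiological 200–260 ms range
at CL 1000 ms, no alternans at CLs 600–350 ms) are asserted in addition.

## Numerics

The engine tabulates every voltage-dependent rate and current helper over
V ∈ [−150, 100] mV in 0.05 mV steps with linear interpolation; gates advance
with the Rush–Larsen exponential update, concentrations and V~m~ with forward
Euler, on a two-level time step:

* **fine step** (`dt_fine`) inside the stimulus + SR-release window
  (`fine_win`, default 60 ms after the stimulus) and wherever
  |dV~m~/dt| exceeds `dvdt_thresh`;
* **coarse step** (`dt_coarse`) elsewhere (plateau, diastole).

Two presets are used. Accuracy-oriented defaults (`build_model()`:
0.005/0.025 ms, threshold 1 mV/ms) integrate a paced beat with APD90 within
about 0.1 ms and CaT amplitude within about 1 % of the adaptive-solver
reference. Throughput-oriented settings used for population screening
(`study_config()`: 0.01/0.1 ms, threshold 3 mV/ms) trade a small systematic
CaT-amplitude bias (about −2 %, identical across models) for a roughly
four-fold speed-up; APD error stays below 0.3 ms. Classification operates on
*differences* between beats of the same model, which this systematic bias
leaves intact (labels were verified stable across step settings and across
doubled conditioning-beat counts on a scan of alternans models).

The stimulus is rectangular, −80 A/F for 0.5 ms (the ORd convention; the
protocol source does not state one). Output is sampled every 0.5 ms. Per-beat
SR and sarcolemmal calcium-balance integrals are accumulated inside the
integrator at full step resolution, so conservation identities hold to
machine-level consistency with the integration scheme itself. One residual
discretization effect matters for balance *closure* measurements: the Euler
update applies linearized instantaneous buffering, so the flux-integral
balances differ from the state-implied calcium change at first order in the
step; the two-beat closure checks therefore run at a fine step
(0.002/0.01 ms), where the closure residual drops below 2 % of the single-beat
balance magnitude.

## Protocols and steady state

Dynamic restitution paces each model at CLs 600 → 350 ms (50 ms steps,
optional 200 ms extension), carrying the state from one CL to the next, with
`n_prebeats` conditioning beats and 8 recorded beats per CL (even, so odd/even
beat averages are balanced during alternans). A beat is *captured* when V~m~
exceeds 0 mV within 50 ms of the stimulus; classification only uses captured
CLs, so 2:1 block at fast rates cannot masquerade as alternans disappearance.

The package default of 500 conditioning beats per CL brings non-alternans
APDs within 1 ms of their fully converged values (test-asserted by doubling).
Population runs use a **screen-and-confirm** scheme. The screening pass (100
beats at the first CL, then 50 per subsequent CL with carry-over) is cheap
and classifies the bulk of the population; but alternans *inherited through
the carry-over staircase* decay over hundreds of beats, so a marginal model
can look alternating at a fast CL long after the underlying steady state has
stopped alternating. Every accepted model whose screen shows any hint of
alternans (ΔAPD ≥ 2 ms or ΔCaT near threshold at any CL) is therefore re-run
with a long confirmation schedule (400 beats at the first CL, then 300 per
CL) and its per-CL summaries replaced by the converged values before the
final classification. The same confirmation is applied to post-intervention
runs that still show alternans, and the kinetics study on the
largest-alternans reference models uses the confirmation schedule for every
condition, because its ΔAPD-vs-balance fits need converged magnitudes.

The scaled-down study size (400 Latin Hypercube models + baseline, seed fixed
in the configuration) is likewise the package's desk-scale default: a
full-scale run (10 000 models, 500 prebeats) is a cluster job, not a desk
job. The statistical consequences of the reduction are visible in the
acceptance outputs and worth spelling out: at the published incidence the
Eye phenotype is drawn roughly once per 300 accepted models, so a desk-scale
run can contain no Eye model at all, making the Eye-vs-Fork onset comparison
and the largest-Eye kinetics fit unevaluable; alternans-vs-normal parameter
comparisons run at n of order 10 vs 200, so true directional differences may
sit near the significance boundary; and per-CL balance-vs-ΔAPD correlations
at the fastest rate are computed over a narrow ΔAPD range (only deep Fork
models survive there), which deflates the correlation a full-scale population
would show. The calibration envelopes are also a factor: the min/max of
thousands of synthetic normal-site ARIs is wider than the original in vivo
envelope, so models with strong, hard-to-suppress alternans are accepted that
a tighter calibration would exclude; this depresses the fraction of alternans
models converted to normal by mild (20 %) exchanger block relative to the
published majority, while complete suppression at 60 % block is reproduced.
Two further envelope-width effects show up in the acceptance suite: normal
models accepted near the alternans boundary can be pushed into genuine
steady alternans by reducing the recovery time constant of I~CaL~
Ca-dependent inactivation (the original study reports none), and the RMP
partial correlations are dominated by repolarization parameters rather than
by the inward rectifier and Na/K pump, because long-APD models encroach on
the diastolic interval at CL 600 ms and elevate the pre-stimulus potential.

## Biomarkers and alternans metrics

Per beat: APD90/APD40 at 90 %/40 % repolarization of the AP amplitude
(APA = V~max~ − RMP; the engine measures from stimulus onset with linear
interpolation of the crossing, the trace-based functions from AP take-off at
10 % of APA — the two differ by the constant activation latency, which
cancels from all beat-to-beat differences); RMP just before the stimulus;
upstroke duration 10→90 % of APA; triangulation = APD90 − APD40; CaT
max/min/amplitude and CaT duration from take-off to 90 % decay. The APD
alternans magnitude (ΔAPD) is the mean absolute consecutive-beat APD
difference over the recorded beats; ΔCaT likewise on CaT amplitude. The
alternans phase (long–short vs short–long) is arbitrary and all magnitudes
are reported as absolute values.

Thresholds: ΔAPD ≥ 5 ms defines an APD-alternans model (the CaT-only
boundary); the CaT-alternans threshold is ΔCaT ≥ 5 % of the mean CaT
amplitude at that CL — no published value exists for the latter, so it is a
configurable package default.

## Calcium balances

* **SRCB** (SR calcium balance) = ∫(J~up~ − J~rel~) dt over one beat window
  [stimulus, next stimulus), volume-referenced to the cytosol
  (µmol per litre cytosol per beat). Since the NSR–JSR transfer flux is
  internal, SRCB equals the per-beat change in total SR Ca content
  (test-asserted).
* **SCB** (sarcolemmal calcium balance) = per-beat integral of the net Ca
  flux carried by I~CaL~, background Ca current, the sarcolemmal Ca pump and
  both Na/Ca exchanger components (one Ca^2+^ per exchanger cycle), positive
  = net cell Ca gain. The exact current list and sign convention are package
  decisions (they are not recoverable from the protocol source); correlations
  with alternans magnitude use magnitudes and are therefore sign-robust.

At a non-alternating steady state both balances vanish (below 1 % of the
per-beat release/influx integrals); during alternans, consecutive beats carry
balances of near-equal magnitude and opposite sign, and the magnitude on the
short-APD beat correlates strongly with ΔAPD across alternans models.

## Population, calibration, statistics

Latin Hypercube sampling (`lhs::randomLHS`) draws one point per equal-width
stratum per dimension in [0, 2]^11^. Calibration is a min/max envelope on APD
alone, per CL (Britton-style): a model is accepted iff its mean steady-state
APD lies inside [lower, upper] at every CL, with capture required. Envelope
sources: a user CSV, or the synthetic in vivo module.

Statistics follow the study conventions: Pearson correlation; linear
residual-on-residual partial correlation of biomarkers against the eleven
factors (a rank variant is offered, since the flavour is not specified in the
source); two-sided Mann–Whitney U (exact for total n ≤ 20 without ties) with
0.05/0.01/0.001 significance stars and no multiple-testing correction.

## The synthetic in vivo module

The original calibration data (sock-electrode recordings: 41 patients ×
240 epicardial sites, CLs 600→350 ms) are not deposited, so
`generate_ari_study()` emulates their structure: ARI(site, patient, CL) =
linear mean curve + patient effect + site effect + beat noise, with roughly
10 % of sites carrying period-2 ARI sequences. Defaults (mean ARI
113 + 0.22·CL ms; patient SD 18 ms; site SD 15 ms; beat noise 4 ms) were
chosen once: the curve is anchored so that the baseline model is accepted
(the real calibrated set contained the original ORd model), and the spreads
are at the scale reported for epicardial ARI mapping. The min/max envelope
over ~8 000 normal-site samples is consequently *wider* than the original
study's envelopes, so the synthetic calibration accepts a larger fraction of
models than the published 23 %; the downstream structure (normal ≫ alternans,
alternans split into Eye/Fork/CaT-only) is unaffected. What passing against
synthetic envelopes demonstrates is the machinery and the mechanism, not
agreement with patient data.

`synth_electrogram()` builds toy unipolar electrograms — a biphasic
depolarization wavelet whose steepest negative slope encodes activation, plus
a Gaussian T wave whose steepest positive slope encodes recovery — and
`ari_extract()` implements the derivative rule (ARI = time of max dV/dt in
the repolarization window minus time of min dV/dt in the depolarization
window), after a symmetric moving-average filter (default 12 ms, about the
synthetic T-wave half-width) — raw finite differences are noise-dominated at
realistic signal-to-noise ratios, and filtering before derivative-based
fiducial detection is standard practice. Window defaults: depolarization
[stimulus, +80 ms], repolarization [+100 ms, next stimulus minus one filter
width] (the trailing margin keeps the next activation deflection out of the
smoothed slope). The encode→extract round trip is exact to 1 ms at zero
noise; the extractor is amplitude-invariant up to floating-point ties.

## Interventions

* `inaca_block_study()` rescales `s_GNaCa` by (1 − f) for f ∈ {0.2, 0.4,
  0.6} on every alternans model, re-runs restitution and re-classifies.
  "Converted to normal" means the post-block class is `normal`. Conversion
  percentages are reported both over the APD-alternans (Eye+Fork) denominator
  and over all alternans models, because the published 63 % figure is
  ambiguous about whether CaT-only models count.
* `ical_kinetics_study()` varies each τ multiplier one at a time over
  {0.5, 0.75, 1, 1.25, 1.5} (matching the per-τ symbol series of the original
  figure), re-runs restitution, and fits ΔAPD against |SCB| and |SRCB| across
  conditions. Reference models: the largest-alternans Eye and Fork models,
  the baseline model, and the longest- and shortest-APD accepted normal
  models.

## Degenerate inputs and numerical edge cases

Scaling a conductance to zero removes that current exactly; `s_GNa = 0`
abolishes the upstroke and the beat fails capture. Models that lose 1:1
capture at a CL are rejected at calibration with that reason. Non-finite
states abort a model's run with an error carrying the beat and CL; population
evaluation records such models as failed and continues. Flat calcium
transients (range < 1e-6 mM) and non-captured beats yield flagged-invalid
biomarkers rather than numbers.

## Known limitations

Single cell only — no tissue coupling, conduction or ECG-level metrics; no
β-adrenergic signalling; no stochastic RyR gating or release-unit spatial
structure, so alternans mechanisms that require RyR refractoriness are out of
reach by construction. ARI is treated as an APD surrogate without modelling
its known bias. The synthetic envelopes stand in for undeposited recordings
and are labelled as such everywhere. Results at the desk-scale population
size carry small-sample noise in every alternans-group statistic; the
configuration scales to the full published size unchanged.
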