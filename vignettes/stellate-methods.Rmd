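---
title: "Modelling clustered firing in entorhinal stellate cells: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling clustered firing in entorhinal stellate cells: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Layer II medial entorhinal cortex stellate cells (mEC-SCs) fire action
potentials in *clusters* — short groups of spikes separated by long
quiescent intervals — and show subthreshold membrane-potential
fluctuations with peak power in the theta (4–12 Hz) band.  This package
implements a single-compartment conductance-based model of an mEC-SC in
which both phenomena can be generated and dissected.

The membrane potential obeys

$$C\,\frac{dV}{dt} = I_{\mathrm{app}}
  - I_{\mathrm{NaT}} - I_{\mathrm{NaP}} - I_{\mathrm{Kdr}}
  - I_{\mathrm{Kaf}} - I_{\mathrm{Kas}} - I_h - I_{\mathrm{AHP}} - I_L
  + \sigma\,\eta(t),$$

with each ionic current of the form $I_X = g_X\,\psi_X\,(V - E_X)$, where
$\psi_X$ is the product of the channel's gating fractions raised to their
integer exponents.  Every gating fraction follows first-order kinetics
$\dot x = \alpha_x(V)(1-x) - \beta_x(V)\,x$, which keeps $x$ in $[0,1]$
whenever the rates are non-negative.  $\eta(t)$ is Gaussian white noise on
the voltage equation only; it stands in for intrinsic channel noise, which
is not modelled explicitly.

The AHP current is the model's one non-smooth ingredient: its opening rate
is not voltage dependent but decays exponentially from the time of the most
recent spike, $\alpha(t) = 1.5\,e^{-(t - t_{\mathrm{spike}})/\tau}$ with
$\tau = 60$ ms and constant closing rate $\beta = 1.6\,\mathrm{ms}^{-1}$,
so the AHP conductance switches on for roughly 100 ms after every spike.
A spike is defined as the membrane potential rising through 0 mV; the most
recent spike overwrites $t_{\mathrm{spike}}$, while the AHP gating fraction
itself remains continuous — only its drive jumps.

Units throughout: mV, ms, mS/cm², µA/cm², µF/cm²; rates in 1/ms.  The
standard parameter table is `model_params()`'s default: $C = 1.46$,
$I_{\mathrm{app}} = 0.3$, $g_{\mathrm{NaT}} = 24$, $g_{\mathrm{NaP}} =
0.075$, $g_{\mathrm{Kdr}} = 11$, $g_{\mathrm{Kaf}} = 0.1$, $g_{\mathrm{Kas}}
= 0.5$, $g_h = 2.8$, $g_{\mathrm{AHP}} = 0.425$, $g_L = 0.15$,
$E_{\mathrm{Na}} = 55$, $E_K = -85$, $E_h = -30$, $E_L = -88.5$, and
$\sigma = 0.197$ (equivalently $\sigma/C = 0.135$ mV·ms$^{-1/2}$).

## The reconstructed channel kinetics

The voltage-dependent rate functions of the six standard channels are not
part of this package's primary literature; they belong to an earlier
stellate-cell model that is not redistributable here.  The file
`inst/extdata/kinetics_default.ini` therefore ships a **reconstruction**,
assembled from the standard lineage of stellate-cell models
(Traub–Miles-type spike currents; a slowly activating persistent sodium
current; fast- and slow-inactivating A-type potassium currents; a
single-component hyperpolarisation-activated cation current) and
constrained, once, by the qualitative regime structure the original model
is reported to have:

* a stable rest state at low $g_h$ (or low $I_{\mathrm{app}}$) that is
  *marginally* lost at the standard operating point — the fold sits just
  below $g_h = 2.8$ in $g_h$ and just below $I_{\mathrm{app}} = 0.3$ in
  $I_{\mathrm{app}}$, with a stable subthreshold state remaining at
  $I_{\mathrm{app}} = 0.25$;
* tonic firing at low $g_{\mathrm{AHP}}$ / high $g_h$;
* periodic bursts of exactly three spikes at
  $(g_{\mathrm{AHP}}, g_h) = (0.425, 2.8)$, produced by a
  subcritical-Hopf/homoclinic fast–slow mechanism with
  $m_{\mathrm{NaP}}$ and $h_{\mathrm{Kas}}$ slow;
* a subthreshold focus in the theta range below the $I_{\mathrm{app}}$
  fold.

Two further structural choices are flagged in the file header rather than
guessed silently: the h current is given a single gating component, and the
AHP open fraction enters its current with exponent 1.

**What this means for quantitative checks.**  Everything that depends only
on the machinery — integrator contracts, the cluster statistic, taper
construction, continuation against closed-form oracles, map Lyapunov
oracles — is kinetics-independent and tested in the unit suite.  Every
*printed number* of the original study (bifurcation landmarks, the
slow-reduction line, spectral peaks, clustering levels) is contingent on
the reconstructed kinetics; those comparisons live in
`tests/testthat/test-acceptance.R` and in `scripts/acceptance.R`, and a
failure there documents a quantitative departure of the reconstruction, not
a software defect.  Known departures, measured by the acceptance suite
itself: the reconstruction has **no bistability window** between a
homoclinic and the fold (the spiking orbit is destroyed essentially at the
saddle-node, with the inter-burst interval diverging as the boundary is
approached — an infinite-period boundary rather than a homoclinic below the
fold); the tonic→period-2→chaos→period-5 route along decreasing $g_h$ at
$g_{\mathrm{AHP}} = 1.2$ is absent (at that row the attractor stays tonic),
while an analogous period-adding structure (3 → 5 → 4 → higher periods)
exists along increasing $g_{\mathrm{AHP}}$ at $g_h = 2.8$; the high-drive
Hopf, the focus frequency and the slow-line coefficients differ from the
printed values.  None of these was tuned toward the printed numbers: the
kinetics were frozen against the qualitative structure above and the
quantitative checks report what follows.

## Integration

Two integrators share one event convention (upward crossing of the spike
threshold, located by interpolation, with a 1 ms refractory guard against
threshold chatter — action-potential width far exceeds the step size):

* **Stochastic Heun** (`integrate_stochastic()`), fixed step
  $\Delta t = 0.01$ ms by default.  The Wiener increment
  $(\sigma/C)\sqrt{\Delta t}\,\mathcal N(0,1)$ enters the voltage equation
  only and the *same* increment is used in the predictor and the corrector
  — the standard stochastic Heun contract for additive noise.  Whether the
  corrector should redraw the noise is ambiguous in many descriptions; the
  single-increment convention is adopted and tested (at $\sigma = 0$ the
  scheme coincides bitwise with deterministic Heun, and on a
  conductance-free membrane it reproduces the Wiener variance law).
* **Adaptive Dormand–Prince 5(4)** (`integrate_deterministic(adaptive =
  TRUE)` and all orbit work), with relative/absolute tolerance $10^{-12}$
  for orbit precision and event times refined by bisection on sub-steps.

For batch sweeps the voltage-dependent rates are pre-tabulated on a
0.02 mV grid inside the compiled kernel (linear interpolation; relative
error near $10^{-9}$); precision work always evaluates the rate
expressions exactly.  Gating fractions are clamped to $[0,1]$ after each
step as a numerical guard — the exact flow cannot leave the box, a
second-order step can overshoot by a rounding-level amount.

Initial conditions: unless given, simulations start at the AHP-free
subthreshold equilibrium with the AHP gate at zero; beyond the fold, where
no such equilibrium exists, they start from $V = -65$ mV with
voltage-local steady-state gates.  Statistics discard a 1 s burn-in.
Every stochastic run takes a mandatory seed; sweeps derive per-replicate
seeds deterministically from a base seed.

## The clustering statistic

A cluster is two or more spikes with every internal inter-spike interval
strictly below 250 ms, preceded and followed by quiescence strictly above
300 ms.  $P_C$ is the fraction of spikes that belong to clusters.  Three
conventions are documented choices: recording edges count as quiescence
(otherwise every finite trace would discard its first and last clusters);
gaps in $[250, 300]$ ms neither chain spikes nor count as quiescence, so
runs flanked by them are unclustered — this is precisely the mechanism by
which $P_C$ collapses when noise stretches tonic intervals into that band;
and a train with a single spike has $P_C = 0$ while an empty train has
undefined $P_C$ (excluded from ensemble means).  Note that tonic firing
with intervals under 250 ms forms a single all-spike cluster with
$P_C = 1$ by construction.

Deterministic regimes are labelled from the same interval rule: `SS` (no
spikes), `T` (intervals within 1%), an integer $n$ (constant spikes per
burst), or `C` (varying burst sizes).  Because the rule chains at 250 ms,
a periodic orbit whose *internal* intervals exceed 250 ms is labelled `C`
even though its return map is periodic; the return-map period, not the
label, is authoritative for bifurcation work.

## Equilibria and continuation

With the AHP removed (it is spike-driven and decays to zero without
spikes), every gating variable sits at $x^*(V) = \alpha/(\alpha+\beta)$ at
an equilibrium, so the equilibrium condition collapses to a scalar current
balance $F(V) = I_{\mathrm{app}} - \sum_X I_X(V, x^*(V)) = 0$.
`find_equilibria()` brackets sign changes on a voltage grid and polishes
each root to $\|F\|_\infty < 10^{-10}$; stability comes from a central
finite-difference Jacobian (step $10^{-6}\max(1,|y_i|)$) of the reduced
system.  For a focus, the resonant frequency is $|\mathrm{Im}\,\lambda| /
2\pi$ converted to Hz.

Because $F$ is affine in $I_{\mathrm{app}}$ and in every maximal
conductance, the continuation branch in those parameters has an *explicit*
parameterisation by voltage: folds are extrema of the closed-form
$p(V)$ curve (localised far below the $10^{-4}$ requirement) and Hopf
points are zero crossings of the leading complex pair's real part along
the branch.  This replaces pseudo-arclength stepping wholesale — there is
nothing to continue when the branch is available in closed form — and is
verified against an independent closed-form fold oracle on a two-variable
toy system.  Continuation in $g_{\mathrm{AHP}}$ is a flat branch by
construction (the reduced system contains no AHP current); the
$g_h$-fold's independence of $g_{\mathrm{AHP}}$ is likewise structural,
and is asserted bitwise in the tests.

## Return maps, orbits and chaos diagnostics

The Poincaré section is the spike-threshold surface $V = 0$ — exactly
where the AHP clock resets, which is where the non-smoothness lives.
Since the clock is zero immediately after every crossing, the return map
acts on the gating vector alone; the incoming inter-spike interval is
recorded as a diagnostic but is not a map coordinate.  (This is a
deliberate economy: a coordinate that is identically reset carries no
forward information.)

Periodic orbits are found by Picard iteration: each new crossing is
compared against past crossings (rolling window of 500) and an orbit of
period $n$ is declared when the Euclidean distance between crossings $k$
and $k+n$ falls below $10^{-12}$; because the integrated map is
deterministic, a stable orbit contracts to the numerical fixed point and
the criterion is reached exactly, typically within tens of crossings.
Non-convergence yields an explicit aperiodic/chaotic candidate distinct
from quiescence.  The map Jacobian about an orbit is built from central
finite differences of the $n$-fold map (step $10^{-6}\max(1,|x_i|)$);
multipliers are its eigenvalues, and the orbit is stable iff all lie
strictly inside the unit circle.  Map Lyapunov exponents accumulate QR
factorisations of per-iterate finite-difference Jacobians along the
crossing sequence; the implementation is verified against the logistic map
at $r = 4$ (exponent $\ln 2$) and linear-map oracles.

Flip (period-doubling / spike-adding) bifurcations are localised by
bisection on the attractor's integer period; homoclinic-type orbit
destruction by bisection on orbit existence, with the trajectory continued
from the spiking side so the orbit rather than a coexisting rest state is
tracked, and with period divergence at the boundary as the diagnostic.
Two conventions matter: a trajectory counts as spiking if its crossing
gaps stay below `gap_max` (default 8 s — near an infinite-period boundary
the gap diverges, so this cap bounds how close to the boundary existence
can be certified), and two-parameter bifurcation curves are assembled from
one-parameter slices, not curve continuation — appropriate for a
non-smooth system.

## Fast–slow analysis

On the bursting orbit the gating variables are ranked by total variation
per burst cycle normalised by range; the two slowest are
$m_{\mathrm{NaP}}$ and $h_{\mathrm{Kas}}$ (asserted, not assumed: if the
ranking ever disagreed, the tests fail loudly).  Freezing them leaves the
fast subsystem.  Its equilibrium condition is again scalar *and affine in
the frozen* $m_{\mathrm{NaP}}$ — also along the collapsed one-dimensional
slow line $h_{\mathrm{Kas}} = a\,m_{\mathrm{slow}} + b$ fitted by ordinary
least squares over one burst period — so fast-subsystem branches are
explicit too.  Subcritical Hopf points (SCH) come from eigenvalue
crossings with the AHP gate clamped to zero on quiescent branches; the
stable periodic branch is swept by direct integration with the AHP active
and driven by the fast subsystem's own spikes (a documented convention:
the AHP decays within a burst and belongs to the fast time scale), and its
homoclinic end (HC) is localised by existence bisection.  Unstable
periodic-orbit fine structure is not computed and is reported as
unavailable.

The burster classification check walks the full orbit against the SCH and
HC curves in the slow plane: burst onset where the slow trajectory crosses
SCH from the stable side, offset at HC, and the inter-burst segment
tracking the fast equilibrium branch within 2 mV; crossing tolerance 0.01
in slow units.  All three together support the subcritical-Hopf/homoclinic
label.

## Spectral analysis

Subthreshold spectra use multitaper estimation with 9 DPSS tapers at
time–bandwidth product 5.  The tapers are computed from the symmetric
tridiagonal commuting matrix (Sturm bisection for the leading eigenvalues,
inverse iteration for eigenvectors) — exact to machine precision and free
of large dense eigenproblems.  Densities are one-sided and calibrated so
the integral over frequency equals the variance (checked to 5%).  Traces
are decimated to 1 kHz through a windowed-sinc anti-alias filter before
spectral work (the 100 kHz integration rate is wasteful; Nyquist 500 Hz
covers the 1–300 Hz broadband).  Documented choices with no stated
counterpart in the source description: spectrogram windows of 2 s with 50%
overlap, and a peak is "dominant" when the in-band maximum exceeds twice
the in-band median.  The theta spectral ratio is trapezoidal theta-band
(4–12 Hz) power over broadband (1–300 Hz) power; band powers are
width-normalised over delta/theta/beta/gamma.

## Sweeps and concordance

`run_pc_sweep()` / `run_regime_sweep()` cover a $(g_{\mathrm{AHP}}, g_h)$
grid (default 11×11 coarse mode; the published-resolution 41×41 grid is a
long-running documented script, not a test).  Per-point failures are
recorded and skipped, not fatal.  The deterministic–stochastic concordance
is a Pearson correlation of spikes-per-cluster; **both** sides are encoded
with the same cluster rule (tonic = one all-spike cluster; quiescent = 0)
— a deliberate departure from encoding tonic deterministic points as 1,
since the stochastic side of a tonic cell measures the all-spike cluster
and the correlation would otherwise compare incommensurable quantities.
The experimental reference values $P_{C,\mathrm{WT}} = 0.69$ and
$P_{C,\mathrm{TG}} = 0.37$ ship as constants (`pc_reference`) for
distance maps; they are inputs, never outputs.

The subthreshold $I_{\mathrm{app}}$ sweep uses the published low-noise
setting $\sigma/C = 0.005$; replicates that spike are excluded and a level
is flagged when more than 10% of its replicates do.

## Known limitations

* All quantitative landmark comparisons inherit the kinetics
  reconstruction's uncertainty; see above for the measured departures.
* The slow time constants ($\tau_{m\mathrm{NaP}}$ voltage-dependent around
  150–1100 ms, $\tau_{h\mathrm{Kas}} = 600$ ms) are functional choices
  that produce the stated burst cadence, not measured values.
* Chaos has not been confirmed in the reconstruction (Picard converges to
  high-period orbits where irregular firing is seen); the chaos
  diagnostics themselves are oracle-verified.
* The Kruskal–Wallis convenience test across $I_{\mathrm{app}}$ groups is
  out of scope, as are network/phase-amplitude-coupling extensions and any
  fitting to experimental recordings.
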