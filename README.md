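# stellate

Simulation and bifurcation analysis of a conductance-based model of layer
II medial entorhinal cortex stellate cells (mEC-SCs).

mEC-SCs fire action potentials in *clusters* — groups of spikes separated
by long quiescent gaps — and generate subthreshold membrane-potential
fluctuations with peak power in the theta band (4–12 Hz).  Both features
degrade in rodent models of tau-pathology dementia, which makes a
controllable single-cell model of clustering a useful tool.  This package
implements such a model and the analysis apparatus around it:

* a single-compartment membrane equation
  `C dV/dt = Iapp − ΣX gX ψX (V − EX) + σ η(t)` with Hodgkin–Huxley-type
  gating (`dx/dt = αx(V)(1−x) − βx(V) x`) for transient/persistent sodium,
  delayed-rectifier and A-type potassium, and h currents, plus a
  spike-triggered AHP current whose opening rate
  `α(t) = 1.5 exp(−(t − tspike)/60)` decays from the last spike time — the
  model's one non-smooth ingredient;
* deterministic and stochastic (Heun, additive voltage noise) integration
  with spike-event interpolation, in compiled code;
* the clustering statistic `P_C` (fraction of spikes in clusters: ≥ 2
  spikes with inter-spike intervals < 250 ms flanked by > 300 ms
  quiescence);
* equilibrium continuation with saddle-node and Hopf detection, via an
  explicit voltage parameterisation of the AHP-free branch;
* Poincaré return-map machinery on the section V = 0: periodic orbits by
  Picard iteration (closure 1e-12), map Jacobians and Floquet multipliers,
  map Lyapunov exponents (QR), flip and homoclinic localisation by
  bisection;
* fast–slow decomposition (slow variables mNaP, hKas), fast-subsystem
  bifurcation diagrams, the one-dimensional slow reduction, and the
  subcritical-Hopf/homoclinic burster verification;
* multitaper (9 DPSS tapers, NW = 5) spectral analysis: power spectra,
  spectrograms, peak frequency, theta spectral ratio, band powers;
* reproducible parameter sweeps: stochastic `P_C` heatmaps, deterministic
  regime maps, deterministic–stochastic concordance, distance-to-reference
  maps, and a subthreshold `Iapp` sweep.

The voltage-dependent rate functions of the six standard channels are a
**documented reconstruction** (`inst/extdata/kinetics_default.ini`): the
original model delegates them to an earlier stellate-cell model that is not
redistributable here.  See the file header and the vignette
(`vignettes/stellate-methods.Rmd`) for what was constrained and which
quantitative landmarks are contingent on it.

## Worked example

Simulate 20 s of the stochastic model at the standard operating point
(`gh = 2.8`, `gAHP = 0.425`, `σ/C = 0.135`), partition the spike train
with the cluster rule, and locate the saddle-node of the AHP-free rest
state in `gh`:

```r
library(stellate)
p <- model_params()                      # standard parameter table

tr <- integrate_stochastic(p, duration = 20000, seed = 7, burn_in = 1000)
part <- partition_clusters(detect_spikes(tr))
part
#> <cluster_partition>  34 spikes, 8 clusters, P_C = 0.6176
#>   spikes per cluster: 3 3 3 3 3 2 2 2

continue_branch(p, "gh", c(1, 4))
#> <equilibrium_branch> in gh: 89 points, 1 fold(s), 0 Hopf point(s)
#>   fold: gh = 2.75251 at V = -58.3041 mV (min |eig| 7.9e-10)
```

The cell fires mostly three-spike clusters (`P_C = 0.62` here: 21 of 34
spikes sit in clusters of ≥ 2 — the model's noise-perturbed rendition of
its deterministic three-spike burst), and the rest state is destroyed in a
fold just below the operating value `gh = 2.8`, which is why the cell
fires at all.  The deterministic skeleton behind the clusters:

```r
orb <- find_periodic_orbit(p)
orb
#> <return_map_orbit>  period 3, closure 1.01e-14, ISIs 1735.9 191.5 233.1 ms
map_jacobian(orb)$multipliers[1]
#> [1] 0.03345132+0i        # strongly stable burst orbit
```

and the subthreshold resonance below the `Iapp` fold:

```r
eq <- find_equilibria(set_params(p, Iapp = 0.25))
focus_frequency(attr(eq[[1]], "eigenvalues"))
#> [1] 11.93527             # Hz; a focus at the upper edge of the theta band
```

A thin command-line front end over the same functions ships in
`inst/cli/stellate.R` (`simulate`, `pc`, `continue`, `orbit`, `spectrum`,
`sweep-pc`, `sweep-regime`, `sweep-iapp`, `refmap`, `fastslow`).

## Acceptance script

`scripts/acceptance.R` recomputes the package's headline quantities from
scratch against the installed package — equilibrium continuation for the
fold/Hopf landmarks, orbit-existence bisection for the spiking-orbit
boundaries, the focus frequency at the subthreshold operating point,
seeded stochastic ensembles for the spectral peak and clustering
statistics, the slow-reduction fit, and the deterministic–stochastic
concordance on a coarse grid — and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

All randomness derives from `--seed`.  Runtime is dominated by the
stochastic sweeps (a few minutes on one CPU).
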