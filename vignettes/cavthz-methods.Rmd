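---
title: "Modeling confined Ca2+ dynamics and THz resonance in the CavAb selectivity filter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling confined Ca2+ dynamics and THz resonance in the CavAb selectivity filter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The physical model

`cavthz` models the axial (permeation-direction) dynamics of Ca^2+^ ions
confined in the selectivity filter (SF) of the bacterial voltage-gated
calcium channel CavAb. The SF is reduced to a one-dimensional effective
energy landscape along the pore axis `z` (in angstrom, increasing toward the
extracellular side): radial motion is frozen out, which is appropriate for a
narrow filter whose binding chemistry is dominated by the EEEE glutamate
locus. The landscape is built from:

* **Two EEEE charge rings** of four point charges of $-1.3\times10^{-19}$ C
  each, at the binding-site planes $z = 14$ Å (S1) and $z = 18$ Å (S2),
  at a radial distance `ring_radius` from the axis.
* **Four mouth dipoles** (partial charges $\pm 0.6\times10^{-19}$ C) near
  $z = -17$ Å, which generate the shallow intracellular-vestibule well that
  guides exiting ions.
* **A dielectric self-energy barrier** $U_{\mathrm{pol}}(z)$, a Gaussian
  bump centered inside the filter. An ion in the narrow, low-permittivity
  filter carries a Born self-energy penalty relative to bulk water; the
  closed form of this correction lives in continuum-electrostatics
  calculations we do not repeat here, so the package represents it as a
  smooth parameterized bump whose amplitude, center and width are fixed by
  calibration (below).
* **Confining walls**: steep order-10 power-law walls at the ends of the
  simulation domain ($z = \pm 40$ Å) only; the force is identically zero
  inside the pore.
* **A linear transmembrane-voltage ramp** across $z \in [-40, 25]$ Å,
  giving each ion the energy $qV\varphi(z)$ with $\varphi$ running 0 to 1
  across the membrane — the standard Brownian-dynamics treatment.

Two screening choices deserve emphasis because they are *structural*
decisions of this package, made on physical grounds and documented here:

1. **Ion–fixed-charge screening.** The ring/dipole Coulomb terms are scaled
   by `1/eps_channel` and additionally attenuated by
   $e^{-r/\lambda_{\mathrm{fix}}}$ with `fixed_screening` $\lambda_{\mathrm{fix}} = 8$ Å.
   Without this attenuation a bare Coulomb tail at protein-like permittivity
   binds ions by several eV across the *entire* pore and reservoirs, and no
   ion can ever leave the filter at physical voltages — permeation becomes
   impossible, contradicting the measurable single-channel currents the
   model is meant to reproduce. Physically the attenuation stands for the
   reaction field of the high-permittivity pore water and bulk reservoirs,
   which confines the electrostatic reach of the EEEE locus to the filter
   neighborhood; 8 Å (a few water layers) is a structural choice, not a
   fitted value — the filter observables do not constrain it.
2. **Ion–ion screening.** The ion–ion repulsion is
   $U(r) = k_e q^2 e^{-r/\lambda}/(\varepsilon_{ii} r)$ with
   $\varepsilon_{ii} = 1$ and a calibrated screening length
   $\lambda \approx 1.88$ Å. An *unscreened* pair term cannot reproduce the
   observed pair dynamics: the out-of-phase/in-phase mode-frequency ratio
   fixes the pair coupling stiffness $k_c = U''(d) \approx 7$ N/m at the
   equilibrium separation $d \approx 5.1$ Å, while the mean positions fix
   the holding force $U'(d)$; for a $1/r$ potential these two are locked
   together ($U'' = 2U'/r$) and are mutually inconsistent with wells soft
   enough to oscillate at 1.65 THz. The exponential factor decouples the
   two ($U'' \approx U'/\lambda$), exactly what induced polarization
   screening between two cations in a polarizable confined medium provides.

## Langevin dynamics

Each ion follows $m\ddot z = F_{\mathrm{cons}} - \gamma\dot z + \xi(t)
[+\,qE_z(t)]$, integrated with the BAOAB splitting (half kick, half drift,
*exact* Ornstein–Uhlenbeck velocity refresh with factor
$e^{-(\gamma/m)\Delta t}$, half drift, half kick) at $\Delta t = 2.5$ fs and
310 K. BAOAB is used for its superior configurational accuracy at this step
size; the integrator's equipartition, Maxwell–Boltzmann and free-diffusion
properties are verified in the test suite.

The damping rate is `gamma_rate` $= \gamma/m = 10^{12}\,\mathrm{s^{-1}}$,
giving the collective modes a quality factor of about 10 so that the 1.65
and 2.84 THz peaks are spectrally resolvable. A bulk-diffusion estimate for
Ca^2+^ ($D \approx 0.8\times10^{-9}\,\mathrm{m^2/s}$) would imply
$\gamma/m \approx 8\times10^{13}\,\mathrm{s^{-1}}$, which overdamps the
modes entirely; the smaller value is therefore an effective, deliberately
underdamped choice exposed in the configuration, and absolute time scales
(diffusive transport rates in particular) inherit this convention.

Ions start at the static two-ion equilibrium with Maxwell–Boltzmann
velocities; 20 ps of equilibration are discarded. The THz drive
$E_z(t) = E_0\sin(2\pi f (t-t_0))$ switches on abruptly at $t_0$ (default
200 ps) with phase 0. Permeation runs use three ions, $-400$ mV, and a reset
boundary: an ion crossing $z = -25$ Å is relocated uniformly into the
extracellular reservoir $z \in [25, 40]$ Å with a fresh thermal velocity,
keeping the ion count constant; the reinserted particle keeps its index.

## Calibration

The full derivation of the reference energy landscape is not available, so
the package *calibrates* its parameterized landscape
(`calibrate_channel()`) against the reported observables of the confined
pair: in-phase/out-of-phase mode frequencies 1.65/2.84 THz, two-ion
mean positions 13.1/18.2 Å, and a 0.63 eV static inter-site barrier. The
calibration is purely static (equilibrium positions by quasi-Newton descent,
mode frequencies from the analytic-force Hessian, barrier from a profile
scan) and uses Nelder–Mead on six log-scaled parameters. The shipped
defaults (`inst/extdata/cavab_calibrated.yaml`) achieve modes 1.656/2.831
THz, equilibrium 13.15/18.27 Å and a 0.631 eV barrier.

With those parameters fixed once, the dynamical pipeline *emergently*
reproduces, with no further adjustment: acceleration-spectrum peaks at
≈1.65/2.80 THz; a single 2.80 THz peak in the inter-ion distance spectrum;
replicate-mean magnitude-squared coherence ≈0.99/0.96 at the two modes;
a radiative coherence enhancement factor ≈1.92 at the in-phase mode;
center-of-mass resonance (≈3.9× amplitude growth at 1.65 THz, none at
10 THz); a driven steady-state barrier ≈0.32 eV under the resonant 0.3 V/nm
field; PMF-derived quantum transitions ≈1.6–1.7/2.6–2.7 THz with the
correct CQHO mode fingerprints; and a resonance-gated permeation
enhancement (mean ≈3 events per 60 ns at 3 V/nm and 1.65 THz versus 0 for
control and 10 THz runs). One reported quantity is *not* reproduced: the
enhancement factor at the out-of-phase mode comes out ≈0.03 rather than
≈0.12 — our calibrated pair is more perfectly anti-correlated at 2.84 THz
than the reference one. The value rises with stronger damping or coarser
spectral bins, but both are pinned by the declared conventions above, so we
report the discrepancy rather than retune. Absolute permeation rates in the
control condition (0 observed vs 0.40 reported per 60 ns) are likewise
calibration-limited: thermal knock-on escape over the deep calibrated wells
is slower than in the reference model, while the resonance-driven
enhancement — the effect under study — is robust.

## Spectral and coherence estimators

Amplitude spectra are one-sided FFTs of mean-removed signals; figure-style
curves are Gaussian-smoothed (σ = 0.05 THz, truncated-kernel renormalized
at the edges). Cross- and auto-spectral densities behind the
magnitude-squared coherence (MSC) and the coherence enhancement factor use
Welch's method: Hann window, 50% overlap, nominal segment count 16 (i.e.,
segment length = duration/16; about 31 averaged segments). At least two
segments are required — the MSC of a single unaveraged segment is
identically 1 — and the estimator's small-sample bias is about
1/(number of segments), a property the tests check on independent noise.
The enhancement factor $\alpha = S_{\mathrm{coh}}/S_{\mathrm{incoh}}$ is
only defined where $S_{\mathrm{incoh}}$ exceeds a relative noise floor
($10^{-9}$ of its peak), and "the value at a mode" means the value at the
incoherent-power peak bin within ±0.12 THz of the nominal frequency (for
MSC, the maximum within ±0.1 THz).

## PMFs and the sampling ceiling

PMFs are Boltzmann inversions $U = -k_BT\ln P$ of position histograms
(1D bin width 0.1 Å; 2D displacement bins 0.02 Å over ±0.8–1 Å), shifted to
zero at the occupied minimum. Empty bins are masked, never extrapolated,
and a barrier whose path crosses masked bins is reported as a *censored
lower bound* with a warning. This matters quantitatively: direct sampling
can only resolve free energies up to roughly $k_BT\ln(\text{peak bin
count})$ — about 0.3 eV at $10^6$ samples — so a 0.63 eV (24 $k_BT$)
equilibrium barrier is unreachable by histogramming any feasible
trajectory. The no-field barrier is therefore a property of the calibrated
static landscape (that is also how the calibration constraint is phrased),
while the driven-field barriers are time-averaged steady-state density
inversions — not equilibrium free energies — measured from 3 × 12 ns driven
runs whose large resonant oscillations do sample the inter-site region.

A note on units: at 310 K, $k_BT = 0.0267$ eV, so 0.3 eV is 11.2 $k_BT$ and
0.63 eV is 23.6 $k_BT$. Reported conversions for these quantities (14.6
and 32.3 $k_BT$) are mutually inconsistent with any single temperature;
the package always reports both units computed independently from the run
temperature.

## Quantum analysis

The equilibrium two-ion displacement PMF becomes the potential of a
two-coordinate Hamiltonian $\hat H = -\frac{\hbar^2}{2m}\left(
\partial^2_{z_1} + \partial^2_{z_2}\right) + U(z_1, z_2)$ with the
single-ion Ca^2+^ mass on each coordinate. It is discretized by 5-point
central differences on the PMF's native 0.02 Å mesh (masked bins filled
with a plateau at $U_{\max} + 0.1$ eV, Dirichlet boundaries) and the lowest
eigenpairs are found by shift-invert Lanczos (ARPACK through
`igraph::arpack()` on the sparse Cholesky-factored operator, with a dense
fallback for small grids). Eigenvalue convergence under mesh refinement and
the exact $(n+1)hf$ ladder of the isotropic 2D oscillator are test-verified
to <0.5% and <1%. The ground-state width at 1.65 THz is
$\sqrt{\hbar/m\omega} \approx 0.12$ Å, comfortably resolved by the mesh.

States are labeled by their density overlap $\int\sqrt{\rho\,\rho_{\rm ref}}$
against the analytic coupled-quantum-harmonic-oscillator (CQHO) reference —
the separable oscillator in rotated coordinates $s = (\Delta z_1+\Delta
z_2)/\sqrt2$ (1.65 THz) and $a = (\Delta z_1-\Delta z_2)/\sqrt2$ (2.84 THz),
with Hermite–Gaussian eigenstates and energies
$E = hf_{\rm in}(n_s{+}\tfrac12) + hf_{\rm out}(n_a{+}\tfrac12)$. A state is
"in-phase" when $(n_s>0, n_a=0)$, "out-of-phase" when $(n_s=0, n_a>0)$,
otherwise mixed; overlaps below 0.5 are flagged. The package reports these
numbers as properties of the model landscape and makes no claim about
physical quantum coherence at 310 K.

## Rare-event statistics

Permeation counts over equal exposures are compared with the exact
conditional test: given totals $c_1, c_2$, under equal rates
$c_1 \sim \mathrm{Bin}(c_1{+}c_2, \tfrac12)$, and the two-sided p-value is
the doubled smaller tail, capped at 1 (the doubled-tail convention is the
one consistent with both reported p-values, 344/262144 ≈ 0.0013 and
2·22/64 = 0.6875). Effect sizes are rate ratios with exact Clopper–Pearson
intervals obtained by Beta-quantile inversion of the conditional proportion
and mapped to the RR scale; a zero denominator gives an infinite upper
bound. Bootstrap CIs of mean counts are seeded 10 000-resample percentile
intervals. Where only a mean and SD of five counts are reported, the
integer count vector is recovered by exhaustive search
(`counts_from_summary()`); mean 0.40/SD 0.55 is uniquely (0,0,0,1,1).
Currents follow $I = \bar n q/T$; the reported current/conductance values
correspond to rounding $2e$ to $3.2\times10^{-19}$ C, so functions accept
the charge as an argument (default: exact $2e$).

## What the synthetic fixtures do and do not emulate

The fixtures generate the *statistical skeleton* each analysis stage
assumes: `oscillator_pair()` two-tone coherent signal pairs (in-phase power
at $f_{\rm in}$, anti-phase at $f_{\rm out}$, optional integrated white
noise) with default acceleration amplitudes of $10^{14}\,\mathrm{m/s^2}$
(sub-angstrom THz displacements, the confined-ion scale);
`gaussian2d()`/`cov_from_modes()` exact Gaussian equilibrium densities whose
quadratic PMF has prescribed mode frequencies; `double_well()` analytic
barrier landscapes; `poisson_counts()` i.i.d. event counts. They are
deterministic per seed. They do *not* emulate anharmonicity, mode coupling,
drive-induced nonstationarity, or knock-on correlations — so fixture-level
passes validate the estimators, while claims about the channel itself rest
on the calibrated simulator.

## Numerical choices and problem sizes

* Coulomb singularities are clamped at 0.5 Å (energies capped, pair force
  held at its clamp-radius value); force-gradient consistency holds to
  $10^{-6}$ relative outside clamp zones.
* Equilibrium analyses use 3 × 400 ps replicates at 2.5 fs (160 000 samples
  each, stride 1); driven-PMF runs 3 × 12 ns (stride 5); permeation runs
  5 × 60 ns per condition (events only). These lengths were chosen so each
  estimate's sampling error is well inside the tolerances quoted above
  while the whole pipeline remains a few CPU-minutes.
* Replicate $r$ of a multi-run call uses seed $\mathrm{base}+r-1$; every
  stochastic function takes an explicit seed.
* PMF well location uses a 0.02–0.05 eV prominence filter against
  histogram noise; peak finding keeps the taller of two peaks closer than
  the minimum separation.

## Known limitations

* The landscape is an effective 1D model: no explicit water, no radial
  dynamics, no protein flexibility; all screening is captured by four
  scalar dielectric parameters.
* Absolute permeation rates are exponentially sensitive to well depths and
  are not calibrated — only the resonance *enhancement* is reproduced.
* The out-of-phase coherence enhancement factor under-shoots the reported
  value (≈0.03 vs ≈0.12), as discussed under Calibration.
* Driven-field PMFs are steady-state density inversions; their "barriers"
  are descriptive, not thermodynamic.
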