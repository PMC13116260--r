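# cavthz

Langevin dynamics and coherence analysis of Ca²⁺ ions confined in the
selectivity filter of the bacterial voltage-gated calcium channel CavAb,
with terahertz-field driving, spectral coherence estimators,
potential-of-mean-force construction, a two-ion Schrödinger eigensolver,
and exact Poisson inference for rare permeation events.

## The problem

The CavAb selectivity filter binds a pair of Ca²⁺ ions at two sites formed
by the EEEE glutamate locus (z = 14 and 18 Å along the pore axis). The
confined pair is a coupled oscillator system with two collective modes: an
in-phase mode near 1.65 THz and an out-of-phase mode near 2.84 THz. A
z-directed THz field tuned to the in-phase mode resonantly pumps the pair's
collective motion, lowers the effective barrier between the binding sites,
and enhances knock-on permeation under a transmembrane voltage, while an
off-resonant field does not. `cavthz` is a tested, configurable
implementation of that entire computational study, aimed at ion-channel
biophysicists and bio-electromagnetics modelers.

Each ion's axial coordinate follows the Langevin equation

    m z̈ = F_cons(z) − γ ż + ξ(t) + q E_z(t),

where `F_cons` derives from an effective electrostatic landscape (EEEE
rings, mouth dipoles, dielectric self-energy, confining walls, voltage
ramp, screened ion–ion Coulomb repulsion), `γ` is an axial damping rate,
`ξ` thermal noise at 310 K, and `E_z(t)` an optional THz drive. Integration
uses the BAOAB splitting at 2.5 fs. Analyses include FFT amplitude spectra,
Welch magnitude-squared coherence `C₁₂ = |P₁₂|²/(P₁₁P₂₂)`, the radiative
coherence enhancement factor `α = S_coh/S_incoh` (2 = in-phase,
1 = uncorrelated, 0 = anti-phase), Boltzmann-inversion PMFs
`U = −k_BT ln P`, the two-ion Schrödinger equation on the equilibrium 2D
PMF with coupled-quantum-harmonic-oscillator mode fingerprints, and exact
conditional-binomial Poisson tests with Clopper–Pearson rate-ratio CIs.
The landscape parameters are calibrated (`calibrate_channel()`) against the
collective-mode observables; the shipped defaults are the calibrated set.
See the methods vignette (`vignettes/cavthz-methods.Rmd`) for the model,
its assumptions, and its limitations.

## Worked example

```r
library(cavthz)

ch <- channel_model()          # calibrated CavAb landscape
summary(ch)
#> Equivalent CavAb channel model (axial Langevin force field)
#>   SF span 10..20 A, sites S1/S2 at z = 14/18 A, exit at -25 A
#>   EEEE rings: 4 x -1.3e-19 C at radius 5.69 A; dipoles: 4 x 6e-20 C at z = -17 A
#>   eps_channel = 1.68, eps_ion_ion = 1, screening length = 1.88 A
#>   self-energy bump: 1.5 eV at z = 15.5 A (width 0.909 A)
#>   ion: m = 6.636e-26 kg, q = 3.204e-19 C, gamma/m = 1e+12 1/s; T = 310 K
#>   two-ion equilibrium: z = 13.14, 18.27 A
#>   collective modes: 1.656 THz (in-phase), 2.831 THz (out-of-phase)
#>   single-ion SF wells at z = 13.80, 17.40 A
#>   static inter-site barrier: 0.631 eV

tr <- simulate(ch, seed = 7, duration = 400e-12)   # 400 ps equilibrium run
sp <- acceleration_spectrum(tr, ion = 1)
find_peaks(sp, prominence = max(sp$smooth) / 8, min_sep = 0.3)
#>   frequency      height
#> 1    2.8100 3.80044e+14
#> 2    1.6475 1.81641e+14

c(spectrum_at(msc(tr), 1.65), spectrum_at(msc(tr), 2.84))
#> [1] 0.986 0.973
```

The two acceleration-spectrum peaks are the collective modes; the
magnitude-squared coherence near 1 at both confirms the phase-locked pair.
Rare-event inference on permeation counts (totals over five 60 ns runs,
resonant 16 vs control 2):

```r
rate_ratio_ci(16, 2)
#> Rate ratio 8 (counts 16 vs 2), 95% CI [1.88, 71.72]
#>   exact Poisson test (two-sided conditional binomial): p = 0.001312
```

The rate ratio of 8 with a CI excluding 1 and p ≈ 0.0013 quantifies the
statistically significant resonant enhancement of Ca²⁺ flux.

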