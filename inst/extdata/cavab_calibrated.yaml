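# Calibrated default parameters of the equivalent CavAb channel model.
# Produced by calibrate_channel() against the static targets:
#   in-phase / out-of-phase collective modes 1.65 / 2.84 THz,
#   two-ion equilibrium positions 13.1 / 18.2 A,
#   static inter-site barrier 0.63 eV.
# Achieved: modes 1.656 / 2.831 THz, equilibrium 13.15 / 18.27 A,
# barrier 0.631 eV (single-ion landscape wells at 13.80 / 17.40 A).
# The fixed-charge screening length (reaction-field screening of the ring
# and dipole Coulomb terms by pore/bulk water) is a structural choice, not
# a fitted quantity; see the methods vignette.
ring_radius: 5.6869977
eps_channel: 1.6822128
eps_ion_ion: 1.0
screening_length: 1.8819756
fixed_screening: 8.0
pol_amplitude: 1.5022227
pol_center: 15.463942
pol_width: 0.9091728
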