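# Nuclide physical constants used by the dose engines.
# Values are standard nuclide-data constants, editable by the user.
#   half_life_days        : physical half-life
#   electron_energy_MeV   : mean energy emitted per decay as electrons
#                           (beta + conversion/Auger), the "non-penetrating"
#                           energy Delta_np of organ-level dosimetry
#   photon_energy_MeV     : mean energy emitted per decay as photons
lu177:
  half_life_days: 6.647
  electron_energy_MeV: 0.147
  photon_energy_MeV: 0.033
y90:
  half_life_days: 2.667
  electron_energy_MeV: 0.933
  photon_energy_MeV: 0.0
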