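# Electron-beam depth-dose anchors per nominal energy (MeV). Depths are mm
# water-equivalent, from the standard clinical rules of thumb
# (R90 ~ E/3.2 cm, R50 ~ E/2.33 cm, Rp ~ E/2 cm; R100 ~ 0.22E cm).
# `surface` is the entrance dose fraction, `tail` the bremsstrahlung level
# beyond the practical range. Replace with measured beam data to model a
# specific LINAC.
energies:
  "6":  {surface: 0.83,  r100: 13.2, r90: 18.8, r50: 25.8, rp: 30.0, tail: 0.011}
  "8":  {surface: 0.84,  r100: 17.6, r90: 25.0, r50: 34.3, rp: 40.0, tail: 0.013}
  "9":  {surface: 0.845, r100: 19.8, r90: 28.1, r50: 38.6, rp: 45.0, tail: 0.014}
  "10": {surface: 0.85,  r100: 22.0, r90: 31.2, r50: 42.9, rp: 50.0, tail: 0.015}
  "12": {surface: 0.86,  r100: 26.4, r90: 37.5, r50: 51.5, rp: 60.0, tail: 0.017}
# Lateral erf-edge penumbra: sigma = sigma0 + k_we * z_we + k_geo * z_geo
lateral:
  sigma0_mm: 2.5
  k_we: 0.08
  k_geo: 0.02
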