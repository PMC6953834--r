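# HU -> physical density (g/cm3) calibration, piecewise linear between
# knots, clamped at the ends. This two-segment table is a generic stand-in
# anchored at air (-1000 HU) and water (0 HU); replace the knots with a
# scanner-specific calibration where one is available.
knots:
  - [-1000, 0.00121]
  - [0, 1.000]
  - [1000, 1.59]
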