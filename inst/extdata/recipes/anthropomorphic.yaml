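# Anthropomorphic phantom surrogate: organ-shaped inserts are approximated by
# ellipsoids (kidneys, spleen, pancreas, liver) and a small sphere (lesion)
# of the published volumes, painted at organ-typical activity concentrations
# over a warm background. Positions are package choices.
name: anthropomorphic
background_MBq_per_ml: 0.03
inserts:
  - {name: Lesion,      kind: sphere,    volume_ml: 2.0,  concentration_MBq_per_ml: 8.34, center_mm: [60, 60, 40]}
  - {name: Pancreas,    kind: ellipsoid, volume_ml: 92,   concentration_MBq_per_ml: 0.99, center_mm: [0, 55, -20]}
  - {name: LeftKidney,  kind: ellipsoid, volume_ml: 142,  concentration_MBq_per_ml: 0.81, center_mm: [-60, -40, -40]}
  - {name: RightKidney, kind: ellipsoid, volume_ml: 142,  concentration_MBq_per_ml: 0.82, center_mm: [60, -40, -40]}
  - {name: Spleen,      kind: ellipsoid, volume_ml: 156,  concentration_MBq_per_ml: 1.10, center_mm: [-65, 40, 10]}
  - {name: Liver,       kind: ellipsoid, volume_ml: 1470, concentration_MBq_per_ml: 0.53, center_mm: [30, 20, 45]}
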