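# Geometric-insert phantom: toroidal, ellipsoidal, pear-shaped and tubular
# inserts, all filled at the same activity concentration in a cold water
# background. Insert names carry the equivalent sphere diameter in mm.
# Positions (mm, relative to grid centre) are package choices: the inserts
# only need to fit without overlap.
name: geometrical
background_MBq_per_ml: 0.0
inserts:
  - {name: To17a, kind: torus,     volume_ml: 2.8,  concentration_MBq_per_ml: 1.53, center_mm: [-55, -55, 0]}
  - {name: To26,  kind: torus,     volume_ml: 9.7,  concentration_MBq_per_ml: 1.53, center_mm: [55, -55, 0]}
  - {name: E20,   kind: ellipsoid, volume_ml: 4.1,  concentration_MBq_per_ml: 1.53, center_mm: [-55, 55, 0]}
  - {name: E30,   kind: ellipsoid, volume_ml: 14.8, concentration_MBq_per_ml: 1.53, center_mm: [0, 0, 0]}
  - {name: E38,   kind: ellipsoid, volume_ml: 28.5, concentration_MBq_per_ml: 1.53, center_mm: [55, 55, 0]}
  - {name: To17b, kind: torus,     volume_ml: 2.8,  concentration_MBq_per_ml: 1.53, center_mm: [-55, 0, 60]}
  - {name: P38,   kind: pear,      volume_ml: 29.2, concentration_MBq_per_ml: 1.53, center_mm: [55, 0, 55]}
  - {name: P39a,  kind: pear,      volume_ml: 30.1, concentration_MBq_per_ml: 1.53, center_mm: [0, -55, 55]}
  - {name: P39b,  kind: pear,      volume_ml: 31.2, concentration_MBq_per_ml: 1.53, center_mm: [0, 55, 55]}
  - {name: Tu38a, kind: tube,      volume_ml: 28.6, concentration_MBq_per_ml: 1.53, center_mm: [-40, -40, -65]}
  - {name: Tu38b, kind: tube,      volume_ml: 28.8, concentration_MBq_per_ml: 1.53, center_mm: [40, 40, -65]}
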