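# Homogeneous cylindrical phantom: one right cylinder filled uniformly.
name: cylindrical
background_MBq_per_ml: 0.0
inserts:
  - name: Cylinder
    kind: cylinder
    volume_ml: 5640
    concentration_MBq_per_ml: 0.25
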