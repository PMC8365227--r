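# Calibrated device preset registry.
#
# The source paper for the study design does not print strut/wire dimensions;
# wire and strut widths here are physically plausible published-order values
# for the three device families, and pitch / braid angle / max compaction
# factor are solved in closed form (scripts/calibrate_devices.R) so that the
# single-device metal coverage rate over the unrolled neck of the default
# geometry (4 mm parent artery) hits the study's measured single-device MCRs:
# Enterprise-like 7.0%, LVIS-like 20.4% (35.4% at max compaction),
# Pipeline-like 26.8% (47.8% at max compaction).  Multi-layer (overlapped)
# coverages are emergent, not calibrated.
enterprise:
  device_class: laser_cut
  strut_width_m: 9.0e-05
  axial_pitch_m: 3.57175508e-03
  circumferential_pitch_m: 3.57175508e-03
  target_mcr: 0.070
lvis:
  device_class: braided
  wire_diameter_m: 6.1e-05
  n_wires: 16
  braid_angle_deg: 68.88749839
  circumference_m: 1.25663706e-02
  max_compaction_factor: 1.91278854
  target_mcr: 0.204
  target_mcr_compacted: 0.354
pipeline:
  device_class: braided
  wire_diameter_m: 3.0e-05
  n_wires: 48
  braid_angle_deg: 66.62778931
  circumference_m: 1.25663706e-02
  max_compaction_factor: 2.04802262
  target_mcr: 0.268
  target_mcr_compacted: 0.478
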