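{
  "comment": "Published reference values used as regime anchors and for the mech report. Units noted per field.",
  "persistence_length_um": 0.39,
  "temperature_k": 295,
  "flexural_rigidity_nm2": 1.59e-27,
  "filament_radius_nm": 2.5,
  "young_modulus_filament_mpa": 51.8,
  "young_modulus_lipid_mpa": 22.9,
  "bending_modulus_kbt": 20,
  "k_lipid_pn_per_um": 0.34,
  "k_ftsz_pn_per_um": 0.59,
  "k_ratio": 1.72,
  "E_ratio": 2.26,
  "k_lipid_range_pn_per_um": [0.15, 0.59],
  "k_ftsz_range_pn_per_um": [0.23, 1.52],
  "k_ftsz_plus_lipid_mean_pn_per_um": 0.9,
  "trap_stiffness_pn_per_um": 74.4,
  "volts_per_um": 1.66,
  "drive_amplitude_um": 3,
  "drive_frequency_hz": 1,
  "qpd_rate_hz": 10000,
  "bead_diameter_um": 1.71,
  "tube_diameter_mean_um": 0.47,
  "ring_diameter_active_um": 0.44,
  "ring_diameter_low_gtpase_um": 0.89,
  "pitch_compressed_um": 1.6,
  "pitch_relaxed_um_min": 3.0,
  "pitch_difference_um": 2.0,
  "rings_per_um": 1.0,
  "per_ring_force_pn": 1.0,
  "gtpase_force_pn": 0.9,
  "vortex_speed_cone_nm_per_s": 43,
  "vortex_speed_flat_nm_per_s": 34,
  "roi_radius_um": 0.5,
  "morphology_active": {"deformed_with_neck": 21, "total": 26},
  "morphology_low_gtpase": {"deformed_with_neck": 4, "total": 15}
}
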