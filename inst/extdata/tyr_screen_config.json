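{
  "rmsd_regions": ["A:2-6", "A:238-245", "A:265-275"],
  "rmsf_regions": ["A:90-96", "A:131-137", "A:173-177"],
  "low_contact_regions": ["A:44-49"],
  "glycine_phi_table": "tyr_gly_phi.csv",
  "energy_tables": [
    {"path": "tyr_ala_scan.csv", "dialect": "csv"},
    {"path": "tyr_saturation.csv", "dialect": "csv"},
    {"path": "tyr_double_mutants.csv", "dialect": "csv"}
  ],
  "exclusions": [
    {"site": 53, "reason": "glycine directly beside the active site"},
    {"site": 38, "reason": "copper-binding histidine"},
    {"site": 191, "reason": "copper-binding histidine"},
    {"site": 195, "reason": "copper-binding histidine"},
    {"site": 216, "reason": "copper-binding histidine"},
    {"site": 217, "reason": "copper-binding histidine"}
  ],
  "seed": 1
}
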