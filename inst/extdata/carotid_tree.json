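{
  "format": "arterial-tree",
  "root_id": "CCA-1",
  "segments": [
    {"id": "CCA-1", "kind": "straight", "radius_mm": 8.5, "bend_angle_deg": null, "parent_id": null, "branch_label": null, "upstream_angle_deg": null, "stress_radius_mm": null},
    {"id": "CCA-2", "kind": "straight", "radius_mm": 8.5, "bend_angle_deg": null, "parent_id": "CCA-1", "branch_label": null, "upstream_angle_deg": null, "stress_radius_mm": null},
    {"id": "CCA-3", "kind": "bifurcation", "radius_mm": 10, "bend_angle_deg": null, "parent_id": "CCA-2", "branch_label": "ECA/ICA", "upstream_angle_deg": null, "stress_radius_mm": null},
    {"id": "ECA-1", "kind": "bend", "radius_mm": 5.0, "bend_angle_deg": 20, "parent_id": "CCA-3", "branch_label": "STA", "upstream_angle_deg": null, "stress_radius_mm": null},
    {"id": "ECA-2", "kind": "bifurcation", "radius_mm": 4.5, "bend_angle_deg": null, "parent_id": "ECA-1", "branch_label": "LA", "upstream_angle_deg": null, "stress_radius_mm": null},
    {"id": "ECA-3", "kind": "bend", "radius_mm": 4.0, "bend_angle_deg": 52, "parent_id": "ECA-2", "branch_label": null, "upstream_angle_deg": 51, "stress_radius_mm": null},
    {"id": "ECA-4", "kind": "bifurcation", "radius_mm": 2.5, "bend_angle_deg": null, "parent_id": "ECA-3", "branch_label": "OA", "upstream_angle_deg": null, "stress_radius_mm": null},
    {"id": "ECA-5", "kind": "bend", "radius_mm": 2.0, "bend_angle_deg": 60, "parent_id": "ECA-4", "branch_label": null, "upstream_angle_deg": null, "stress_radius_mm": null},
    {"id": "ECA-6", "kind": "straight", "radius_mm": 2.0, "bend_angle_deg": null, "parent_id": "ECA-5", "branch_label": null, "upstream_angle_deg": null, "stress_radius_mm": null},
    {"id": "ECA-7", "kind": "bend", "radius_mm": 2.0, "bend_angle_deg": 30, "parent_id": "ECA-6", "branch_label": null, "upstream_angle_deg": null, "stress_radius_mm": null},
    {"id": "ECA-8", "kind": "bifurcation", "radius_mm": 1.5, "bend_angle_deg": null, "parent_id": "ECA-7", "branch_label": "MA", "upstream_angle_deg": null, "stress_radius_mm": null},
    {"id": "ECA-9", "kind": "bifurcation", "radius_mm": 1.5, "bend_angle_deg": null, "parent_id": "ECA-8", "branch_label": "MA terminal", "upstream_angle_deg": null, "stress_radius_mm": null},
    {"id": "ICA-1", "kind": "bend", "radius_mm": 5.5, "bend_angle_deg": 28, "parent_id": "CCA-3", "branch_label": null, "upstream_angle_deg": null, "stress_radius_mm": null},
    {"id": "ICA-2", "kind": "bend", "radius_mm": 5.0, "bend_angle_deg": 48, "parent_id": "ICA-1", "branch_label": null, "upstream_angle_deg": null, "stress_radius_mm": 5.5},
    {"id": "ICA-3", "kind": "straight", "radius_mm": 5.0, "bend_angle_deg": null, "parent_id": "ICA-2", "branch_label": null, "upstream_angle_deg": null, "stress_radius_mm": null}
  ]
}
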