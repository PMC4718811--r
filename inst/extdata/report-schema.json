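{
  "$comment": "Structural schema for metconn pipeline reports",
  "required": ["schema", "seed", "groups", "n_volumes", "parameters"],
  "properties": {
    "schema": {"const": "metconn-report-1"},
    "seed": {"type": "integer"},
    "n_volumes": {"type": "integer"},
    "parameters": {
      "required": ["fwhm_mm", "fdr_q", "extent", "n_perm", "z_threshold",
                   "voi_radius_mm", "family_alpha"]
    },
    "connectivity": {
      "comparison_required": ["comparison", "n_edges", "edges"]
    }
  }
}
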