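{
  "version": "psalloc-reference-1.0",
  "provenance": "Reconstruction of the published Personal Support Algorithm narrative with documented default cut-points; cut-points are configurable data, not code.",
  "target": "weekly_billed_hours",
  "root": "n_root",
  "nodes": [
    {"id": "n_root", "type": "split", "variable": "self_reliance_impaired", "cuts": [1], "children": ["n_sri0_iadl", "n_sri1_adl"]},

    {"id": "n_sri0_iadl", "type": "split", "variable": "iadl_difficulty", "cuts": [2], "children": ["l_1a", "n_sri0_iadl_hi"]},
    {"id": "n_sri0_iadl_hi", "type": "split", "variable": "iadl_difficulty", "cuts": [5], "children": ["l_1b", "l_1c"]},
    {"id": "l_1a", "type": "leaf", "group": "1A"},
    {"id": "l_1b", "type": "leaf", "group": "1B"},
    {"id": "l_1c", "type": "leaf", "group": "1C"},

    {"id": "n_sri1_adl", "type": "split", "variable": "adl_short", "cuts": [3], "children": ["n_low_dress", "n_modhigh_adl"]},

    {"id": "n_low_dress", "type": "split", "variable": "dressing_upper", "cuts": [2], "children": ["l_2a", "n_low_dm"]},
    {"id": "n_low_dm", "type": "split", "variable": "decision_making", "cuts": [1], "children": ["n_low_iadl", "l_3a"]},
    {"id": "n_low_iadl", "type": "split", "variable": "iadl_difficulty", "cuts": [5], "children": ["l_2b", "l_3b"]},
    {"id": "l_2a", "type": "leaf", "group": "2"},
    {"id": "l_2b", "type": "leaf", "group": "2"},
    {"id": "l_3a", "type": "leaf", "group": "3"},
    {"id": "l_3b", "type": "leaf", "group": "3"},

    {"id": "n_modhigh_adl", "type": "split", "variable": "adl_short", "cuts": [11], "children": ["n_mod_cps", "n_high_bowel"]},

    {"id": "n_mod_cps", "type": "split", "variable": "cps", "cuts": [3], "children": ["n_mod_unstable", "n_mod_bladder"]},
    {"id": "n_mod_unstable", "type": "split", "variable": "unstable_conditions", "cuts": [1], "children": ["l_3c", "l_4a"]},
    {"id": "n_mod_bladder", "type": "split", "variable": "bladder_incontinence", "cuts": [2], "children": ["l_4b", "l_5a"]},
    {"id": "l_3c", "type": "leaf", "group": "3"},
    {"id": "l_4a", "type": "leaf", "group": "4"},
    {"id": "l_4b", "type": "leaf", "group": "4"},
    {"id": "l_5a", "type": "leaf", "group": "5"},

    {"id": "n_high_bowel", "type": "split", "variable": "bowel_incontinence", "cuts": [2], "children": ["n_high_comm", "n_high_cgd2"]},
    {"id": "n_high_comm", "type": "split", "variable": "making_self_understood", "cuts": [2], "children": ["l_5b", "n_high_cgd1"]},
    {"id": "n_high_cgd1", "type": "split", "variable": "caregiver_distress", "cuts": [1], "children": ["l_5c", "l_6a"]},
    {"id": "n_high_cgd2", "type": "split", "variable": "caregiver_distress", "cuts": [1], "children": ["l_5d", "l_6b"]},
    {"id": "l_5b", "type": "leaf", "group": "5"},
    {"id": "l_5c", "type": "leaf", "group": "5"},
    {"id": "l_5d", "type": "leaf", "group": "5"},
    {"id": "l_6a", "type": "leaf", "group": "6"},
    {"id": "l_6b", "type": "leaf", "group": "6"}
  ]
}
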