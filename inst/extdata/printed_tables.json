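{
  "comment": "Published summary values used as fixtures: percentages as printed (one decimal), AUC on the 0-1 scale (three decimals). 'annotation' records rows whose five printed percentages admit no consistent integer confusion matrix over 116 remission / 114 active patients, or whose printed AUC differs from (sens+spec)/2 computed on the reconstructed counts.",
  "study": {
    "n_enrolled": 268,
    "n_missing_fcal": 38,
    "n_analyzed": 230,
    "msescd_categories": { "labels": ["0", "1-2", "3-4", "5-10", "11-15"], "counts": [97, 19, 54, 57, 3] },
    "n_remission": 116,
    "n_active": 114
  },
  "cutoffs": { "lrg": 13.2, "crp": 0.15, "fcal": 180 },
  "marker_marginals": {
    "lrg":  { "median": 13.1, "q1": 8.5,  "q3": 16.7, "units": "ug/mL" },
    "crp":  { "median": 0.10, "q1": 0.04, "q3": 0.22, "units": "mg/dL" },
    "fcal": { "median": 202,  "q1": 61,   "q3": 687,  "units": "ug/g" }
  },
  "single_marker_auc": {
    "lrg":  { "auc": 0.886, "ci": [0.845, 0.927] },
    "crp":  { "auc": 0.816, "ci": [0.746, 0.866] },
    "fcal": { "auc": 0.876, "ci": [0.833, 0.919] },
    "cdai": { "auc": 0.614, "ci": [0.573, 0.652] }
  },
  "spearman_msescd": { "lrg": 0.69, "crp": 0.60, "fcal": 0.67 },
  "table2": [
    { "rule": "crp_lrg",      "sens": 74.2, "spec": 90.0,  "ppv": 89.0,  "npv": 76.2, "accuracy": 81.7, "auc": 0.831,
      "annotation": "no integer (tp, tn) over 116/114 reproduces all five percentages" },
    { "rule": "crp_fcal",     "sens": 69.0, "spec": 93.9,  "ppv": 92.0,  "npv": 74.8, "accuracy": 81.3, "auc": 0.814,
      "annotation": null },
    { "rule": "fcal_lrg",     "sens": 65.5, "spec": 97.4,  "ppv": 96.2,  "npv": 73.5, "accuracy": 81.3, "auc": 0.814,
      "annotation": null },
    { "rule": "two_of_three", "sens": 89.4, "spec": 83.3,  "ppv": 81.6,  "npv": 90.5, "accuracy": 86.1, "auc": 0.860,
      "annotation": "no integer (tp, tn) over 116/114 reproduces all five percentages" },
    { "rule": "all_three",    "sens": 71.3, "spec": 100.0, "ppv": 100.0, "npv": 60.3, "accuracy": 80.0, "auc": 0.794,
      "annotation": "sens/NPV pair (71.3, 60.3) admits no consistent integer matrix" }
  ],
  "table3": [
    { "rule": "two_of_three", "sens": 89.7, "spec": 80.7,  "ppv": 82.5,  "npv": 88.5, "accuracy": 85.2, "auc": 0.852, "p_vs_reference": null,
      "annotation": null },
    { "rule": "all_three",    "sens": 56.9, "spec": 100.0, "ppv": 100.0, "npv": 69.5, "accuracy": 78.3, "auc": 0.785, "p_vs_reference": 0.0190,
      "annotation": "printed AUC 0.785; (66/116 + 114/114)/2 = 0.7845 rounds to 0.784 from the reconstructed counts (consistent with averaging the printed one-decimal percentages instead)" },
    { "rule": "crp_fcal",     "sens": 67.2, "spec": 93.9,  "ppv": 91.8,  "npv": 73.8, "accuracy": 80.4, "auc": 0.806, "p_vs_reference": 0.0654,
      "annotation": null },
    { "rule": "fcal_lrg",     "sens": 63.8, "spec": 96.5,  "ppv": 94.9,  "npv": 72.4, "accuracy": 80.0, "auc": 0.801, "p_vs_reference": 0.0589,
      "annotation": null },
    { "rule": "crp_lrg",      "sens": 72.4, "spec": 90.4,  "ppv": 88.4,  "npv": 76.3, "accuracy": 81.3, "auc": 0.814, "p_vs_reference": 0.0906,
      "annotation": null }
  ],
  "fig5c_two_step": { "sens": 89.4, "spec": 83.3, "ppv": 81.6, "npv": 90.5, "accuracy": 86.1 },
  "clopper_pearson_lower_bounds": { "n114": 96.8, "n66": 94.6 },
  "hazard_ratios": {
    "relapse": { "hr": 0.20, "ci": [0.09, 0.45] },
    "hosp":    { "hr": 0.21, "ci": [0.06, 0.77] },
    "surg":    { "hr": 0.24, "ci": [0.07, 0.88] }
  },
  "events": { "relapse": 35, "hosp": 14, "surg": 13 },
  "followup_years": { "median": 3.6, "q1": 1.8, "q3": 4.7 }
}
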