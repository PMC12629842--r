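{
  "description": "Packaged default region-specific CADD Phred thresholds with the Mann-Whitney/FDR significance and AUC each was derived with. Usability requires AUC > 0.7 and a significant adjusted p-value.",
  "regions": {
    "region": ["upstream", "utr5", "intronic", "splicing", "utr3", "ncRNA_exonic", "ncRNA_intronic", "downstream", "intergenic"],
    "threshold": [34, 16.79, 12.76, 25.5, 11.08, 11.44, 3.03, 0.82, 11.0],
    "p": [5.5983e-18, 5.2879e-23, 0.0, 0.0, 1.2086e-20, 4.3687e-72, 1.9291e-11, 1.6134e-01, 2.2073e-04],
    "significance": ["***", "***", "***", "***", "***", "***", "***", "n.s.", "**"],
    "auc": [0.347, 0.714, 0.886, 0.904, 0.820, 0.872, 0.620, 0.629, 0.664]
  }
}
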