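{
  "mlp": { "hidden": 1024 },
  "knn": { "k": 5 },
  "svm": { "C": 1.0, "epochs": 50 },
  "rf": { "n_trees": 50, "min_split": 5, "max_depth": 25 },
  "lda": {}
}
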