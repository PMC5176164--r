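# Published best hyperparameters per model family, one arm per feature
# setting. The RLR "Param1/Param2" pair is read as elastic-net
# (mixing, strength); both pure-L1 and pure-L2 penalties are reachable by
# setting mixing to 1 or 0.
features_true:
  gbm:
    - hyperparameters:
        learning_rate: 0.01
        max_depth: 4
        n_rounds: 5000
        subsample: 0.8
  random_forest:
    - hyperparameters:
        vars_per_split: 12
        n_trees: 1000
        min_node_size: 3
  penalised_logistic:
    - hyperparameters:
        mixing: 0.10
        strength: 0.0018
  svm:
    - kernel: polynomial
      hyperparameters:
        cost: 0.1
        coef0: 4
        gamma: 0.01
        degree: 4
features_false:
  gbm:
    - hyperparameters:
        learning_rate: 0.01
        max_depth: 5
        n_rounds: 5000
        subsample: 0.7
  random_forest:
    - hyperparameters:
        vars_per_split: 10
        n_trees: 1400
        min_node_size: 1
  penalised_logistic:
    - hyperparameters:
        mixing: 0.810
        strength: 0.0012
  svm:
    - kernel: polynomial
      hyperparameters:
        degree: 4
        gamma: 0.01
        coef0: 4
        cost: 1
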