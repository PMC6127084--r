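{
  "subcommand": "tree",
  "seed": 1,
  "out_dir": ".",
  "verbose": false,
  "n_subclones": 4,
  "n_cells": 300,
  "ado": 0.1,
  "failure": 0.05,
  "ct_max": 38,
  "min_cells": 2,
  "bootstrap_reps": 0,
  "max_missing_frac": 0.3,
  "threshold": 8.55
}
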