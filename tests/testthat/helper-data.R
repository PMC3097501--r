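# Small deterministic builders shared across tests.

# n x k descriptor matrix of standard normals with stable names.
rand_table <- function(n, k, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n * k), n, k,
         dimnames = list(sprintf("c%02d", seq_len(n)),
                         paste0("D", seq_len(k))))
}

# Activity fixture split into the published train/test roles.
phenol_sets <- function() {
  act <- phenols_activity()
  list(act = act, train = !act$test_set, test = act$test_set,
       ym = mean(act$pIC50[!act$test_set]))
}
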