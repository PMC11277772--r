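# shared helpers for building small test fixtures in code

random_table <- function(N = 60, M = 4, nclass = 2, seed = 1) {
  set.seed(seed)
  feature_table(matrix(rnorm(N * M), N, M), rep_len(seq_len(nclass), N))
}

# table whose first feature equals the label (perfectly separable)
label_feature_table <- function(N = 100, M = 4, seed = 1) {
  set.seed(seed)
  y <- rep_len(1:2, N)
  X <- cbind(y + rnorm(N, 0, 1e-6), matrix(rnorm(N * (M - 1)), N))
  feature_table(X, y)
}

tiny_scnn_config <- function() {
  scnn_config(f1 = 3, n1 = 4, m = 6, n2 = 4, nh = 4, f4 = 3, k_iters = 3,
              patch = 8, stride = 4, factor = 2)
}
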