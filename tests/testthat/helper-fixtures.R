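# Shared small fixtures, built in code. Kept deliberately tiny so the whole
# suite stays fast; heavyweight runs live in test-acceptance.R.

fix_machine <- machine_model()

fix_grid_small <- grid_spec(24, 6)   # 144 mm cube
fix_phantom_small <- sample_phantom(11, fix_grid_small)
fix_plan_small <- sample_plan(12, fix_machine, fix_phantom_small,
                              n_segments_range = c(1, 3))

# a smooth random positive dose volume
smooth_volume <- function(seed, n = 16, passes = 3) {
  set.seed(seed)
  v <- array(runif(n^3), c(n, n, n))
  for (i in seq_len(passes)) {
    v <- (v +
            v[c(2:n, n), , ] + v[c(1, 1:(n - 1)), , ] +
            v[, c(2:n, n), ] + v[, c(1, 1:(n - 1)), ] +
            v[, , c(2:n, n)] + v[, , c(1, 1:(n - 1))]) / 7
  }
  v / max(v) * 100
}

tiny_train_config <- function(...) {
  do.call(train_config,
          utils::modifyList(list(epochs = 1, base_filters = 3,
                                 base_filters_d = 3, n_down = 3),
                            list(...)))
}
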