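## Shared fixtures: built once per test run, in code.

toy_bank <- local({
  bank <- NULL
  function() {
    if (is.null(bank)) bank <<- make_toy_bank()
    bank
  }
})

## small, fast training dataset from the designated plant
toy_dataset <- local({
  td <- NULL
  function() {
    if (is.null(td)) {
      td <<- simulate_training_data(toy_bank()$models$C, noise_sd = 0.05,
                                    seed = 1)
    }
    td
  }
})

## a target object that follows an arbitrary reference curve (used to test
## the zero-effort optimum when the plant should just be left alone)
curve_target <- function(t, z) {
  structure(list(t_off = NA_real_, p_ss = NA_real_,
                 value_fn = stats::approxfun(t, z, rule = 2)),
            class = "target_trajectory")
}
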