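# Shared fixtures.  Heavy objects are built lazily once per test run and
# cached in this environment.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixtures))
    assign(name, force(expr), envir = .fixtures)
  get(name, envir = .fixtures)
}

# a small config for fast unit-level training (window stays 512)
tiny_config <- function(...) {
  defaults <- list(bilstm_units = 8L, conv_filters = 4L, kernel_size = 3L,
                   fusion_fc_widths = 16L, feature_fc_width = 8L,
                   epochs = 2L, batch_size = 16L, validation_interval = 1L,
                   seed = 11L)
  do.call(model_config, utils::modifyList(defaults, list(...)))
}

# even smaller nets on short windows for gradient checks
grad_config <- function() {
  model_config(bilstm_units = 3L, conv_filters = 2L, kernel_size = 3L,
               fusion_fc_widths = 4L, feature_fc_width = 3L, seed = 9L)
}

tiny_dataset <- function() memo("tiny_dataset", generate_dataset(30, seed = 5))

tiny_pairs <- function() memo("tiny_pairs", {
  ds <- tiny_dataset()
  make_windowed_pairs(ds$records, ds$split)
})

# a quickly trained dual-branch fit shared by method/uncertainty tests
tiny_fit <- function() memo("tiny_fit", {
  ecg_reconstruct(tiny_pairs(), "dual", tiny_config())
})

# add small random offsets to all bias vectors so finite-difference checks
# never sit exactly on a ReLU kink (zero-initialized biases otherwise give
# exactly-zero pre-activations)
jitter_biases <- function(net, sd = 0.3, seed = 99) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  for (nm in grep("_b$|lstm_b", names(net$params), value = TRUE))
    net$params[[nm]] <- net$params[[nm]] + rnorm(length(net$params[[nm]]), 0, sd)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  net
}
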