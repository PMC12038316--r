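# Shared fixtures, built once per test run and memoised.  Training the two
# demonstration models takes a few seconds each; several test files reuse
# them.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

alpha_scene <- function() memo("alpha_scene", demo_scene_alphanumeric)

alpha_model <- function() {
  memo("alpha_model", function() {
    model <- build_model(config_alphanumeric_demo(), seed = 1L)
    suppressMessages(train(model, alpha_scene(), training_schedule(seed = 1L)))
  })
}

natural_scene <- function() memo("natural_scene", function() demo_scene_natural(42L))

natural_model <- function() {
  memo("natural_model", function() {
    model <- build_model(config_natural_demo(), seed = 1L)
    suppressMessages(train(model, natural_scene(), training_schedule(seed = 1L)))
  })
}

active_set <- function(rates) which(as.numeric(rates) > 0)

# index range widened by m on both sides, clipped to the 32-neuron grid
range_pad <- function(idx, m) max(1L, min(idx) - m):min(32L, max(idx) + m)

`%||%` <- function(a, b) if (is.null(a)) b else a
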