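# Shared fixtures: the nominal expanded network and its unstressed steady
# state are expensive (seconds), so they are built once per test run.

.shared <- new.env(parent = emptyenv())

nominal_network <- function() {
  if (is.null(.shared$net))
    .shared$net <- expand_network(build_model())
  .shared$net
}

no_feedback_network <- function() {
  network_with_params(nominal_network(), list(p6 = 0))
}

unstressed_ss <- function() {
  if (is.null(.shared$ss))
    .shared$ss <- unstressed_state(nominal_network())
  .shared$ss
}

# state after stepping the inputs from the unstressed steady state
stressed_state <- function(ampk = NULL, rapa = NULL) {
  net <- nominal_network()
  set_inputs(net, unstressed_ss()$state, ampk_star = ampk,
             rapamycin_star = rapa)
}
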