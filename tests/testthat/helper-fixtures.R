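# Shared fixture constructors. T1: 3-step linear chain under a defined
# medium; T2: conserved cofactor cycle; T3: folate-dependent purine toy.

t1_model <- function() {
  apply_medium(make_linear(3)$model, c(EX_A1 = 10))
}

t2_model <- function() {
  make_cofactor_cycle()$model
}

t3 <- function() {
  make_purine_toy()
}

# LP-vs-oracle agreement over every metabolite of a model state
agreement_ok <- function(model, epsilon = 1e-6) {
  sunk <- if (any(model$reactions$sink)) model else add_sinks(model)
  all(vapply(model$metabolites$id, function(met) {
    (max_production(sunk, met) > epsilon) == oracle_producible(model, met)
  }, logical(1)))
}
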