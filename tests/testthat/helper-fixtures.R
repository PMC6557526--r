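# shared fixtures: built once per test run, all deterministic
geom <- cell_geometry()
prot1 <- challenge_protocol(FeCHG = 20, duration = 15)
prot2 <- challenge_protocol()

# random admissible states for property-style checks
random_state <- function(model = "swing", rng) {
  P <- rng(6)
  if (model == "switch") P[6] <- 0
  P <- P / sum(P)
  model_state(P = P, FeIN = rng(1), FeOUT = 20 * rng(1),
              mode = sample(c("endocytic", "exocytic"), 1),
              j = 1L, FeUP_history = 0, FeCHG_history = 20)
}
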