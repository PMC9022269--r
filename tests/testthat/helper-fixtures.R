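# deterministic fixture models built in code

# Tf_I-like geometry: duplicated 212-bp monomer, 197-bp M1, 205-bp tether
tf_like_model <- function(seed = 11) {
  random_promoter_model(
    monomer_lengths = c(212L, 212L, 197L), tether_length = 205L,
    divergence = 0.1, subfamily = "SimTf", seed = seed
  )
}

# small model for fast end-to-end tests
toy_model <- function(seed = 3) {
  random_promoter_model(
    monomer_lengths = c(60L, 60L), tether_length = 40L,
    divergence = 0.15, subfamily = "Toy", seed = seed
  )
}
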