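# Small fixtures built in code, shared across test files.

tiny_sim <- function(N = 60, J = 8, K = 2, model = "4PL",
                     missing_proportion = 0.25, seed = 11,
                     item_structure = "between") {
  sim_mirt_data(sim_config(N = N, J = J, K = K, model = model,
                           missing_proportion = missing_proportion,
                           item_structure = item_structure, seed = seed))
}

tiny_control <- function(T_max = 1500L, patience = 5L,
                         hidden = c(16L, 8L), ...) {
  iwvae_control(T_max = T_max, patience = patience, hidden = hidden, ...)
}

# random 4PL parameter set on a dense support, away from clamping regions
random_params <- function(J, K, model = "4PL", seed = 5) {
  set.seed(seed)
  item_parameters(A = matrix(rnorm(J * K, 0, 0.4), J, K),
                  b = rnorm(J),
                  c = if (model != "2PL") plogis(rnorm(J, -2, 0.3)) else NULL,
                  d = if (model == "4PL") plogis(rnorm(J, 2, 0.3)) else NULL,
                  model = model)
}

# deterministic encoder with all weights zero and given head biases
zero_encoder <- function(J, K, hidden = c(4L), b_mu = rep(0, K),
                         b_lv = rep(0, K)) {
  enc <- local({ set.seed(1); init_encoder(J, K, hidden) })
  for (l in seq_along(enc$W)) {
    enc$W[[l]][] <- 0
    enc$b[[l]][] <- 0
  }
  enc$W_mu[] <- 0; enc$W_lv[] <- 0
  enc$b_mu <- b_mu; enc$b_lv <- b_lv
  enc
}
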