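# The compiled training core must agree exactly with the R reference
# implementations of the objectives, and its hand-derived gradients must
# match finite differences of those references.

make_instance <- function(n = 5, J = 7, K = 2, seed = 31) {
  sim <- tiny_sim(N = n, J = J, K = K, missing_proportion = 0.3, seed = seed)
  set.seed(seed + 1)
  enc <- init_encoder(J, K, c(6L))
  A <- matrix(rnorm(J * K, 0, 0.3), J, K)
  b <- rnorm(J)
  craw <- rnorm(J, -2, 0.3)
  draw <- rnorm(J, 2, 0.3)
  list(sim = sim, enc = enc, A = A, b = b, craw = craw, draw = draw,
       n = n, J = J, K = K)
}

r_elbo <- function(inst, enc = inst$enc, A = inst$A, b = inst$b,
                   craw = inst$craw, draw = inst$draw, S, eps, klw = 0.7) {
  p <- item_parameters(A, b, plogis(craw), plogis(draw), "4PL")
  elbo(inst$sim$data, enc, p, S = S, kl_weight = klw, eps = eps)
}

r_iwelbo <- function(inst, enc = inst$enc, A = inst$A, b = inst$b,
                     craw = inst$craw, draw = inst$draw, R, eps) {
  p <- item_parameters(A, b, plogis(craw), plogis(draw), "4PL")
  post <- encode(inst$sim$data$Y, enc)
  person <- rep(seq_len(inst$n), each = R)
  sigma <- exp(post$log_var / 2)
  rp <- list(theta = post$mu[person, , drop = FALSE] +
               sigma[person, , drop = FALSE] * eps,
             eps = eps, person = person)
  iw_elbo(log_importance_weights(inst$sim$data, p, post, rp))
}

cpp_grad <- function(inst, eps, S, R, klw, mode) {
  iwirt:::cpp_objective_grad(inst$sim$data$Y, inst$sim$data$mask,
                             unclass(inst$enc), inst$A, inst$b,
                             inst$craw, inst$draw, 4L, eps,
                             as.integer(S), as.integer(R), klw,
                             as.integer(mode))
}

test_that("compiled objectives equal the R reference implementations", {
  inst <- make_instance()
  set.seed(32)
  eps1 <- matrix(rnorm(inst$n * 2 * inst$K), inst$n * 2, inst$K)
  g1 <- cpp_grad(inst, eps1, S = 2, R = 1, klw = 0.7, mode = 1)
  expect_equal(g1$objective, r_elbo(inst, S = 2, eps = eps1), tolerance = 1e-12)
  eps2 <- matrix(rnorm(inst$n * 4 * inst$K), inst$n * 4, inst$K)
  g2 <- cpp_grad(inst, eps2, S = 1, R = 4, klw = 1, mode = 2)
  expect_equal(g2$objective, r_iwelbo(inst, R = 4, eps = eps2),
               tolerance = 1e-12)
})

test_that("compiled gradients match finite differences of the R objectives", {
  inst <- make_instance()
  set.seed(33)
  eps <- matrix(rnorm(inst$n * inst$K), inst$n, inst$K)
  g <- cpp_grad(inst, eps, S = 1, R = 1, klw = 0.7, mode = 1)
  h <- 1e-6
  fd <- function(f) (f(h) - f(-h)) / (2 * h)
  checks <- list(
    list(g$grad_A[2, 1], function(d) {
      A <- inst$A; A[2, 1] <- A[2, 1] + d
      r_elbo(inst, A = A, S = 1, eps = eps) }),
    list(g$grad_b[3], function(d) {
      b <- inst$b; b[3] <- b[3] + d
      r_elbo(inst, b = b, S = 1, eps = eps) }),
    list(g$grad_c_raw[1], function(d) {
      cr <- inst$craw; cr[1] <- cr[1] + d
      r_elbo(inst, craw = cr, S = 1, eps = eps) }),
    list(g$grad_d_raw[4], function(d) {
      dr <- inst$draw; dr[4] <- dr[4] + d
      r_elbo(inst, draw = dr, S = 1, eps = eps) }),
    list(g$grad_enc$W[[1]][3, 2], function(d) {
      e <- inst$enc; e$W[[1]][3, 2] <- e$W[[1]][3, 2] + d
      r_elbo(inst, enc = e, S = 1, eps = eps) }),
    list(g$grad_enc$W_mu[1, 2], function(d) {
      e <- inst$enc; e$W_mu[1, 2] <- e$W_mu[1, 2] + d
      r_elbo(inst, enc = e, S = 1, eps = eps) }),
    list(g$grad_enc$W_lv[2, 4], function(d) {
      e <- inst$enc; e$W_lv[2, 4] <- e$W_lv[2, 4] + d
      r_elbo(inst, enc = e, S = 1, eps = eps) }),
    list(g$grad_enc$b_mu[1], function(d) {
      e <- inst$enc; e$b_mu[1] <- e$b_mu[1] + d
      r_elbo(inst, enc = e, S = 1, eps = eps) }))
  for (ch in checks) {
    expect_equal(ch[[1]], fd(ch[[2]]), tolerance = 1e-4)
  }
  # decoder gradients in the IW stage follow the plain weighted estimator,
  # which is the total derivative of the IW-ELBO: finite differences apply
  set.seed(34)
  epsR <- matrix(rnorm(inst$n * 5 * inst$K), inst$n * 5, inst$K)
  gw <- cpp_grad(inst, epsR, S = 1, R = 5, klw = 1, mode = 2)
  expect_equal(gw$grad_A[2, 1], fd(function(d) {
    A <- inst$A; A[2, 1] <- A[2, 1] + d
    r_iwelbo(inst, A = A, R = 5, eps = epsR) }), tolerance = 1e-4)
  expect_equal(gw$grad_c_raw[1], fd(function(d) {
    cr <- inst$craw; cr[1] <- cr[1] + d
    r_iwelbo(inst, craw = cr, R = 5, eps = epsR) }), tolerance = 1e-4)
})

test_that("compiled DReG encoder gradient matches the R formula", {
  inst <- make_instance(n = 3, J = 6, K = 2)
  R <- 4
  set.seed(35)
  eps <- matrix(rnorm(inst$n * R * inst$K), inst$n * R, inst$K)
  g <- cpp_grad(inst, eps, S = 1, R = R, klw = 1, mode = 2)
  p <- item_parameters(inst$A, inst$b, plogis(inst$craw), plogis(inst$draw),
                       "4PL")
  post <- encode(inst$sim$data$Y, inst$enc)
  person <- rep(seq_len(inst$n), each = R)
  sigma <- exp(post$log_var / 2)
  theta <- post$mu[person, ] + sigma[person, ] * eps
  rp <- list(theta = theta, eps = eps, person = person)
  v <- log_importance_weights(inst$sim$data, p, post, rp)
  w <- normalized_weights(v)
  # dv/dtheta via central differences of the per-row log weight
  dv <- matrix(0, nrow(theta), inst$K)
  h <- 1e-6
  for (m in seq_len(nrow(theta))) for (k in seq_len(inst$K)) {
    vfun <- function(d) {
      th <- theta; th[m, k] <- th[m, k] + d
      ll <- masked_loglik(inst$sim$data$Y[person[m], , drop = FALSE],
                          inst$sim$data$mask[person[m], , drop = FALSE],
                          th[m, , drop = FALSE], p)
      lq <- sum(dnorm(th[m, ], post$mu[person[m], ], sigma[person[m], ],
                      log = TRUE))
      ll + log_prior(th[m, , drop = FALSE]) - lq
    }
    dv[m, k] <- (vfun(h) - vfun(-h)) / (2 * h)
  }
  # chain through theta = mu + sigma * eps into the head biases
  n <- inst$n
  g_bmu <- rep(0, inst$K); g_blv <- rep(0, inst$K)
  for (m in seq_len(nrow(theta))) {
    i <- person[m]; r <- (m - 1) %% R + 1
    w2 <- w[i, r]^2 / n
    g_bmu <- g_bmu + w2 * dv[m, ]
    g_blv <- g_blv + w2 * dv[m, ] * 0.5 * sigma[i, ] * eps[m, ]
  }
  expect_equal(as.numeric(g$grad_enc$b_mu), g_bmu, tolerance = 1e-5)
  expect_equal(as.numeric(g$grad_enc$b_lv), g_blv, tolerance = 1e-5)
})

test_that("values at unobserved cells cannot influence training", {
  # two complete response matrices that differ only where the mask will be
  # zero must yield identical training problems after ingestion: the
  # likelihood never reads masked cells (structural, see the masked_loglik
  # invariance tests) and the encoder sees the zero-imputed value
  set.seed(36)
  full_a <- matrix(rbinom(60, 1, 0.5), 10, 6)
  full_b <- full_a
  mask <- matrix(rbinom(60, 1, 0.7), 10, 6)
  mask[rowSums(mask) == 0, 1] <- 1
  full_b[mask == 0] <- 1 - full_b[mask == 0]
  rd_a <- response_data(ifelse(mask == 1, full_a, NA))
  rd_b <- response_data(ifelse(mask == 1, full_b, NA))
  expect_identical(rd_a, rd_b)
  fit_a <- fit_iwvae(rd_a, "2PL", K = 1, control = tiny_control(T_max = 300L),
                     seed = 4)
  fit_b <- fit_iwvae(rd_b, "2PL", K = 1, control = tiny_control(T_max = 300L),
                     seed = 4)
  expect_identical(fit_a$parameters, fit_b$parameters)
})
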