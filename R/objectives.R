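#' Evidence lower bound for a batch of persons
#'
#' Monte Carlo ELBO `(1/S) sum_s loglik(theta_s) - kl_weight * KL`, averaged
#' over the batch. `kl_weight` implements KL annealing: it rises linearly
#' from 0 to 1 during the first training stage and equals 1 afterwards.
#' This is the R reference implementation used for validation; the trainer
#' evaluates the identical quantity in compiled code.
#'
#' @param data a [response_data] (or matrix with `NA`s).
#' @param state an encoder state.
#' @param params an [item_parameters] object.
#' @param S Monte Carlo sample count.
#' @param kl_weight KL annealing weight in `[0, 1]`.
#' @param eps optional (n*S) x K matrix of standard-normal draws (for
#'   deterministic comparisons); drawn internally when `NULL`.
#' @return scalar ELBO estimate (mean over the batch).
#' @export
elbo <- function(data, state, params, S = 1L, kl_weight = 1, eps = NULL) {
  stopifnot(kl_weight >= 0, kl_weight <= 1)
  data <- as_response_data(data)
  n <- nrow(data$Y)
  post <- encode(data$Y, state)
  if (is.null(eps)) {
    rp <- reparameterize(post, S = S, R = 1L)
  } else {
    person <- rep(seq_len(n), each = S)
    sigma <- exp(post$log_var / 2)
    rp <- list(theta = post$mu[person, , drop = FALSE] +
                 sigma[person, , drop = FALSE] * eps,
               eps = eps, person = person)
  }
  ll <- masked_loglik(data$Y[rp$person, , drop = FALSE],
                      data$mask[rp$person, , drop = FALSE],
                      rp$theta, params)
  recon <- mean(rowsum(ll, rp$person) / S)
  recon - kl_weight * mean(analytic_kl(post))
}

#' Log importance weights
#'
#' `v_ir = loglik(theta_ir) + log p(theta_ir) - log q(theta_ir | y_i)`,
#' the log of the unnormalized importance weight
#' `w = p(y, theta | M_p) / q(theta | y)`. Computed entirely in log space;
#' a last-resort clamp at `|v| = 1e6` guards the downstream exponentials.
#'
#' @param data a [response_data].
#' @param params an [item_parameters] object.
#' @param post the encoder posterior for the same rows.
#' @param rp a sample set from [reparameterize()] with R draws per person.
#' @return n x R matrix of log weights (persons in rows).
#' @export
log_importance_weights <- function(data, params, post, rp) {
  data <- as_response_data(data)
  R <- length(rp$person) / nrow(post$mu)
  ll <- masked_loglik(data$Y[rp$person, , drop = FALSE],
                      data$mask[rp$person, , drop = FALSE],
                      rp$theta, params)
  v <- ll + log_prior(rp$theta) - log_q_density(rp$theta, post, rp$person)
  v <- pmin(pmax(v, -1e6), 1e6)
  matrix(v, ncol = R, byrow = TRUE)
}

#' Importance-weighted ELBO from log weights
#'
#' `mean_i [ logsumexp_r(v_ir) - log R ]`, the stabilized Monte Carlo
#' estimate of the importance-weighted bound. With `R = 1` this reduces to
#' the single-sample ELBO estimate built from the same draws.
#'
#' @param v n x R matrix of log importance weights.
#' @return scalar IW-ELBO estimate.
#' @export
iw_elbo <- function(v) {
  v <- as.matrix(v)
  mean(row_logsumexp(v) - log(ncol(v)))
}

row_logsumexp <- function(v) {
  m <- apply(v, 1, max)
  m + log(rowSums(exp(v - m)))
}

#' Self-normalized importance weights
#'
#' Row-wise softmax `exp(v - max) / sum exp(v - max)`: nonnegative, sums to
#' one per person, and invariant to adding a constant to a row. Stable for
#' log-weight spreads of hundreds.
#'
#' @param v n x R matrix of log importance weights.
#' @return n x R matrix of simplex weights.
#' @export
normalized_weights <- function(v) {
  v <- as.matrix(v)
  e <- exp(v - apply(v, 1, max))
  e / rowSums(e)
}

# Unstabilized log-mean-exp, used only as a small-|v| oracle in tests.
naive_log_mean_exp <- function(v) {
  v <- as.matrix(v)
  log(rowMeans(exp(v)))
}

# Per-draw gradient estimators of the IW-ELBO with respect to a single
# person's variational parameters (mu, log_var), for a user-supplied
# likelihood. Used to validate the compiled DReG update on conjugate toys
# where independent oracles exist.
#
# method "dreg":  sum_r wtilde_r^2 * (dv/dtheta) * (dtheta/dphi), with the
#                 variational parameters inside v treated as constants.
# method "naive": sum_r wtilde_r * d(log w_r)/dphi, the plain importance-
#                 weighted (total-derivative) estimator.
iw_phi_gradient <- function(loglik_fn, dloglik_fn, mu, log_var, eps,
                            method = c("dreg", "naive")) {
  method <- match.arg(method)
  sigma <- exp(log_var / 2)
  theta <- mu + sigma * eps
  v <- loglik_fn(theta) + dnorm(theta, log = TRUE) -
    dnorm(theta, mu, sigma, log = TRUE)
  w <- as.numeric(normalized_weights(matrix(v, nrow = 1)))
  dll <- dloglik_fn(theta)
  if (method == "dreg") {
    dv <- dll - theta + (theta - mu) / sigma^2   # q params frozen
    g_mu <- sum(w^2 * dv)
    g_lv <- sum(w^2 * dv * 0.5 * sigma * eps)
  } else {
    # total derivative: the explicit dependence of log q on (mu, log_var)
    # cancels part of the pathwise term
    g_mu <- sum(w * (dll - theta))
    g_lv <- sum(w * ((dll - theta + eps / sigma) * 0.5 * sigma * eps +
                       0.5 - 0.5 * eps^2))
  }
  c(mu = g_mu, log_var = g_lv)
}
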