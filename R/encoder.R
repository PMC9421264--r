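#' Initialize the amortized inference (encoder) network
#'
#' A multilayer perceptron with hyperbolic-tangent hidden layers and two
#' linear output heads producing the per-person variational mean and
#' log-variance. Weights use symmetric-uniform fan-in/fan-out (Glorot)
#' scaling; biases start at zero, so the initial posterior standard
#' deviation is 1 and training starts near the ability prior. Draws from
#' the current R random stream, so results are reproducible under
#' `set.seed()`.
#'
#' @param J input width (number of items).
#' @param K latent dimension (width of both heads).
#' @param hidden integer vector of hidden-layer sizes (nonempty).
#' @return An object of class `encoder_state`: lists `W`, `b` of hidden-layer
#'   weights/biases plus head matrices `W_mu`, `b_mu`, `W_lv`, `b_lv`.
#' @export
init_encoder <- function(J, K, hidden = c(130L, 65L)) {
  stopifnot(length(hidden) >= 1, all(hidden >= 1))
  sizes <- c(J, hidden)
  glorot <- function(nout, nin) {
    lim <- sqrt(6 / (nin + nout))
    matrix(runif(nout * nin, -lim, lim), nout, nin)
  }
  W <- vector("list", length(hidden))
  b <- vector("list", length(hidden))
  for (l in seq_along(hidden)) {
    W[[l]] <- glorot(sizes[l + 1], sizes[l])
    b[[l]] <- rep(0, sizes[l + 1])
  }
  structure(list(W = W, b = b,
                 W_mu = glorot(K, hidden[length(hidden)]), b_mu = rep(0, K),
                 W_lv = glorot(K, hidden[length(hidden)]), b_lv = rep(0, K)),
            class = "encoder_state")
}

#' @export
print.encoder_state <- function(x, ...) {
  dims <- c(ncol(x$W[[1]]), vapply(x$W, nrow, 1L), nrow(x$W_mu))
  cat("<encoder_state> tanh MLP ", paste(dims, collapse = " -> "),
      " (mu, log sigma^2 heads)\n", sep = "")
  invisible(x)
}

#' Encode responses into a diagonal-Gaussian variational posterior
#'
#' Deterministic forward pass `h = tanh(b_L + W_L tanh(... tanh(b_1 + W_1 y)))`
#' followed by the linear heads `mu = W_mu h + b_mu` and
#' `log sigma^2 = W_lv h + b_lv`. Missing responses must enter as exact
#' zeros (the zero-imputation convention), which removes their influence on
#' every neuron.
#'
#' @param y_filled n x J matrix of responses with zeros at missing cells.
#' @param state an [init_encoder] state.
#' @return An object of class `variational_posterior` with `mu` and
#'   `log_var` (both n x K).
#' @export
encode <- function(y_filled, state) {
  y_filled <- as.matrix(y_filled)
  if (ncol(y_filled) != ncol(state$W[[1]]))
    stop("encoder expects input width ", ncol(state$W[[1]]),
         ", got ", ncol(y_filled))
  H <- y_filled
  for (l in seq_along(state$W)) {
    H <- tanh(sweep(H %*% t(state$W[[l]]), 2, state$b[[l]], "+"))
  }
  mu <- sweep(H %*% t(state$W_mu), 2, state$b_mu, "+")
  lv <- sweep(H %*% t(state$W_lv), 2, state$b_lv, "+")
  structure(list(mu = mu, log_var = lv), class = "variational_posterior")
}

#' Reparameterized posterior sampling
#'
#' Draws `theta = mu + sigma * e`, `e ~ N(0, I)`, producing `S * R` samples
#' per person stacked person-major with the importance index `r` fastest
#' (matching the training core). Both the samples and the underlying
#' standard-normal draws are returned so pathwise gradients can flow
#' through `mu` and `sigma` only.
#'
#' @param post a `variational_posterior`.
#' @param S Monte Carlo sample count.
#' @param R importance sample count.
#' @return list with `theta`, `eps` ((n*S*R) x K matrices) and `person`
#'   (row-to-person index).
#' @export
reparameterize <- function(post, S = 1L, R = 1L) {
  stopifnot(S >= 1, R >= 1)
  n <- nrow(post$mu); K <- ncol(post$mu)
  M <- n * S * R
  eps <- matrix(rnorm(M * K), M, K)
  person <- rep(seq_len(n), each = S * R)
  sigma <- exp(post$log_var / 2)
  theta <- post$mu[person, , drop = FALSE] +
    sigma[person, , drop = FALSE] * eps
  list(theta = theta, eps = eps, person = person)
}

#' Analytic KL divergence to the standard-normal prior
#'
#' For a diagonal Gaussian posterior,
#' `KL = 1/2 sum_k (mu_k^2 + sigma_k^2 - 1 - log sigma_k^2)`, per person.
#' Nonnegative, and zero exactly at the prior.
#'
#' @param post a `variational_posterior`.
#' @return numeric vector, one KL per person.
#' @export
analytic_kl <- function(post) {
  s2 <- exp(post$log_var)
  0.5 * rowSums(post$mu^2 + s2 - 1 - post$log_var)
}

#' Variational log-density at sampled abilities
#'
#' Diagonal-Gaussian log-density `log q(theta | mu, sigma^2)` evaluated
#' row-wise, with posterior rows recycled over the per-person samples.
#'
#' @param theta (n*S*R) x K sample matrix.
#' @param post a `variational_posterior`.
#' @param person row-to-person index as returned by [reparameterize()].
#' @return numeric vector with one log-density per sample row.
#' @export
log_q_density <- function(theta, post, person) {
  mu <- post$mu[person, , drop = FALSE]
  sd <- exp(post$log_var / 2)[person, , drop = FALSE]
  rowSums(dnorm(theta, mu, sd, log = TRUE))
}
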