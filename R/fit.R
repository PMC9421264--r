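#' Training hyperparameters for the three-stage estimator
#'
#' Defaults follow the estimator's standard recipe: minibatch size 16,
#' `S = 1` Monte Carlo sample throughout, `R = 5` importance samples in the
#' final stage, fixed step size 0.01 for the encoder, loadings and easiness
#' and 0.001 for the asymptotes (their range is smaller), a hard iteration
#' cap `T_max = 200000`, KL annealing over the first 1% of `T_max`, and a
#' windowed convergence rule (mean objective over non-overlapping windows
#' of 100 steps must stop improving on its running best for 50 consecutive
#' windows).
#'
#' @param batch_size minibatch size (persons drawn with replacement).
#' @param S Monte Carlo samples per step.
#' @param R importance samples in the IW-ELBO stage.
#' @param lr_main step size for encoder weights, `A` and `b`.
#' @param lr_asymptote step size for the asymptote logits `c_raw`, `d_raw`.
#' @param T_max maximum iterations per convergence-monitored stage.
#' @param anneal_fraction fraction of `T_max` spent annealing the KL term,
#'   so `T_anl = ceiling(anneal_fraction * T_max)`.
#' @param window steps per convergence window.
#' @param patience windows without improvement before declaring convergence.
#' @param hidden hidden-layer sizes of the encoder MLP.
#' @return list of class `iwvae_control`.
#' @export
iwvae_control <- function(batch_size = 16L, S = 1L, R = 5L,
                          lr_main = 0.01, lr_asymptote = 0.001,
                          T_max = 200000L, anneal_fraction = 0.01,
                          window = 100L, patience = 50L,
                          hidden = c(130L, 65L)) {
  stopifnot(batch_size >= 1, S >= 1, R >= 1, lr_main > 0, lr_asymptote > 0,
            T_max >= 1, anneal_fraction > 0, anneal_fraction < 1,
            window >= 1, patience >= 1, length(hidden) >= 1)
  structure(list(batch_size = as.integer(batch_size), S = as.integer(S),
                 R = as.integer(R), lr_main = lr_main,
                 lr_asymptote = lr_asymptote, T_max = as.integer(T_max),
                 anneal_fraction = anneal_fraction,
                 T_anl = as.integer(ceiling(anneal_fraction * T_max)),
                 window = as.integer(window), patience = as.integer(patience),
                 hidden = as.integer(hidden)),
            class = "iwvae_control")
}

#' KL annealing weight
#'
#' Linear ramp `min(1, t / T_anl)`: the KL term's weight grows from 0 to 1
#' over the annealing stage and stays at 1 afterwards.
#'
#' @param t step number (>= 1).
#' @param T_anl length of the annealing stage.
#' @return weight in `[0, 1]` (vectorized over `t`).
#' @export
anneal_weight <- function(t, T_anl) {
  stopifnot(all(t >= 1), T_anl >= 1)
  pmin(1, t / T_anl)
}

#' Windowed convergence rule
#'
#' Maintains the running best window-mean objective; every window whose
#' mean fails to exceed the best increments a counter and an improving
#' window resets it and updates the best. Training in a stage stops when
#' the counter reaches `patience` consecutive non-improving windows.
#' `converged()` replays a full sequence of window means through the rule.
#'
#' @param window_means numeric vector of consecutive non-overlapping window
#'   means.
#' @param patience required run of non-improving windows.
#' @return list with `converged` (logical), `window` (index at which the
#'   rule fired, or `NA`), and the final monitor `state`.
#' @export
converged <- function(window_means, patience) {
  state <- monitor_state()
  for (i in seq_along(window_means)) {
    state <- monitor_update(state, window_means[i])
    if (state$counter >= patience)
      return(list(converged = TRUE, window = i, state = state))
  }
  list(converged = FALSE, window = NA_integer_, state = state)
}

monitor_state <- function() list(best = -Inf, counter = 0L)

monitor_update <- function(state, window_mean) {
  if (window_mean > state$best) {
    list(best = window_mean, counter = 0L)
  } else {
    list(best = state$best, counter = state$counter + 1L)
  }
}

#' Fit a MIRT model by importance-weighted amortized variational inference
#'
#' Three-stage stochastic gradient ascent: (1) KL-annealed ELBO for
#' `T_anl` steps with the asymptotes frozen, (2) ELBO until the windowed
#' convergence rule fires (or `T_max`), (3) IW-ELBO with `R` importance
#' samples and doubly reparameterized encoder gradients until it converges
#' again. The run is fully reproducible given `seed`. A fit is flagged
#' successful only if both monitored stages terminated via the convergence
#' rule rather than the iteration cap.
#'
#' @param data a [response_data], or a persons x items matrix/data frame
#'   with `NA` at unobserved cells.
#' @param model `"2PL"`, `"3PL"` or `"4PL"`.
#' @param K latent dimension.
#' @param control an [iwvae_control] list.
#' @param seed integer seed for initialization, minibatching and sampling.
#' @return An object of class `iwvae_fit`: `parameters`
#'   (an [item_parameters]), `encoder`, `trace` (tibble of window means by
#'   stage), `iterations` (per stage), `success`, `model`, `K`, `seed`,
#'   `control`.
#' @examples
#' sim <- sim_mirt_data(sim_config(N = 150, J = 12, K = 1, model = "2PL",
#'                                 missing_proportion = 0.3, seed = 7))
#' fit <- fit_iwvae(sim$data, model = "2PL", K = 1,
#'                  control = iwvae_control(T_max = 1500, patience = 5,
#'                                          hidden = c(16L, 8L)),
#'                  seed = 7)
#' glance(fit)
#' @export
fit_iwvae <- function(data, model = c("4PL", "3PL", "2PL"), K,
                      control = iwvae_control(), seed = 1L) {
  model <- normalize_model(model)
  stopifnot(inherits(control, "iwvae_control"), K >= 1)
  data <- as_response_data(data)
  J <- ncol(data$Y)
  const_cols <- which(colSums(data$mask) > 0 &
                        (colSums(data$Y * data$mask) == 0 |
                           colSums(data$Y * data$mask) == colSums(data$mask)))
  if (length(const_cols))
    warning("items observed as constant (all 0 or all 1): ",
            paste(head(const_cols), collapse = ", "))

  set.seed(seed)
  enc <- init_encoder(J, K, control$hidden)
  A0 <- matrix(rnorm(J * K, 0, 0.1), J, K)
  b0 <- rep(0, J)
  c_raw0 <- rep(qlogis(0.1), J)
  d_raw0 <- rep(qlogis(0.9), J)

  res <- cpp_fit(data$Y, data$mask, unclass(enc), A0, b0, c_raw0, d_raw0,
                 model_npar(model),
                 list(batch_size = control$batch_size, S = control$S,
                      R = control$R, lr_main = control$lr_main,
                      lr_asymptote = control$lr_asymptote,
                      T_max = control$T_max, T_anl = control$T_anl,
                      window = control$window, patience = control$patience))

  npl <- model_npar(model)
  params <- item_parameters(
    A = res$A, b = as.numeric(res$b),
    c = if (npl >= 3) plogis(as.numeric(res$c_raw)) else NULL,
    d = if (npl == 4) plogis(as.numeric(res$d_raw)) else NULL,
    model = model)

  trace <- dplyr::bind_rows(
    tibble::tibble(stage = "anneal", window = seq_along(res$trace_anneal),
                   objective = as.numeric(res$trace_anneal)),
    tibble::tibble(stage = "elbo", window = seq_along(res$trace_elbo),
                   objective = as.numeric(res$trace_elbo)),
    tibble::tibble(stage = "iwelbo", window = seq_along(res$trace_iwelbo),
                   objective = as.numeric(res$trace_iwelbo)))

  structure(list(parameters = params,
                 encoder = structure(res$encoder, class = "encoder_state"),
                 trace = trace,
                 iterations = stats::setNames(as.integer(res$iterations),
                                              c("anneal", "elbo", "iwelbo")),
                 converged = stats::setNames(as.logical(res$converged),
                                             c("anneal", "elbo", "iwelbo")),
                 success = isTRUE(all(res$converged)),
                 n_clamped = res$n_clamped,
                 model = model, K = as.integer(K), seed = as.integer(seed),
                 control = control),
            class = "iwvae_fit")
}

#' @export
print.iwvae_fit <- function(x, ...) {
  cat(sprintf("<iwvae_fit> M%s, K=%d, seed %d\n", x$model, x$K, x$seed))
  cat(sprintf("  iterations: anneal %d, elbo %d, iwelbo %d; success: %s\n",
              x$iterations[["anneal"]], x$iterations[["elbo"]],
              x$iterations[["iwelbo"]], x$success))
  invisible(x)
}

#' Posterior ability estimates for a fitted model
#'
#' Runs the fitted encoder on (zero-filled) responses and returns the
#' variational posterior means and standard deviations -- the amortized
#' analogue of EAP ability scores.
#'
#' @param object an `iwvae_fit`.
#' @param newdata a [response_data] or matrix with `NA`s at unobserved
#'   cells (fits do not store a copy of their training data, so the
#'   responses to score must be supplied).
#' @param ... unused.
#' @return tibble with person, factor, mean and sd columns.
#' @export
predict.iwvae_fit <- function(object, newdata, ...) {
  data <- as_response_data(newdata)
  post <- encode(data$Y, object$encoder)
  n <- nrow(post$mu); K <- ncol(post$mu)
  tibble::tibble(person = rep(seq_len(n), times = K),
                 factor = rep(seq_len(K), each = n),
                 mean = as.numeric(post$mu),
                 sd = as.numeric(exp(post$log_var / 2)))
}
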