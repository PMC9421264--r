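#' Simulation configuration for sparse-loading MIRT data
#'
#' Bundles the design of the synthetic-data generator: sample size, test
#' length, latent dimension, between- vs within-item multidimensionality,
#' independent vs correlated factors, the per-row missingness proportion,
#' and the model flavor.
#'
#' @param N number of persons (>= 1).
#' @param J number of items (>= K).
#' @param K latent dimension (>= 1; within-item structure needs K >= 2).
#' @param item_structure `"between"` (each item loads one factor) or
#'   `"within"` (each item loads two factors).
#' @param factor_mode `"independent"` (identity factor covariance) or
#'   `"correlated"` (unit-variance factors with Uniform(0,1) correlations).
#' @param missing_proportion fraction of each person's responses masked as
#'   unobserved; `round(missing_proportion * J)` cells per row. Default 0.8,
#'   i.e. each respondent answers 20% of the items.
#' @param model `"2PL"`, `"3PL"` or `"4PL"`.
#' @param seed integer seed making the whole generated bundle reproducible.
#' @param block_rows rows per factor in the seed block of the s-shaped
#'   loading pattern; default `max(1, round(J / (2 * K)))` so the pattern is
#'   built from at least two horizontally flipped copies of the seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(N, J, K,
                       item_structure = c("between", "within"),
                       factor_mode = c("independent", "correlated"),
                       missing_proportion = 0.8,
                       model = c("4PL", "3PL", "2PL"),
                       seed = 1L,
                       block_rows = NULL) {
  item_structure <- match.arg(item_structure)
  factor_mode <- match.arg(factor_mode)
  model <- normalize_model(model)
  stopifnot(N >= 1, J >= K, K >= 1,
            missing_proportion >= 0, missing_proportion < 1)
  if (item_structure == "within" && K < 2)
    stop("within-item structure requires K >= 2")
  if (is.null(block_rows)) block_rows <- max(1L, round(J / (2 * K)))
  structure(list(N = as.integer(N), J = as.integer(J), K = as.integer(K),
                 item_structure = item_structure, factor_mode = factor_mode,
                 missing_proportion = missing_proportion, model = model,
                 seed = as.integer(seed), block_rows = as.integer(block_rows)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config> M%s: N=%d, J=%d, K=%d, %s-item, %s ",
                     "factors, %.0f%% missing, seed %d\n"),
              x$model, x$N, x$J, x$K, x$item_structure, x$factor_mode,
              100 * x$missing_proportion, x$seed))
  invisible(x)
}

#' S-shaped sparse loading pattern
#'
#' Builds the binary support of the loading matrix: a blocked-diagonal seed
#' block with `block_rows` consecutive rows per factor is flipped left-right
#' and appended repeatedly until at least `J` rows exist, then truncated at
#' the bottom. Between-item rows carry exactly one loading; within-item rows
#' additionally load the (cyclically) next factor, giving two loadings.
#'
#' @param J,K item count and latent dimension.
#' @param structure `"between"` or `"within"`.
#' @param block_rows rows per factor in the seed block.
#' @return binary J x K matrix.
#' @export
loading_pattern <- function(J, K, structure = c("between", "within"),
                            block_rows = max(1L, round(J / (2 * K)))) {
  structure <- match.arg(structure)
  stopifnot(J >= K, K >= 1, block_rows >= 1)
  if (structure == "within" && K < 2)
    stop("within-item structure requires K >= 2")
  seed <- matrix(0L, nrow = block_rows * K, ncol = K)
  for (k in seq_len(K)) {
    rows <- ((k - 1) * block_rows + 1):(k * block_rows)
    seed[rows, k] <- 1L
    if (structure == "within") seed[rows, if (k == K) 1L else k + 1L] <- 1L
  }
  out <- seed
  block <- seed
  while (nrow(out) < J) {
    block <- block[, rev(seq_len(K)), drop = FALSE]  # horizontal flip
    out <- rbind(out, block)
  }
  out[seq_len(J), , drop = FALSE]
}

#' Draw item parameters on a fixed loading support
#'
#' Nonzero discriminations are Uniform(0.5, 1.5) on the pattern's support
#' (structural zeros stay exactly zero); easiness `b_j` is standard normal
#' (the conventional choice; configurable via `b_sampler`); guessing and
#' slipping asymptotes are drawn jointly as `c_j ~ Beta(1, 9)`,
#' `d_j ~ Beta(9, 1)` and the whole vector pair is redrawn until
#' `c_j < d_j` holds for every item. M3PL fixes `d = 1`; M2PL fixes
#' `c = 0, d = 1`.
#'
#' @param pattern binary J x K support matrix.
#' @param model `"2PL"`, `"3PL"` or `"4PL"`.
#' @param b_sampler function of `n` returning easiness draws.
#' @param max_redraws cap on the joint (c, d) rejection loop.
#' @return An [item_parameters] object whose `A` respects `pattern` exactly.
#' @export
sim_item_parameters <- function(pattern, model = c("4PL", "3PL", "2PL"),
                                b_sampler = function(n) rnorm(n),
                                max_redraws = 10000L) {
  model <- normalize_model(model)
  pattern <- as.matrix(pattern)
  stopifnot(all(pattern %in% c(0, 1)))
  J <- nrow(pattern)
  A <- matrix(0, J, ncol(pattern))
  nz <- which(pattern == 1)
  A[nz] <- runif(length(nz), 0.5, 1.5)
  b <- b_sampler(J)
  npl <- model_npar(model)
  c <- rep(0, J); d <- rep(1, J)
  if (npl == 4) {
    for (i in seq_len(max_redraws)) {
      c <- rbeta(J, 1, 9)
      d <- rbeta(J, 9, 1)
      if (all(c < d)) break
      if (i == max_redraws)
        stop("asymptote rejection loop exceeded ", max_redraws, " redraws")
    }
  } else if (npl == 3) {
    c <- rbeta(J, 1, 9)
  }
  item_parameters(A = A, b = b, c = c, d = d, model = model)
}

#' Draw a unit-variance factor covariance matrix
#'
#' Independent mode returns the identity. Correlated mode sets the diagonal
#' to 1, draws upper-triangle entries iid Uniform(0, 1), mirrors them, and
#' accepts the matrix if its smallest eigenvalue is `>= -tol`, redrawing
#' otherwise.
#'
#' @param K latent dimension.
#' @param mode `"independent"` or `"correlated"`.
#' @param max_redraws cap on the positive-semidefiniteness rejection loop.
#' @param tol eigenvalue tolerance for acceptance.
#' @return K x K covariance (correlation) matrix.
#' @export
sim_factor_covariance <- function(K, mode = c("independent", "correlated"),
                                  max_redraws = 10000L, tol = 1e-10) {
  mode <- match.arg(mode)
  if (mode == "independent" || K == 1) return(diag(K))
  for (i in seq_len(max_redraws)) {
    S <- diag(K)
    S[upper.tri(S)] <- runif(K * (K - 1) / 2)
    S[lower.tri(S)] <- t(S)[lower.tri(S)]
    if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) >= -tol)
      return(S)
  }
  stop("factor covariance rejection loop exceeded ", max_redraws, " redraws")
}

#' Simulate binary responses from the IRF
#'
#' Independent Bernoulli draws `Y_ij ~ Bernoulli(IRF(theta_i; item j))`
#' (local independence).
#'
#' @param theta N x K ability matrix.
#' @param params an [item_parameters] object.
#' @return N x J binary matrix.
#' @export
sim_responses <- function(theta, params) {
  P <- irf(theta, params)
  matrix(rbinom(length(P), 1, P), nrow = nrow(P))
}

#' Mask a fixed fraction of each person's responses
#'
#' For each row independently, a uniformly random subset of exactly
#' `round(proportion * J)` cells is marked unobserved, so every person has
#' the same observed count (deterministic design rather than iid Bernoulli
#' masking).
#'
#' @param Y N x J binary matrix.
#' @param proportion fraction of each row to mask, in `[0, 1)`.
#' @return A [response_data] object.
#' @export
mask_responses <- function(Y, proportion = 0.8) {
  stopifnot(proportion >= 0, proportion < 1)
  J <- ncol(Y)
  n_miss <- round(proportion * J)
  Ym <- Y
  if (n_miss > 0) {
    for (i in seq_len(nrow(Y))) Ym[i, sample.int(J, n_miss)] <- NA
  }
  response_data(Ym)
}

#' Generate a full synthetic MIRT dataset with ground truth
#'
#' Composes the generator: s-shaped loading pattern, item parameters,
#' factor covariance, abilities `theta ~ N(0, Sigma)`, Bernoulli responses,
#' and row-wise masking. Deterministic given `cfg$seed`.
#'
#' @param cfg a [sim_config].
#' @return A list of class `sim_mirt` with elements `data` (a
#'   [response_data]) and `truth` (list with `params`, `theta`, `sigma`,
#'   `pattern`), plus the `config`.
#' @export
sim_mirt_data <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  pattern <- loading_pattern(cfg$J, cfg$K, cfg$item_structure, cfg$block_rows)
  params <- sim_item_parameters(pattern, cfg$model)
  sigma <- sim_factor_covariance(cfg$K, cfg$factor_mode)
  theta <- rmvnorm_chol(cfg$N, sigma)
  Y <- sim_responses(theta, params)
  data <- mask_responses(Y, cfg$missing_proportion)
  structure(list(data = data,
                 truth = list(params = params, theta = theta,
                              sigma = sigma, pattern = pattern),
                 config = cfg),
            class = "sim_mirt")
}

# N draws from N(0, sigma) via the (upper) Cholesky factor
rmvnorm_chol <- function(N, sigma) {
  K <- ncol(sigma)
  Z <- matrix(rnorm(N * K), N, K)
  if (all(sigma == diag(K))) Z else Z %*% chol(sigma)
}

#' @export
print.sim_mirt <- function(x, ...) {
  print(x$config)
  print(x$data)
  invisible(x)
}
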