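#' Promax rotation of an estimated loading matrix
#'
#' Standard promax (varimax followed by a powered-target oblique
#' procrustes, via `stats::promax`): resolves the rotational indeterminacy
#' of exploratory loadings while allowing correlated factors. Also returns
#' the factor correlation implied by the oblique transform,
#' `Phi = solve(crossprod(rotmat))`. With `K = 1` the input is returned
#' unchanged.
#'
#' @param A_hat J x K estimated loading matrix.
#' @param kappa promax power (Hendrickson-White default 4).
#' @return list with `loadings`, `rotmat` and `phi`.
#' @export
promax_rotate <- function(A_hat, kappa = 4) {
  A_hat <- as.matrix(A_hat)
  K <- ncol(A_hat)
  if (K == 1)
    return(list(loadings = A_hat, rotmat = diag(1), phi = diag(1)))
  if (qr(A_hat)$rank < K)
    stop("rank-deficient loading matrix (rank ", qr(A_hat)$rank,
         " < K = ", K, "): promax rotation is undefined")
  pm <- stats::promax(A_hat, m = kappa)
  rot <- pm$rotmat
  phi <- solve(crossprod(rot))
  phi <- (phi + t(phi)) / 2
  list(loadings = unclass(pm$loadings), rotmat = rot, phi = phi)
}

#' Sign-align rotated loadings
#'
#' Every column of the rotated loadings with a negative sum is negated,
#' and the corresponding row and column of the factor correlation are
#' negated with it (the diagonal is unchanged). A column summing exactly
#' to zero keeps its sign with a warning.
#'
#' @param A_r J x K rotated loadings.
#' @param R_r K x K factor correlation.
#' @return list with `loadings`, `phi`, `signs`.
#' @export
sign_align <- function(A_r, R_r = diag(ncol(A_r))) {
  A_r <- as.matrix(A_r)
  cs <- colSums(A_r)
  if (any(cs == 0)) warning("column sum exactly zero; sign kept as is")
  s <- ifelse(cs < 0, -1, 1)
  D <- diag(s, ncol(A_r))
  list(loadings = A_r %*% D, phi = D %*% R_r %*% D, signs = s)
}

#' Best column permutation against a reference
#'
#' Exhaustively searches the `K!` column orders of the sign-aligned
#' loadings for the one minimizing the mean squared deviation from the
#' reference matrix (ties broken by lexicographically first permutation).
#' Limited to `K <= 8`.
#'
#' @param A_rf J x K candidate loadings.
#' @param A_true J x K reference loadings.
#' @return list with `permutation`, `loadings` (permuted candidate) and
#'   `mse`.
#' @export
best_permutation <- function(A_rf, A_true) {
  A_rf <- as.matrix(A_rf); A_true <- as.matrix(A_true)
  K <- ncol(A_rf)
  stopifnot(all(dim(A_rf) == dim(A_true)))
  if (K > 8)
    stop("exhaustive permutation search limited to K <= 8; ",
         "use assignment-based matching for larger K")
  perms <- permutations(K)
  mses <- apply(perms, 1, function(p) mean((A_rf[, p] - A_true)^2))
  best <- which.min(mses)   # first minimum = lexicographic tie-break
  p <- perms[best, ]
  list(permutation = p, loadings = A_rf[, p, drop = FALSE], mse = mses[best])
}

# all K! permutations of 1:k in lexicographic row order
permutations <- function(k) {
  if (k == 1) return(matrix(1L))
  sub <- permutations(k - 1L)
  out <- do.call(rbind, lapply(seq_len(k), function(i) {
    rest <- seq_len(k)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
  dimnames(out) <- NULL
  out
}

#' Full rotation / sign / permutation alignment of estimated loadings
#'
#' Applies promax rotation, sign flips, and the best column permutation
#' against the generating loadings, returning the aligned matrix and the
#' correspondingly adjusted implied factor correlation.
#'
#' @param A_hat J x K estimated loadings.
#' @param A_true J x K reference (generating) loadings.
#' @param kappa promax power.
#' @return list of class `alignment` with `A_aligned`, `rotation`, `signs`,
#'   `permutation` and `R_hat`.
#' @export
align_loadings <- function(A_hat, A_true, kappa = 4) {
  pr <- promax_rotate(A_hat, kappa = kappa)
  sa <- sign_align(pr$loadings, pr$phi)
  bp <- best_permutation(sa$loadings, A_true)
  R_hat <- sa$phi[bp$permutation, bp$permutation, drop = FALSE]
  structure(list(A_aligned = bp$loadings, rotation = pr$rotmat,
                 signs = sa$signs, permutation = bp$permutation,
                 R_hat = R_hat),
            class = "alignment")
}

#' Root mean squared error across replications
#'
#' For each scalar parameter, `RMSE = sqrt((1/B) sum_b (xi_hat_b - xi)^2)`
#' over `B` replications. `estimates` holds one replication per row.
#'
#' @param estimates B x P matrix (or length-P vector for B = 1).
#' @param truth length-P vector of generating values.
#' @return length-P vector of per-parameter RMSEs.
#' @export
rmse <- function(estimates, truth) {
  if (is.null(dim(estimates))) estimates <- matrix(estimates, nrow = 1)
  stopifnot(ncol(estimates) == length(truth))
  sqrt(colMeans((sweep(estimates, 2, truth))^2))
}

#' Evaluate a set of replicated fits against the generating parameters
#'
#' For each fit the estimated loadings are promax-rotated, sign-flipped and
#' column-permuted against the true `A`; easiness and asymptotes are
#' item-indexed and compared directly (only factor-indexed quantities
#' suffer rotational indeterminacy). Per-parameter RMSEs over the
#' replications are then averaged within each parameter block, with the
#' standard error of that average taken across parameters. The success
#' rate is the fraction of fits whose monitored stages converged before
#' the iteration cap.
#'
#' @param fits list of `iwvae_fit` objects for the same dataset.
#' @param truth the `truth` element of a [sim_mirt_data()] bundle (or any
#'   list with an [item_parameters] element `params`).
#' @param kappa promax power for the alignment.
#' @return An object of class `iwvae_report`: tibble `report` with columns
#'   `parameter`, `rmse`, `se`, `n_params`, plus `success_rate` and `B`.
#' @export
evaluate_replications <- function(fits, truth, kappa = 4) {
  if (length(fits) == 0) stop("empty list of fits")
  pt <- truth$params
  npl <- model_npar(fits[[1]]$model)
  B <- length(fits)

  A_est <- t(vapply(fits, function(f)
    as.numeric(align_loadings(f$parameters$A, pt$A, kappa)$A_aligned),
    numeric(length(pt$A))))
  blocks <- list(loading = list(est = A_est, truth = as.numeric(pt$A)))
  blocks$b <- list(
    est = t(vapply(fits, function(f) f$parameters$b, numeric(length(pt$b)))),
    truth = pt$b)
  if (npl >= 3)
    blocks$c <- list(
      est = t(vapply(fits, function(f) f$parameters$c, numeric(length(pt$c)))),
      truth = pt$c)
  if (npl == 4)
    blocks$d <- list(
      est = t(vapply(fits, function(f) f$parameters$d, numeric(length(pt$d)))),
      truth = pt$d)

  report <- purrr::map_dfr(names(blocks), function(nm) {
    r <- rmse(blocks[[nm]]$est, blocks[[nm]]$truth)
    tibble::tibble(parameter = nm, rmse = mean(r),
                   se = stats::sd(r) / sqrt(length(r)),
                   n_params = length(r))
  })

  structure(list(report = report,
                 success_rate = mean(vapply(fits, function(f) f$success,
                                            logical(1))),
                 B = B),
            class = "iwvae_report")
}

#' @export
print.iwvae_report <- function(x, ...) {
  cat(sprintf("<iwvae_report> B = %d replications, success rate %.2f\n",
              x$B, x$success_rate))
  print(as.data.frame(x$report), row.names = FALSE)
  invisible(x)
}

#' Held-out prediction accuracy and per-item log-likelihood
#'
#' Scores a fitted model on cells held out from training: the encoder's
#' posterior means on the training responses feed the IRF, a response is
#' predicted correct when its probability reaches `threshold`, accuracy is
#' the agreement fraction over held-out observed cells, and the per-item
#' log-likelihood is the mean Bernoulli log-likelihood of the held-out
#' cells of each item.
#'
#' @param train_data [response_data] used for fitting (held-out cells
#'   masked).
#' @param heldout_data [response_data] holding the held-out responses; its
#'   observed cells must be disjoint from the training-observed cells.
#' @param fit an `iwvae_fit`.
#' @param threshold classification cut for predicted probabilities.
#' @return list with `accuracy`, `mean_loglik` and tibble `item_loglik`.
#' @export
heldout_predict <- function(train_data, heldout_data, fit, threshold = 0.5) {
  train_data <- as_response_data(train_data)
  heldout_data <- as_response_data(heldout_data)
  if (any(train_data$mask * heldout_data$mask == 1))
    stop("held-out cells must be disjoint from training-observed cells")
  hm <- heldout_data$mask
  if (sum(hm) == 0) stop("empty held-out set")
  post <- encode(train_data$Y, fit$encoder)
  P <- irf(post$mu, fit$parameters)
  P <- pmin(pmax(P, 1e-7), 1 - 1e-7)
  pred <- 1 * (P >= threshold)
  acc <- sum(hm * (pred == heldout_data$Y)) / sum(hm)
  ll_cell <- hm * (heldout_data$Y * log(P) + (1 - heldout_data$Y) * log(1 - P))
  n_item <- colSums(hm)
  item_ll <- ifelse(n_item > 0, colSums(ll_cell) / n_item, NA_real_)
  list(accuracy = acc,
       mean_loglik = sum(ll_cell) / sum(hm),
       item_loglik = tibble::tibble(item = seq_along(item_ll),
                                    n_heldout = n_item,
                                    loglik = item_ll))
}

#' Split observed cells into training and held-out sets
#'
#' Uniformly marks `proportion` of the observed cells of each person as
#' held out, returning disjoint training and held-out response objects --
#' the standard held-out validation design for missing-data IRT fits.
#'
#' @param data a [response_data].
#' @param proportion fraction of observed cells per person to hold out.
#' @return list with `train` and `heldout` [response_data] objects.
#' @export
heldout_split <- function(data, proportion = 0.2) {
  data <- as_response_data(data)
  stopifnot(proportion > 0, proportion < 1)
  Ytr <- ifelse(data$mask == 1, data$Y, NA)
  Yho <- matrix(NA_real_, nrow(data$Y), ncol(data$Y))
  for (i in seq_len(nrow(data$Y))) {
    obs <- which(data$mask[i, ] == 1)
    n_ho <- max(1L, round(proportion * length(obs)))
    if (n_ho >= length(obs)) n_ho <- length(obs) - 1L
    ho <- obs[sample.int(length(obs), n_ho)]
    Yho[i, ho] <- data$Y[i, ho]
    Ytr[i, ho] <- NA
  }
  list(train = response_data(Ytr),
       heldout = response_data(Yho, allow_empty_rows = TRUE))
}
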