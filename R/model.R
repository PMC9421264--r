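#' Item parameter sets for multidimensional logistic IRT models
#'
#' Container for the measurement ("decoder") parameters of an M2PL, M3PL or
#' M4PL model: a J x K loading (discrimination) matrix `A`, a length-J
#' easiness vector `b`, and lower/upper asymptotes `c`, `d` in (0, 1).
#' The asymptotes are stored both on the probability scale and as
#' unconstrained logits (`c_raw`, `d_raw`), the scale on which gradient
#' updates operate. M3PL fixes `d = 1` (no slipping); M2PL additionally
#' fixes `c = 0` (no guessing).
#'
#' @param A numeric J x K loading matrix.
#' @param b numeric length-J easiness vector. `-b_j / ||a_j||` is the usual
#'   item difficulty.
#' @param c lower asymptotes (guessing probabilities), length J. Ignored for
#'   `"2PL"`.
#' @param d upper asymptotes (1 - slipping probabilities), length J. Ignored
#'   for `"2PL"` and `"3PL"`.
#' @param model one of `"2PL"`, `"3PL"`, `"4PL"` (a leading "M" is accepted).
#' @return An object of class `item_parameters`.
#' @export
item_parameters <- function(A, b, c = NULL, d = NULL,
                            model = c("4PL", "3PL", "2PL")) {
  model <- normalize_model(model)
  A <- as.matrix(A)
  J <- nrow(A)
  stopifnot(length(b) == J)
  npl <- model_npar(model)
  if (npl >= 3) {
    if (is.null(c)) stop("`c` is required for the ", model, " model")
    stopifnot(length(c) == J, all(c >= 0), all(c < 1))
  } else {
    c <- rep(0, J)
  }
  if (npl == 4) {
    if (is.null(d)) stop("`d` is required for the 4PL model")
    stopifnot(length(d) == J, all(d > 0), all(d <= 1))
  } else {
    d <- rep(1, J)
  }
  structure(
    list(A = A, b = as.numeric(b),
         c = as.numeric(c), d = as.numeric(d),
         c_raw = if (npl >= 3) unconstrain_unit(c) else rep(NA_real_, J),
         d_raw = if (npl == 4) unconstrain_unit(d) else rep(NA_real_, J),
         model = model),
    class = "item_parameters")
}

normalize_model <- function(model) {
  model <- toupper(match.arg(sub("^M", "", toupper(model[1])),
                             c("4PL", "3PL", "2PL")))
  model
}

model_npar <- function(model) as.integer(substr(model, 1, 1))

#' @export
print.item_parameters <- function(x, ...) {
  cat(sprintf("<item_parameters> M%s: %d items, %d factors\n",
              x$model, nrow(x$A), ncol(x$A)))
  invisible(x)
}

#' Map (0,1)-constrained asymptotes to the unconstrained logit scale
#'
#' `constrain_unit()` is the inverse logit and `unconstrain_unit()` the
#' logit. Values at exactly 0 or 1 are clamped into (0, 1) with a warning
#' so that the transform stays finite; the pair is an exact round trip on
#' the open interval.
#'
#' @param x_raw,x numeric vectors on the unconstrained / probability scale.
#' @return numeric vector of the same length.
#' @export
constrain_unit <- function(x_raw) plogis(x_raw)

#' @rdname constrain_unit
#' @export
unconstrain_unit <- function(x) {
  eps <- 1e-12
  if (any(x <= 0 | x >= 1)) {
    warning("values at or beyond {0, 1} clamped before logit transform")
    x <- pmin(pmax(x, eps), 1 - eps)
  }
  qlogis(x)
}

#' Item response function
#'
#' Probability of a correct response, `P = c + (d - c) * plogis(A theta + b)`,
#' evaluated for a batch of ability vectors. As `a'theta + b -> -Inf` the
#' probability tends to the guessing floor `c`; as it tends to `+Inf` the
#' probability tends to the ceiling `d`.
#'
#' @param theta numeric length-K vector or n x K matrix of abilities.
#' @param params an [item_parameters] object.
#' @return n x J matrix of response probabilities.
#' @export
irf <- function(theta, params) {
  theta <- to_theta_matrix(theta, ncol(params$A))
  if (any(!is.finite(theta))) stop("non-finite abilities passed to irf()")
  eta <- theta %*% t(params$A)
  eta <- sweep(eta, 2, params$b, "+")
  s <- plogis(eta)
  sweep(sweep(s, 2, params$d - params$c, "*"), 2, params$c, "+")
}

to_theta_matrix <- function(theta, K) {
  if (is.null(dim(theta))) theta <- matrix(theta, ncol = K)
  stopifnot(ncol(theta) == K)
  theta
}

#' Masked Bernoulli log-likelihood
#'
#' Per-person log-likelihood of binary responses under the IRF, summing
#' `mask * [y log P + (1 - y) log(1 - P)]` over items: unobserved cells
#' contribute exactly zero regardless of the placeholder stored there.
#' Probabilities are clamped to `[1e-7, 1 - 1e-7]` before the logs so that
#' asymptotes at the boundary cannot produce `-Inf`.
#'
#' @param Y n x J binary matrix (placeholders allowed at masked cells).
#' @param mask n x J observation indicators (1 = observed).
#' @param theta n x K ability matrix, one row per row of `Y` (a length-K
#'   vector is recycled across rows).
#' @param params an [item_parameters] object.
#' @return numeric vector of length n.
#' @export
masked_loglik <- function(Y, mask, theta, params) {
  Y <- as.matrix(Y); mask <- as.matrix(mask)
  stopifnot(all(dim(Y) == dim(mask)))
  if (any(rowSums(mask) == 0)) stop("every row must have at least one observed item")
  if (is.null(dim(theta)) && nrow(Y) > 1)
    theta <- matrix(theta, nrow = nrow(Y), ncol = length(theta), byrow = TRUE)
  P <- irf(theta, params)
  P <- pmin(pmax(P, 1e-7), 1 - 1e-7)
  Y0 <- ifelse(mask == 1, Y, 0)   # neutralize placeholders
  rowSums(mask * (Y0 * log(P) + (1 - Y0) * log(1 - P)))
}

#' Log-density of the standard Gaussian ability prior
#'
#' `log N(theta; 0, I_K)` per row.
#'
#' @param theta length-K vector or n x K matrix.
#' @return numeric vector of length n.
#' @export
log_prior <- function(theta) {
  if (is.null(dim(theta))) theta <- matrix(theta, nrow = 1)
  if (any(!is.finite(theta))) stop("non-finite abilities passed to log_prior()")
  K <- ncol(theta)
  -K / 2 * log(2 * pi) - rowSums(theta^2) / 2
}

#' Binary response data with an observation mask
#'
#' Wraps a persons x items binary matrix together with its missingness
#' mask. `NA` entries in `Y` are treated as unobserved; internally they are
#' stored as 0 (the zero-imputation the encoder relies on) with `mask = 0`,
#' so data zeros and missingness are never conflated.
#'
#' @param Y numeric matrix with entries in `{0, 1, NA}`.
#' @param allow_empty_rows keep rows with no observed entry (used for
#'   held-out containers); the default rejects them, since a person with no
#'   observed response cannot be encoded.
#' @return An object of class `response_data` with elements `Y` (zero-filled
#'   matrix), `mask`, and `ids` (row/column labels).
#' @export
response_data <- function(Y, allow_empty_rows = FALSE) {
  Y <- as.matrix(Y)
  mask <- 1 * !is.na(Y)
  obs <- Y[!is.na(Y)]
  if (!all(obs %in% c(0, 1)))
    stop("observed responses must be 0 or 1; found: ",
         paste(utils::head(setdiff(unique(obs), c(0, 1))), collapse = ", "))
  bad <- which(rowSums(mask) == 0)
  if (length(bad) && !allow_empty_rows)
    stop("rows with no observed responses: ", paste(head(bad), collapse = ", "))
  Y[is.na(Y)] <- 0
  structure(list(Y = Y, mask = mask,
                 ids = list(persons = rownames(Y), items = colnames(Y))),
            class = "response_data")
}

as_response_data <- function(x) {
  if (inherits(x, "response_data")) return(x)
  if (is.data.frame(x)) x <- as.matrix(x)
  response_data(x)
}

#' @export
print.response_data <- function(x, ...) {
  cat(sprintf("<response_data> %d persons x %d items, %.1f%% observed\n",
              nrow(x$Y), ncol(x$Y), 100 * mean(x$mask)))
  invisible(x)
}
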