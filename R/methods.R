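#' Tidy item-parameter estimates from a fit
#'
#' One row per item parameter: loadings are indexed by item and factor,
#' easiness and asymptotes by item only.
#'
#' @param x an `iwvae_fit`.
#' @param ... unused.
#' @return tibble with `parameter`, `item`, `factor`, `estimate`.
#' @export
tidy.iwvae_fit <- function(x, ...) {
  p <- x$parameters
  J <- nrow(p$A); K <- ncol(p$A)
  out <- tibble::tibble(parameter = "loading",
                        item = rep(seq_len(J), times = K),
                        factor = rep(seq_len(K), each = J),
                        estimate = as.numeric(p$A))
  out <- dplyr::bind_rows(
    out,
    tibble::tibble(parameter = "b", item = seq_len(J), factor = NA_integer_,
                   estimate = p$b))
  npl <- model_npar(x$model)
  if (npl >= 3)
    out <- dplyr::bind_rows(out, tibble::tibble(
      parameter = "c", item = seq_len(J), factor = NA_integer_,
      estimate = p$c))
  if (npl == 4)
    out <- dplyr::bind_rows(out, tibble::tibble(
      parameter = "d", item = seq_len(J), factor = NA_integer_,
      estimate = p$d))
  out
}

#' One-row fit summary
#'
#' @param x an `iwvae_fit`.
#' @param ... unused.
#' @return tibble with model, dimensions, per-stage iteration counts, the
#'   final window-mean objectives and the success flag.
#' @export
glance.iwvae_fit <- function(x, ...) {
  last_obj <- function(st) {
    v <- x$trace$objective[x$trace$stage == st]
    if (length(v)) v[length(v)] else NA_real_
  }
  tibble::tibble(model = paste0("M", x$model), K = x$K,
                 J = nrow(x$parameters$A),
                 iter_anneal = x$iterations[["anneal"]],
                 iter_elbo = x$iterations[["elbo"]],
                 iter_iwelbo = x$iterations[["iwelbo"]],
                 elbo = last_obj("elbo"),
                 iw_elbo = last_obj("iwelbo"),
                 success = x$success, seed = x$seed)
}

#' Tidy an evaluation report
#'
#' @param x an `iwvae_report`.
#' @param ... unused.
#' @return the report tibble with `success_rate` and `B` columns appended.
#' @export
tidy.iwvae_report <- function(x, ...) {
  dplyr::mutate(x$report, success_rate = x$success_rate, B = x$B)
}

#' Objective trace plot for a fit
#'
#' Window-mean objective by training stage: the annealed ELBO ramp, the
#' ELBO plateau, and the jump to the (tighter) importance-weighted bound.
#'
#' @param object an `iwvae_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.iwvae_fit <- function(object, ...) {
  tr <- dplyr::mutate(object$trace,
                      stage = factor(.data$stage,
                                     levels = c("anneal", "elbo", "iwelbo")),
                      step = (dplyr::row_number() - 1L) *
                        object$control$window)
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$step, y = .data$objective,
                                   colour = .data$stage)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "training step", y = "window-mean objective",
                  colour = "stage") +
    ggplot2::theme_minimal()
}

#' RMSE report plot
#'
#' Mean RMSE per parameter block with +/- 1 SE error bars.
#'
#' @param object an `iwvae_report`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.iwvae_report <- function(object, ...) {
  ggplot2::ggplot(object$report,
                  ggplot2::aes(x = .data$parameter, y = .data$rmse)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$rmse - .data$se,
                                        ymax = .data$rmse + .data$se),
                           width = 0.2) +
    ggplot2::labs(x = NULL, y = "mean RMSE") +
    ggplot2::theme_minimal()
}

#' Loading-matrix heat map
#'
#' @param A J x K loading matrix (estimated, aligned, or generating).
#' @param title optional plot title.
#' @return a ggplot.
#' @export
plot_loadings <- function(A, title = NULL) {
  df <- tibble::tibble(item = rep(seq_len(nrow(A)), times = ncol(A)),
                       factor = rep(seq_len(ncol(A)), each = nrow(A)),
                       loading = as.numeric(A))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$factor, y = .data$item,
                                   fill = .data$loading)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "firebrick", mid = "white",
                                  high = "navy") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(title = title, x = "factor", y = "item") +
    ggplot2::theme_minimal()
}
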