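#' Read and write binary response tables
#'
#' Responses travel as delimited text: persons in rows, a header row of
#' item ids, and a configurable missing code (default `"NA"`) marking
#' unobserved cells, so data zeros and missingness are never conflated.
#' Any observed symbol other than 0/1 is rejected with its location.
#'
#' @param path file path.
#' @param missing_code string marking unobserved cells.
#' @param data a [response_data] to write.
#' @return `read_responses()` returns a [response_data];
#'   `write_responses()` returns `path` invisibly.
#' @export
read_responses <- function(path, missing_code = "NA") {
  df <- readr::read_csv(path, na = missing_code, col_types = readr::cols(
    .default = readr::col_double()))
  M <- as.matrix(df)
  bad <- which(!is.na(M) & !(M %in% c(0, 1)), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-binary response %g at row %d, column '%s'",
                 M[bad[1, 1], bad[1, 2]], bad[1, 1], colnames(M)[bad[1, 2]]))
  response_data(M)
}

#' @rdname read_responses
#' @export
write_responses <- function(data, path, missing_code = "NA") {
  data <- as_response_data(data)
  Y <- ifelse(data$mask == 1, data$Y, NA)
  colnames(Y) <- data$ids$items %||% paste0("item", seq_len(ncol(Y)))
  readr::write_csv(tibble::as_tibble(Y), path, na = missing_code)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write and read a simulated ground-truth bundle
#'
#' Stores the generating quantities of a [sim_mirt_data()] bundle as a
#' directory of delimited matrices (`A`, `b`, `c`, `d`, `theta`, `sigma`,
#' `pattern`) plus a YAML manifest recording the configuration and a
#' checksum per artifact.
#'
#' @param sim a `sim_mirt` bundle.
#' @param dir output directory (created if needed).
#' @return `write_ground_truth()` returns `dir` invisibly;
#'   `read_ground_truth()` returns a `truth` list.
#' @export
write_ground_truth <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_mirt"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tr <- sim$truth
  mats <- list(A = tr$params$A, b = matrix(tr$params$b),
               c = matrix(tr$params$c), d = matrix(tr$params$d),
               theta = tr$theta, sigma = tr$sigma, pattern = tr$pattern)
  for (nm in names(mats)) {
    utils::write.csv(mats[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  cfg <- unclass(sim$config)
  files <- file.path(dir, paste0(names(mats), ".csv"))
  manifest <- list(config = cfg, model = sim$config$model,
                   artifacts = as.list(stats::setNames(
                     unname(tools::md5sum(files)), basename(files))))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  rd <- function(nm) as.matrix(utils::read.csv(file.path(dir,
                                                         paste0(nm, ".csv"))))
  A <- unname(rd("A"))
  params <- item_parameters(A = A, b = as.numeric(rd("b")),
                            c = as.numeric(rd("c")), d = as.numeric(rd("d")),
                            model = manifest$model)
  list(params = params, theta = unname(rd("theta")),
       sigma = unname(rd("sigma")), pattern = unname(rd("pattern")),
       config = manifest$config)
}

#' Write a fitted model as a directory of plain-text artifacts
#'
#' Parameter matrices and the trace go to CSV, the encoder weights to YAML,
#' and a manifest lists configuration, seed, iteration counts and a
#' checksum for every artifact written, which is sufficient to reproduce
#' the run.
#'
#' @param fit an `iwvae_fit`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_fit <- function(fit, dir) {
  stopifnot(inherits(fit, "iwvae_fit"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- fit$parameters
  utils::write.csv(p$A, file.path(dir, "A.csv"), row.names = FALSE)
  utils::write.csv(data.frame(b = p$b, c = p$c, d = p$d),
                   file.path(dir, "items.csv"), row.names = FALSE)
  readr::write_csv(fit$trace, file.path(dir, "trace.csv"))
  enc <- lapply(unclass(fit$encoder), function(x)
    if (is.list(x)) lapply(x, as.numeric_with_dim) else as.numeric_with_dim(x))
  yaml::write_yaml(enc, file.path(dir, "encoder.yaml"), precision = 15L)
  files <- file.path(dir, c("A.csv", "items.csv", "trace.csv", "encoder.yaml"))
  manifest <- list(model = fit$model, K = fit$K, seed = fit$seed,
                   control = unclass(fit$control),
                   iterations = as.list(fit$iterations),
                   success = fit$success,
                   artifacts = as.list(stats::setNames(
                     unname(tools::md5sum(files)), basename(files))))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

as.numeric_with_dim <- function(x) {
  if (is.matrix(x)) list(dim = dim(x), data = as.numeric(x))
  else list(dim = length(x), data = as.numeric(x))
}

from_numeric_with_dim <- function(x) {
  if (length(x$dim) == 2) matrix(unlist(x$data), x$dim[[1]], x$dim[[2]])
  else unlist(x$data)
}

#' Read a fitted model written by [write_fit()]
#'
#' @param dir directory written by [write_fit()].
#' @return an `iwvae_fit` (without the original control's class retained
#'   for unknown fields).
#' @export
read_fit <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  A <- unname(as.matrix(utils::read.csv(file.path(dir, "A.csv"))))
  items <- utils::read.csv(file.path(dir, "items.csv"))
  npl <- model_npar(manifest$model)
  params <- item_parameters(A = A, b = items$b,
                            c = if (npl >= 3) items$c else NULL,
                            d = if (npl == 4) items$d else NULL,
                            model = manifest$model)
  enc_raw <- yaml::read_yaml(file.path(dir, "encoder.yaml"))
  enc <- list(W = lapply(enc_raw$W, from_numeric_with_dim),
              b = lapply(enc_raw$b, from_numeric_with_dim),
              W_mu = from_numeric_with_dim(enc_raw$W_mu),
              b_mu = from_numeric_with_dim(enc_raw$b_mu),
              W_lv = from_numeric_with_dim(enc_raw$W_lv),
              b_lv = from_numeric_with_dim(enc_raw$b_lv))
  control <- do.call(iwvae_control, manifest$control[
    setdiff(names(manifest$control), "T_anl")])
  structure(list(parameters = params,
                 encoder = structure(enc, class = "encoder_state"),
                 trace = readr::read_csv(file.path(dir, "trace.csv"),
                                         col_types = "cid"),
                 iterations = unlist(manifest$iterations),
                 success = manifest$success,
                 model = manifest$model, K = manifest$K,
                 seed = manifest$seed, control = control),
            class = "iwvae_fit")
}

#' Read a simulation or training configuration from YAML
#'
#' @param path YAML file with a `simulation:` and/or `training:` section
#'   whose keys match the arguments of [sim_config()] / [iwvae_control()].
#' @return list with elements `simulation` (a [sim_config] or `NULL`) and
#'   `training` (an [iwvae_control] or `NULL`).
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim <- if (!is.null(raw$simulation)) {
    s <- raw$simulation
    # YAML 1.1 reads a bare key `N` as a boolean; map it back
    names(s)[names(s) == "FALSE"] <- "N"
    do.call(sim_config, s)
  }
  trn <- if (!is.null(raw$training)) do.call(iwvae_control, raw$training)
  list(simulation = sim, training = trn)
}
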