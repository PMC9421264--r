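#' Simulate, refit, and evaluate a full replication experiment
#'
#' Generates one dataset from `sim_cfg`, fits it `B` times with seeds
#' `seed + 1, ..., seed + B` (replication randomness lives in
#' initialization, minibatching and sampling, matching a
#' one-dataset/many-fits replication design), and evaluates the fits
#' against the generating parameters. With `fresh_data = TRUE` a new
#' dataset is generated per replication instead.
#'
#' @param sim_cfg a [sim_config]; its `model` decides the fitted flavor.
#' @param control an [iwvae_control].
#' @param B replication count.
#' @param seed top-level seed; defaults to `sim_cfg$seed`.
#' @param fresh_data regenerate the data each replication.
#' @param verbose print one line per completed fit.
#' @return An `iwvae_report` (see [evaluate_replications()]) with the fits
#'   attached as attribute `"fits"`.
#' @export
run_benchmark <- function(sim_cfg, control = iwvae_control(), B = 5L,
                          seed = sim_cfg$seed, fresh_data = FALSE,
                          verbose = FALSE) {
  stopifnot(inherits(sim_cfg, "sim_config"), B >= 1)
  sim <- sim_mirt_data(sim_cfg)
  fits <- vector("list", B)
  for (b in seq_len(B)) {
    if (fresh_data && b > 1) {
      cfg_b <- sim_cfg
      cfg_b$seed <- sim_cfg$seed + b
      sim <- sim_mirt_data(cfg_b)
    }
    fits[[b]] <- fit_iwvae(sim$data, model = sim_cfg$model, K = sim_cfg$K,
                           control = control, seed = seed + b)
    if (verbose)
      message(sprintf("fit %d/%d: %s after %s iterations", b, B,
                      if (fits[[b]]$success) "converged" else "hit cap",
                      paste(fits[[b]]$iterations, collapse = "/")))
  }
  rep <- evaluate_replications(fits, sim$truth)
  attr(rep, "fits") <- fits
  attr(rep, "truth") <- sim$truth
  rep
}
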