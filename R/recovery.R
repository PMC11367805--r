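#' Simulate response frequencies from a fitted model
#'
#' Draws, for every participant and condition cell, a binomial number of
#' correct responses with success probability given by the model tree
#' evaluated at the participant's individual point estimates -- the
#' "simulate behavioral data from the original parameters" step of
#' parameter recovery.
#'
#' @param fit An [fit_mpt()] result.
#' @param trial_totals Per-cell trial totals: a matrix (participants x
#'   conditions) or a single number; defaults to the totals observed in the
#'   fitted data, mirroring the original design's information content.
#' @param seed Integer seed.
#'
#' @return A frequency tibble (`participant`, `condition`, `n_correct`,
#'   `n_trials`).
#' @export
simulate_from_fit <- function(fit, trial_totals = NULL, seed = 1) {
  stopifnot(inherits(fit, "mpt_fit"))
  model <- fit$model
  ids <- fit$data$ids
  conds <- model$conditions
  if (is.null(trial_totals)) trial_totals <- fit$data$N
  if (length(trial_totals) == 1) {
    trial_totals <- matrix(trial_totals, length(ids), length(conds),
                           dimnames = list(ids, conds))
  }
  if (!all(dim(trial_totals) == c(length(ids), length(conds))) ||
      any(is.na(trial_totals))) {
    stop("trial_totals must give a count for every participant x cell",
         call. = FALSE)
  }
  theta_hat <- fit$individual |>
    tidyr::pivot_wider(names_from = "parameter", values_from = "estimate")
  theta_mat <- as.matrix(theta_hat[match(ids, theta_hat$participant),
                                   model$parameters])
  p <- prob_correct_matrix(model, theta_mat)
  withr_seed(seed, {
    counts <- rbinom(length(p), size = as.vector(t(trial_totals)),
                     prob = as.vector(t(p)))
    tibble::tibble(
      participant = rep(ids, each = length(conds)),
      condition = rep(conds, length(ids)),
      n_correct = counts,
      n_trials = as.vector(t(trial_totals))
    )
  })
}

#' Parameter recovery within a measurement occasion
#'
#' The four-step recovery procedure: (1) estimate individual parameters
#' from the observed frequencies ("original"), (2) simulate new frequencies
#' from those estimates with the observed per-cell trial totals, (3) refit
#' the model to the simulated data ("recovered"), and (4) correlate
#' original with recovered individual estimates, per parameter.  Recovery
#' is conventionally considered acceptable when `r > .70`.
#'
#' @param freq A single-occasion frequency tibble.
#' @param model An [mpt_model].
#' @param control An [mcmc_control()] used for both fits.
#' @param seed Seed for the simulation step (fit seeds come from
#'   `control`).
#' @param original_fit Optionally, an existing [fit_mpt()] of `freq` to
#'   reuse for step 1.
#'
#' @return An object of class `mpt_recovery`: a tibble with one row per
#'   parameter (`parameter`, `r`, `n`, `z`, `se_z`, `acceptable`) and
#'   attributes `converged_original`, `converged_recovered`, `seed`.
#' @export
run_recovery <- function(freq, model, control = mcmc_control(), seed = 1,
                         original_fit = NULL) {
  if (is.null(original_fit)) original_fit <- fit_mpt(freq, model, control)
  sim <- simulate_from_fit(original_fit, seed = seed)
  recovered_fit <- fit_mpt(sim, model, control)
  orig <- original_fit$individual |>
    dplyr::rename(original = "estimate")
  rec <- recovered_fit$individual |>
    dplyr::rename(recovered = "estimate")
  res <- dplyr::inner_join(orig, rec, by = c("participant", "parameter")) |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(r = cor(.data$original, .data$recovered),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(z = atanh(pmin(pmax(.data$r, -1 + 1e-12), 1 - 1e-12)),
                  se_z = sqrt(1 / (.data$n - 3)),
                  acceptable = .data$r > 0.70) |>
    dplyr::arrange(match(.data$parameter, model$parameters))
  structure(res, class = c("mpt_recovery", class(res)),
            converged_original = original_fit$converged,
            converged_recovered = recovered_fit$converged,
            refit_glance = glance(recovered_fit),
            seed = seed)
}

#' Repeatability of simulated response frequencies
#'
#' Simulates `m` frequency tables from one fit and correlates the
#' participant-by-cell correct-count vectors: between every pair of
#' simulations, and between each simulation and the originally observed
#' frequencies.  High simulation-to-simulation correlations mean the
#' fitted parameters pin down behavior tightly.
#'
#' @param fit An [fit_mpt()] result.
#' @param m Number of simulations (>= 2).
#' @param seed Base seed; simulation `j` uses `seed + j`.
#' @param trial_totals As in [simulate_from_fit()].
#'
#' @return A list of class `mpt_repeatability`: `sim_sim` (tibble of the
#'   `m(m-1)/2` pairwise correlations), `sim_orig` (tibble of the `m`
#'   simulation-vs-original correlations), and `summary` (their means).
#' @export
repeatability <- function(fit, m = 5, seed = 1, trial_totals = NULL) {
  stopifnot(inherits(fit, "mpt_fit"), m >= 2)
  sims <- lapply(seq_len(m), function(j) {
    simulate_from_fit(fit, trial_totals = trial_totals, seed = seed + j)
  })
  vecs <- lapply(sims, function(s) s$n_correct)
  orig_vec <- as.vector(t(fit$data$y))
  pairs <- utils::combn(m, 2)
  sim_sim <- tibble::tibble(
    sim_i = pairs[1, ], sim_j = pairs[2, ],
    r = apply(pairs, 2, function(ij) cor(vecs[[ij[1]]], vecs[[ij[2]]]))
  )
  sim_orig <- tibble::tibble(
    sim = seq_len(m),
    r = vapply(vecs, function(v) cor(v, orig_vec), numeric(1))
  )
  structure(list(
    sim_sim = sim_sim, sim_orig = sim_orig,
    summary = tibble::tibble(mean_sim_sim = mean(sim_sim$r),
                             mean_sim_orig = mean(sim_orig$r))
  ), class = "mpt_repeatability")
}

#' @export
print.mpt_repeatability <- function(x, ...) {
  cat("<mpt_repeatability> mean sim-vs-sim r = ",
      formatC(x$summary$mean_sim_sim, digits = 3, format = "f"),
      ", mean sim-vs-original r = ",
      formatC(x$summary$mean_sim_orig, digits = 3, format = "f"), "\n",
      sep = "")
  invisible(x)
}
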