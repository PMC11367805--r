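#' Default probit-scale group means for a shipped model
#'
#' Chosen so implied cell accuracies fall in the plausible IAT regime
#' (~.70-.95): modest association activation, moderate detection/control,
#' neutral guessing.
#'
#' @param model `"quad"` or `"pdp"`.
#' @return Named numeric vector of probit-scale means.
#' @export
synth_default_mu <- function(model = c("quad", "pdp")) {
  model <- match.arg(model)
  probs <- switch(model,
    quad = c(AC_wg = 0.20, AC_bb = 0.20, D = 0.65, OB = 0.40, G = 0.50),
    pdp = c(A_White = 0.60, A_Black = 0.45, C_White = 0.60, C_Black = 0.60,
            C_good = 0.60, C_bad = 0.60)
  )
  qnorm(probs)
}

#' Configure a synthetic two-occasion IAT dataset
#'
#' Describes the generative model the package uses for end-to-end testing:
#' individual probit-scale parameter vectors are drawn from a multivariate
#' normal `MVN(mu, Sigma)` at occasion 1; occasion-2 latents have the same
#' marginals with per-parameter between-occasion correlation `rho` (the
#' ground-truth stability the downstream ICC estimates).  Trials per cell
#' follow the 7-block design (60 critical trials per pairing, 15 per cell)
#' or the abbreviated 5-block design (two 32-trial critical blocks, 8 per
#' cell).
#'
#' @param model `"quad"` or `"pdp"`.
#' @param n_participants Number of participants.
#' @param design `"standard"` (15 trials/cell) or `"abbreviated"`
#'   (8 trials/cell); ignored when `trials_per_cell` is given.
#' @param trials_per_cell Trials in each of the 8 cells (per occasion).
#' @param mu Probit-scale group means (named; defaults to
#'   [synth_default_mu()]).
#' @param sd Probit-scale between-person SDs (scalar or named vector,
#'   default 0.5).
#' @param corr Between-parameter correlation matrix (default identity).
#' @param rho Between-occasion latent stability per parameter in `[-1, 1]`
#'   (scalar or named vector, default 0.5).
#' @param seed Integer seed.
#' @param study Dataset label.
#' @param time_rank Ordered rank of the between-occasion time interval
#'   (used by the moderator analysis).
#'
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(model = c("quad", "pdp"), n_participants = 100,
                         design = c("standard", "abbreviated"),
                         trials_per_cell = NULL, mu = NULL, sd = 0.5,
                         corr = NULL, rho = 0.5, seed = 1,
                         study = "synthetic", time_rank = NA_integer_) {
  model <- match.arg(model)
  design <- match.arg(design)
  spec <- if (model == "quad") mpt_quad() else mpt_pdp()
  pars <- spec$parameters
  P <- length(pars)
  if (is.null(trials_per_cell)) {
    trials_per_cell <- if (design == "standard") 15L else 8L
  }
  stopifnot(trials_per_cell >= 1, n_participants >= 1)
  if (is.null(mu)) mu <- synth_default_mu(model)
  mu <- expand_named(mu, pars, "mu")
  sd <- expand_named(sd, pars, "sd")
  rho <- expand_named(rho, pars, "rho")
  stopifnot(all(rho >= -1 & rho <= 1), all(sd > 0))
  if (is.null(corr)) corr <- diag(P)
  stopifnot(nrow(corr) == P, ncol(corr) == P)
  if (min(eigen(corr, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stop("corr is not positive semi-definite", call. = FALSE)
  }
  structure(list(model = model, n_participants = as.integer(n_participants),
                 design = design, trials_per_cell = as.integer(trials_per_cell),
                 mu = mu, sd = sd, corr = corr, rho = rho,
                 seed = as.integer(seed), study = study,
                 time_rank = as.integer(time_rank)),
            class = "synth_config")
}

expand_named <- function(x, pars, what) {
  if (length(x) == 1 && is.null(names(x))) {
    return(setNames(rep(x, length(pars)), pars))
  }
  if (is.null(names(x)) && length(x) == length(pars)) {
    return(setNames(x, pars))
  }
  if (!all(pars %in% names(x))) {
    stop(what, " must cover all model parameters", call. = FALSE)
  }
  x[pars]
}

#' Generate a synthetic two-occasion IAT dataset with known ground truth
#'
#' Occasion-1 latents are drawn `eta1 ~ MVN(mu, Sigma)` with
#' `Sigma = diag(sd) corr diag(sd)`; occasion-2 latents are
#' `eta2 = mu + R (eta1 - mu) + e` with `R = diag(rho)` and
#' `e ~ MVN(0, Sigma - R Sigma R)`, so marginals are preserved and
#' `cor(eta1_p, eta2_p) = rho_p`.  Probability-scale parameters are
#' `theta = Phi(eta)` and each cell's trials are Bernoulli with the model's
#' predicted accuracy.
#'
#' @param cfg A [synth_config()].
#' @param output `"trials"` (default) emits trial-level records in the
#'   [read_trials()] format; `"frequencies"` draws per-cell binomial counts
#'   directly (use for very large trial counts).
#'
#' @return A list of class `synth_iat`: `trials` (or `frequencies`),
#'   `truth` (per participant x occasion latent `eta` and probability-scale
#'   `theta`, plus `mu`, `Sigma`, `rho`), and the config.
#' @export
generate_iat <- function(cfg, output = c("trials", "frequencies")) {
  stopifnot(inherits(cfg, "synth_config"))
  output <- match.arg(output)
  model <- if (cfg$model == "quad") mpt_quad() else mpt_pdp()
  pars <- model$parameters
  P <- length(pars)
  Sigma <- diag(cfg$sd) %*% cfg$corr %*% diag(cfg$sd)
  dimnames(Sigma) <- list(pars, pars)
  R <- diag(cfg$rho, P)
  resid <- Sigma - R %*% Sigma %*% R
  if (min(eigen(resid, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stop("stability rho incompatible with Sigma: residual covariance is ",
         "not positive semi-definite", call. = FALSE)
  }
  n <- cfg$n_participants
  withr_seed(cfg$seed, {
    eta1 <- MASS::mvrnorm(n, cfg$mu, Sigma)
    eta2 <- matrix(cfg$mu, n, P, byrow = TRUE) +
      sweep(eta1 - matrix(cfg$mu, n, P, byrow = TRUE), 2, cfg$rho, `*`) +
      MASS::mvrnorm(n, rep(0, P), resid + diag(1e-12, P))
    colnames(eta1) <- colnames(eta2) <- pars
    ids <- sprintf("p%04d", seq_len(n))
    theta <- list(pnorm(eta1), pnorm(eta2))
    pcorr <- lapply(theta, function(th) prob_correct_matrix(model, th))
    tpc <- cfg$trials_per_cell
    conds <- model$conditions
    if (output == "trials") {
      rows <- lapply(1:2, function(occ) {
        p_flat <- rep(as.vector(t(pcorr[[occ]])), each = tpc)
        tibble::tibble(
          participant = rep(ids, each = length(conds) * tpc),
          occasion = occ,
          condition = rep(rep(conds, each = tpc), n),
          correct = rbinom(length(p_flat), 1, p_flat)
        )
      })
      trials <- dplyr::bind_rows(rows) |>
        tidyr::separate_wider_delim("condition", "_",
                                    names = c("category", "block")) |>
        dplyr::select("participant", "occasion", "block", "category",
                      "correct")
      payload <- list(trials = trials)
    } else {
      freqs <- lapply(1:2, function(occ) {
        counts <- rbinom(n * length(conds), tpc, as.vector(t(pcorr[[occ]])))
        tibble::tibble(
          participant = rep(ids, each = length(conds)),
          occasion = occ,
          condition = rep(conds, n),
          n_correct = counts,
          n_trials = tpc
        )
      })
      payload <- list(frequencies = dplyr::bind_rows(freqs))
    }
    truth_tab <- dplyr::bind_rows(lapply(1:2, function(occ) {
      tibble::tibble(
        participant = rep(ids, times = P),
        occasion = occ,
        parameter = rep(pars, each = n),
        eta = as.vector(if (occ == 1) eta1 else eta2),
        theta = as.vector(theta[[occ]])
      )
    }))
    structure(c(payload, list(
      truth = list(parameters = truth_tab, mu = cfg$mu, Sigma = Sigma,
                   rho = cfg$rho),
      config = cfg
    )), class = "synth_iat")
  })
}

# evaluate expr under a temporary seed, restoring RNG state afterwards
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Write a synthetic dataset to disk
#'
#' Emits the trial-level CSV (in the [read_trials()] input format) and a
#' ground-truth JSON.
#'
#' @param x A `synth_iat` from [generate_iat()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_synth <- function(x, dir) {
  stopifnot(inherits(x, "synth_iat"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stem <- file.path(dir, x$config$study)
  paths <- c(trials = paste0(stem, "_trials.csv"),
             truth = paste0(stem, "_truth.json"))
  tab <- if (!is.null(x$trials)) x$trials else x$frequencies
  readr::write_csv(tab, paths[["trials"]])
  jsonlite::write_json(
    list(mu = as.list(x$truth$mu), rho = as.list(x$truth$rho),
         Sigma = x$truth$Sigma, parameters = x$truth$parameters,
         seed = x$config$seed),
    paths[["truth"]], digits = NA, auto_unbox = TRUE
  )
  invisible(paths)
}

#' Preset six-dataset panel mirroring a multi-study two-occasion design
#'
#' Six configurations whose sample sizes (1240, 105, 80, 463, 116, 32) and
#' time-interval ordering (one browser session < 24-48 hr < 1-4 days (two
#' studies, tied) < 1 month < 2 years) reflect the sample-size spread and
#' retest intervals of real two-occasion race-IAT studies; the two
#' 1-4-day studies use the abbreviated 5-block design.  All
#' six share the default group means and covariance and carry distinct
#' seeds, so the full meta-analytic pipeline can be exercised at
#' realistic or reduced scale.
#'
#' @param scale Multiplier on the sample sizes (rounded half-up, floor of
#'   4 participants).
#' @param model `"quad"` or `"pdp"`.
#' @param rho Stability passed to every config (scalar or named).
#' @param base_seed Seeds are `base_seed + 1:6`.
#' @param ... Further arguments passed to [synth_config()].
#'
#' @return A list of six [synth_config()] objects.
#' @export
preset_panel <- function(scale = 1, model = "quad", rho = 0.5,
                         base_seed = 100, ...) {
  n_full <- c(1240, 105, 80, 463, 116, 32)
  studies <- c("browser_session", "day1_2", "lai_study1", "lai_study2",
               "month1", "year2")
  designs <- c("standard", "standard", "abbreviated", "abbreviated",
               "standard", "standard")
  ranks <- c(1L, 2L, 3L, 3L, 4L, 5L)
  n <- pmax(4, floor(n_full * scale + 0.5))
  lapply(seq_along(n_full), function(i) {
    synth_config(model = model, n_participants = n[i], design = designs[i],
                 rho = rho, seed = base_seed + i, study = studies[i],
                 time_rank = ranks[i], ...)
  })
}
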