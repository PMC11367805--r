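#' MCMC settings for the hierarchical latent-trait fit
#'
#' @param n_chains Number of MCMC chains (>= 2; split R-hat needs several).
#' @param n_adapt Adaptation iterations for the sampler.
#' @param n_burnin Burn-in iterations discarded after adaptation.
#' @param n_iter Sampling iterations per chain (before thinning).
#' @param thin Thinning interval.
#' @param rhat_threshold Convergence criterion: the fit is flagged as
#'   converged when every group-level split R-hat is below this (default
#'   1.05).
#' @param seed Integer seed; chain `k` uses `seed + k`.
#' @param prior_mu_mean,prior_mu_sd Normal prior on the probit-scale group
#'   means (weakly informative, zero-centered by default).
#' @param xi_upper Upper bound of the uniform prior on the covariance scale
#'   factors of the scaled inverse-Wishart prior (Wishart with identity
#'   scale and `P + 1` degrees of freedom on the raw precision).
#' @param point_estimate `"mean"` (default) or `"median"`: the posterior
#'   summary used for individual-level parameter estimates.
#'
#' @return A list of class `mcmc_control`.
#' @export
mcmc_control <- function(n_chains = 2, n_adapt = 1000, n_burnin = 1000,
                         n_iter = 4000, thin = 2, rhat_threshold = 1.05,
                         seed = 1, prior_mu_mean = 0, prior_mu_sd = 1,
                         xi_upper = 10, point_estimate = c("mean", "median")) {
  stopifnot(n_chains >= 2, rhat_threshold > 1, n_adapt >= 0,
            n_burnin >= 0, n_iter >= thin, thin >= 1)
  structure(list(
    n_chains = as.integer(n_chains), n_adapt = as.integer(n_adapt),
    n_burnin = as.integer(n_burnin), n_iter = as.integer(n_iter),
    thin = as.integer(thin), rhat_threshold = rhat_threshold,
    seed = as.integer(seed), prior_mu_mean = prior_mu_mean,
    prior_mu_sd = prior_mu_sd, xi_upper = xi_upper,
    point_estimate = match.arg(point_estimate)
  ), class = "mcmc_control")
}

# BUGS expression for P(correct) in one condition: sum over correct branches
# of products of theta[i,k] / (1-theta[i,k]) terms.
bugs_cell_expression <- function(model, condition) {
  br <- model$branches[model$branches$condition == condition &
                         model$branches$response == "correct", ]
  if (nrow(br) == 0) return("0")
  terms <- vapply(br$factors, function(f) {
    idx <- match(f$parameter, model$parameters)
    paste(ifelse(f$complement,
                 sprintf("(1-theta[i,%d])", idx),
                 sprintf("theta[i,%d]", idx)),
          collapse = "*")
  }, character(1))
  paste(terms, collapse = " + ")
}

# Full BUGS model: probit latent traits under a multivariate normal with a
# scaled inverse-Wishart covariance prior (raw effects keep the Wishart
# conjugate), binomial cell counts.
bugs_model_code <- function(model, control) {
  cells <- vapply(seq_along(model$conditions), function(j) {
    sprintf("    pr[i,%d] <- %s", j,
            bugs_cell_expression(model, model$conditions[j]))
  }, character(1))
  prec <- 1 / control$prior_mu_sd^2
  paste0(
    "model {\n",
    "  for (i in 1:S) {\n",
    "    etaRaw[i,1:P] ~ dmnorm(zeros[1:P], TauRaw[1:P,1:P])\n",
    "    for (p in 1:P) {\n",
    "      theta[i,p] <- phi(mu[p] + xi[p]*etaRaw[i,p])\n",
    "    }\n",
    paste(cells, collapse = "\n"), "\n",
    "    for (c in 1:C) {\n",
    # squeeze keeps dbin off the exact 0/1 boundary at extreme thetas
    "      prc[i,c] <- 1.0E-9 + 0.999999998*pr[i,c]\n",
    "      y[i,c] ~ dbin(prc[i,c], N[i,c])\n",
    "    }\n",
    "  }\n",
    sprintf("  for (p in 1:P) { mu[p] ~ dnorm(%g, %g) }\n",
            control$prior_mu_mean, prec),
    "  TauRaw[1:P,1:P] ~ dwish(V[1:P,1:P], df)\n",
    sprintf("  for (p in 1:P) { xi[p] ~ dunif(0, %g) }\n", control$xi_upper),
    "  SigmaRaw[1:P,1:P] <- inverse(TauRaw[,])\n",
    "  for (p in 1:P) { for (q in 1:P) {\n",
    "    Sigma[p,q] <- SigmaRaw[p,q]*xi[p]*xi[q]\n",
    "  } }\n",
    "}\n"
  )
}

freq_to_matrices <- function(freq, model) {
  freq <- dplyr::arrange(freq, .data$participant,
                         match(.data$condition, model$conditions))
  ids <- unique(freq$participant)
  shape <- function(col) {
    m <- matrix(freq[[col]], nrow = length(ids), ncol = length(model$conditions),
                byrow = TRUE, dimnames = list(ids, model$conditions))
    m
  }
  if (nrow(freq) != length(ids) * length(model$conditions)) {
    stop("frequency table must have one row per participant x condition ",
         "cell; use aggregate_frequencies()", call. = FALSE)
  }
  list(ids = ids, y = shape("n_correct"), N = shape("n_trials"))
}

#' Fit a hierarchical latent-trait MPT model
#'
#' Individual probit-scale parameter vectors are modeled as draws from a
#' multivariate normal population distribution, `theta_i = Phi(eta_i)` with
#' `eta_i ~ MVN(mu, Sigma)`; each participant's eight cell counts are
#' binomial with success probabilities given by the model tree.  Posterior
#' sampling runs in JAGS on code generated from the model's branch table;
#' convergence is assessed with split R-hat on all group-level quantities.
#'
#' @param freq A frequency tibble from [aggregate_frequencies()] (or
#'   [generate_iat()]), restricted to a single measurement occasion.
#' @param model An [mpt_model].
#' @param control An [mcmc_control()].
#' @param occasion If `freq` spans several occasions, which one to fit.
#'
#' @return An object of class `mpt_fit` with elements `group` (per-parameter
#'   posterior summaries of the population mean on probit and probability
#'   scales, with R-hats), `Sigma` (posterior-mean probit-scale covariance),
#'   `individual` (per-participant point estimates on the probability
#'   scale), `rhats`, `converged`, plus the model, control and data used.
#' @export
fit_mpt <- function(freq, model, control = mcmc_control(), occasion = NULL) {
  if (!is.null(occasion)) freq <- dplyr::filter(freq, .data$occasion == !!occasion)
  if (nrow(freq) == 0) stop("empty frequency table", call. = FALSE)
  if ("occasion" %in% names(freq) && dplyr::n_distinct(freq$occasion) > 1) {
    stop("freq spans multiple occasions; fit each occasion separately ",
         "(occasion = ...)", call. = FALSE)
  }
  P <- length(model$parameters)
  dat <- freq_to_matrices(freq, model)
  inits <- lapply(seq_len(control$n_chains), function(k) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = control$seed + k)
  })
  jm <- withCallingHandlers(
    rjags::jags.model(
      textConnection(bugs_model_code(model, control)),
      data = list(y = dat$y, N = dat$N, S = nrow(dat$y), P = P,
                  C = length(model$conditions), V = diag(P), df = P + 1,
                  zeros = rep(0, P)),
      inits = inits, n.chains = control$n_chains, n.adapt = control$n_adapt,
      quiet = TRUE
    ),
    # expected under deliberately short adaptation budgets; convergence is
    # judged by R-hat, not by the adaptation flag
    warning = function(w) {
      if (grepl("Adaptation incomplete", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  if (control$n_burnin > 0) update(jm, control$n_burnin)
  draws <- rjags::coda.samples(jm, c("mu", "Sigma", "theta"),
                               n.iter = control$n_iter, thin = control$thin)
  chain_mat <- function(name) sapply(draws, function(ch) as.numeric(ch[, name]))

  mu_names <- sprintf("mu[%d]", seq_len(P))
  sigma_names <- as.vector(outer(seq_len(P), seq_len(P),
                                 function(p, q) sprintf("Sigma[%d,%d]", p, q)))
  group_rhats <- vapply(c(mu_names, sigma_names),
                        function(nm) rhat(chain_mat(nm)), numeric(1))
  rhats <- tibble::tibble(quantity = names(group_rhats), rhat = group_rhats)

  all_draws <- do.call(rbind, lapply(draws, as.matrix))
  summarise_fun <- if (control$point_estimate == "mean") mean else stats::median
  mu_draws <- all_draws[, mu_names, drop = FALSE]
  prob_draws <- pnorm(mu_draws)
  group <- tibble::tibble(
    parameter = model$parameters,
    mean_probit = colMeans(mu_draws),
    sd_probit = apply(mu_draws, 2, stats::sd),
    mean_prob = colMeans(prob_draws),
    ci_low_prob = apply(prob_draws, 2, stats::quantile, 0.025),
    ci_high_prob = apply(prob_draws, 2, stats::quantile, 0.975),
    rhat = unname(group_rhats[mu_names])
  )
  Sigma <- matrix(colMeans(all_draws[, sigma_names, drop = FALSE]), P, P,
                  dimnames = list(model$parameters, model$parameters))
  n_part <- length(dat$ids)
  theta_names <- as.vector(outer(seq_len(n_part), seq_len(P),
                                 function(i, p) sprintf("theta[%d,%d]", i, p)))
  theta_est <- apply(all_draws[, theta_names, drop = FALSE], 2, summarise_fun)
  individual <- tidyr::expand_grid(parameter = model$parameters,
                                   participant = dat$ids)[, 2:1] |>
    dplyr::mutate(estimate = unname(theta_est)) |>
    dplyr::arrange(.data$participant,
                   match(.data$parameter, model$parameters))
  max_rhat <- max(rhats$rhat, na.rm = TRUE)
  structure(list(
    group = group, Sigma = Sigma, individual = individual, rhats = rhats,
    converged = is.finite(max_rhat) && max_rhat < control$rhat_threshold,
    max_rhat = max_rhat, model = model, control = control,
    data = list(y = dat$y, N = dat$N, ids = dat$ids),
    n_participants = n_part
  ), class = "mpt_fit")
}

#' @export
print.mpt_fit <- function(x, ...) {
  cat("<mpt_fit> ", x$model$name, ": ", x$n_participants,
      " participants\n", sep = "")
  cat("  converged: ", x$converged, " (max R-hat ",
      formatC(x$max_rhat, digits = 3, format = "f"), ", threshold ",
      x$control$rhat_threshold, ")\n", sep = "")
  print(as.data.frame(x$group), digits = 3)
  invisible(x)
}

#' Split R-hat (Gelman--Rubin potential scale reduction)
#'
#' Each chain is split in half, and the potential scale reduction factor is
#' computed over the resulting half-chains: `sqrt(((n-1)/n * W + B/n) / W)`.
#' Stationary, well-mixed chains give values near 1.
#'
#' @param x A matrix with one column per chain (iterations in rows), or a
#'   list of equal-length numeric chains.
#'
#' @return A single R-hat value; `NA` (with a warning) when the chains have
#'   zero variance, for which the statistic is undefined.
#' @export
rhat <- function(x) {
  if (is.list(x)) {
    lens <- lengths(x)
    if (length(unique(lens)) != 1) {
      stop("chains must have equal lengths", call. = FALSE)
    }
    x <- do.call(cbind, x)
  }
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("R-hat requires at least 2 chains", call. = FALSE)
  n2 <- floor(nrow(x) / 2)
  halves <- do.call(cbind, lapply(seq_len(ncol(x)), function(j) {
    cbind(x[seq_len(n2), j], x[seq(nrow(x) - n2 + 1, nrow(x)), j])
  }))
  n <- nrow(halves)
  m <- ncol(halves)
  W <- mean(apply(halves, 2, var))
  if (!is.finite(W) || W == 0) {
    warning("zero within-chain variance; R-hat undefined", call. = FALSE)
    return(NA_real_)
  }
  B <- n * var(colMeans(halves))
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Individual maximum-likelihood MPT estimate
#'
#' Fits one participant's cell counts by direct numeric maximization of the
#' product-binomial likelihood on the probit scale.  This is a
#' non-hierarchical estimator intended for diagnostics and as an
#' independent check of the hierarchical fit in the large-count limit.
#'
#' @param freq A frequency tibble for a single participant and occasion
#'   (one row per condition cell).
#' @param model An [mpt_model].
#' @param eta_bound Probit-scale magnitude beyond which an estimate is
#'   reported as a boundary solution.
#'
#' @return A tibble with columns `parameter`, `estimate` (probability
#'   scale) and `boundary` (logical).
#' @export
fit_mle_individual <- function(freq, model, eta_bound = 4) {
  if ("participant" %in% names(freq) &&
      dplyr::n_distinct(freq$participant) > 1) {
    stop("fit_mle_individual expects a single participant", call. = FALSE)
  }
  freq <- dplyr::arrange(freq, match(.data$condition, model$conditions))
  y <- freq$n_correct
  N <- freq$n_trials
  if (all(N == 0)) stop("all cells have zero trials", call. = FALSE)
  P <- length(model$parameters)
  nll <- function(eta) {
    theta <- matrix(pnorm(eta), nrow = 1,
                    dimnames = list(NULL, model$parameters))
    p <- pmin(pmax(prob_correct_matrix(model, theta)[1, ], 1e-12), 1 - 1e-12)
    -sum(y * log(p) + (N - y) * log(1 - p))
  }
  opt <- optim(rep(0, P), nll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  tibble::tibble(
    parameter = model$parameters,
    estimate = pnorm(opt$par),
    boundary = abs(opt$par) > eta_bound
  )
}

#' @export
#' @method tidy mpt_fit
#' @rdname fit_mpt
#' @param x An `mpt_fit`.
#' @param ... Unused.
tidy.mpt_fit <- function(x, ...) x$individual

#' @export
#' @method glance mpt_fit
#' @rdname fit_mpt
glance.mpt_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model$name,
    n_participants = x$n_participants,
    n_parameters = length(x$model$parameters),
    max_rhat = x$max_rhat,
    converged = x$converged,
    n_chains = x$control$n_chains,
    n_draws = x$control$n_chains * (x$control$n_iter %/% x$control$thin),
    seed = x$control$seed
  )
}
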