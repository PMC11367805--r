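# Independent oracles used across the suite.

# Brute-force tree enumeration: evaluate every branch product with plain
# scalar arithmetic and accumulate per (condition, response).
oracle_category_prob <- function(model, theta) {
  out <- list()
  for (b in seq_len(nrow(model$branches))) {
    f <- model$branches$factors[[b]]
    prob <- 1
    for (k in seq_len(nrow(f))) {
      v <- theta[[f$parameter[k]]]
      prob <- prob * (if (f$complement[k]) 1 - v else v)
    }
    key <- paste(model$branches$condition[b], model$branches$response[b])
    out[[key]] <- (out[[key]] %||% 0) + prob
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Two-way ANOVA oracle for the consistency ICC, via aov() mean squares.
oracle_icc31 <- function(x1, x2) {
  d <- data.frame(
    v = c(x1, x2),
    subj = factor(rep(seq_along(x1), 2)),
    occ = factor(rep(1:2, each = length(x1)))
  )
  ms <- summary(aov(v ~ subj + occ, data = d))[[1]][, "Mean Sq"]
  (ms[1] - ms[3]) / (ms[1] + ms[3])
}

# Brute-force REML tau2: profile the restricted log-likelihood on a grid,
# then refine by 1-d optimization.
oracle_reml_tau2 <- function(y, v, upper = 5) {
  restricted_ll <- function(tau2) {
    w <- 1 / (v + tau2)
    mu <- sum(w * y) / sum(w)
    -0.5 * sum(log(v + tau2)) - 0.5 * log(sum(w)) -
      0.5 * sum(w * (y - mu)^2)
  }
  grid <- seq(0, upper, length.out = 401)
  best <- grid[which.max(vapply(grid, restricted_ll, numeric(1)))]
  lo <- max(0, best - 0.05)
  hi <- min(upper, best + 0.05)
  opt <- optimize(restricted_ll, c(lo, hi), maximum = TRUE, tol = 1e-9)
  if (restricted_ll(0) >= opt$objective) 0 else opt$maximum
}

# Small, fast MCMC settings for smoke-level hierarchical fits in unit tests.
fast_control <- function(seed = 1, ...) {
  mcmc_control(n_chains = 2, n_adapt = 200, n_burnin = 200, n_iter = 600,
               thin = 1, seed = seed, ...)
}

quad_theta <- function(AC_wg = .3, AC_bb = .3, D = .6, OB = .5, G = .5) {
  c(AC_wg = AC_wg, AC_bb = AC_bb, D = D, OB = OB, G = G)
}

pdp_theta <- function(A_White = .5, A_Black = .5, C_White = .5,
                      C_Black = .5, C_good = .5, C_bad = .5) {
  c(A_White = A_White, A_Black = A_Black, C_White = C_White,
    C_Black = C_Black, C_good = C_good, C_bad = C_bad)
}

# toy trial tibble: one participant-occasion block of per-cell trials
toy_trials <- function(participant, occasion, per_cell = 2, correct = 1) {
  grid <- expand.grid(category = c("White", "Black", "good", "bad"),
                      block = c("compatible", "incompatible"),
                      trial = seq_len(per_cell),
                      stringsAsFactors = FALSE)
  tibble::tibble(
    participant = participant, occasion = occasion,
    block = grid$block, category = grid$category,
    correct = rep_len(correct, nrow(grid))
  )
}
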