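test_that("split R-hat behaves as the convergence statistic should", {
  set.seed(14)
  # long i.i.d. chains: near 1
  expect_lt(rhat(matrix(rnorm(20000), 10000, 2)), 1.01)
  # separated chains: far above 1
  expect_gt(rhat(cbind(rnorm(500), rnorm(500, 5))), 1.5)
  # list input is equivalent to matrix input
  ch <- list(rnorm(100), rnorm(100))
  expect_equal(rhat(ch), rhat(cbind(ch[[1]], ch[[2]])))
  expect_error(rhat(list(rnorm(10), rnorm(11))), "equal lengths")
  expect_error(rhat(matrix(rnorm(10), 10, 1)), "at least 2 chains")
  # constant chains: undefined, flagged
  expect_warning(res <- rhat(matrix(1, 100, 2)), "undefined")
  expect_true(is.na(res))
  # a within-chain trend inflates split R-hat even for identical chains
  trend <- matrix(seq(0, 1, length.out = 200), 200, 2)
  expect_gt(rhat(trend), 1.5)
})

test_that("individual MLE inverts PDP frequencies in closed form", {
  pdp <- mpt_pdp()
  # face cells generated exactly at p_c = .9, p_i = .6 -> C = .5, A = .8;
  # word cells at matching theta so the joint optimum is interior
  theta <- pdp_theta(A_White = .8, A_Black = .8, C_White = .5, C_Black = .5,
                     C_good = .5, C_bad = .5)
  probs <- category_probabilities(pdp, theta)
  n_per <- 1000
  freq <- probs[probs$response == "correct", ] |>
    dplyr::transmute(participant = "p1", condition,
                     n_correct = round(probability * n_per),
                     n_trials = n_per)
  est <- fit_mle_individual(freq, pdp)
  expect_equal(est$estimate[est$parameter == "C_White"], .5,
               tolerance = 1e-3)
  expect_equal(est$estimate[est$parameter == "A_White"], .8,
               tolerance = 1e-3)
})

test_that("individual MLE is consistent at large counts on both models", {
  set.seed(6)
  for (model in list(mpt_quad(), mpt_pdp())) {
    theta <- setNames(runif(length(model$parameters), .25, .75),
                      model$parameters)
    probs <- category_probabilities(model, theta)
    freq <- probs[probs$response == "correct", ] |>
      dplyr::transmute(participant = "p1", condition,
                       n_correct = round(probability * 1e6),
                       n_trials = 1e6)
    est <- fit_mle_individual(freq, model)
    recovered <- setNames(est$estimate, est$parameter)
    # OB and G are weakly identified at a single point; check the rest
    strong <- setdiff(model$parameters, c("OB", "G"))
    expect_equal(recovered[strong], theta[strong], tolerance = .01)
  }
  expect_error(
    fit_mle_individual(
      tibble::tibble(participant = "p", condition = iat_conditions(),
                     n_correct = 0L, n_trials = 0L), mpt_quad()),
    "zero trials")
})

test_that("hierarchical fit recovers group means and is seed-deterministic", {
  cfg <- synth_config(model = "quad", n_participants = 60,
                      trials_per_cell = 40, seed = 11)
  g <- generate_iat(cfg, output = "frequencies")
  freq <- dplyr::filter(g$frequencies, occasion == 1)
  f <- fit_mpt(freq, mpt_quad(), control = fast_control(seed = 5))
  expect_s3_class(f, "mpt_fit")
  # probability-scale outputs stay inside (0, 1)
  expect_true(all(f$individual$estimate > 0 & f$individual$estimate < 1))
  expect_true(all(f$group$mean_prob > 0 & f$group$mean_prob < 1))
  # covariance stays symmetric positive semi-definite
  expect_equal(f$Sigma, t(f$Sigma))
  expect_gte(min(eigen(f$Sigma, symmetric = TRUE)$values), -1e-8)
  # R-hat reported for every group-level quantity (5 means + 25 covariances)
  expect_equal(nrow(f$rhats), 30)
  # strongly identified group means land near the generating truth
  truth <- pnorm(cfg$mu)
  for (p in c("AC_wg", "D", "G")) {
    expect_lt(abs(f$group$mean_prob[f$group$parameter == p] - truth[p]), .1)
  }
  # same data, same seed: identical posterior summaries
  f2 <- fit_mpt(freq, mpt_quad(), control = fast_control(seed = 5))
  expect_identical(f$group, f2$group)
  expect_identical(f$individual, f2$individual)
  # tidy/glance interface
  expect_equal(nrow(tidy(f)), 60 * 5)
  expect_true(is.logical(glance(f)$converged))
  expect_error(fit_mpt(freq[0, ], mpt_quad()), "empty")
  expect_error(fit_mpt(g$frequencies, mpt_quad()), "multiple occasions")
})

test_that("an always-correct participant is detection-dominated under Quad", {
  freq <- tibble::tibble(participant = "ace", condition = iat_conditions(),
                         n_correct = 100L, n_trials = 100L)
  est <- fit_mle_individual(freq, mpt_quad())
  expect_gt(est$estimate[est$parameter == "D"], .9)
  expect_true(any(est$boundary))
})

test_that("hierarchical shrinkage: posterior means vary less than MLEs", {
  cfg <- synth_config(model = "quad", n_participants = 40,
                      trials_per_cell = 15, seed = 23)
  g <- generate_iat(cfg, output = "frequencies")
  freq <- dplyr::filter(g$frequencies, occasion == 1)
  f <- fit_mpt(freq, mpt_quad(), control = fast_control(seed = 2))
  mles <- freq |>
    dplyr::group_by(participant) |>
    dplyr::group_modify(~ fit_mle_individual(
      dplyr::mutate(.x, participant = .y$participant), mpt_quad())) |>
    dplyr::ungroup()
  var_h <- f$individual |>
    dplyr::group_by(parameter) |>
    dplyr::summarise(v = var(estimate)) |>
    dplyr::pull(v, name = parameter)
  var_m <- mles |>
    dplyr::group_by(parameter) |>
    dplyr::summarise(v = var(estimate)) |>
    dplyr::pull(v, name = parameter)
  expect_true(all(var_h[mpt_quad()$parameters] <
                    var_m[mpt_quad()$parameters]))
})
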