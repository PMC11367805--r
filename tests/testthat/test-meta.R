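make_effects <- function(z, se = .1, study = NULL) {
  tibble::tibble(study = study %||% paste0("s", seq_along(z)),
                 z = z, se_z = rep_len(se, length(z)))
}

test_that("homogeneous effects pool to the common value with no heterogeneity", {
  m <- meta_random(make_effects(c(.5, .5, .5)))
  expect_equal(m$pooled$z, .5, tolerance = 1e-10)
  expect_equal(m$pooled$r, tanh(.5), tolerance = 1e-10)
  expect_equal(m$pooled$Q, 0, tolerance = 1e-10)
  expect_equal(m$pooled$i2, 0)
  expect_equal(m$pooled$tau2, 0, tolerance = 1e-10)
  # Q = 0 iff all z equal; unequal z's give Q > 0
  expect_gt(meta_random(make_effects(c(.4, .6, .5)))$pooled$Q, 0)
})

test_that("pooled estimate and Q match hand inverse-variance arithmetic", {
  m <- meta_random(make_effects(c(0, 1), se = .1))
  expect_equal(m$pooled$z, .5, tolerance = 1e-8)
  expect_equal(m$pooled$Q, 50, tolerance = 1e-8)
  expect_equal(m$pooled$i2, max(0, (50 - 1) / 50) * 100, tolerance = 1e-8)
  # with tau2 = 0 and equal SEs the pooled z is the arithmetic mean
  z <- c(.2, .3, .4, .5)
  m2 <- meta_random(make_effects(z, se = .2), method = "DL")
  # DL floor can be > 0 here, so force equal-weight check via REML=0 case
  m3 <- meta_random(make_effects(rep(.35, 4), se = .2))
  expect_equal(m3$pooled$z, .35, tolerance = 1e-10)
})

test_that("REML tau2 matches the profile-likelihood grid oracle", {
  set.seed(31)
  for (rep in 1:10) {
    k <- sample(5:9, 1)
    v <- runif(k, .01, .1)
    y <- rnorm(k, .5, sd = sqrt(v + .04))
    m <- meta_random(tibble::tibble(z = y, se_z = sqrt(v)))
    expect_lt(abs(m$pooled$tau2 - oracle_reml_tau2(y, v)), 1e-4)
  }
})

test_that("random-effects pooling covers the simulated truth", {
  set.seed(77)
  hits <- 0
  reps <- 400
  for (rep in seq_len(reps)) {
    true_z <- .55
    tau <- .15
    k <- 6
    se <- runif(k, .10, .25)
    z <- rnorm(k, true_z + rnorm(k, 0, tau), se)
    m <- meta_random(tibble::tibble(z = z, se_z = se))
    if (m$pooled$ci_low_z <= true_z && true_z <= m$pooled$ci_high_z) {
      hits <- hits + 1
    }
  }
  expect_gte(hits / reps, 0.90)
})

test_that("single effect passes through with a warning", {
  expect_warning(m <- meta_random(make_effects(.3)), "single effect")
  expect_equal(m$pooled$r, tanh(.3))
  expect_equal(m$pooled$k, 1)
})

test_that("multilevel pooling finds no occasion variance in duplicated data", {
  eff <- tibble::tibble(
    study = rep(paste0("s", 1:4), each = 2),
    occasion = rep(1:2, 4),
    z = rep(c(.3, .5, .6, .4), each = 2),
    se_z = .1
  )
  m <- meta_multilevel(eff)
  expect_lt(m$pooled$tau2_occasion, 1e-6)
  # collapsing duplicated occasions degenerates to the per-study pooling
  collapsed <- eff |>
    dplyr::group_by(study) |>
    dplyr::summarise(z = mean(z), se_z = .1)
  m2 <- meta_random(collapsed)
  expect_equal(m$pooled$z, m2$pooled$z, tolerance = .02)
  expect_error(meta_multilevel(dplyr::filter(eff, study == "s1")),
               "at least 2 studies")
})

test_that("multilevel variance components are recovered from simulation", {
  set.seed(55)
  tau_study <- .2
  tau_occ <- .1
  est_s <- est_o <- numeric(50)
  for (rep in 1:50) {
    studies <- paste0("s", 1:6)
    b_study <- rnorm(6, 0, tau_study)
    eff <- tidyr::expand_grid(study = studies, occasion = 1:2) |>
      dplyr::mutate(
        z = .5 + b_study[match(study, studies)] +
          rnorm(12, 0, tau_occ) + rnorm(12, 0, .05),
        se_z = .05
      )
    m <- meta_multilevel(eff)
    est_s[rep] <- m$pooled$tau2_study
    est_o[rep] <- m$pooled$tau2_occasion
  }
  expect_lt(abs(mean(est_s) - tau_study^2), .5 * tau_study^2)
  expect_lt(abs(mean(est_o) - tau_occ^2), .5 * tau_occ^2)
})

test_that("polynomial moderators detect the trend they are fed", {
  # exactly linear trend with tiny SEs: linear term dominates, higher ~ 0
  eff <- tibble::tibble(z = seq(.2, 1, length.out = 10),
                        se_z = .01, time_rank = rep(1:5, each = 2))
  m <- meta_moderators(eff)
  expect_gt(m$pooled$QM, 100)
  expect_gt(abs(m$moderators$beta[m$moderators$term == "Linear"]), .1)
  expect_lt(max(abs(m$moderators$beta[m$moderators$term != "Linear"])), 1e-6)
  # constant effects: all moderator coefficients ~ 0
  m0 <- meta_moderators(tibble::tibble(z = rep(.5, 10), se_z = .05,
                                       time_rank = rep(1:5, each = 2)))
  expect_lt(max(abs(m0$moderators$beta)), 1e-8)
  # degree reduced when ranks cover fewer levels
  expect_warning(
    meta_moderators(tibble::tibble(z = rnorm(6, .5, .05), se_z = .1,
                                   time_rank = rep(1:3, 2)), degree = 4),
    "reducing polynomial degree")
  expect_error(
    meta_moderators(tibble::tibble(z = c(.1, .2), se_z = .1,
                                   time_rank = c(1, 2))),
    "at least 3 levels")
})

test_that("quadratic moderation trend is recovered across simulations", {
  set.seed(88)
  correct_sign <- 0
  for (rep in 1:50) {
    rank <- rep(1:5, each = 2)
    z <- .5 - .08 * (rank - 3)^2 + rnorm(10, 0, .03)
    m <- meta_moderators(tibble::tibble(z = z, se_z = .05,
                                        time_rank = rank))
    beta_q <- m$moderators$beta[m$moderators$term == "Quadratic"]
    if (beta_q < 0) correct_sign <- correct_sign + 1
  }
  expect_gte(correct_sign, 45)
})

test_that("CI-overlap verdicts are disjointness, with touching = overlap", {
  tab <- tibble::tibble(
    parameter = c("Detection", "Associations", "Guessing"),
    ci_low = c(.44, .06, .10),
    ci_high = c(.59, .15, .30)
  )
  res <- compare_by_ci(tab)
  verdict <- function(a, b) {
    res$different[(res$parameter1 == a & res$parameter2 == b) |
                    (res$parameter1 == b & res$parameter2 == a)]
  }
  expect_true(verdict("Detection", "Associations"))
  expect_true(verdict("Detection", "Guessing"))
  expect_false(verdict("Associations", "Guessing"))
  # identical CIs: not different; touching endpoints: not different
  tab2 <- tibble::tibble(parameter = c("a", "b", "c"),
                         ci_low = c(.1, .1, .3),
                         ci_high = c(.3, .3, .5))
  res2 <- compare_by_ci(tab2)
  expect_false(any(res2$different))
  expect_error(compare_by_ci(tab[1, ]), "at least 2")
})

test_that("forest data carries per-study rows plus a pooled row", {
  m <- meta_random(make_effects(c(.2, .4, .6)))
  fd <- forest_data(m)
  expect_equal(nrow(fd), 4)
  expect_equal(sum(fd$pooled), 1)
  expect_equal(fd$r[fd$pooled], m$pooled$r)
  expect_s3_class(ggplot2::autoplot(m), "ggplot")
})
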