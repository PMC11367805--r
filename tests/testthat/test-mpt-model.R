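test_that("Quad worked values match the hand-enumerated tree", {
  quad <- mpt_quad()
  theta <- quad_theta(AC_wg = .3, D = .6, OB = .5, G = .5)
  probs <- category_probabilities(quad, theta)
  p <- function(cond, resp = "correct") {
    probs$probability[probs$condition == cond & probs$response == resp]
  }
  expect_equal(p("White_compatible"), .86, tolerance = 1e-12)
  expect_equal(p("White_incompatible"), .65, tolerance = 1e-12)
})

test_that("detection dominance: D = 1 (with OB = 1) is always correct", {
  quad <- mpt_quad()
  for (rep in 1:5) {
    theta <- setNames(runif(5), mpt_quad()$parameters)
    theta["D"] <- 1
    theta["OB"] <- 1
    probs <- category_probabilities(quad, theta)
    expect_true(all(probs$probability[probs$response == "correct"] == 1))
  }
})

test_that("pure guessing toward 'good' is correct only on good-key cells", {
  quad <- mpt_quad()
  probs <- category_probabilities(
    quad, quad_theta(AC_wg = 0, AC_bb = 0, D = 0, OB = 0, G = 1))
  correct <- probs[probs$response == "correct", ]
  good_key <- c("White_compatible", "good_compatible",
                "Black_incompatible", "good_incompatible")
  expect_true(all(correct$probability[correct$condition %in% good_key] == 1))
  expect_true(all(correct$probability[!correct$condition %in% good_key] == 0))
})

test_that("PDP control and automatic combine as the tree prescribes", {
  pdp <- mpt_pdp()
  # full control is always correct
  probs <- category_probabilities(
    pdp, pdp_theta(C_White = 1, C_Black = 1, C_good = 1, C_bad = 1,
                   A_White = .2, A_Black = .9))
  expect_true(all(probs$probability[probs$response == "correct"] == 1))
  # automatic drives the good-key response when control fails
  probs <- category_probabilities(pdp, pdp_theta(C_White = .5, A_White = 1))
  p <- function(cond) {
    probs$probability[probs$condition == cond & probs$response == "correct"]
  }
  expect_equal(p("White_compatible"), 1.0)
  expect_equal(p("White_incompatible"), 0.5)
  # neutral automatic bias: equal accuracy in both blocks
  probs <- category_probabilities(pdp, pdp_theta(A_White = .5, C_White = .5))
  expect_equal(p2 <- probs$probability[probs$condition == "White_compatible" &
                                         probs$response == "correct"],
               probs$probability[probs$condition == "White_incompatible" &
                                   probs$response == "correct"])
})

test_that("PDP face-trial accuracies invert to C and A in closed form", {
  pdp <- mpt_pdp()
  set.seed(42)
  for (rep in 1:20) {
    theta <- setNames(runif(6), pdp$parameters)
    probs <- category_probabilities(pdp, theta)
    p_c <- probs$probability[probs$condition == "White_compatible" &
                               probs$response == "correct"]
    p_i <- probs$probability[probs$condition == "White_incompatible" &
                               probs$response == "correct"]
    C <- p_c + p_i - 1
    expect_equal(C, theta[["C_White"]], tolerance = 1e-12)
    if (C < 1 - 1e-8) {
      expect_equal((p_c - C) / (1 - C), theta[["A_White"]],
                   tolerance = 1e-9)
    }
  }
})

test_that("branch probabilities partition every condition (normalization)", {
  set.seed(7)
  for (model in list(mpt_quad(), mpt_pdp())) {
    P <- length(model$parameters)
    for (rep in 1:250) {
      theta <- setNames(runif(P), model$parameters)
      probs <- category_probabilities(model, theta)
      sums <- tapply(probs$probability, probs$condition, sum)
      expect_true(all(abs(sums - 1) < 1e-12))
    }
  }
})

test_that("category probabilities agree with brute-force tree enumeration", {
  set.seed(11)
  for (model in list(mpt_quad(), mpt_pdp())) {
    for (rep in 1:40) {
      theta <- setNames(runif(length(model$parameters)), model$parameters)
      probs <- category_probabilities(model, theta)
      oracle <- oracle_category_prob(model, as.list(theta))
      for (key in names(oracle)) {
        parts <- strsplit(key, " ")[[1]]
        got <- probs$probability[probs$condition == parts[1] &
                                   probs$response == parts[2]]
        expect_equal(got, oracle[[key]], tolerance = 1e-12)
      }
    }
  }
})

test_that("accuracy is monotone in detection (Quad) and control (PDP)", {
  quad <- mpt_quad()
  pdp <- mpt_pdp()
  set.seed(3)
  d_grid <- seq(0, 1, by = .1)
  for (rep in 1:10) {
    base <- setNames(runif(5), quad$parameters)
    acc <- sapply(d_grid, function(d) {
      th <- base; th["D"] <- d
      p <- category_probabilities(quad, th)
      p$probability[p$response == "correct"]
    })
    expect_true(all(diff(t(acc)) >= -1e-12))
    base_p <- setNames(runif(6), pdp$parameters)
    acc_w <- sapply(d_grid, function(cw) {
      th <- base_p; th["C_White"] <- cw
      p <- category_probabilities(pdp, th)
      p$probability[p$response == "correct" & grepl("White", p$condition)]
    })
    expect_true(all(diff(t(acc_w)) >= -1e-12))
  }
})

test_that("EQN round trip preserves category probabilities", {
  set.seed(5)
  for (model in list(mpt_quad(), mpt_pdp())) {
    text <- write_eqn(model)
    reparsed <- read_eqn(text, name = model$name,
                         parameters = model$parameters,
                         conditions = model$conditions)
    for (rep in 1:40) {
      theta <- setNames(runif(length(model$parameters)), model$parameters)
      expect_equal(category_probabilities(reparsed, theta),
                   category_probabilities(model, theta))
    }
  }
})

test_that("EQN parsing handles toy models and rejects malformed input", {
  coin <- read_eqn(c("cond1 correct p", "cond1 incorrect (1-p)"),
                   name = "coin")
  probs <- category_probabilities(coin, c(p = .7))
  expect_equal(probs$probability[probs$response == "correct"], .7)
  expect_error(read_eqn(""), "no branch lines")
  expect_error(read_eqn(c("c1 correct p", "c1 wrong (1-p)")), "line 2")
  expect_error(read_eqn("c1 correct p*(1-"), "malformed factor")
  expect_error(read_eqn("c2 correct p", conditions = "c1"),
               "undeclared condition")
  expect_error(read_eqn("c1 correct q", parameters = "p"),
               "undeclared parameter")
})

test_that("theta validation catches bad names and out-of-range values", {
  quad <- mpt_quad()
  expect_error(category_probabilities(quad, c(D = .5)), "match the model")
  bad <- quad_theta(); bad["D"] <- 1.2
  expect_error(category_probabilities(quad, bad), "\\[0, 1\\]")
  expect_error(
    mpt_model("broken", parameters = "p",
              branches = tibble::tibble(
                condition = "c1", response = "correct",
                factors = list(tibble::tibble(parameter = "q",
                                              complement = FALSE)))),
    "unknown parameter")
})
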