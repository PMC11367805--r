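#' Random-effects meta-analysis of Fisher-z effects
#'
#' Pools per-study effects (consistency ICCs or recovery correlations,
#' already on the Fisher-z scale) with an inverse-variance random-effects
#' model; the between-study variance is estimated by REML by default.
#' Pooled estimates and Wald 95% confidence limits are back-transformed to
#' the correlation scale with [z_to_r()].  Heterogeneity is summarized by
#' the fixed-effect-weights Q statistic and `I2 = max(0, (Q - df)/Q) * 100`
#' (the REML-based I2 is reported alongside as `i2_reml`).
#'
#' @param effects A tibble with columns `z`, `se_z` and (recommended)
#'   `study`; extra columns are carried through.
#' @param method Between-study variance estimator passed to the pooling
#'   backend: `"REML"` (default) or `"DL"` (DerSimonian-Laird).
#' @param knapp_hartung Apply the Knapp-Hartung adjustment (default FALSE).
#'
#' @return An object of class `mpt_meta`: `pooled` (one-row tibble with the
#'   pooled z and r, CIs, tau2, Q, df, p, I2), `studies` (the input effects
#'   with weights and r-scale values), and the underlying fit object.
#' @export
meta_random <- function(effects, method = "REML", knapp_hartung = FALSE) {
  effects <- tibble::as_tibble(effects)
  stopifnot(all(c("z", "se_z") %in% names(effects)), all(effects$se_z > 0))
  if (nrow(effects) < 1) stop("no effects to pool", call. = FALSE)
  if (nrow(effects) == 1) {
    warning("single effect: returning it unpooled", call. = FALSE)
    pooled <- meta_pooled_row(effects$z, effects$se_z, tau2 = 0, Q = 0,
                              df = 0, k = 1)
    return(new_mpt_meta(pooled,
                        dplyr::mutate(effects, weight = 1,
                                      r = z_to_r(.data$z)),
                        fit = NULL, method = method))
  }
  fit <- metafor::rma(yi = effects$z, sei = effects$se_z, method = method,
                      test = if (knapp_hartung) "knha" else "z",
                      control = list(maxiter = 1000, stepadj = 0.5))
  pooled <- meta_pooled_row(as.numeric(fit$beta), fit$se, tau2 = fit$tau2,
                            Q = fit$QE, df = fit$k - 1, k = fit$k,
                            ci_lb = fit$ci.lb, ci_ub = fit$ci.ub,
                            p = fit$pval, i2_reml = fit$I2)
  studies <- effects |>
    dplyr::mutate(weight = as.numeric(stats::weights(fit)),
                  r = z_to_r(.data$z),
                  ci_low_r = z_to_r(.data$z - 1.96 * .data$se_z),
                  ci_high_r = z_to_r(.data$z + 1.96 * .data$se_z))
  new_mpt_meta(pooled, studies, fit, method)
}

meta_pooled_row <- function(est, se, tau2, Q, df, k, ci_lb = NULL,
                            ci_ub = NULL, p = NULL, i2_reml = NA_real_) {
  if (is.null(ci_lb)) ci_lb <- est - 1.96 * se
  if (is.null(ci_ub)) ci_ub <- est + 1.96 * se
  if (is.null(p)) p <- 2 * pnorm(-abs(est / se))
  q_p <- if (df > 0) stats::pchisq(Q, df, lower.tail = FALSE) else NA_real_
  tibble::tibble(
    k = k, z = est, se = se, ci_low_z = ci_lb, ci_high_z = ci_ub,
    r = z_to_r(est), ci_low = z_to_r(ci_lb), ci_high = z_to_r(ci_ub),
    p = p, tau2 = tau2, Q = Q, df = df, Q_p = q_p,
    i2 = if (Q > 0) max(0, (Q - df) / Q) * 100 else 0,
    i2_reml = i2_reml
  )
}

new_mpt_meta <- function(pooled, studies, fit, method, extra = list()) {
  structure(c(list(pooled = pooled, studies = studies, fit = fit,
                   method = method), extra),
            class = "mpt_meta")
}

#' @export
print.mpt_meta <- function(x, ...) {
  cat("<mpt_meta> k = ", x$pooled$k, ", method = ", x$method, "\n", sep = "")
  cat(sprintf("  pooled r = %.3f [%.3f, %.3f], tau2 = %.4f, Q(%d) = %.3f, I2 = %.1f\n",
              x$pooled$r, x$pooled$ci_low, x$pooled$ci_high, x$pooled$tau2,
              x$pooled$df, x$pooled$Q, x$pooled$i2))
  if (!is.null(x$moderators)) {
    cat(sprintf("  moderators: QM(%d) = %.3f, p = %.4f\n",
                x$pooled$QM_df, x$pooled$QM, x$pooled$QM_p))
    print(as.data.frame(x$moderators), digits = 3)
  }
  invisible(x)
}

#' Multilevel meta-analysis with occasions nested in studies
#'
#' Pools effects measured at several occasions per study with random
#' intercepts at the study and occasion-within-study levels (two variance
#' components, REML).  Used for recovery correlations, which yield one
#' effect per study per measurement occasion.
#'
#' @param effects A tibble with columns `z`, `se_z`, `study`, `occasion`.
#'
#' @return An `mpt_meta`; `pooled` additionally carries `tau2_study` and
#'   `tau2_occasion`.
#' @export
meta_multilevel <- function(effects) {
  effects <- tibble::as_tibble(effects)
  stopifnot(all(c("z", "se_z", "study", "occasion") %in% names(effects)),
            all(effects$se_z > 0))
  if (dplyr::n_distinct(effects$study) < 2) {
    stop("multilevel pooling requires at least 2 studies", call. = FALSE)
  }
  fit <- tryCatch(
    metafor::rma.mv(yi = z, V = se_z^2, random = ~ 1 | study / occasion,
                    data = effects, method = "REML", sparse = FALSE),
    error = function(e) NULL
  )
  fixed_occasion <- FALSE
  if (is.null(fit)) {
    # occasion-within-study component inestimable on this panel: fix it at
    # zero and flag, rather than fail
    fixed_occasion <- TRUE
    fit <- metafor::rma.mv(yi = z, V = se_z^2,
                           random = ~ 1 | study / occasion,
                           sigma2 = c(NA, 0),
                           data = effects, method = "REML", sparse = FALSE)
  }
  pooled <- meta_pooled_row(as.numeric(fit$beta), fit$se,
                            tau2 = sum(fit$sigma2), Q = fit$QE,
                            df = fit$k - 1, k = fit$k,
                            ci_lb = fit$ci.lb, ci_ub = fit$ci.ub,
                            p = fit$pval)
  pooled$tau2_study <- fit$sigma2[1]
  pooled$tau2_occasion <- fit$sigma2[2]
  pooled$occasion_component_fixed <- fixed_occasion
  studies <- effects |>
    dplyr::mutate(r = z_to_r(.data$z),
                  ci_low_r = z_to_r(.data$z - 1.96 * .data$se_z),
                  ci_high_r = z_to_r(.data$z + 1.96 * .data$se_z))
  new_mpt_meta(pooled, studies, fit, "REML (multilevel)")
}

#' Meta-regression with orthogonal polynomial time contrasts
#'
#' Moderates pooled effects by the rank order of the between-occasion time
#' interval, using orthogonal polynomial contrasts (linear, quadratic, ...)
#' of the ordered categories, plus an omnibus moderator test Q_M.
#'
#' @param effects A tibble with columns `z`, `se_z` and `time_rank`
#'   (ordered category rank; ties share a rank).
#' @param degree Maximum polynomial degree; reduced (with a warning) when
#'   the number of distinct ranks supports fewer.
#'
#' @return An `mpt_meta` with a `moderators` tibble (`term`, `beta`, `se`,
#'   `zval`, `p`) and `QM`, `QM_df`, `QM_p` in `pooled`.
#' @export
meta_moderators <- function(effects, degree = 4) {
  effects <- tibble::as_tibble(effects)
  stopifnot(all(c("z", "se_z", "time_rank") %in% names(effects)))
  n_levels <- dplyr::n_distinct(effects$time_rank)
  if (n_levels < 3) {
    stop("moderator analysis needs ranks covering at least 3 levels",
         call. = FALSE)
  }
  # leave at least one residual df so the regression is estimable
  max_deg <- min(n_levels - 1, nrow(effects) - 2)
  if (degree > max_deg) {
    warning("reducing polynomial degree to ", max_deg,
            " (ranks cover ", n_levels, " levels over ", nrow(effects),
            " effects)", call. = FALSE)
    degree <- max_deg
  }
  contrasts <- stats::poly(effects$time_rank, degree = degree)
  colnames(contrasts) <- c("Linear", "Quadratic", "Cubic", "Quartic",
                           paste0("poly", 5:20))[seq_len(degree)]
  fit <- metafor::rma(yi = effects$z, sei = effects$se_z,
                      mods = contrasts, method = "REML",
                      control = list(maxiter = 1000, stepadj = 0.5))
  est <- as.numeric(fit$beta)
  pooled <- meta_pooled_row(est[1], fit$se[1], tau2 = fit$tau2, Q = fit$QE,
                            df = fit$k - fit$p, k = fit$k,
                            ci_lb = fit$ci.lb[1], ci_ub = fit$ci.ub[1],
                            p = fit$pval[1])
  pooled$QM <- fit$QM
  pooled$QM_df <- fit$m
  pooled$QM_p <- fit$QMp
  moderators <- tibble::tibble(
    term = rownames(fit$beta)[-1],
    beta = est[-1], se = fit$se[-1], zval = fit$zval[-1], p = fit$pval[-1]
  )
  new_mpt_meta(pooled, dplyr::mutate(effects, r = z_to_r(.data$z)),
               fit, "REML (meta-regression)",
               extra = list(moderators = moderators))
}

#' Pairwise CI-overlap comparison of pooled estimates
#'
#' Declares two parameters' pooled estimates "different" if and only if
#' their confidence intervals are disjoint; intervals touching at a single
#' point count as overlapping.
#'
#' @param results A named list of `mpt_meta` objects, or a tibble with
#'   columns `parameter`, `ci_low`, `ci_high` (r scale).
#'
#' @return A tibble of all pairs with columns `parameter1`, `parameter2`,
#'   `different`.
#' @export
compare_by_ci <- function(results) {
  if (inherits(results, "mpt_meta")) {
    stop("compare_by_ci needs at least 2 results", call. = FALSE)
  }
  tab <- if (is.data.frame(results)) {
    tibble::as_tibble(results)
  } else {
    dplyr::bind_rows(lapply(names(results), function(nm) {
      p <- results[[nm]]$pooled
      tibble::tibble(parameter = nm, ci_low = p$ci_low, ci_high = p$ci_high)
    }))
  }
  if (nrow(tab) < 2) stop("compare_by_ci needs at least 2 results",
                          call. = FALSE)
  pairs <- utils::combn(nrow(tab), 2)
  tibble::tibble(
    parameter1 = tab$parameter[pairs[1, ]],
    parameter2 = tab$parameter[pairs[2, ]],
    different = tab$ci_low[pairs[1, ]] > tab$ci_high[pairs[2, ]] |
      tab$ci_low[pairs[2, ]] > tab$ci_high[pairs[1, ]]
  )
}

#' Forest-plot data for a meta-analysis
#'
#' Tabular twin of a forest plot: one row per study (estimate, CI, weight)
#' plus a pooled row.
#'
#' @param meta An `mpt_meta`.
#' @return A tibble with columns `label`, `r`, `ci_low`, `ci_high`,
#'   `weight`, `pooled`.
#' @export
forest_data <- function(meta) {
  stopifnot(inherits(meta, "mpt_meta"))
  s <- meta$studies
  label <- if ("study" %in% names(s)) {
    if ("occasion" %in% names(s)) {
      paste0(s$study, " (occ ", s$occasion, ")")
    } else as.character(s$study)
  } else paste("effect", seq_len(nrow(s)))
  dplyr::bind_rows(
    tibble::tibble(label = label, r = s$r,
                   ci_low = if ("ci_low_r" %in% names(s)) s$ci_low_r else NA,
                   ci_high = if ("ci_high_r" %in% names(s)) s$ci_high_r else NA,
                   weight = if ("weight" %in% names(s)) s$weight else NA,
                   pooled = FALSE),
    tibble::tibble(label = "Pooled", r = meta$pooled$r,
                   ci_low = meta$pooled$ci_low, ci_high = meta$pooled$ci_high,
                   weight = NA, pooled = TRUE)
  )
}

#' @export
#' @method tidy mpt_meta
#' @rdname meta_random
#' @param x An `mpt_meta`.
#' @param ... Unused.
tidy.mpt_meta <- function(x, ...) x$studies

#' @export
#' @method glance mpt_meta
#' @rdname meta_random
glance.mpt_meta <- function(x, ...) x$pooled
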