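#' Two-way mixed-effects consistency ICC for two occasions
#'
#' Computes the single-measure consistency intraclass correlation, ICC(3,1),
#' from the two-way (participants x occasions) mean-squares decomposition:
#' `(MS_between - MS_error) / (MS_between + (k - 1) * MS_error)` with
#' `k = 2`.  Consistency ignores occasion mean shifts (adding a constant to
#' one occasion leaves it unchanged), unlike absolute agreement.  The
#' confidence interval and p value are F-based (Shrout & Fleiss
#' conventions).
#'
#' @param x1,x2 Per-participant values at occasions 1 and 2 (equal length,
#'   n >= 4).
#' @param conf_level Confidence level for the interval (default .95).
#'
#' @return A one-row tibble: `icc`, `ci_low`, `ci_high`, `f`, `df1`, `df2`,
#'   `p`, `n`, `k`, `fisher_z`, `se_z`, `interpretation`.  When
#'   between-participant variance is zero the ICC is undefined and returned
#'   as `NA` with a warning.
#' @export
icc31 <- function(x1, x2, conf_level = 0.95) {
  stopifnot(length(x1) == length(x2))
  n <- length(x1)
  if (n < 4) stop("icc31 requires at least 4 participants", call. = FALSE)
  k <- 2
  m <- cbind(x1, x2)
  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_total <- sum((m - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  ms_rows <- ss_rows / (n - 1)
  ms_err <- ss_err / ((n - 1) * (k - 1))
  if (ms_rows <= .Machine$double.eps && ms_err <= .Machine$double.eps) {
    warning("zero between-participant variance; ICC undefined",
            call. = FALSE)
    return(tibble::tibble(icc = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, f = NA_real_,
                          df1 = n - 1, df2 = (n - 1) * (k - 1), p = NA_real_,
                          n = n, k = k, fisher_z = NA_real_, se_z = NA_real_,
                          interpretation = NA_character_))
  }
  icc <- (ms_rows - ms_err) / (ms_rows + (k - 1) * ms_err)
  fvalue <- ms_rows / ms_err
  df1 <- n - 1
  df2 <- (n - 1) * (k - 1)
  alpha <- 1 - conf_level
  fl <- fvalue / stats::qf(1 - alpha / 2, df1, df2)
  fu <- fvalue * stats::qf(1 - alpha / 2, df2, df1)
  ci_low <- (fl - 1) / (fl + k - 1)
  ci_high <- (fu - 1) / (fu + k - 1)
  p <- stats::pf(fvalue, df1, df2, lower.tail = FALSE)
  fz <- fisher_z(icc, n)
  tibble::tibble(icc = icc, ci_low = ci_low, ci_high = ci_high, f = fvalue,
                 df1 = df1, df2 = df2, p = p, n = n, k = k,
                 fisher_z = fz$z, se_z = fz$se,
                 interpretation = interpret_icc(icc))
}

#' Between-occasion consistency of every model parameter
#'
#' Convenience wrapper: given tidy individual estimates from two
#' per-occasion fits, computes [icc31()] for each parameter.
#'
#' @param estimates A tibble with columns `participant`, `occasion` (1/2),
#'   `parameter`, `estimate` -- e.g. the row-bound `tidy()` output of two
#'   [fit_mpt()] objects with an `occasion` column added.
#'
#' @return A tibble with one [icc31()] row per parameter.
#' @export
parameter_consistency <- function(estimates) {
  wide <- estimates |>
    dplyr::select("participant", "occasion", "parameter", "estimate") |>
    tidyr::pivot_wider(names_from = "occasion", values_from = "estimate",
                       names_prefix = "occ")
  if (!all(c("occ1", "occ2") %in% names(wide))) {
    stop("estimates must contain occasions 1 and 2", call. = FALSE)
  }
  wide <- tidyr::drop_na(wide, "occ1", "occ2")
  wide |>
    dplyr::group_by(.data$parameter) |>
    dplyr::group_modify(~ icc31(.x$occ1, .x$occ2)) |>
    dplyr::ungroup()
}

#' Fisher r-to-z transformation and its standard error
#'
#' `z = atanh(r)` with standard error `sqrt(1 / (n - 3))`; the inverse is
#' `tanh`.  Used to put correlations and consistency ICCs on an
#' approximately normal scale for meta-analytic pooling.
#'
#' @param r Correlation(s) in `(-1, 1)`; values of exactly +/-1 give an
#'   infinite z and a warning.
#' @param n Sample size(s) (> 3 for a finite standard error).
#'
#' @return A tibble with columns `z` and `se`.
#' @export
fisher_z <- function(r, n) {
  if (any(abs(r) >= 1, na.rm = TRUE)) {
    warning("|r| = 1 gives an infinite Fisher z", call. = FALSE)
  }
  tibble::tibble(z = atanh(r), se = sqrt(1 / (n - 3)))
}

#' @rdname fisher_z
#' @param z Fisher-z value(s).
#' @export
z_to_r <- function(z) tanh(z)

#' Interpret a consistency ICC
#'
#' Bins an ICC into the conventional qualitative labels: below .40 is poor,
#' .40 up to .60 is fair, .60 to .75 is good, and above .75 is excellent.
#' Boundaries resolve toward the better label (.40 is fair, .60 and .75 are
#' good).
#'
#' @param icc Numeric ICC value(s).
#' @return Character vector of labels.
#' @export
interpret_icc <- function(icc) {
  dplyr::case_when(
    is.na(icc) ~ NA_character_,
    icc < 0.40 ~ "poor",
    icc < 0.60 ~ "fair",
    icc <= 0.75 ~ "good",
    TRUE ~ "excellent"
  )
}
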