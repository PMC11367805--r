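#' Configure a full multi-dataset study run
#'
#' @param datasets A list of [synth_config()] objects (e.g.
#'   [preset_panel()]) and/or named lists `list(path = , time_rank = ,
#'   study = , column_map = )` pointing at trial-level CSV files.
#' @param models Character vector of models to run (`"quad"`, `"pdp"`).
#' @param control An [mcmc_control()]; its seed is combined with the
#'   dataset index so every fit is independently seeded but reproducible.
#' @param seed Global seed for the simulation steps.
#' @param output_dir If non-`NULL`, per-stage CSV/JSON artifacts are
#'   written there.
#'
#' @return A list of class `study_config`.
#' @export
study_config <- function(datasets, models = "quad",
                         control = mcmc_control(), seed = 1,
                         output_dir = NULL) {
  stopifnot(length(datasets) >= 1, all(models %in% c("quad", "pdp")))
  labels <- vapply(datasets, function(d) {
    if (inherits(d, "synth_config")) d$study else d$study
  }, character(1))
  if (anyDuplicated(labels)) stop("dataset labels must be unique",
                                  call. = FALSE)
  structure(list(datasets = datasets, models = models, control = control,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "study_config")
}

#' Run the full reliability-and-stability study
#'
#' For each dataset and model: load or generate trial data, apply the
#' exclusion rules, aggregate to frequencies, fit the hierarchical model
#' per occasion, compute between-occasion consistency ICCs and
#' per-occasion parameter recovery; then, per parameter, pool consistency
#' effects across datasets with a random-effects meta-analysis and
#' recovery effects with a multilevel meta-analysis (occasion nested in
#' study), compare pooled estimates by CI overlap, and moderate
#' consistency by the time-interval rank with orthogonal polynomial
#' contrasts.  The recovery meta-analysis consumes exactly twice as many
#' effect records per parameter as the consistency meta-analysis (one per
#' occasion instead of one per study).
#'
#' @param cfg A [study_config()].
#'
#' @return An object of class `mpt_study` with, per model: `icc`
#'   (per-dataset per-parameter ICC table), `recovery` (per-dataset,
#'   per-occasion recovery table), `meta_consistency` and `meta_recovery`
#'   (named lists of `mpt_meta` per parameter), `comparisons` (CI-overlap
#'   verdicts), `moderation` (per-parameter `mpt_meta` with polynomial
#'   contrasts, where estimable), plus `exclusions`, `fits` (glance rows
#'   for every fit), and `log` (seeds and convergence flags).
#' @export
run_study <- function(cfg) {
  stopifnot(inherits(cfg, "study_config"))
  out <- list(models = list(), exclusions = list(), log = list())
  fits_log <- list()
  for (model_name in cfg$models) {
    model <- if (model_name == "quad") mpt_quad() else mpt_pdp()
    icc_all <- list()
    rec_all <- list()
    for (di in seq_along(cfg$datasets)) {
      d <- cfg$datasets[[di]]
      if (inherits(d, "synth_config")) {
        synth <- generate_iat(d)
        trials <- read_trials(synth$trials)
        label <- d$study
        rank <- d$time_rank
      } else {
        trials <- read_trials(d$path, column_map = d$column_map)
        label <- d$study
        rank <- d$time_rank
      }
      excl <- apply_exclusions(trials)
      out$exclusions[[paste(model_name, label, sep = ".")]] <- excl$report
      freq <- aggregate_frequencies(excl$trials)
      if (nrow(freq) == 0) {
        warning("dataset ", label, ": no participants after exclusions; ",
                "skipped", call. = FALSE)
        next
      }
      ests <- list()
      for (occ in 1:2) {
        ctl <- cfg$control
        ctl$seed <- ctl$seed + 1000L * di + 10L * occ
        f <- fit_mpt(freq, model, control = ctl, occasion = occ)
        fits_log[[length(fits_log) + 1]] <-
          dplyr::mutate(glance(f), study = label, occasion = occ,
                        stage = "fit", .before = 1)
        ests[[occ]] <- dplyr::mutate(f$individual, occasion = occ)
        rec <- run_recovery(NULL, model, control = ctl,
                            seed = cfg$seed + 1000L * di + occ,
                            original_fit = f)
        fits_log[[length(fits_log) + 1]] <-
          dplyr::mutate(attr(rec, "refit_glance"), study = label,
                        occasion = occ, stage = "recovery_refit",
                        .before = 1)
        rec_all[[length(rec_all) + 1]] <- rec |>
          dplyr::mutate(study = label, occasion = occ, time_rank = rank)
      }
      icc_all[[length(icc_all) + 1]] <-
        parameter_consistency(dplyr::bind_rows(ests)) |>
        dplyr::mutate(study = label, time_rank = rank)
    }
    icc_tab <- dplyr::bind_rows(icc_all)
    rec_tab <- dplyr::bind_rows(rec_all)
    pars <- model$parameters
    meta_cons <- lapply(setNames(pars, pars), function(par) {
      eff <- icc_tab |>
        dplyr::filter(.data$parameter == .env$par,
                      is.finite(.data$fisher_z)) |>
        dplyr::transmute(study = .data$study, z = .data$fisher_z,
                         se_z = .data$se_z, n = .data$n,
                         time_rank = .data$time_rank)
      meta_random(eff)
    })
    meta_rec <- lapply(setNames(pars, pars), function(par) {
      eff <- rec_tab |>
        dplyr::filter(.data$parameter == .env$par, is.finite(.data$z)) |>
        dplyr::select("study", "occasion", "z", "se_z", "n", "time_rank")
      if (dplyr::n_distinct(eff$study) >= 2) {
        meta_multilevel(eff)
      } else {
        meta_random(eff)
      }
    })
    moderation <- lapply(setNames(pars, pars), function(par) {
      eff <- meta_cons[[par]]$studies
      if (is.null(eff$time_rank) ||
          dplyr::n_distinct(eff$time_rank) < 3) return(NULL)
      meta_moderators(eff)
    })
    comparisons <- compare_by_ci(meta_cons)
    out$models[[model_name]] <- list(
      icc = icc_tab, recovery = rec_tab,
      meta_consistency = meta_cons, meta_recovery = meta_rec,
      comparisons = comparisons, moderation = moderation
    )
  }
  out$fits <- dplyr::bind_rows(fits_log)
  out$log <- list(seed = cfg$seed, control_seed = cfg$control$seed,
                  all_converged = all(out$fits$converged))
  res <- structure(out, class = "mpt_study")
  if (!is.null(cfg$output_dir)) write_study(res, cfg$output_dir)
  res
}

#' @export
print.mpt_study <- function(x, ...) {
  cat("<mpt_study> models: ", paste(names(x$models), collapse = ", "),
      "\n", sep = "")
  cat("  fits: ", nrow(x$fits), " (all converged: ",
      x$log$all_converged, ")\n", sep = "")
  for (m in names(x$models)) {
    cons <- summarise_meta_list(x$models[[m]]$meta_consistency)
    cat("  [", m, "] pooled consistency ICCs:\n", sep = "")
    print(as.data.frame(cons), digits = 3, row.names = FALSE)
  }
  invisible(x)
}

summarise_meta_list <- function(metas) {
  dplyr::bind_rows(lapply(names(metas), function(p) {
    dplyr::mutate(metas[[p]]$pooled[, c("k", "r", "ci_low", "ci_high",
                                        "tau2", "Q", "i2")],
                  parameter = p, .before = 1)
  }))
}

#' Tabular study report
#'
#' Collapses an [run_study()] result into tidy per-model tables.
#'
#' @param study An `mpt_study`.
#' @return A named list of tibbles: `consistency_pooled`,
#'   `recovery_pooled`, `icc`, `recovery`, `comparisons`, `fits`.
#' @export
study_report <- function(study) {
  stopifnot(inherits(study, "mpt_study"))
  per_model <- function(extract) {
    dplyr::bind_rows(lapply(names(study$models), function(m) {
      dplyr::mutate(extract(study$models[[m]]), model = m, .before = 1)
    }))
  }
  list(
    consistency_pooled = per_model(function(x)
      summarise_meta_list(x$meta_consistency)),
    recovery_pooled = per_model(function(x)
      summarise_meta_list(x$meta_recovery)),
    icc = per_model(function(x) x$icc),
    recovery = per_model(function(x) x$recovery),
    comparisons = per_model(function(x) x$comparisons),
    fits = study$fits
  )
}

write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rep <- study_report(study)
  for (nm in setdiff(names(rep), "fits")) {
    readr::write_csv(rep[[nm]], file.path(dir, paste0(nm, ".csv")))
  }
  readr::write_csv(rep$fits, file.path(dir, "fits.csv"))
  jsonlite::write_json(study$log, file.path(dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
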