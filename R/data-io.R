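#' Read trial-level IAT data
#'
#' Reads a CSV of trial-level records and validates it against the closed
#' vocabularies of the two-occasion race-IAT design.  The expected columns
#' are `participant`, `occasion` (1 or 2), `block` (`compatible` /
#' `incompatible`), `category` (`White`, `Black`, `good`, `bad`),
#' `correct` (logical or 0/1) and optionally `latency_ms` (parsed, unused)
#' and `block_number` (practice blocks 1, 2 and 5 are dropped when present).
#'
#' @param path Path to a CSV file, or a data frame already in memory.
#' @param column_map Optional named character vector mapping standard names
#'   to the file's column names, e.g.
#'   `c(participant = "subj_id", correct = "acc")`.
#'
#' @return A tibble of validated trial records with the standard columns.
#' @export
read_trials <- function(path, column_map = NULL) {
  df <- if (is.data.frame(path)) {
    tibble::as_tibble(path)
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  if (!is.null(column_map)) {
    missing_src <- setdiff(unname(column_map), names(df))
    if (length(missing_src) > 0) {
      stop("column_map refers to absent column(s): ",
           paste(missing_src, collapse = ", "), call. = FALSE)
    }
    for (std in names(column_map)) {
      names(df)[names(df) == column_map[[std]]] <- std
    }
  }
  needed <- c("participant", "occasion", "block", "category", "correct")
  if (!all(needed %in% names(df))) {
    stop("trial data lacks column(s): ",
         paste(setdiff(needed, names(df)), collapse = ", "),
         " (use column_map to rename)", call. = FALSE)
  }
  # drop practice blocks if a block-number column is present
  if ("block_number" %in% names(df)) {
    df <- dplyr::filter(df, !.data$block_number %in% c(1, 2, 5))
  }
  check_vocab <- function(col, allowed) {
    bad <- which(!df[[col]] %in% allowed)
    if (length(bad) > 0) {
      stop("invalid ", col, " value '", df[[col]][bad[1]], "' at data row ",
           bad[1], call. = FALSE)
    }
  }
  df$participant <- as.character(df$participant)
  df$occasion <- as.integer(df$occasion)
  check_vocab("occasion", c(1L, 2L))
  check_vocab("block", iat_blocks)
  check_vocab("category", iat_categories)
  if (is.logical(df$correct)) df$correct <- as.integer(df$correct)
  check_vocab("correct", c(0L, 1L))
  keep <- intersect(c("participant", "occasion", "block", "category",
                      "correct", "latency_ms"), names(df))
  df[keep]
}

#' Apply participant-level exclusion rules
#'
#' Removes participants who lack critical-trial data at either measurement
#' occasion, and participants whose error rate exceeds 50% (random
#' responding) at either occasion.  A participant failing either rule is
#' excluded entirely.  Exactly 50% errors is retained.
#'
#' @param trials A trials tibble as returned by [read_trials()].
#'
#' @return A list with `trials` (the retained records) and `report`, a
#'   tibble of excluded participants with columns `participant` and
#'   `reason` (`"incomplete"` or `"error_rate"`).
#' @export
apply_exclusions <- function(trials) {
  by_part <- trials |>
    dplyr::group_by(.data$participant, .data$occasion) |>
    dplyr::summarise(n = dplyr::n(),
                     error_rate = mean(1 - .data$correct), .groups = "drop")
  incomplete <- by_part |>
    dplyr::group_by(.data$participant) |>
    dplyr::summarise(ok = dplyr::n_distinct(.data$occasion) == 2,
                     .groups = "drop") |>
    dplyr::filter(!.data$ok) |>
    dplyr::pull(.data$participant)
  high_error <- by_part |>
    dplyr::filter(.data$error_rate > 0.5) |>
    dplyr::pull(.data$participant) |>
    unique() |>
    setdiff(incomplete)
  report <- dplyr::bind_rows(
    tibble::tibble(participant = incomplete, reason = "incomplete"),
    tibble::tibble(participant = high_error, reason = "error_rate")
  )
  list(
    trials = dplyr::filter(trials, !.data$participant %in% report$participant),
    report = report
  )
}

#' Aggregate trials to per-cell response frequencies
#'
#' Collapses trial records to correct/total counts for each of the 8
#' condition cells (stimulus category x block compatibility), per
#' participant and occasion.  Cells with no trials are kept with a total of
#' zero (with a warning), since the hierarchical fit tolerates them.
#'
#' @param trials A trials tibble (after exclusions).
#'
#' @return A frequency tibble with columns `participant`, `occasion`,
#'   `condition`, `n_correct`, `n_trials`.
#' @export
aggregate_frequencies <- function(trials) {
  if (nrow(trials) == 0) {
    return(tibble::tibble(participant = character(), occasion = integer(),
                          condition = character(), n_correct = integer(),
                          n_trials = integer()))
  }
  freq <- trials |>
    dplyr::mutate(condition = paste(.data$category, .data$block, sep = "_")) |>
    dplyr::group_by(.data$participant, .data$occasion, .data$condition) |>
    dplyr::summarise(n_correct = sum(.data$correct),
                     n_trials = dplyr::n(), .groups = "drop")
  full <- freq |>
    dplyr::distinct(.data$participant, .data$occasion) |>
    tidyr::expand_grid(condition = iat_conditions()) |>
    dplyr::left_join(freq, by = c("participant", "occasion", "condition")) |>
    dplyr::mutate(n_correct = dplyr::coalesce(.data$n_correct, 0L),
                  n_trials = dplyr::coalesce(.data$n_trials, 0L)) |>
    dplyr::arrange(.data$participant, .data$occasion,
                   match(.data$condition, iat_conditions()))
  if (any(full$n_trials == 0)) {
    warning("some participant-occasion cells have zero trials; retained",
            call. = FALSE)
  }
  full
}
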