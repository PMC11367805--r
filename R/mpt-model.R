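#' @importFrom rlang .data .env
#' @importFrom stats pnorm qnorm rbinom setNames optim cor var aov
#' @importFrom utils combn head
NULL

# Canonical 8-cell condition grid of the race IAT: four stimulus categories
# crossed with the two critical-block pairings.  "compatible" = White/good
# share a response key.
iat_categories <- c("White", "Black", "good", "bad")
iat_blocks <- c("compatible", "incompatible")

#' Canonical IAT condition labels
#'
#' The eight condition cells used throughout the package: each of the four
#' stimulus categories (White, Black, good, bad) under each critical-block
#' pairing (compatible = White/good share a response key; incompatible =
#' White/bad share a key).
#'
#' @return Character vector of eight labels, e.g. `"White_compatible"`.
#' @export
iat_conditions <- function() {
  as.vector(vapply(iat_blocks, function(b) paste(iat_categories, b, sep = "_"),
                   character(4)))
}

#' Construct a multinomial processing tree model
#'
#' An `mpt_model` maps parameter vectors to response-category probabilities:
#' for each condition, the probability of each response is the sum over tree
#' branches of products of process probabilities (a parameter `p` or its
#' complement `1 - p`).
#'
#' @param name Model name.
#' @param parameters Character vector of parameter names (order is the
#'   canonical parameter order of the model).
#' @param branches A data frame with columns `condition`, `response`
#'   (`"correct"`/`"incorrect"`) and `factors`, a list column in which each
#'   element is a data frame with columns `parameter` (character) and
#'   `complement` (logical; `TRUE` means the factor is `1 - p`).
#' @param conditions Character vector of condition labels; defaults to the
#'   distinct conditions in `branches`, in order of first appearance.
#' @param check If `TRUE` (default), verify that every branch parameter is
#'   declared and that branch probabilities partition each condition
#'   (sum to 1 for random parameter vectors).
#'
#' @return An object of class `mpt_model`.
#' @export
mpt_model <- function(name, parameters, branches, conditions = NULL,
                      check = TRUE) {
  branches <- tibble::as_tibble(branches)
  stopifnot(all(c("condition", "response", "factors") %in% names(branches)))
  if (is.null(conditions)) conditions <- unique(branches$condition)
  if (!all(branches$response %in% c("correct", "incorrect"))) {
    stop("branch responses must be 'correct' or 'incorrect'", call. = FALSE)
  }
  if (!all(branches$condition %in% conditions)) {
    bad <- setdiff(unique(branches$condition), conditions)
    stop("branch refers to undeclared condition(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  used <- unique(unlist(lapply(branches$factors, function(f) f$parameter)))
  if (!all(used %in% parameters)) {
    stop("branch refers to unknown parameter(s): ",
         paste(setdiff(used, parameters), collapse = ", "), call. = FALSE)
  }
  model <- structure(
    list(name = name, parameters = parameters, conditions = conditions,
         branches = branches),
    class = "mpt_model"
  )
  if (check) {
    ok <- partition_holds(model, n_theta = 25, tol = 1e-9)
    if (!ok) {
      stop("branches do not partition the tree: per-condition response ",
           "probabilities do not sum to 1", call. = FALSE)
    }
  }
  model
}

#' @export
print.mpt_model <- function(x, ...) {
  cat("<mpt_model> ", x$name, "\n", sep = "")
  cat("  parameters: ", paste(x$parameters, collapse = ", "), "\n", sep = "")
  cat("  conditions: ", length(x$conditions), " (",
      paste(head(x$conditions, 4), collapse = ", "), ", ...)\n", sep = "")
  cat("  branches:   ", nrow(x$branches), "\n", sep = "")
  invisible(x)
}

# Evaluate one branch product for a theta matrix (rows = parameter vectors).
branch_product <- function(factors, theta_mat) {
  out <- rep(1, nrow(theta_mat))
  for (k in seq_len(nrow(factors))) {
    v <- theta_mat[, factors$parameter[k]]
    out <- out * if (factors$complement[k]) 1 - v else v
  }
  out
}

#' Response-category probabilities of an MPT model
#'
#' Computes, for one parameter vector, the probability of each (condition,
#' response) category: the sum over branches of the products of their
#' factors.
#'
#' @param model An [mpt_model].
#' @param theta Named numeric vector of parameter values in `[0, 1]`; names
#'   must be exactly the model's parameters.
#'
#' @return A tibble with columns `condition`, `response`, `probability`.
#' @examples
#' quad <- mpt_quad()
#' theta <- c(AC_wg = .3, AC_bb = .3, D = .6, OB = .5, G = .5)
#' category_probabilities(quad, theta)
#' @export
category_probabilities <- function(model, theta) {
  theta <- check_theta(model, theta)
  mat <- matrix(theta, nrow = 1, dimnames = list(NULL, names(theta)))
  p <- vapply(model$branches$factors, branch_product, numeric(1),
              theta_mat = mat)
  out <- model$branches |>
    dplyr::mutate(probability = p) |>
    dplyr::group_by(.data$condition, .data$response) |>
    dplyr::summarise(probability = sum(.data$probability), .groups = "drop")
  # every (condition, response) pair present, even if no branch ends there
  grid <- tidyr::expand_grid(condition = model$conditions,
                             response = c("correct", "incorrect"))
  grid |>
    dplyr::left_join(out, by = c("condition", "response")) |>
    dplyr::mutate(probability = dplyr::coalesce(.data$probability, 0))
}

check_theta <- function(model, theta) {
  theta <- unlist(theta)
  if (is.null(names(theta)) || !setequal(names(theta), model$parameters) ||
      anyDuplicated(names(theta))) {
    stop("theta names must match the model parameters exactly: ",
         paste(model$parameters, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(theta)) || any(theta < 0) || any(theta > 1)) {
    stop("theta values must lie in [0, 1]", call. = FALSE)
  }
  theta[model$parameters]
}

# P(correct) for each condition, vectorized over rows of a theta matrix
# (columns named by parameter).  Workhorse for simulation and fitting.
prob_correct_matrix <- function(model, theta_mat) {
  theta_mat <- as.matrix(theta_mat)
  if (is.null(colnames(theta_mat))) colnames(theta_mat) <- model$parameters
  out <- matrix(0, nrow(theta_mat), length(model$conditions),
                dimnames = list(NULL, model$conditions))
  br <- model$branches
  for (b in which(br$response == "correct")) {
    out[, br$condition[b]] <- out[, br$condition[b]] +
      branch_product(br$factors[[b]], theta_mat)
  }
  out
}

# Does each condition's branch set partition the tree?  Checked by random
# sampling of parameter vectors.
partition_holds <- function(model, n_theta = 100, tol = 1e-12, seed = NULL) {
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  P <- length(model$parameters)
  theta_mat <- matrix(stats::runif(n_theta * P), n_theta, P,
                      dimnames = list(NULL, model$parameters))
  total <- matrix(0, n_theta, length(model$conditions),
                  dimnames = list(NULL, model$conditions))
  br <- model$branches
  for (b in seq_len(nrow(br))) {
    total[, br$condition[b]] <- total[, br$condition[b]] +
      branch_product(br$factors[[b]], theta_mat)
  }
  all(abs(total - 1) < tol)
}

#' The Quad model for the race IAT
#'
#' Five parameters: `AC_wg` and `AC_bb`, the probabilities that the
#' White-good and Black-bad association is activated (AC_wg applies on White
#' faces and good words, AC_bb on Black faces and bad words); `D`, detection
#' of the correct response; `OB`, overcoming bias, the inhibitory process
#' that resolves a conflict between an activated association and a detected
#' correct response (it enters the tree only in incompatible blocks, where
#' association-driven responses are errors); and `G`, the tendency to guess
#' the "good"-assigned key when no other process drives the response.
#'
#' The tree is frozen in the packaged `quad.eqn` file, which documents every
#' branch.
#'
#' @return An [mpt_model] with parameters `AC_wg, AC_bb, D, OB, G`.
#' @export
mpt_quad <- function() {
  read_eqn(mptstab_eqn_file("quad.eqn"), name = "quad",
           parameters = c("AC_wg", "AC_bb", "D", "OB", "G"),
           conditions = iat_conditions())
}

#' The process dissociation procedure (PDP) for the race IAT
#'
#' Six parameters: stimulus-specific control `C_White, C_Black, C_good,
#' C_bad` (success always yields the correct response) and automatic
#' evaluations `A_White, A_Black`, which drive responses only when control
#' fails; automatic values above 0.5 reflect a positive evaluation of the
#' target group.  On attribute-word trials the automatic evaluation of the
#' target category sharing the response key applies.  The tree is frozen in
#' the packaged `pdp.eqn` file.
#'
#' @return An [mpt_model] with parameters
#'   `A_White, A_Black, C_White, C_Black, C_good, C_bad`.
#' @export
mpt_pdp <- function() {
  read_eqn(mptstab_eqn_file("pdp.eqn"), name = "pdp",
           parameters = c("A_White", "A_Black",
                          "C_White", "C_Black", "C_good", "C_bad"),
           conditions = iat_conditions())
}

mptstab_eqn_file <- function(file) {
  path <- system.file("extdata", file, package = "mptstab")
  if (!nzchar(path)) {
    # uninstalled tree (e.g. pkgload during development)
    path <- file.path("inst", "extdata", file)
  }
  path
}

#' Read and write EQN-style MPT model files
#'
#' The interchange format is one branch per line:
#' `condition response factor*factor*...`, where each factor is a parameter
#' name `p` or its complement `(1-p)`.  Lines starting with `#` and blank
#' lines are ignored.
#'
#' @param path Path to an EQN file, or a character vector of lines (anything
#'   containing a newline or of length > 1 is treated as text).
#' @param name Model name for the resulting object.
#' @param parameters Optional parameter order; defaults to order of first
#'   appearance. An error is raised if the file uses parameters not listed.
#' @param conditions Optional condition order; defaults to order of first
#'   appearance. An error is raised if the file uses conditions not listed.
#'
#' @return `read_eqn()` returns an [mpt_model]; `write_eqn()` returns the
#'   EQN text invisibly (and writes it to `path` unless `path` is `NULL`).
#' @export
read_eqn <- function(path, name = "mpt", parameters = NULL,
                     conditions = NULL) {
  if (length(path) > 1 || grepl("[\n ]", path[1]) || !nzchar(path[1])) {
    lines <- unlist(strsplit(path, "\n", fixed = TRUE))
  } else {
    if (!file.exists(path)) stop("no such EQN file: ", path, call. = FALSE)
    lines <- readLines(path)
  }
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0) {
    stop("EQN input contains no branch lines", call. = FALSE)
  }
  rows <- lapply(keep, function(i) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 3) {
      stop("EQN parse error at line ", i,
           ": expected 'condition response factors'", call. = FALSE)
    }
    if (!parts[2] %in% c("correct", "incorrect")) {
      stop("EQN parse error at line ", i, ": response must be ",
           "'correct' or 'incorrect', got '", parts[2], "'", call. = FALSE)
    }
    facs <- strsplit(parts[3], "*", fixed = TRUE)[[1]]
    compl <- grepl("^\\(1-[A-Za-z][A-Za-z0-9_.]*\\)$", facs)
    plain <- grepl("^[A-Za-z][A-Za-z0-9_.]*$", facs)
    if (any(!(compl | plain)) || length(facs) == 0) {
      stop("EQN parse error at line ", i, ": malformed factor '",
           facs[which(!(compl | plain))[1]], "'", call. = FALSE)
    }
    par <- ifelse(compl, sub("^\\(1-", "", sub("\\)$", "", facs)), facs)
    tibble::tibble(
      condition = parts[1], response = parts[2],
      factors = list(tibble::tibble(parameter = par, complement = compl)),
      line = i
    )
  })
  branches <- dplyr::bind_rows(rows)
  used_par <- unique(unlist(lapply(branches$factors, function(f) f$parameter)))
  if (is.null(parameters)) parameters <- used_par
  if (!all(used_par %in% parameters)) {
    stop("EQN uses undeclared parameter(s): ",
         paste(setdiff(used_par, parameters), collapse = ", "), call. = FALSE)
  }
  if (!is.null(conditions) && !all(branches$condition %in% conditions)) {
    bad <- branches[!branches$condition %in% conditions, ]
    stop("EQN parse error at line ", bad$line[1],
         ": undeclared condition '", bad$condition[1], "'", call. = FALSE)
  }
  mpt_model(name, parameters, branches[c("condition", "response", "factors")],
            conditions = conditions)
}

#' @param model An [mpt_model] to serialize.
#' @rdname read_eqn
#' @export
write_eqn <- function(model, path = NULL) {
  fmt <- vapply(seq_len(nrow(model$branches)), function(b) {
    f <- model$branches$factors[[b]]
    facs <- ifelse(f$complement, paste0("(1-", f$parameter, ")"), f$parameter)
    paste(model$branches$condition[b], model$branches$response[b],
          paste(facs, collapse = "*"))
  }, character(1))
  text <- paste0(paste(fmt, collapse = "\n"), "\n")
  if (!is.null(path)) writeLines(sub("\n$", "", text), path)
  invisible(text)
}
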