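pb_schema <- c("participant_id", "group", "run", "trial_index", "n_shown",
               "truth", "e1", "peer_confidence", "peer_estimate", "e2",
               "is_filler")

validate_trials <- function(data) {
  missing_cols <- setdiff(pb_schema, names(data))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(data),
                   c(pb_schema, "s", "included", "exclusion_reason"))
  if (length(extra) > 0) {
    warning("unknown column(s) kept as-is: ",
            paste(extra, collapse = ", "), call. = FALSE)
  }
  bad_row <- function(ok, what) {
    if (any(!ok, na.rm = FALSE)) {
      i <- which(!ok | is.na(ok))[1]
      stop("invalid ", what, " at row ", i, call. = FALSE)
    }
  }
  in_range <- function(x, allow_na = FALSE) {
    ok <- x >= 0 & x <= 100
    if (allow_na) ok[is.na(x)] <- TRUE else ok[is.na(x)] <- FALSE
    ok
  }
  bad_row(in_range(data$truth), "truth (must be 0-100)")
  bad_row(in_range(data$e1, allow_na = TRUE), "e1 (must be 0-100)")
  bad_row(in_range(data$e2, allow_na = TRUE), "e2 (must be 0-100)")
  bad_row(in_range(data$peer_estimate), "peer_estimate (must be 0-100)")
  bad_row(!is.na(data$peer_confidence) & data$peer_confidence %in% 1:3,
          "peer_confidence (must be 1, 2 or 3)")
  bad_row(!is.na(data$n_shown) & data$n_shown %in% c(5, 45),
          "n_shown (must be 5 or 45)")
  bad_row(!is.na(data$is_filler), "is_filler (must be logical)")
  dup <- data |>
    dplyr::count(.data$participant_id, .data$trial_index) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("duplicate trial_index within participant ",
         dup$participant_id[1], call. = FALSE)
  }
  invisible(data)
}

#' Read and write trial-level cohort CSV files
#'
#' The interchange format is a comma-separated UTF-8 table with header
#' `participant_id, group, run, trial_index, n_shown, truth, e1,
#' peer_confidence, peer_estimate, e2, is_filler`; percentages are stored on
#' the 0-100 slider scale and a blank `e2` marks a missed trial. Leading
#' `#` comment lines (the provenance header written by `write_trials()`)
#' are skipped on read. Validation failures abort naming the offending row
#' and column; unknown extra columns are kept with a warning.
#'
#' @param path File path.
#' @return `read_trials()`: a validated tibble in schema order.
#' @export
read_trials <- function(path) {
  data <- readr::read_csv(
    path, comment = "#", show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      group = readr::col_character(),
      run = readr::col_integer(),
      trial_index = readr::col_integer(),
      n_shown = readr::col_integer(),
      truth = readr::col_double(),
      e1 = readr::col_double(),
      peer_confidence = readr::col_integer(),
      peer_estimate = readr::col_double(),
      e2 = readr::col_double(),
      is_filler = readr::col_logical(),
      .default = readr::col_guess()
    )
  )
  validate_trials(data)
  dplyr::relocate(data, dplyr::all_of(pb_schema))
}

#' @rdname read_trials
#' @param data Trial-level tibble (e.g. from [simulate_cohort()]).
#' @param seeds Optional list of seeds recorded in the provenance header;
#'   defaults to `attr(data, "seeds")`.
#' @export
write_trials <- function(data, path, seeds = attr(data, "seeds")) {
  validate_trials(data)
  out <- dplyr::relocate(tibble::as_tibble(data), dplyr::all_of(pb_schema))
  header <- paste0(
    "# peerbayes cohort",
    if (!is.null(seeds)) {
      paste0("; ", paste(names(seeds), unlist(seeds), sep = "=",
                         collapse = "; "))
    },
    "; hash=", rlang::hash(out)
  )
  writeLines(header, path)
  readr::write_csv(out, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' Ground-truth sidecar for simulated cohorts
#'
#' Saves (and restores) the generating parameters and seeds of a simulated
#' cohort as JSON, for use as the reference in recovery analyses.
#'
#' @param data Output of [simulate_cohort()] (must carry a `ground_truth`
#'   attribute).
#' @param path File path for the JSON sidecar.
#' @export
write_ground_truth <- function(data, path) {
  gt <- attr(data, "ground_truth")
  if (is.null(gt)) stop("no ground_truth attribute on data", call. = FALSE)
  jsonlite::write_json(
    list(seeds = attr(data, "seeds"), ground_truth = gt),
    path, auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(path)
}

#' @rdname write_ground_truth
#' @return `read_ground_truth()`: list with `seeds` and the `ground_truth`
#'   tibble.
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::fromJSON(path)
  x$ground_truth <- tibble::as_tibble(x$ground_truth)
  x
}
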