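#' Model-recovery confusion matrix
#'
#' For each of the nine parameterized models: simulate a cohort with
#' generating parameters drawn uniformly within the configured ranges, fit
#' every candidate model to every simulated participant, and declare the
#' per-participant winner by lowest BIC (ties broken by fewer parameters,
#' then model order). Entries are the fraction of each generating model's
#' participants won by each candidate; rows sum to one.
#'
#' @param models Character vector of model ids to cross (default: the nine
#'   parameterized models, the base model having nothing to recover).
#' @param n_per_dataset Simulated participants per generating model.
#' @param fit_config A [fit_config()].
#' @param seed Integer master seed; all simulation randomness derives from
#'   it.
#' @param param_ranges Optional named list (by model id) of range lists
#'   overriding [default_param_ranges()].
#' @param exact_e1 Passed to [simulate_cohort()].
#' @return A list of class `pb_confusion`: `fractions` and `counts`
#'   (matrices, generating model in rows), `n_per_dataset`, `n_failures`.
#' @export
model_recovery <- function(models = pb_model_ids(parameterized = TRUE),
                           n_per_dataset = 20,
                           fit_config = fit_config(),
                           seed = 1,
                           param_ranges = NULL,
                           exact_e1 = FALSE) {
  stopifnot(n_per_dataset >= 1)
  sub_seeds <- withr::with_seed(as.integer(seed), {
    matrix(sample.int(.Machine$integer.max, 2 * length(models)), ncol = 2)
  })
  counts <- matrix(0L, nrow = length(models), ncol = length(models),
                   dimnames = list(generating = models, fitted = models))
  n_failures <- 0L
  for (gi in seq_along(models)) {
    gen <- models[gi]
    ranges <- if (!is.null(param_ranges)) param_ranges[[gen]] else NULL
    cohort <- simulate_cohort(
      list(group_spec("sim", n_per_dataset, gen, ranges)),
      design_seed = sub_seeds[gi, 1], behavior_seed = sub_seeds[gi, 2],
      exact_e1 = exact_e1, miss_rate = 0
    )
    flagged <- apply_exclusions(
      cohort, exclusion_config(stay_fraction_threshold = 1)
    )
    fits <- fit_cohort(flagged, models = models, config = fit_config)
    winners <- fits |>
      dplyr::group_by(.data$participant_id) |>
      dplyr::arrange(.data$bic, .data$k,
                     match(.data$model_id, models), .by_group = TRUE) |>
      dplyr::slice(1) |>
      dplyr::ungroup()
    n_failures <- n_failures + sum(!fits$converged)
    tab <- table(factor(winners$model_id, levels = models))
    counts[gi, ] <- counts[gi, ] + as.integer(tab)
  }
  fractions <- counts / rowSums(counts)
  structure(
    list(fractions = fractions, counts = counts,
         n_per_dataset = n_per_dataset, n_failures = n_failures),
    class = "pb_confusion"
  )
}

#' @export
print.pb_confusion <- function(x, ...) {
  cat("<pb_confusion> ", x$n_per_dataset,
      " simulated participants per generating model\n", sep = "")
  print(round(x$fractions, 3))
  if (x$n_failures > 0) {
    cat("non-converged fits:", x$n_failures, "\n")
  }
  invisible(x)
}

#' Tidy a confusion matrix
#'
#' @param x A `pb_confusion` object.
#' @param ... Unused.
#' @return Long tibble: `generating`, `fitted`, `fraction`, `count`.
#' @method tidy pb_confusion
#' @export
tidy.pb_confusion <- function(x, ...) {
  long <- as.data.frame.table(x$fractions, responseName = "fraction")
  long$count <- as.vector(x$counts)
  tibble::as_tibble(long)
}

#' Parameter-recovery report
#'
#' Draws generating parameters per simulated participant uniformly within
#' the given ranges, simulates each participant's session, refits the same
#' model, and correlates generating with fitted values per parameter
#' (Pearson).
#'
#' @param model A `pb_model` or model id string.
#' @param n_participants Number of simulated participants (at least 3).
#' @param param_ranges Named list of `c(lower, upper)` ranges; default
#'   [default_param_ranges()].
#' @param fit_config A [fit_config()].
#' @param seed Integer master seed.
#' @param n_repeats,n_filler,exact_e1 Passed to [simulate_cohort()] (larger
#'   `n_repeats` gives more trials per participant).
#' @return A tibble of class `pb_recovery` with one row per parameter:
#'   `parameter`, `r`, `p.value`, `n`. The per-participant generating and
#'   fitted values are attached as `attr(result, "scatter")`.
#' @export
parameter_recovery <- function(model, n_participants = 132,
                               param_ranges = NULL,
                               fit_config = fit_config(),
                               seed = 1,
                               n_repeats = 2, n_filler = 15,
                               exact_e1 = FALSE) {
  model <- as_model(model)
  stopifnot(n_participants >= 3, model$k >= 1)
  if (is.null(param_ranges)) param_ranges <- default_param_ranges(model)
  for (p in model$parameters) {
    r <- param_ranges[[p]]
    if (is.null(r) || diff(r) <= 0) {
      stop("degenerate (zero-width) generating range for parameter ", p,
           call. = FALSE)
    }
  }
  sub_seeds <- withr::with_seed(as.integer(seed),
                                sample.int(.Machine$integer.max, 2))
  cohort <- simulate_cohort(
    list(group_spec("sim", n_participants, model, param_ranges)),
    design_seed = sub_seeds[1], behavior_seed = sub_seeds[2],
    n_repeats = n_repeats, n_filler = n_filler,
    exact_e1 = exact_e1, miss_rate = 0
  )
  truth <- attr(cohort, "ground_truth")
  flagged <- apply_exclusions(
    cohort, exclusion_config(stay_fraction_threshold = 1)
  )
  fits <- fit_cohort(flagged, models = model$model_id, config = fit_config)
  scatter <- truth |>
    tidyr::pivot_longer(dplyr::all_of(model$parameters),
                        names_to = "parameter", values_to = "generating") |>
    dplyr::left_join(
      fits |>
        dplyr::select("participant_id", dplyr::all_of(model$parameters)) |>
        tidyr::pivot_longer(dplyr::all_of(model$parameters),
                            names_to = "parameter", values_to = "fitted"),
      by = c("participant_id", "parameter")
    )
  out <- scatter |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(
      r = stats::cor(.data$generating, .data$fitted),
      p.value = stats::cor.test(.data$generating, .data$fitted)$p.value,
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$parameter, model$parameters))
  attr(out, "scatter") <- scatter
  class(out) <- c("pb_recovery", class(out))
  out
}
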