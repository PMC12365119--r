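#' Fitting configuration
#'
#' Controls the two-stage maximum-likelihood search: a full factorial grid
#' within the model's parameter bounds (log-spaced for the alpha/theta scale
#' parameters whose bounds span several decades, linear for the beta
#' probabilities), followed by bounded L-BFGS-B refinement launched from the
#' best grid points.
#'
#' @param grid_points_per_param Grid resolution per parameter (default 5).
#' @param n_local_starts Number of best grid points used as local-
#'   optimization starts (default 3).
#' @param convergence_tol Relative objective-improvement tolerance of the
#'   local optimizer (default 1e-6).
#' @param max_iter Iteration cap of the local optimizer (default 500).
#' @param seed Integer recorded with results; the procedure itself is
#'   deterministic (grid order and first-start order break ties).
#' @return A list of class `pb_fit_config`.
#' @export
fit_config <- function(grid_points_per_param = 5, n_local_starts = 3,
                       convergence_tol = 1e-6, max_iter = 500, seed = 1) {
  stopifnot(grid_points_per_param >= 2, n_local_starts >= 1,
            convergence_tol > 0, max_iter >= 1)
  structure(
    list(grid_points_per_param = as.integer(grid_points_per_param),
         n_local_starts = as.integer(n_local_starts),
         convergence_tol = convergence_tol,
         max_iter = as.integer(max_iter),
         seed = as.integer(seed)),
    class = "pb_fit_config"
  )
}

#' Bayesian Information Criterion
#'
#' `2 * negll + k * log(n)`, with `n` the number of trials entering the
#' likelihood. Lower values indicate better fit after the complexity
#' penalty.
#'
#' @param negll Negative log-likelihood at the optimum.
#' @param k Number of free parameters.
#' @param n Number of observations (included trials).
#' @return The BIC value.
#' @examples
#' bic(100, 5, 60)
#' @export
bic <- function(negll, k, n) {
  stopifnot(n >= 1, k >= 0)
  2 * negll + k * log(n)
}

param_grid <- function(model, n_points) {
  axes <- lapply(model$parameters, function(p) {
    lo <- model$lower[[p]]
    hi <- model$upper[[p]]
    if (startsWith(p, "beta")) {
      seq(lo, hi, length.out = n_points)
    } else {
      exp(seq(log(lo), log(hi), length.out = n_points))
    }
  })
  names(axes) <- model$parameters
  as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
}

#' Fit one model to one participant by maximum likelihood
#'
#' Evaluates the negative log-likelihood on a full factorial grid within the
#' model's bounds, then refines from the best grid points with bounded
#' L-BFGS-B (finite-difference gradients). The reported optimum is the best
#' point seen anywhere, so refinement can never worsen the grid incumbent.
#' Deterministic for a given configuration and data.
#'
#' @param trials One participant's trials (rows with `included == FALSE`
#'   are ignored; if no `included` column is present all rows are used).
#'   Must contain `e1`, `e2`, `peer_estimate`, `n_shown`, `peer_confidence`.
#' @param model A `pb_model` or model id string.
#' @param config A [fit_config()].
#' @return A list of class `pb_fit`: `model_id`, `params` (named vector),
#'   `negll`, `n_trials`, `k`, `bic`, `converged`, `participant_id` (if the
#'   data identify one).
#' @export
fit_participant <- function(trials, model, config = fit_config()) {
  model <- as_model(model)
  stopifnot(inherits(config, "pb_fit_config"))
  if ("included" %in% names(trials)) {
    trials <- trials[trials$included, , drop = FALSE]
  }
  if (nrow(trials) == 0) {
    stop("participant has no included trials", call. = FALSE)
  }
  pid <- if ("participant_id" %in% names(trials)) {
    unique(trials$participant_id)[1]
  } else {
    NA_character_
  }
  n <- nrow(trials)
  negll_fn <- make_negll(trials, model)

  if (model$k == 0) {
    nll <- negll_fn(numeric(0))
    return(new_pb_fit(model, numeric(0), nll, n, TRUE, pid))
  }

  grid <- param_grid(model, config$grid_points_per_param)
  grid_nll <- apply(grid, 1, negll_fn)
  ord <- order(grid_nll)
  starts <- ord[seq_len(min(config$n_local_starts, length(ord)))]

  best_par <- grid[starts[1], ]
  best_nll <- grid_nll[starts[1]]
  converged <- FALSE
  for (si in starts) {
    opt <- tryCatch(
      stats::optim(
        par = grid[si, ], fn = negll_fn, method = "L-BFGS-B",
        lower = model$lower, upper = model$upper,
        control = list(maxit = config$max_iter,
                       factr = config$convergence_tol / 1e-13)
      ),
      error = function(e) NULL
    )
    if (!is.null(opt)) {
      converged <- converged || opt$convergence == 0
      if (opt$value < best_nll) {
        best_nll <- opt$value
        best_par <- opt$par
      }
    }
  }
  new_pb_fit(model, stats::setNames(best_par, model$parameters),
             best_nll, n, converged, pid)
}

new_pb_fit <- function(model, params, negll, n, converged, pid) {
  structure(
    list(model_id = model$model_id, params = params, negll = negll,
         n_trials = n, k = model$k, bic = bic(negll, model$k, n),
         converged = converged, participant_id = pid),
    class = "pb_fit"
  )
}

#' @export
print.pb_fit <- function(x, ...) {
  cat("<pb_fit> ", x$model_id,
      if (!is.na(x$participant_id)) paste0(" [", x$participant_id, "]"),
      ": negll = ", format(x$negll), ", BIC = ", format(x$bic),
      " (n = ", x$n_trials, ", k = ", x$k, ")\n", sep = "")
  if (x$k > 0) print(round(x$params, 4))
  invisible(x)
}

#' Broom-style accessors for fitted objects
#'
#' `tidy()` returns one row per fitted parameter with its bounds; `glance()`
#' a one-row model summary.
#'
#' @param x A `pb_fit` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy pb_fit
#' @export
tidy.pb_fit <- function(x, ...) {
  spec <- model_spec(x$model_id)
  tibble::tibble(
    term = spec$parameters,
    estimate = unname(x$params[spec$parameters]),
    lower = unname(spec$lower),
    upper = unname(spec$upper)
  )
}

#' @rdname tidy.pb_fit
#' @method glance pb_fit
#' @export
glance.pb_fit <- function(x, ...) {
  tibble::tibble(
    model_id = x$model_id, participant_id = x$participant_id,
    negll = x$negll, k = x$k, n_trials = x$n_trials, bic = x$bic,
    converged = x$converged
  )
}

#' Fit models to every participant in a cohort
#'
#' Applies [fit_participant()] per participant and model. If the data have
#' not been through [apply_exclusions()] yet, the default exclusion rules
#' are applied first, so fitting always operates on the analysable trials.
#'
#' @param data Trial-level cohort tibble.
#' @param models Character vector of model ids (default: all ten).
#' @param config A [fit_config()].
#' @param exclusions An [exclusion_config()] used when `data` lacks
#'   inclusion flags.
#' @return A tibble of class `pb_fits`, one row per participant x model:
#'   `participant_id`, `group`, `model_id`, one column per parameter in the
#'   family (NA where a model lacks it), `negll`, `k`, `n_trials`, `bic`,
#'   `converged`.
#' @export
fit_cohort <- function(data, models = pb_model_ids(),
                       config = fit_config(),
                       exclusions = exclusion_config()) {
  if (!"included" %in% names(data)) {
    data <- apply_exclusions(data, exclusions)
  }
  data <- included_trials(data)
  if (nrow(data) == 0) stop("no included trials to fit", call. = FALSE)
  parts <- split(data, data$participant_id)
  rows <- purrr::map(parts, function(ptrials) {
    purrr::map(models, function(mid) {
      fit <- fit_participant(ptrials, mid, config)
      out <- glance.pb_fit(fit)
      out$group <- ptrials$group[1]
      if (fit$k > 0) {
        out <- dplyr::bind_cols(out, tibble::as_tibble(as.list(fit$params)))
      }
      out
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  all_pars <- unique(unlist(lapply(pb_model_ids(), function(m) {
    model_spec(m)$parameters
  })))
  for (p in setdiff(all_pars, names(rows))) rows[[p]] <- NA_real_
  out <- dplyr::select(
    rows, "participant_id", "group", "model_id",
    dplyr::all_of(all_pars), "negll", "k", "n_trials", "bic", "converged"
  )
  class(out) <- c("pb_fits", class(out))
  out
}

#' Group-level BIC model comparison
#'
#' Sums per-participant BIC within each group for every model and reports
#' each model's excess over the group's best (lowest) total. The layout
#' mirrors the standard model-comparison table: model, description, number
#' of parameters, and the BIC difference per group.
#'
#' @param fits A `pb_fits` tibble from [fit_cohort()] (every participant
#'   must be fitted by every model).
#' @return A tibble of class `pb_model_comparison` with columns `group`,
#'   `model_id`, `description`, `k`, `n_participants`, `total_bic`,
#'   `delta_bic`.
#' @export
compare_models <- function(fits) {
  stopifnot(all(c("participant_id", "group", "model_id", "bic")
                %in% names(fits)))
  counts <- fits |>
    dplyr::count(.data$group, .data$model_id)
  if (length(unique(counts$n)) > 1) {
    stop("incomplete fits: every participant must be fitted by every model",
         call. = FALSE)
  }
  info <- purrr::map(unique(fits$model_id), function(m) {
    spec <- model_spec(m)
    tibble::tibble(model_id = m, description = spec$description, k = spec$k)
  }) |> dplyr::bind_rows()
  out <- fits |>
    dplyr::group_by(.data$group, .data$model_id) |>
    dplyr::summarise(total_bic = sum(.data$bic),
                     n_participants = dplyr::n(), .groups = "drop_last") |>
    dplyr::mutate(delta_bic = .data$total_bic - min(.data$total_bic)) |>
    dplyr::ungroup() |>
    dplyr::left_join(info, by = "model_id") |>
    dplyr::select("group", "model_id", "description", "k",
                  "n_participants", "total_bic", "delta_bic")
  class(out) <- c("pb_model_comparison", class(out))
  out
}

#' Wide model-comparison table
#'
#' Reshapes a [compare_models()] result into one row per model with a
#' delta-BIC column per group.
#'
#' @param comparison A `pb_model_comparison` tibble.
#' @return A tibble: `model_id`, `description`, `k`, then one
#'   `delta_bic_<group>` column per group.
#' @export
comparison_table <- function(comparison) {
  comparison |>
    dplyr::select("model_id", "description", "k", "group", "delta_bic") |>
    tidyr::pivot_wider(names_from = "group", values_from = "delta_bic",
                       names_prefix = "delta_bic_") |>
    dplyr::arrange(match(.data$model_id, pb_model_ids()))
}
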