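#' Reference group-median parameter values for the winning model
#'
#' Typical median fitted M3d parameters for adolescent and adult cohorts on
#' this task, used as anchors for the synthetic cohort defaults:
#' `alpha_uncertain` and `alpha_certain` scale the
#' perceived evidence in the 5- and 45-mushroom conditions, `theta_ic` and
#' `theta_slope` map peer confidence onto the assumed peer sample size, and
#' `beta` is the stay-bias base.
#'
#' @param group `"adolescent"` or `"adult"`.
#' @return Named numeric vector of five M3d parameters.
#' @examples
#' group_median_params("adult")
#' @export
group_median_params <- function(group = c("adolescent", "adult")) {
  group <- match.arg(group)
  switch(group,
    adolescent = c(alpha_uncertain = 28.4, alpha_certain = 4.9,
                   theta_ic = 54.2, theta_slope = 62.0, beta = 0.22),
    adult = c(alpha_uncertain = 29.5, alpha_certain = 5.9,
              theta_ic = 55.3, theta_slope = 89.2, beta = 0.15)
  )
}

# Pooled anchor values (both groups' medians) per parameter, used to build
# default sampling ranges. Parameters absent from the winning model anchor on
# the corresponding winning-model quantity: a single alpha on both alphas, a
# confidence-independent theta on theta_ic, per-level thetas on
# theta_ic + theta_slope * (level - 1).
param_anchors <- function() {
  ado <- group_median_params("adolescent")
  adu <- group_median_params("adult")
  list(
    alpha = c(ado[["alpha_certain"]], adu[["alpha_certain"]],
              ado[["alpha_uncertain"]], adu[["alpha_uncertain"]]),
    alpha_uncertain = c(ado[["alpha_uncertain"]], adu[["alpha_uncertain"]]),
    alpha_certain = c(ado[["alpha_certain"]], adu[["alpha_certain"]]),
    theta = c(ado[["theta_ic"]], adu[["theta_ic"]]),
    theta_ic = c(ado[["theta_ic"]], adu[["theta_ic"]]),
    theta_slope = c(ado[["theta_slope"]], adu[["theta_slope"]]),
    theta_low = c(ado[["theta_ic"]], adu[["theta_ic"]]),
    theta_medium = c(ado[["theta_ic"]] + ado[["theta_slope"]],
                     adu[["theta_ic"]] + adu[["theta_slope"]]),
    theta_high = c(ado[["theta_ic"]] + 2 * ado[["theta_slope"]],
                   adu[["theta_ic"]] + 2 * adu[["theta_slope"]]),
    beta = c(ado[["beta"]], adu[["beta"]]),
    beta_uncertain = c(ado[["beta"]], adu[["beta"]]),
    beta_certain = c(ado[["beta"]], adu[["beta"]])
  )
}

#' Default generating-parameter ranges for a model
#'
#' Uniform sampling ranges spanning half to twice the pooled group-median
#' anchor values, clipped to the model's fitting bounds. Used wherever
#' realistic parameter spread is needed (cohort simulation, model and
#' parameter recovery).
#'
#' @param model A `pb_model` or model id string.
#' @return Named list of `c(lower, upper)` ranges, one per model parameter.
#' @examples
#' default_param_ranges("M3d")
#' @export
default_param_ranges <- function(model) {
  model <- as_model(model)
  anchors <- param_anchors()
  out <- lapply(model$parameters, function(p) {
    a <- anchors[[p]]
    c(max(0.5 * min(a), model$lower[[p]]),
      min(2 * max(a), model$upper[[p]]))
  })
  stats::setNames(out, model$parameters)
}

#' Specification of one simulated group
#'
#' @param group Group label (free string; `"adolescent"` and `"adult"` are
#'   the documented defaults).
#' @param n_participants Number of participants to simulate.
#' @param model Generating model (`pb_model` or id string). Default `"M3d"`.
#' @param params How generating parameters are drawn per participant:
#'   a named numeric vector (every participant gets these fixed values), a
#'   named list of `c(lower, upper)` ranges (independent uniform draws), or
#'   `NULL` for [default_param_ranges()] of the model.
#' @return A list of class `pb_group_spec`.
#' @export
group_spec <- function(group, n_participants, model = "M3d", params = NULL) {
  model <- as_model(model)
  stopifnot(n_participants >= 1, n_participants == as.integer(n_participants))
  if (is.null(params)) params <- default_param_ranges(model)
  if (is.numeric(params)) {
    check_params(params, model)
    pv <- params[model$parameters]
    bad <- pv < model$lower | pv > model$upper
    if (any(bad, na.rm = TRUE)) {
      stop("fixed parameter value(s) outside model bounds: ",
           paste(model$parameters[bad], collapse = ", "), call. = FALSE)
    }
  } else {
    check_params(params, model)
    for (p in model$parameters) {
      r <- params[[p]]
      if (length(r) != 2 || r[1] > r[2] || r[1] < model$lower[[p]] ||
            r[2] > model$upper[[p]]) {
        stop("invalid range for parameter ", p, call. = FALSE)
      }
    }
  }
  structure(
    list(group = group, n_participants = as.integer(n_participants),
         model = model, params = params),
    class = "pb_group_spec"
  )
}

#' Default two-group study specification
#'
#' The study-scale cohort: 64 adolescents and 68 adults, both generated from
#' the winning model M3d with parameters drawn uniformly within
#' [default_param_ranges()].
#'
#' @return List of two `pb_group_spec` objects.
#' @export
default_group_specs <- function() {
  list(
    group_spec("adolescent", 64, "M3d"),
    group_spec("adult", 68, "M3d")
  )
}

draw_params <- function(spec) {
  if (is.numeric(spec$params)) {
    return(spec$params[spec$model$parameters])
  }
  vapply(spec$model$parameters, function(p) {
    r <- spec$params[[p]]
    stats::runif(1, r[1], r[2])
  }, numeric(1))
}

#' Sample a first estimate from perceived mushrooms
#'
#' Perception is modelled as observing the colour of each of the `n_shown`
#' mushrooms independently: `blue ~ Binomial(n_shown, truth/100)`, and the
#' first estimate is the observed percentage rounded to the slider. With
#' `exact = TRUE` the truth itself is reported (rounded half-up to the
#' integer slider).
#'
#' @param truth True percentage (0-100). Vectorized.
#' @param n_shown Mushrooms shown (5 or 45). Vectorized.
#' @param exact If `TRUE`, noise-free reporting of the truth.
#' @return Integer-valued estimates on 0-100.
#' @export
sample_e1 <- function(truth, n_shown, exact = FALSE) {
  stopifnot(all(truth >= 0 & truth <= 100))
  if (exact) {
    return(round_half_up(truth))
  }
  n <- max(length(truth), length(n_shown))
  truth <- rep_len(truth, n)
  n_shown <- rep_len(n_shown, n)
  blue <- stats::rbinom(n, n_shown, truth / 100)
  round_half_up(100 * blue / n_shown)
}

#' Sample a peer estimate at the task's controlled distance
#'
#' Standard (non-filler) trials: an integer distance of 15-18 slider points
#' from the first estimate, in the direction of the truth where possible;
#' if stepping toward the truth would leave the 0-100 scale, the direction
#' is flipped so the distance constraint is preserved.
#'
#' @param e1 First estimate (0-100). Vectorized.
#' @param truth True percentage (0-100). Vectorized.
#' @return Integer peer estimates with `15 <= |P - e1| <= 18`.
#' @export
sample_peer <- function(e1, truth) {
  n <- max(length(e1), length(truth))
  e1 <- rep_len(e1, n)
  truth <- rep_len(truth, n)
  d <- sample(15:18, n, replace = TRUE)
  dir <- sign(truth - e1)
  tie <- dir == 0
  if (any(tie)) dir[tie] <- sample(c(-1, 1), sum(tie), replace = TRUE)
  p <- e1 + dir * d
  flip <- p < 0 | p > 100
  p[flip] <- e1[flip] - dir[flip] * d[flip]
  p
}

#' Sample a filler-trial peer estimate
#'
#' Filler trials place the peer either very close (distance < 3) or very far
#' (distance > 40) from the first estimate, each with probability one half;
#' the estimate is drawn uniformly from all slider values satisfying the
#' chosen constraint.
#'
#' @param e1 First estimate (0-100). Vectorized.
#' @return Integer peer estimates with `|P - e1| < 3` or `> 40`.
#' @export
sample_peer_filler <- function(e1) {
  vapply(e1, function(x) {
    near <- stats::runif(1) < 0.5
    all_p <- 0:100
    cand <- if (near) {
      all_p[abs(all_p - x) < 3]
    } else {
      all_p[abs(all_p - x) > 40]
    }
    cand[sample.int(length(cand), 1)]
  }, numeric(1))
}

#' Sample second estimates from a model
#'
#' With probability equal to the model's stay bias the first estimate is
#' repeated; otherwise a response is drawn from the discretized beta
#' posterior (a continuous beta draw assigned to its slider bin, which is
#' distributionally identical to sampling the bin probabilities).
#'
#' @param trials Data frame with columns `e1`, `peer_estimate`, `n_shown`,
#'   `peer_confidence`.
#' @param params Named numeric vector of generating parameter values.
#' @param model A `pb_model` or model id string.
#' @return Integer second estimates on 0-100, one per row.
#' @export
sample_e2 <- function(trials, params = numeric(), model = "M3d") {
  model <- as_model(model)
  n <- nrow(trials)
  counts <- evidence_counts(trials, params, model)
  cond <- own_condition(trials$n_shown)
  stay <- stay_prob(params, model, cond, trials$peer_confidence)
  is_stay <- stats::runif(n) < stay
  x <- stats::rbeta(n, counts$e2_blue, counts$e2_red)
  e2 <- round_half_up(100 * x)
  e2[is_stay] <- round_half_up(trials$e1[is_stay])
  e2
}

#' Simulate a full cohort of task sessions
#'
#' For each participant: a fresh seeded 75-trial design
#' ([generate_design()]), generating parameters drawn from the group
#' specification, a perception-based first estimate ([sample_e1()]), a
#' constraint-satisfying peer estimate ([sample_peer()] /
#' [sample_peer_filler()]), and a model-generated second estimate
#' ([sample_e2()]). A small fraction of second estimates can be dropped as
#' missed responses to exercise downstream exclusion rules. Fully
#' reproducible from the two seeds.
#'
#' @param group_specs List of [group_spec()] objects (default:
#'   [default_group_specs()], the 132-participant study scale).
#' @param design_seed,behavior_seed Integer seeds for the trial designs and
#'   for parameter draws / responses respectively.
#' @param n_repeats,n_filler Passed to [generate_design()].
#' @param exact_e1 If `TRUE`, first estimates report the truth noise-free.
#' @param miss_rate Probability that a trial's second estimate is missing
#'   (a missed response). Default 0.01.
#' @return A tibble with one row per trial and columns `participant_id`,
#'   `group`, `run`, `trial_index`, `n_shown`, `truth`, `e1`,
#'   `peer_confidence`, `peer_estimate`, `e2`, `is_filler`. The generating
#'   parameters are attached as `attr(result, "ground_truth")` (a tibble,
#'   one row per participant) and the seeds as `attr(result, "seeds")`.
#' @examples
#' cohort <- simulate_cohort(
#'   list(group_spec("adult", 2, "M3d", group_median_params("adult"))),
#'   design_seed = 1, behavior_seed = 2
#' )
#' dplyr::count(cohort, participant_id)
#' @export
simulate_cohort <- function(group_specs = default_group_specs(),
                            design_seed, behavior_seed,
                            n_repeats = 2, n_filler = 15,
                            exact_e1 = FALSE, miss_rate = 0.01) {
  stopifnot(is.list(group_specs), length(group_specs) >= 1)
  if (inherits(group_specs, "pb_group_spec")) group_specs <- list(group_specs)
  for (gs in group_specs) stopifnot(inherits(gs, "pb_group_spec"))
  stopifnot(miss_rate >= 0, miss_rate < 1)
  n_total <- sum(vapply(group_specs, `[[`, integer(1), "n_participants"))
  part_design_seeds <- withr::with_seed(
    as.integer(design_seed),
    sample.int(.Machine$integer.max, n_total)
  )
  rows <- vector("list", n_total)
  truth_rows <- vector("list", n_total)
  withr::with_seed(as.integer(behavior_seed), {
    idx <- 0
    for (gs in group_specs) {
      for (i in seq_len(gs$n_participants)) {
        idx <- idx + 1
        pid <- sprintf("%s_%03d", gs$group, i)
        pars <- draw_params(gs)
        design <- generate_design(part_design_seeds[idx],
                                  n_repeats = n_repeats,
                                  n_filler = n_filler)
        e1 <- sample_e1(design$truth, design$n_shown, exact = exact_e1)
        peer <- numeric(nrow(design))
        peer[!design$is_filler] <- sample_peer(e1[!design$is_filler],
                                               design$truth[!design$is_filler])
        if (any(design$is_filler)) {
          peer[design$is_filler] <- sample_peer_filler(e1[design$is_filler])
        }
        trials <- design
        trials$e1 <- e1
        trials$peer_estimate <- peer
        e2 <- sample_e2(trials, pars, gs$model)
        if (miss_rate > 0) {
          e2[stats::runif(nrow(trials)) < miss_rate] <- NA_real_
        }
        rows[[idx]] <- tibble::tibble(
          participant_id = pid, group = gs$group,
          run = design$run, trial_index = design$trial_index,
          n_shown = design$n_shown, truth = design$truth,
          e1 = e1, peer_confidence = design$peer_confidence,
          peer_estimate = peer, e2 = e2, is_filler = design$is_filler
        )
        truth_rows[[idx]] <- tibble::tibble(
          participant_id = pid, group = gs$group,
          model_id = gs$model$model_id,
          !!!as.list(pars)
        )
      }
    }
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "ground_truth") <- dplyr::bind_rows(truth_rows)
  attr(out, "seeds") <- list(design_seed = design_seed,
                             behavior_seed = behavior_seed)
  out
}
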