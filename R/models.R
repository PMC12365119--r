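#' Model specifications for the evidence-fusion family
#'
#' The package implements ten nested models of how a first estimate (E1) is
#' revised into a second estimate (E2) after seeing a peer estimate (P) and
#' the peer's confidence rating. All models represent beliefs as beta
#' pseudo-counts: personal evidence contributes `1 + (E1/100) * N_perceived`
#' blue and `1 + (1 - E1/100) * N_perceived` red pseudo-counts (a flat prior
#' of one mushroom of each colour), the peer contributes
#' `(P/100) * N_peer` and `(1 - P/100) * N_peer`, and the posterior over the
#' 101 slider responses is the beta density with the summed counts,
#' discretized into bins of width 0.01. The models differ in how `N_perceived`
#' and `N_peer` are modulated and whether a stay-bias point mass at E1 is
#' mixed in:
#'
#' * `M0`: no free parameters; `N_perceived = N` (mushrooms shown),
#'   `N_peer = 25`.
#' * `M1a`: `N_perceived = N * alpha`.
#' * `M1b`: separate `alpha_uncertain` (N = 5) and `alpha_certain` (N = 45).
#' * `M2a`: M1b plus `N_peer = theta`.
#' * `M2b`: M1b plus `N_peer = theta_ic + theta_slope * (confidence - 1)`.
#' * `M2c`: M1b plus one `theta` per peer-confidence level.
#' * `M3a`: M2b plus a constant stay bias `beta`.
#' * `M3b`: M2b plus `beta_uncertain` / `beta_certain`.
#' * `M3c`: M2b plus stay bias `beta / confidence`.
#' * `M3d`: M2b plus stay bias `beta ^ confidence`.
#'
#' @param model_id One of `"M0"`, `"M1a"`, `"M1b"`, `"M2a"`, `"M2b"`, `"M2c"`,
#'   `"M3a"`, `"M3b"`, `"M3c"`, `"M3d"`.
#' @return A list of class `pb_model` with elements `model_id`, `description`,
#'   `parameters` (ordered character vector), `lower`, `upper` (named bounds)
#'   and `k` (number of free parameters).
#' @examples
#' model_spec("M3d")
#' @export
model_spec <- function(model_id) {
  model_id <- match.arg(model_id, pb_model_ids())
  b_alpha <- c(0.1, 100)
  b_theta <- c(0.1, 1000)
  b_theta_lin <- c(0.1, 500)
  b_beta <- c(0.01, 0.99)
  par_tbl <- switch(model_id,
    M0  = list(),
    M1a = list(alpha = b_alpha),
    M1b = list(alpha_uncertain = b_alpha, alpha_certain = b_alpha),
    M2a = list(alpha_uncertain = b_alpha, alpha_certain = b_alpha,
               theta = b_theta),
    M2b = list(alpha_uncertain = b_alpha, alpha_certain = b_alpha,
               theta_ic = b_theta_lin, theta_slope = b_theta_lin),
    M2c = list(alpha_uncertain = b_alpha, alpha_certain = b_alpha,
               theta_low = b_theta, theta_medium = b_theta,
               theta_high = b_theta),
    M3a = list(alpha_uncertain = b_alpha, alpha_certain = b_alpha,
               theta_ic = b_theta_lin, theta_slope = b_theta_lin,
               beta = b_beta),
    M3b = list(alpha_uncertain = b_alpha, alpha_certain = b_alpha,
               theta_ic = b_theta_lin, theta_slope = b_theta_lin,
               beta_uncertain = b_beta, beta_certain = b_beta),
    M3c = list(alpha_uncertain = b_alpha, alpha_certain = b_alpha,
               theta_ic = b_theta_lin, theta_slope = b_theta_lin,
               beta = b_beta),
    M3d = list(alpha_uncertain = b_alpha, alpha_certain = b_alpha,
               theta_ic = b_theta_lin, theta_slope = b_theta_lin,
               beta = b_beta)
  )
  desc <- c(
    M0  = "Base model",
    M1a = "M0 + modulation of the weight of E1",
    M1b = "M0 + modulation of the weight of E1, per own certainty condition",
    M2a = "M1b + modulation of the weight of the peer estimate",
    M2b = "M1b + peer weight linearly dependent on peer confidence",
    M2c = "M1b + peer weight per peer confidence level",
    M3a = "M2b + overall stay bias",
    M3b = "M2b + stay bias per own certainty condition",
    M3c = "M2b + stay bias linearly dependent on peer confidence",
    M3d = "M2b + stay bias exponentially dependent on peer confidence"
  )[[model_id]]
  structure(
    list(
      model_id = model_id,
      description = desc,
      parameters = names(par_tbl),
      lower = vapply(par_tbl, `[`, numeric(1), 1),
      upper = vapply(par_tbl, `[`, numeric(1), 2),
      k = length(par_tbl)
    ),
    class = "pb_model"
  )
}

#' All model identifiers
#'
#' @param parameterized If `TRUE`, drop the parameter-free base model `M0`
#'   (the nine models used in recovery simulations).
#' @return Character vector of model ids in nesting order.
#' @export
pb_model_ids <- function(parameterized = FALSE) {
  ids <- c("M0", "M1a", "M1b", "M2a", "M2b", "M2c", "M3a", "M3b", "M3c", "M3d")
  if (parameterized) ids[-1] else ids
}

#' @export
print.pb_model <- function(x, ...) {
  cat("<pb_model> ", x$model_id, ": ", x$description, "\n", sep = "")
  if (x$k == 0) {
    cat("  no free parameters\n")
  } else {
    for (p in x$parameters) {
      cat(sprintf("  %-16s in [%g, %g]\n", p, x$lower[[p]], x$upper[[p]]))
    }
  }
  invisible(x)
}

#' Serialize / deserialize a model specification
#'
#' @param model A `pb_model` object.
#' @return `model_to_json()` returns a JSON string; `model_from_json()` the
#'   corresponding `pb_model`.
#' @export
model_to_json <- function(model) {
  stopifnot(inherits(model, "pb_model"))
  jsonlite::toJSON(
    list(model_id = model$model_id, parameters = model$parameters,
         lower = model$lower, upper = model$upper),
    auto_unbox = TRUE, digits = NA
  )
}

#' @rdname model_to_json
#' @param json A JSON string produced by `model_to_json()`.
#' @export
model_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  spec <- model_spec(x$model_id)
  # bounds are constants of the family; the id fully determines the spec
  spec
}

as_model <- function(model) {
  if (inherits(model, "pb_model")) model else model_spec(model)
}

check_params <- function(params, model, subset = NULL) {
  model <- as_model(model)
  need <- if (is.null(subset)) model$parameters else {
    intersect(model$parameters, subset)
  }
  missing <- setdiff(need, names(params))
  if (length(missing) > 0) {
    stop("model ", model$model_id, " requires parameter(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(params)
}

# uncertain condition = few-mushroom trials (N = 5); certain = N = 45
own_condition <- function(n_shown) {
  ifelse(n_shown <= 25, "uncertain", "certain")
}

#' Perceived number of mushrooms underlying the first estimate
#'
#' The subjective evidence mass behind E1. The base model takes the shown
#' count at face value; M1a scales it by a single `alpha`; M1b and all richer
#' models scale it by `alpha_uncertain` or `alpha_certain` depending on the
#' own-certainty condition (5 vs 45 mushrooms shown).
#'
#' @param n_shown Total mushrooms shown (5 or 45). Vectorized.
#' @param params Named numeric vector/list of parameter values.
#' @param model A `pb_model` or model id string.
#' @param condition `"uncertain"` or `"certain"`; defaults to the condition
#'   implied by `n_shown`.
#' @return Numeric vector of perceived totals.
#' @examples
#' n_perceived(45, c(), "M0")
#' n_perceived(5, c(alpha = 2), "M1a")
#' @export
n_perceived <- function(n_shown, params = numeric(), model = "M0",
                        condition = own_condition(n_shown)) {
  model <- as_model(model)
  check_params(params, model,
               c("alpha", "alpha_uncertain", "alpha_certain"))
  params <- as.list(params)
  switch(model$model_id,
    M0 = n_shown + numeric(length(n_shown)),
    M1a = n_shown * params$alpha,
    n_shown * ifelse(condition == "uncertain",
                     params$alpha_uncertain, params$alpha_certain)
  )
}

#' Assumed number of mushrooms seen by the peer
#'
#' The evidence mass attributed to the peer estimate. Fixed at 25 in
#' M0/M1a/M1b (the across-trial average of the participant's own totals), a
#' free `theta` in M2a, linear in confidence (`theta_ic + theta_slope *
#' (confidence - 1)`) in M2b and all M3 models, and one `theta` per
#' confidence level in M2c.
#'
#' @param params Named numeric vector/list of parameter values.
#' @param model A `pb_model` or model id string.
#' @param confidence Peer confidence level, integer in 1..3 (low/medium/high).
#'   Vectorized.
#' @return Numeric vector of assumed peer totals.
#' @examples
#' n_peer(c(), "M0", 2)
#' n_peer(c(theta_ic = 54.8, theta_slope = 79), "M2b", 1:3)
#' @export
n_peer <- function(params = numeric(), model = "M0", confidence) {
  model <- as_model(model)
  check_params(params, model,
               c("theta", "theta_ic", "theta_slope",
                 "theta_low", "theta_medium", "theta_high"))
  if (!all(confidence %in% 1:3)) {
    stop("peer confidence must be 1, 2 or 3", call. = FALSE)
  }
  params <- as.list(params)
  switch(model$model_id,
    M0 = , M1a = , M1b = rep(25, length(confidence)),
    M2a = rep(params$theta, length(confidence)),
    M2c = c(params$theta_low, params$theta_medium,
            params$theta_high)[confidence],
    params$theta_ic + params$theta_slope * (confidence - 1)
  )
}

#' Stay-bias probability
#'
#' The probability of repeating the first estimate without processing the
#' peer input. Zero for models without a stay bias; `beta` in M3a; per
#' own-certainty condition in M3b; decaying linearly (`beta / confidence`,
#' M3c) or exponentially (`beta ^ confidence`, M3d) with peer confidence.
#'
#' @inheritParams n_peer
#' @param condition `"uncertain"` or `"certain"`. Vectorized.
#' @return Numeric vector of probabilities in `[0, 1)`.
#' @examples
#' stay_prob(c(beta = 0.5), "M3d", condition = "uncertain", confidence = 2)
#' @export
stay_prob <- function(params = numeric(), model = "M0",
                      condition = "uncertain", confidence = 1) {
  model <- as_model(model)
  n <- max(length(condition), length(confidence))
  if (!model$model_id %in% c("M3a", "M3b", "M3c", "M3d")) {
    return(numeric(n))
  }
  check_params(params, model,
               c("beta", "beta_uncertain", "beta_certain"))
  params <- as.list(params)
  switch(model$model_id,
    M3a = rep(params$beta, n),
    M3b = ifelse(rep_len(condition, n) == "uncertain",
                 params$beta_uncertain, params$beta_certain),
    M3c = params$beta / rep_len(confidence, n),
    M3d = params$beta ^ rep_len(confidence, n)
  )
}

#' Pseudo-count representation of a trial's evidence
#'
#' Converts slider estimates into beta pseudo-counts: the prior contributes
#' one blue and one red mushroom, E1 is spread over `n_perceived` mushrooms,
#' and the peer estimate over `n_peer`. The posterior counts are the sums.
#'
#' @param trials Data frame with columns `e1`, `peer_estimate`, `n_shown`,
#'   `peer_confidence` (one row per trial).
#' @param params Named numeric vector/list of parameter values.
#' @param model A `pb_model` or model id string.
#' @return A tibble with one row per trial: `e1_blue`, `e1_red`, `p_blue`,
#'   `p_red`, `e2_blue`, `e2_red`, `n_perceived`, `n_peer`.
#' @examples
#' evidence_counts(
#'   tibble::tibble(e1 = 20, peer_estimate = 60, n_shown = 45,
#'                  peer_confidence = 2),
#'   model = "M0"
#' )
#' @export
evidence_counts <- function(trials, params = numeric(), model = "M0") {
  model <- as_model(model)
  stopifnot(all(c("e1", "peer_estimate", "n_shown", "peer_confidence")
                %in% names(trials)))
  cond <- own_condition(trials$n_shown)
  npc <- n_perceived(trials$n_shown, params, model, cond)
  npr <- n_peer(params, model, trials$peer_confidence)
  e1_blue <- 1 + trials$e1 / 100 * npc
  e1_red <- 1 + (1 - trials$e1 / 100) * npc
  p_blue <- trials$peer_estimate / 100 * npr
  p_red <- (1 - trials$peer_estimate / 100) * npr
  tibble::tibble(
    e1_blue = e1_blue, e1_red = e1_red,
    p_blue = p_blue, p_red = p_red,
    e2_blue = e1_blue + p_blue, e2_red = e1_red + p_red,
    n_perceived = npc, n_peer = npr
  )
}

# Bin edges on the belief scale [0, 1] for slider response j in 0..100:
# [(j - 0.5)/100, (j + 0.5)/100) intersected with [0, 1].
bin_lower <- function(j) pmax((j - 0.5) / 100, 0)
bin_upper <- function(j) pmin((j + 0.5) / 100, 1)

# round() in R is half-even; slider responses use the conventional half-up.
round_half_up <- function(x) floor(x + 0.5)

#' Discretized mixture distribution over slider responses
#'
#' The beta posterior density is integrated over bins of width 0.01 centered
#' on the 101 slider values (half-width bins at 0 and 100), scaled by
#' `1 - stay`, and a point mass of `stay` is placed on the bin of the first
#' estimate. The probability of observing response `r` is
#' `bin_probs[r] + stay_mass * (r == e1_bin)`.
#'
#' @param e2_blue,e2_red Posterior beta shape parameters (pseudo-counts),
#'   both positive.
#' @param stay Stay-bias probability in `[0, 1)`.
#' @param e1 First estimate (0-100); its rounded value is the stay response.
#' @return A list of class `pb_response_model` with `bin_probs` (length 101),
#'   `stay_mass` and `e1_bin`.
#' @examples
#' rm <- response_model(1, 1, stay = 0.5, e1 = 50)
#' rm$stay_mass + sum(rm$bin_probs)  # 1
#' @export
response_model <- function(e2_blue, e2_red, stay = 0, e1 = 50) {
  if (e2_blue <= 0 || e2_red <= 0) {
    stop("beta shape parameters must be positive", call. = FALSE)
  }
  stopifnot(stay >= 0, stay < 1)
  j <- 0:100
  cdf <- stats::pbeta(c(0, bin_upper(j)), e2_blue, e2_red)
  probs <- (1 - stay) * diff(cdf)
  structure(
    list(bin_probs = probs, stay_mass = stay,
         e1_bin = round_half_up(e1)),
    class = "pb_response_model"
  )
}

#' @export
print.pb_response_model <- function(x, ...) {
  cat("<pb_response_model> stay mass", format(x$stay_mass),
      "at response", x$e1_bin, "\n")
  cat("  beta mass", format(sum(x$bin_probs)),
      "| mode bin", which.max(x$bin_probs) - 1, "\n")
  invisible(x)
}

# Vectorized response probability for observed responses e2 (slider units).
# Shapes a, b, stay and e1 recycled to the length of e2.
response_prob <- function(a, b, stay, e1, e2) {
  e1b <- round_half_up(e1)
  e2b <- round_half_up(e2)
  beta_mass <- stats::pbeta(bin_upper(e2b), a, b) -
    stats::pbeta(bin_lower(e2b), a, b)
  (1 - stay) * beta_mass + stay * (e2b == e1b)
}

#' Trial-level log-likelihood and participant-level objective
#'
#' `trial_loglik()` returns the log-probability of each observed second
#' estimate under the model's discretized mixture distribution, floored at
#' `log(1e-12)` so the fitting objective stays finite.
#' `participant_negll()` is the negative sum over a participant's included
#' trials — the quantity minimized during fitting.
#'
#' @param trials Data frame with columns `e1`, `e2`, `peer_estimate`,
#'   `n_shown`, `peer_confidence`. Rows with an `included` column set to
#'   `FALSE` are ignored by `participant_negll()`.
#' @param params Named numeric vector/list of parameter values.
#' @param model A `pb_model` or model id string.
#' @return `trial_loglik()`: numeric vector (one value per row);
#'   `participant_negll()`: a single number.
#' @export
trial_loglik <- function(trials, params = numeric(), model = "M0") {
  model <- as_model(model)
  counts <- evidence_counts(trials, params, model)
  cond <- own_condition(trials$n_shown)
  stay <- stay_prob(params, model, cond, trials$peer_confidence)
  p <- response_prob(counts$e2_blue, counts$e2_red, stay,
                     trials$e1, trials$e2)
  log(pmax(p, 1e-12))
}

#' @rdname trial_loglik
#' @export
participant_negll <- function(trials, params = numeric(), model = "M0") {
  if ("included" %in% names(trials)) {
    trials <- trials[trials$included, , drop = FALSE]
  }
  if (nrow(trials) == 0) {
    stop("participant has no included trials", call. = FALSE)
  }
  if (any(is.na(trials$e2))) {
    stop("included trials must have a second estimate", call. = FALSE)
  }
  -sum(trial_loglik(trials, params, model))
}

# Fast closure for optimization: pre-extracts trial vectors once, then
# evaluates the negative log-likelihood for a parameter vector in model order.
make_negll <- function(trials, model) {
  model <- as_model(model)
  if ("included" %in% names(trials)) {
    trials <- trials[trials$included, , drop = FALSE]
  }
  stopifnot(nrow(trials) > 0, !any(is.na(trials$e2)))
  e1 <- trials$e1
  e2 <- trials$e2
  p <- trials$peer_estimate
  n_shown <- trials$n_shown
  conf <- trials$peer_confidence
  uncertain <- own_condition(n_shown) == "uncertain"
  e1b <- round_half_up(e1)
  e2b <- round_half_up(e2)
  is_stay_resp <- e2b == e1b
  lo <- bin_lower(e2b)
  hi <- bin_upper(e2b)
  id <- model$model_id
  pn <- model$parameters
  function(par) {
    par <- as.list(stats::setNames(par, pn))
    npc <- switch(id,
      M0 = n_shown,
      M1a = n_shown * par$alpha,
      n_shown * ifelse(uncertain, par$alpha_uncertain, par$alpha_certain)
    )
    npr <- switch(id,
      M0 = , M1a = , M1b = 25,
      M2a = par$theta,
      M2c = c(par$theta_low, par$theta_medium, par$theta_high)[conf],
      par$theta_ic + par$theta_slope * (conf - 1)
    )
    stay <- switch(id,
      M3a = par$beta,
      M3b = ifelse(uncertain, par$beta_uncertain, par$beta_certain),
      M3c = par$beta / conf,
      M3d = par$beta ^ conf,
      0
    )
    a <- 1 + e1 / 100 * npc + p / 100 * npr
    b <- 1 + (1 - e1 / 100) * npc + (1 - p / 100) * npr
    pr <- (1 - stay) * (stats::pbeta(hi, a, b) - stats::pbeta(lo, a, b)) +
      stay * is_stay_resp
    -sum(log(pmax(pr, 1e-12)))
  }
}
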