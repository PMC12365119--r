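#' Social information use
#'
#' The fraction of the distance from the first estimate toward the peer
#' estimate that the second estimate covers:
#' `s = (e2 - e1) / (p - e1)`. A value of 0 means the peer was ignored, 1
#' means the peer was copied, values below 0 mean adjustment away from the
#' peer, and values above 1 over-adjustment beyond the peer.
#'
#' When `p == e1` the denominator vanishes and `s` is undefined; those
#' elements are returned as `NA` with a warning so callers can mark the
#' trial unusable.
#'
#' @param e1,e2 First and second estimates (0-100). Vectorized.
#' @param p Peer estimate (0-100). Vectorized.
#' @return Numeric vector of `s` values.
#' @examples
#' social_info_use(40, 48, 56)  # 0.5
#' @export
social_info_use <- function(e1, e2, p) {
  undef <- !is.na(p) & !is.na(e1) & p == e1
  if (any(undef)) {
    warning("social information use undefined where peer estimate equals ",
            "the first estimate; returning NA", call. = FALSE)
  }
  out <- (e2 - e1) / (p - e1)
  out[undef] <- NA_real_
  out
}

#' Deviance of the first estimate from the truth
#'
#' Absolute difference between the first estimate and the true percentage of
#' blue mushrooms; the task's performance index.
#'
#' @param e1 First estimate (0-100). Vectorized.
#' @param truth True percentage (0-100). Vectorized.
#' @return Nonnegative numeric vector.
#' @export
deviance_from_truth <- function(e1, truth) {
  stopifnot(all(e1 >= 0 & e1 <= 100, na.rm = TRUE),
            all(truth >= 0 & truth <= 100, na.rm = TRUE))
  abs(e1 - truth)
}

#' Exclusion-rule configuration
#'
#' @param sd_threshold Trials whose first or second estimate deviates more
#'   than this many standard deviations from the mean of their
#'   (own certainty x truth level x group) cell are dropped. Default 3.
#' @param stay_fraction_threshold Participants whose fraction of `s == 0`
#'   among their remaining trials strictly exceeds this are dropped entirely.
#'   Default 0.70.
#' @param require_s_in_unit_interval Drop trials with `s` outside `[0, 1]`
#'   (i.e. the second estimate is not a weighted average of the first and
#'   the peer estimate). Default `TRUE`.
#' @return A list of class `pb_exclusion_config`.
#' @export
exclusion_config <- function(sd_threshold = 3,
                             stay_fraction_threshold = 0.70,
                             require_s_in_unit_interval = TRUE) {
  stopifnot(sd_threshold > 0,
            stay_fraction_threshold > 0, stay_fraction_threshold <= 1)
  structure(
    list(sd_threshold = sd_threshold,
         stay_fraction_threshold = stay_fraction_threshold,
         require_s_in_unit_interval = require_s_in_unit_interval),
    class = "pb_exclusion_config"
  )
}

#' Apply the trial and participant exclusion rules
#'
#' Flags trials in this order: (1) filler trials; (2) missed trials (missing
#' first or second estimate); (3) trials where the peer estimate equals the
#' first estimate, leaving `s` undefined; (4) trials whose first or second
#' estimate lies more than `sd_threshold` standard deviations from the mean
#' of its (own certainty x truth x group) cell, with cell statistics computed
#' over all trials surviving rules 1-3; (5) trials with `s` outside `[0, 1]`;
#' (6) whole participants whose fraction of `s == 0` among their remaining
#' trials strictly exceeds `stay_fraction_threshold`. Trial-level rules run
#' before the participant-level rule so the stay-fraction criterion is
#' evaluated on analysable trials.
#'
#' The input rows are returned unchanged and in order, with three columns
#' (re)computed from the raw data: `s`, `included` and `exclusion_reason`
#' (`NA` for included trials). Because flags are always derived afresh from
#' the raw columns, applying the function twice gives the same result as
#' applying it once. `attr(result, "exclusion_log")` is a tibble of every
#' drop with its reason (participant-level drops have `trial_index = NA`).
#'
#' @param data Trial-level data frame with columns `participant_id`, `group`,
#'   `n_shown`, `truth`, `e1`, `peer_estimate`, `e2`, `is_filler`.
#' @param config An [exclusion_config()].
#' @return The input as a tibble with `s`, `included`, `exclusion_reason`
#'   columns and an `exclusion_log` attribute.
#' @export
apply_exclusions <- function(data, config = exclusion_config()) {
  stopifnot(inherits(config, "pb_exclusion_config"))
  data <- tibble::as_tibble(data)
  need <- c("participant_id", "group", "n_shown", "truth", "e1",
            "peer_estimate", "e2", "is_filler")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(data)
  reason <- rep(NA_character_, n)
  s <- rep(NA_real_, n)
  if (n > 0) {
    defined <- !is.na(data$e1) & !is.na(data$peer_estimate) &
      data$peer_estimate != data$e1 & !is.na(data$e2)
    s[defined] <- (data$e2[defined] - data$e1[defined]) /
      (data$peer_estimate[defined] - data$e1[defined])

    reason[data$is_filler] <- "filler"
    missed <- is.na(reason) & (is.na(data$e1) | is.na(data$e2))
    reason[missed] <- "missed"
    undef <- is.na(reason) & !is.na(data$peer_estimate) &
      data$peer_estimate == data$e1
    reason[undef] <- "undefined_s"

    # SD rule: cell statistics over trials surviving rules 1-3
    alive <- is.na(reason)
    cell <- interaction(own_condition(data$n_shown), data$truth, data$group,
                        drop = TRUE)
    out_by_sd <- function(x) {
      m <- stats::ave(ifelse(alive, x, NA), cell,
                      FUN = function(v) mean(v, na.rm = TRUE))
      sd_ <- stats::ave(ifelse(alive, x, NA), cell,
                        FUN = function(v) stats::sd(v, na.rm = TRUE))
      alive & !is.na(sd_) & sd_ > 0 & abs(x - m) > config$sd_threshold * sd_
    }
    sd_out <- out_by_sd(data$e1) | out_by_sd(data$e2)
    reason[sd_out] <- "sd_outlier"

    if (config$require_s_in_unit_interval) {
      s_out <- is.na(reason) & (s < 0 | s > 1)
      reason[s_out] <- "s_outside_unit_interval"
    }

    # participant-level stay-fraction rule on the remaining trials
    alive <- is.na(reason)
    frac0 <- tapply(s[alive] == 0, data$participant_id[alive], mean)
    bad_ids <- names(frac0)[!is.na(frac0) &
                              frac0 > config$stay_fraction_threshold]
    drop_p <- alive & data$participant_id %in% bad_ids
    reason[drop_p] <- "stay_fraction"
  }
  data$s <- s
  data$included <- is.na(reason)
  data$exclusion_reason <- reason

  log <- tibble::tibble(
    participant_id = data$participant_id[!data$included],
    trial_index = if ("trial_index" %in% names(data)) {
      data$trial_index[!data$included]
    } else {
      which(!data$included) - 1L
    },
    reason = reason[!data$included]
  )
  if (n > 0 && any(reason %in% "stay_fraction")) {
    plog <- tibble::tibble(
      participant_id = unique(data$participant_id[reason %in% "stay_fraction"]),
      trial_index = NA_integer_,
      reason = "participant_stay_fraction"
    )
    log <- dplyr::bind_rows(log, plog)
  }
  attr(data, "exclusion_log") <- log
  data
}

#' Keep only the analysable trials
#'
#' Convenience filter for the output of [apply_exclusions()].
#'
#' @param data Output of [apply_exclusions()].
#' @return Tibble of included rows.
#' @export
included_trials <- function(data) {
  stopifnot("included" %in% names(data))
  dplyr::filter(data, .data$included)
}

#' Task-understanding diagnostic
#'
#' Per-participant Pearson correlation between the first estimate and the
#' true percentage over non-filler trials. Participants who understood the
#' task track the truth closely; a low or negative correlation flags a
#' participant for manual review. This is a report, never an automatic
#' exclusion.
#'
#' @param data Trial-level data frame.
#' @return Tibble with `participant_id`, `group`, `r_e1_truth`, `n_trials`.
#' @export
understanding_diagnostic <- function(data) {
  data |>
    dplyr::filter(!.data$is_filler, !is.na(.data$e1)) |>
    dplyr::group_by(.data$participant_id, .data$group) |>
    dplyr::summarise(
      r_e1_truth = if (dplyr::n() >= 3 && stats::sd(.data$e1) > 0 &&
                         stats::sd(.data$truth) > 0) {
        stats::cor(.data$e1, .data$truth)
      } else {
        NA_real_
      },
      n_trials = dplyr::n(),
      .groups = "drop"
    )
}

#' Condition-level summary of social information use
#'
#' Averages `s` within participant for each (own certainty x peer confidence)
#' cell, then summarises across participants within group: mean, standard
#' error and number of contributing participants. Cells with no data are
#' absent from the table (reported as missing, never as zero). The overall
#' mean of the per-participant means is attached as
#' `attr(result, "overall_mean_s")`.
#'
#' @param data Output of [apply_exclusions()] (only included trials are
#'   used).
#' @return A tibble of class `pb_condition_summary` with columns `group`,
#'   `certainty`, `peer_confidence`, `mean_s`, `se_s`, `n`.
#' @export
summarize_conditions <- function(data) {
  stopifnot("included" %in% names(data), "s" %in% names(data))
  per_part <- data |>
    included_trials() |>
    dplyr::mutate(certainty = own_condition(.data$n_shown)) |>
    dplyr::group_by(.data$group, .data$participant_id, .data$certainty,
                    .data$peer_confidence) |>
    dplyr::summarise(mean_s = mean(.data$s), .groups = "drop")
  out <- per_part |>
    dplyr::group_by(.data$group, .data$certainty, .data$peer_confidence) |>
    dplyr::summarise(
      se_s = stats::sd(.data$mean_s) / sqrt(dplyr::n()),
      mean_s = mean(.data$mean_s),
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::select("group", "certainty", "peer_confidence", "mean_s",
                  "se_s", "n")
  overall <- data |>
    included_trials() |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(m = mean(.data$s), .groups = "drop")
  attr(out, "overall_mean_s") <- mean(overall$m)
  class(out) <- c("pb_condition_summary", class(out))
  out
}

#' Nonparametric group comparison of a fitted parameter or metric
#'
#' Two-sided Mann-Whitney U test via [stats::wilcox.test()]. The reported
#' statistic is the U (W) count for the first group. Exact p-values are used
#' for small samples without ties; with ties, midranks and the normal
#' approximation with continuity correction are used (the standard
#' treatment).
#'
#' @param values_a,values_b Numeric vectors (e.g. one parameter's fitted
#'   values per group).
#' @return One-row tibble with `statistic` (U for group a), `p.value`,
#'   `n_a`, `n_b`, `method`.
#' @examples
#' compare_groups(c(1, 2, 3), c(4, 5, 6))
#' @export
compare_groups <- function(values_a, values_b) {
  stopifnot(length(values_a) > 0, length(values_b) > 0)
  w <- suppressWarnings(
    stats::wilcox.test(values_a, values_b, alternative = "two.sided")
  )
  tibble::tibble(
    statistic = unname(w$statistic),
    p.value = w$p.value,
    n_a = length(values_a),
    n_b = length(values_b),
    method = w$method
  )
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Thin wrapper over [stats::p.adjust()] with `method = "BH"`; adjusted
#' values are never smaller than the raw ones and never exceed 1.
#'
#' @param pvals Numeric vector of p-values.
#' @return Numeric vector of FDR-adjusted p-values.
#' @export
adjust_bh <- function(pvals) {
  stats::p.adjust(pvals, method = "BH")
}
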