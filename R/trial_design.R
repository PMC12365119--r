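#' Generate the factorial trial design of the estimation task
#'
#' Builds one session of the mushroom estimation task: a factorial block of
#' 2 own-certainty conditions (5 vs 45 mushrooms shown) x 3 peer-confidence
#' levels x 5 true percentages (12.5, 25, 37.5, 62.5, 75), each cell repeated
#' `n_repeats` times, plus `n_filler` filler trials whose true percentage is
#' a uniform integer on 0-100 (filler peer estimates are constrained later,
#' at sampling time, to be very close or very far from the first estimate).
#' Trials are shuffled with the given seed and split contiguously into three
#' runs of (near-)equal size.
#'
#' @param seed Integer seed; the same seed always yields the same design.
#' @param n_repeats Repeats per factorial cell (default 2, giving the 60
#'   analysable trials of a standard session).
#' @param n_filler Number of filler trials (default 15).
#' @return A tibble with one row per trial and columns `trial_index` (0-based,
#'   in presentation order), `run` (1-3), `n_shown`, `truth`,
#'   `peer_confidence`, `is_filler`.
#' @examples
#' design <- generate_design(seed = 1)
#' nrow(design)        # 75
#' sum(!design$is_filler)  # 60
#' @export
generate_design <- function(seed, n_repeats = 2, n_filler = 15) {
  stopifnot(
    length(seed) == 1, is.finite(seed), seed == as.integer(seed),
    length(n_repeats) == 1, n_repeats == as.integer(n_repeats),
    n_repeats >= 1,
    length(n_filler) == 1, n_filler == as.integer(n_filler), n_filler >= 0
  )
  factorial <- tidyr::expand_grid(
    n_shown = c(5L, 45L),
    peer_confidence = 1:3,
    truth = c(12.5, 25, 37.5, 62.5, 75),
    rep = seq_len(n_repeats)
  )
  factorial$rep <- NULL
  factorial$is_filler <- FALSE
  withr::with_seed(as.integer(seed), {
    if (n_filler > 0) {
      filler <- tibble::tibble(
        n_shown = sample(c(5L, 45L), n_filler, replace = TRUE),
        peer_confidence = sample(1:3, n_filler, replace = TRUE),
        truth = as.numeric(sample(0:100, n_filler, replace = TRUE)),
        is_filler = TRUE
      )
      design <- dplyr::bind_rows(factorial, filler)
    } else {
      design <- factorial
    }
    design <- design[sample.int(nrow(design)), ]
  })
  n <- nrow(design)
  base <- n %/% 3
  run_sizes <- c(base, base, n - 2 * base)
  design$run <- rep(1:3, times = run_sizes)
  design$trial_index <- seq_len(n) - 1L
  dplyr::select(design, "trial_index", "run", "n_shown", "truth",
                "peer_confidence", "is_filler")
}
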