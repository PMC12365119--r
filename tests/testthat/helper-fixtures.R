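# Shared in-code fixtures for the test suite.

# A small simulated two-group cohort used wherever a realistic dataset is
# needed cheaply.
tiny_cohort <- function(n_per_group = 3, model = "M3d", miss_rate = 0) {
  simulate_cohort(
    list(
      group_spec("adolescent", n_per_group, model,
                 group_median_params("adolescent")),
      group_spec("adult", n_per_group, model,
                 group_median_params("adult"))
    ),
    design_seed = 101, behavior_seed = 202, miss_rate = miss_rate
  )
}

# Hand-built 30-row table exercising each exclusion rule exactly once
# (rules 1-5 at the trial level, rule 6 at the participant level).
#
# Cell layout: participants A and B share the (certain, truth 25) cell;
# participant C sits alone in the (uncertain, truth 62.5) cell.
#  - 12 normal A trials + 2 normal B trials: e1 30, peer 46, e2 38 (s = 0.5)
#  - 1 filler trial (A)
#  - 2 missed trials (A): one missing e2, one missing e1
#  - 1 undefined-s trial (A): peer == e1
#  - 1 SD outlier (A): e1 95 in a cell of e1 30 (cell mean 34.06, sd 16.25,
#    so |95 - 34.06| > 3 sd; every e1 = 30 row stays well inside)
#  - 1 out-of-unit-interval trial (A): e2 below e1, s = -0.3125
#  - 10 C trials: 8 stays (s = 0) and 2 adjustments, stay fraction 0.8 > 0.7
make_exclusion_fixture <- function() {
  normal <- function(pid, k, idx0) {
    tibble::tibble(
      participant_id = pid, group = "g", run = 1L,
      trial_index = idx0 + seq_len(k) - 1L,
      n_shown = 45L, truth = 25, e1 = 30, peer_confidence = 2L,
      peer_estimate = 46, e2 = 38, is_filler = FALSE
    )
  }
  a_normal <- normal("A", 12, 0L)
  special <- tibble::tibble(
    participant_id = "A", group = "g", run = 1L,
    trial_index = 12:17,
    n_shown = 45L,
    truth = c(40, 25, 25, 25, 25, 25),
    e1 = c(30, 30, NA, 30, 95, 30),
    peer_confidence = 2L,
    peer_estimate = c(46, 46, 46, 30, 79, 46),
    e2 = c(38, NA, 38, 30, 87, 25),
    is_filler = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)
  )
  b_normal <- normal("B", 2, 0L)
  c_trials <- tibble::tibble(
    participant_id = "C", group = "g", run = 1L,
    trial_index = 0:9,
    n_shown = 5L, truth = 62.5, e1 = 60, peer_confidence = 2L,
    peer_estimate = 76,
    e2 = c(rep(60, 8), 68, 68),
    is_filler = FALSE
  )
  dplyr::bind_rows(a_normal, special, b_normal, c_trials)
}

# Expected exclusion_reason counts for make_exclusion_fixture().
exclusion_fixture_expected <- c(
  filler = 1L, missed = 2L, undefined_s = 1L, sd_outlier = 1L,
  s_outside_unit_interval = 1L, stay_fraction = 10L
)
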