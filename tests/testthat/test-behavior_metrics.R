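test_that("social information use covers the canonical cases", {
  expect_equal(social_info_use(40, 40, 56), 0)   # no adjustment
  expect_equal(social_info_use(40, 56, 56), 1)   # full copy
  expect_equal(social_info_use(40, 48, 56), 0.5) # halfway
  expect_equal(social_info_use(40, 36, 56), -0.25)
  expect_warning(s <- social_info_use(40, 45, 40), "undefined")
  expect_true(is.na(s))
})

test_that("s is invariant to swapping the blue/red coding", {
  withr::with_seed(5, {
    e1 <- sample(0:100, 50, replace = TRUE)
    p <- (e1 + sample(15:18, 50, TRUE)) %% 101
    keep <- p != e1
    e2 <- sample(0:100, 50, replace = TRUE)
    expect_equal(social_info_use(e1[keep], e2[keep], p[keep]),
                 social_info_use(100 - e1[keep], 100 - e2[keep],
                                 100 - p[keep]))
  })
})

test_that("deviance is the absolute error of the first estimate", {
  expect_equal(deviance_from_truth(25, 25), 0)
  expect_equal(deviance_from_truth(20, 25), 5)
  expect_equal(deviance_from_truth(80, 62.5), 17.5)
  expect_error(deviance_from_truth(120, 25))
})

test_that("each exclusion rule drops exactly the intended fixture rows", {
  fixture <- make_exclusion_fixture()
  flagged <- apply_exclusions(fixture)
  expect_equal(nrow(flagged), nrow(fixture))
  got <- table(flagged$exclusion_reason)
  expect_equal(as.integer(got[names(exclusion_fixture_expected)]),
               unname(exclusion_fixture_expected))
  expect_equal(sum(flagged$included), 14)  # 12 normal A + 2 normal B
  # the SD rule caught precisely the shifted-E1 trial
  sd_row <- flagged[which(flagged$exclusion_reason == "sd_outlier"), ]
  expect_equal(sd_row$e1, 95)
  # the whole of participant C went by the stay-fraction rule
  expect_true(all(flagged$participant_id[
    flagged$exclusion_reason %in% "stay_fraction"] == "C"))
  log <- attr(flagged, "exclusion_log")
  expect_true("participant_stay_fraction" %in% log$reason)
})

test_that("a participant with over 70% stays is excluded, at 70% kept", {
  base <- make_exclusion_fixture()
  keep <- base[base$participant_id != "C", ]
  # 7 of 10 stays: fraction 0.70 is not > 0.70, participant stays in
  c_on_boundary <- base[base$participant_id == "C", ]
  c_on_boundary$e2 <- c(rep(60, 7), 68, 68, 68)
  flagged <- apply_exclusions(dplyr::bind_rows(keep, c_on_boundary))
  expect_false(any(flagged$exclusion_reason %in% "stay_fraction"))
  # 8 of 10 (0.8 > 0.7) excluded, as in the fixture itself
  flagged2 <- apply_exclusions(base)
  expect_equal(sum(flagged2$exclusion_reason %in% "stay_fraction"), 10)
})

test_that("applying the exclusion rules twice changes nothing", {
  cohort <- tiny_cohort(n_per_group = 4, miss_rate = 0.05)
  once <- apply_exclusions(cohort)
  twice <- apply_exclusions(once)
  expect_identical(
    once[c("included", "exclusion_reason", "s")],
    twice[c("included", "exclusion_reason", "s")]
  )
})

test_that("empty input yields empty flagged output and log", {
  empty <- make_exclusion_fixture()[0, ]
  flagged <- apply_exclusions(empty)
  expect_equal(nrow(flagged), 0)
  expect_equal(nrow(attr(flagged, "exclusion_log")), 0)
})

test_that("condition summaries average within participant first", {
  fixture <- apply_exclusions(make_exclusion_fixture())
  summ <- summarize_conditions(fixture)
  # all included fixture trials have s = 0.5
  expect_true(all(summ$mean_s == 0.5))
  expect_equal(attr(summ, "overall_mean_s"), 0.5)
  # a lone participant with s in {0, 1} within one cell averages to 0.5
  one <- tibble::tibble(
    participant_id = "x", group = "g", n_shown = 5, truth = 25,
    e1 = c(30, 30), peer_confidence = 1L, peer_estimate = c(46, 46),
    e2 = c(30, 46), is_filler = FALSE
  )
  s1 <- summarize_conditions(
    apply_exclusions(one, exclusion_config(stay_fraction_threshold = 1))
  )
  expect_equal(s1$mean_s, 0.5)
  expect_equal(s1$n, 1)
})

test_that("the Mann-Whitney comparison matches hand enumeration", {
  # all 9 pairwise comparisons favour b: U = 0 for group a
  res <- compare_groups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, 0)
  # exact two-sided p: 2 * P(U <= 0) = 2 / choose(6, 3)
  expect_equal(res$p.value, 2 / choose(6, 3))
  # identical groups: symmetric, p = 1
  same <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p.value, 1, tolerance = 1e-12)
})

test_that("the BH correction follows the step-up formula", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  withr::with_seed(11, {
    p <- stats::runif(20)
    adj <- adjust_bh(p)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    # monotone non-decreasing after sorting by raw p
    expect_true(all(diff(adj[order(p)]) >= 0))
  })
})

test_that("understanding diagnostic reports E1-truth tracking", {
  cohort <- tiny_cohort(n_per_group = 2)
  diag <- understanding_diagnostic(cohort)
  expect_equal(nrow(diag), 4)
  # simulated participants perceive the truth binomially: strong tracking
  expect_true(all(diag$r_e1_truth > 0.5))
})
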