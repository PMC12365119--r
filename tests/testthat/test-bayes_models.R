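test_that("perceived evidence follows the model ladder", {
  expect_equal(n_perceived(45, model = "M0"), 45)
  expect_equal(n_perceived(5, c(alpha = 2), "M1a"), 10)
  expect_equal(n_perceived(45, c(alpha_uncertain = 28.4, alpha_certain = 5.3),
                           "M1b", "certain"), 238.5)
  # vectorized over trials, condition derived from n_shown
  expect_equal(
    n_perceived(c(5, 45), c(alpha_uncertain = 2, alpha_certain = 3), "M3d"),
    c(10, 135)
  )
  expect_error(n_perceived(5, c(), "M1a"), "requires parameter")
})

test_that("assumed peer evidence follows the model ladder", {
  expect_equal(n_peer(model = "M0", confidence = 1:3), rep(25, 3))
  expect_equal(n_peer(c(theta = 80), "M2a", 2), 80)
  th <- c(theta_ic = 54.8, theta_slope = 79.0)
  expect_equal(n_peer(th, "M2b", 1), 54.8)
  expect_equal(n_peer(th, "M2b", 3), 212.8)
  expect_equal(
    n_peer(c(theta_low = 10, theta_medium = 20, theta_high = 30), "M2c", 3:1),
    c(30, 20, 10)
  )
  expect_error(n_peer(th, "M2b", 4), "confidence")
})

test_that("stay bias depends on model, condition and confidence", {
  expect_equal(stay_prob(c(beta = 0.5), "M3d", confidence = 2), 0.25)
  expect_equal(stay_prob(c(beta = 0.6), "M3c", confidence = 3), 0.2)
  expect_equal(stay_prob(model = "M2b", confidence = 2), 0)
  expect_equal(
    stay_prob(c(beta_uncertain = 0.3, beta_certain = 0.1), "M3b",
              condition = c("uncertain", "certain"), confidence = 1),
    c(0.3, 0.1)
  )
  # exponential decay: strictly decreasing in confidence for beta in (0, 1)
  for (b in c(0.05, 0.5, 0.95)) {
    sp <- stay_prob(c(beta = b), "M3d", confidence = 1:3)
    expect_true(all(diff(sp) < 0))
  }
})

test_that("pseudo-counts reproduce the worked base-model example", {
  trial <- tibble::tibble(e1 = 20, peer_estimate = 60, n_shown = 45,
                          peer_confidence = 2)
  counts <- evidence_counts(trial, model = "M0")
  expect_equal(counts$e1_blue, 10)   # 1 + 0.2 * 45
  expect_equal(counts$e1_red, 37)    # 1 + 0.8 * 45
  expect_equal(counts$p_blue, 15)    # 0.6 * 25
  expect_equal(counts$p_red, 10)
  expect_equal(counts$e2_blue, counts$e1_blue + counts$p_blue)
  expect_equal(counts$e2_red, counts$e1_red + counts$p_red)
  expect_true(counts$e1_blue >= 1 && counts$e1_red >= 1)
})

test_that("the uniform belief discretizes to flat bins with half-edges", {
  rm <- response_model(1, 1, stay = 0)
  expect_equal(rm$bin_probs[c(1, 101)], c(0.005, 0.005))
  expect_equal(rm$bin_probs[2:100], rep(0.01, 99))
  rm2 <- response_model(1, 1, stay = 0.5, e1 = 50)
  p50 <- rm2$bin_probs[51] + rm2$stay_mass
  expect_equal(p50, 0.505)
  expect_error(response_model(0, 1), "positive")
})

test_that("discretized bins match adaptive quadrature of the beta density", {
  # adaptive quadrature handles the infinite-derivative endpoints that
  # appear for shapes just above 1
  quad_bins <- function(a, b) {
    vapply(0:100, function(j) {
      lo <- max((j - 0.5) / 100, 0)
      hi <- min((j + 0.5) / 100, 1)
      stats::integrate(stats::dbeta, lo, hi, shape1 = a, shape2 = b,
                       rel.tol = 1e-10, abs.tol = 1e-12)$value
    }, numeric(1))
  }
  withr::with_seed(3, {
    for (i in 1:5) {
      a <- exp(stats::runif(1, log(1), log(400)))
      b <- exp(stats::runif(1, log(1), log(400)))
      rm <- response_model(a, b, stay = 0)
      expect_lt(max(abs(rm$bin_probs - quad_bins(a, b))), 1e-6)
    }
  })
})

test_that("the response distribution is a proper mixture", {
  withr::with_seed(8, {
    for (i in 1:50) {
      rm <- response_model(exp(stats::runif(1, 0, 6)),
                           exp(stats::runif(1, 0, 6)),
                           stay = stats::runif(1, 0, 0.95),
                           e1 = sample(0:100, 1))
      expect_equal(rm$stay_mass + sum(rm$bin_probs), 1, tolerance = 1e-9)
    }
  })
})

test_that("trial log-likelihoods agree with the response-model path", {
  cohort <- tiny_cohort(n_per_group = 1)
  trials <- apply_exclusions(cohort) |> included_trials()
  pars <- group_median_params("adult")
  for (mid in c("M0", "M2b", "M3d")) {
    p_use <- pars[model_spec(mid)$parameters]
    ll <- trial_loglik(trials, p_use, mid)
    # independent recomputation trial by trial through response_model()
    oracle <- vapply(seq_len(nrow(trials)), function(i) {
      tr <- trials[i, ]
      cnt <- evidence_counts(tr, p_use, mid)
      cond <- ifelse(tr$n_shown == 5, "uncertain", "certain")
      stay <- stay_prob(p_use, mid, cond, tr$peer_confidence)
      rm <- response_model(cnt$e2_blue, cnt$e2_red, stay, tr$e1)
      r <- round(tr$e2)
      log(max(rm$bin_probs[r + 1] +
                ifelse(r == rm$e1_bin, rm$stay_mass, 0), 1e-12))
    }, numeric(1))
    expect_equal(ll, oracle, tolerance = 1e-12)
    expect_equal(participant_negll(trials, p_use, mid), -sum(ll))
  }
})

test_that("likelihoods are floored, never -Inf", {
  # second estimate far in the tail of a concentrated posterior
  trial <- tibble::tibble(e1 = 20, e2 = 99, peer_estimate = 36,
                          n_shown = 45, peer_confidence = 3)
  pars <- c(alpha_uncertain = 50, alpha_certain = 50,
            theta_ic = 400, theta_slope = 400)
  ll <- trial_loglik(trial, pars, "M2b")
  expect_equal(ll, log(1e-12))
  expect_error(participant_negll(trial[0, ], pars, "M2b"), "no included")
})

test_that("the optimization closure matches the reference likelihood", {
  cohort <- tiny_cohort(n_per_group = 1)
  trials <- apply_exclusions(cohort) |> included_trials()
  pars <- group_median_params("adolescent")
  for (mid in c("M1a", "M2a", "M2c", "M3b", "M3c")) {
    spec <- model_spec(mid)
    pv <- switch(mid,
      M1a = c(alpha = 3),
      M2a = c(pars[c("alpha_uncertain", "alpha_certain")], theta = 60),
      M2c = c(pars[c("alpha_uncertain", "alpha_certain")],
              theta_low = 50, theta_medium = 120, theta_high = 200),
      M3b = c(pars[c("alpha_uncertain", "alpha_certain",
                     "theta_ic", "theta_slope")],
              beta_uncertain = 0.3, beta_certain = 0.1),
      M3c = pars
    )
    fn <- peerbayes:::make_negll(trials, mid)
    expect_equal(fn(unname(pv[spec$parameters])),
                 participant_negll(trials, pv, mid))
  }
})

test_that("nested models reduce exactly to their parents", {
  cohort <- tiny_cohort(n_per_group = 2)
  trials <- apply_exclusions(cohort) |> included_trials()
  ll_m0 <- trial_loglik(trials, model = "M0")
  ll_m1a <- trial_loglik(trials, c(alpha = 1), "M1a")
  expect_lt(max(abs(ll_m0 - ll_m1a)), 1e-9)
  alphas <- c(alpha_uncertain = 12, alpha_certain = 3)
  ll_m1b <- trial_loglik(trials, alphas, "M1b")
  ll_m2a <- trial_loglik(trials, c(alphas, theta = 25), "M2a")
  expect_lt(max(abs(ll_m1b - ll_m2a)), 1e-9)
  # the stay-bias mixture vanishes as beta -> 0; a stay response with
  # parent probability p gains log(1 + beta/p), so a 1e-6 agreement needs
  # p >> beta: compare on trials with p > 1e-3 (the bulk of the data)
  th <- c(alphas, theta_ic = 55, theta_slope = 80)
  ll_m2b <- trial_loglik(trials, th, "M2b")
  ll_m3a <- trial_loglik(trials, c(th, beta = 1e-9), "M3a")
  body <- ll_m2b > log(1e-3)
  expect_gt(sum(body), 0.8 * length(body))
  expect_lt(max(abs(ll_m2b[body] - ll_m3a[body])), 1e-6)
})

test_that("posterior means respond to confidence and alpha as they should", {
  trial <- tibble::tibble(e1 = 30, peer_estimate = 46, n_shown = 5,
                          peer_confidence = 1)
  th <- c(alpha_uncertain = 10, alpha_certain = 10,
          theta_ic = 55, theta_slope = 80)
  post_mean <- function(params, model, conf) {
    tr <- trial
    tr$peer_confidence <- conf
    cnt <- evidence_counts(tr, params, model)
    cnt$e2_blue / (cnt$e2_blue + cnt$e2_red)
  }
  # under M2b, rising peer confidence pulls the posterior toward P
  means <- vapply(1:3, function(cf) post_mean(th, "M2b", cf), numeric(1))
  expect_true(all(diff(means) > 0))       # toward P = 46 (> E1 = 30)
  expect_true(all(means < 0.46 & means > 0.30))
  # under M1b, more own evidence pulls the posterior back toward E1
  m_small <- post_mean(c(alpha_uncertain = 2, alpha_certain = 2), "M1b", 1)
  m_large <- post_mean(c(alpha_uncertain = 50, alpha_certain = 50), "M1b", 1)
  expect_lt(abs(m_large - 0.30), abs(m_small - 0.30))
})

test_that("model specs expose the published parameter counts and bounds", {
  ids <- pb_model_ids()
  ks <- vapply(ids, function(m) model_spec(m)$k, integer(1))
  expect_equal(unname(ks), c(0, 1, 2, 3, 4, 5, 5, 6, 5, 5))
  m3d <- model_spec("M3d")
  expect_equal(unname(m3d$lower),  c(0.1, 0.1, 0.1, 0.1, 0.01))
  expect_equal(unname(m3d$upper),  c(100, 100, 500, 500, 0.99))
  expect_equal(model_spec("M2c")$upper[["theta_high"]], 1000)
  rt <- model_from_json(model_to_json(m3d))
  expect_equal(rt$parameters, m3d$parameters)
})
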