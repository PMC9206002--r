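test_that("Rescorla-Wagner update matches hand evaluation", {
  expect_identical(q_update(0, 0.5, 2, 1), 1)
  expect_identical(q_update(3.7, 0, 5, 1), 3.7)     # zero learning rate
  expect_identical(q_update(1, 0.5, 3, 0), 0.5)     # decay toward rho * 0
  # convex combination: q stays within [min, max] of (q_prev, rho * r)
  q <- 0
  withr::with_seed(1, {
    for (i in 1:200) {
      r <- sample(c(-1, 0, 1), 1)
      q <- q_update(q, 0.3, 2.5, r)
      expect_lte(abs(q), 2.5)
    }
  })
})

test_that("action weights add Go and valence-weighted motivational bias", {
  w <- action_weights(0, 0, b = 0.2, pi = 0.4, valence = "win")
  expect_equal(w$w_go, 0.4)
  expect_equal(w$w_nogo, 0)
  w <- action_weights(0, 0, b = 0.2, pi = 0.4, valence = "avoid")
  expect_equal(w$w_go, 0.0)
  w <- action_weights(1.3, -0.7, b = 0, pi = 0, valence = "win")  # M1 reduction
  expect_equal(w, list(w_go = 1.3, w_nogo = -0.7))
  expect_error(action_weights(0, 0, valence = "neutral"), "valence")
})

test_that("softmax is symmetric, logistic in the weight difference, and stable", {
  expect_equal(choice_probability(1.7, 1.7), 0.5)
  expect_equal(choice_probability(0.4, 0), 1 / (1 + exp(-0.4)))
  expect_equal(choice_probability(53, 3), 1 / (1 + exp(-50)))
  p_hi <- choice_probability(1000, 0)
  expect_true(is.finite(p_hi) && p_hi <= 1 && p_hi > 1 - 1e-12)
  # p_go + p_nogo = 1 and monotonicity in the weight difference
  d <- seq(-5, 5, length.out = 41)
  p <- choice_probability(d, 0)
  expect_equal(p + choice_probability(0, d), rep(1, length(d)))
  expect_true(all(diff(p) > 0))
  expect_error(choice_probability(Inf, 0), "finite")
})

test_that("single uniform-choice trial has NLL log(2)", {
  d <- make_trials("G2W", "go", "reward")
  p <- param_set(rho = 1, epsilon = 0.5)     # b = pi = 0, fresh Q
  expect_equal(negative_log_likelihood(p, d, "M2"), log(2), tolerance = 1e-12)
})

test_that("two-trial NLL matches the symbolic hand computation", {
  # G2W, Go+reward then Go+neutral; rho=2, eps=0.5, b=0.3, pi=0.4
  # trial 1: w_go = 0.3 + 0.5*0.4 = 0.5 -> -log p = log(1 + exp(-0.5))
  # Q(go) <- 0 + 0.5*(2*1 - 0) = 1
  # trial 2: w_go = 1 + 0.5 = 1.5 -> -log p = log(1 + exp(-1.5))
  d <- make_trials(c("G2W", "G2W"), c("go", "go"), c("reward", "neutral"))
  p <- param_set(2, 0.5, b = 0.3, pi = 0.4)
  expected <- log1p(exp(-0.5)) + log1p(exp(-1.5))
  expect_equal(negative_log_likelihood(p, d, "M3"), expected, tolerance = 1e-12)
})

test_that("compiled likelihood agrees with the pure-R replay oracle", {
  for (seed in 1:4) {
    p <- withr::with_seed(seed, param_set(runif(1, 0.5, 5), runif(1, 0.05, 0.6),
                                          rnorm(1, 0, 0.5), rnorm(1, 0, 0.8)))
    d <- sim_two_sessions(p, seed * 10)
    expect_equal(
      negative_log_likelihood(p, d, "M3"),
      r_nll_oracle(list(placebo = p, drug = p), d),
      tolerance = 1e-10
    )
    # M4 with distinct sets per session
    p2 <- param_set(p$rho * 1.3, p$epsilon, p$b - 0.2, p$pi + 0.5)
    expect_equal(
      negative_log_likelihood(list(placebo = p, drug = p2), d, "M4"),
      r_nll_oracle(list(placebo = p, drug = p2), d),
      tolerance = 1e-10
    )
  }
})

test_that("model nesting holds trial-by-trial to machine precision", {
  p3 <- param_set(2.2, 0.3, b = 0.4, pi = 0)
  p2 <- param_set(2.2, 0.3, b = 0.4)
  p1 <- param_set(2.2, 0.3)
  d <- sim_two_sessions(p3, 42)
  expect_equal(negative_log_likelihood(p3, d, "M3"),
               negative_log_likelihood(p2, d, "M2"), tolerance = 1e-12)
  p2b0 <- param_set(2.2, 0.3, b = 0)
  expect_equal(negative_log_likelihood(p2b0, d, "M2"),
               negative_log_likelihood(p1, d, "M1"), tolerance = 1e-12)
  # degenerate drug split reproduces M3
  pfull <- param_set(2.2, 0.3, 0.4, 0.6)
  expect_equal(
    negative_log_likelihood(list(placebo = pfull, drug = pfull), d, "M4"),
    negative_log_likelihood(pfull, d, "M3"), tolerance = 1e-12)
})

test_that("missing responses are skipped; malformed data raise errors", {
  d <- make_trials(c("G2W", "G2W", "G2W"), c("go", "na", "go"),
                   c("reward", "na", "neutral"))
  p <- param_set(2, 0.5, 0.3, 0.4)
  d_clean <- d[d$response != "na", ]
  d_clean$trial <- seq_len(nrow(d_clean))
  expect_equal(negative_log_likelihood(p, d, "M3"),
               negative_log_likelihood(p, d_clean, "M3"))
  expect_error(negative_log_likelihood(p, d[0, ], "M3"), "empty")
  bad <- d; bad$cue[1] <- "ZZZ"
  expect_error(negative_log_likelihood(p, bad, "M3"), "unknown cue")
  allna <- make_trials("G2W", "na", "na")
  expect_error(negative_log_likelihood(p, allna, "M3"), "non-missing")
  expect_error(negative_log_likelihood(p, d, "M4"), "placebo")
})

test_that("Q values stay within the rho bound during replay", {
  p <- param_set(3, 0.7, 0.2, 0.5)
  d <- sim_two_sessions(p, 5)
  tr <- r_nll_oracle(list(placebo = p, drug = p), d, return_q = TRUE)
  expect_true(all(abs(tr$q) <= p$rho + 1e-12))
})

test_that("simulated agents are reproducible and show bias dominance", {
  s <- generate_schedule(3)
  p_bias <- param_set(1, 0.001, b = 0, pi = 5)
  d <- simulate_agent(p_bias, s, "M3", seed = 9)
  expect_identical(d, simulate_agent(p_bias, s, "M3", seed = 9))
  go_win <- mean(d$response[cue_valence(d$cue) > 0] == "go")
  go_avoid <- mean(d$response[cue_valence(d$cue) < 0] == "go")
  expect_gt(go_win, go_avoid + 0.5)
})

test_that("strong instrumental learners exceed chance on all four cues", {
  p <- param_set(8, 0.5)
  s <- generate_schedule(4)
  d <- simulate_agent(p, s, "M1", seed = 11)
  second_half <- d[d$trial > 80, ]
  acc <- mean(second_half$response == correct_response(second_half$cue))
  expect_gt(acc, 0.5)
  for (cc in unique(d$cue)) {
    dd <- second_half[second_half$cue == cc, ]
    expect_gt(mean(dd$response == correct_response(dd$cue)), 0.5)
  }
})

test_that("increasing pi raises Go probability for Win and lowers it for Avoid", {
  pis <- seq(-1, 1, by = 0.25)
  w_win <- vapply(pis, function(x)
    choice_probability(action_weights(0.3, 0.1, 0.2, x, "win")$w_go, 0.1),
    numeric(1))
  w_avd <- vapply(pis, function(x)
    choice_probability(action_weights(0.3, 0.1, 0.2, x, "avoid")$w_go, 0.1),
    numeric(1))
  expect_true(all(diff(w_win) > 0))
  expect_true(all(diff(w_avd) < 0))
})
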