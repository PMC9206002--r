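test_that("cue taxonomy couples action, valence and congruency", {
  cc <- cue_conditions()
  expect_equal(nrow(cc), 4)
  expect_setequal(cc$cue, c("G2W", "G2A", "N2W", "N2A"))
  expect_equal(correct_response(c("G2W", "N2A", "G2A", "N2W")),
               c("go", "nogo", "go", "nogo"))
  expect_equal(cc$congruent,
               (cc$required_action == "go") == (cc$valence == "win"))
  expect_equal(cue_valence(c("G2W", "G2A")), c(0.5, -0.5))
  expect_error(correct_response("XX"), "unknown cue")
})

test_that("schedules are balanced, jitter-constrained and seed-reproducible", {
  s <- generate_schedule(seed = 1)
  expect_equal(nrow(s), 160)
  counts <- table(s$block, s$cue)
  expect_true(all(counts == 20))
  expect_true(all(s$iti_ms %in% seq(2200, 3400, 200)))
  expect_true(all(s$cue_feedback_interval_ms %in% seq(1400, 2600, 200)))
  # per-cue jitter counts as even as 40 presentations over 7 steps allow
  for (cc in unique(s$cue)) {
    tab <- table(factor(s$iti_ms[s$cue == cc], levels = seq(2200, 3400, 200)))
    expect_lte(max(tab) - min(tab), 1)
    expect_equal(sum(tab), 40)
  }
  expect_identical(s, generate_schedule(seed = 1))
  s2 <- generate_schedule(seed = 2)
  expect_equal(table(s2$block, s2$cue), counts)
  expect_false(identical(s$cue, s2$cue))
  expect_equal(attr(s, "cue_ms"), 1300L)
  expect_equal(attr(s, "feedback_ms"), 750L)
})

test_that("minimal and invalid schedule arguments behave as specified", {
  tiny <- generate_schedule(seed = 1, n_blocks = 1,
                            presentations_per_cue_per_block = 1)
  expect_equal(nrow(tiny), 4)
  expect_setequal(tiny$cue, c("G2W", "G2A", "N2W", "N2A"))
  expect_error(generate_schedule(1, n_blocks = 0), "positive")
  expect_error(generate_schedule(1, presentations_per_cue_per_block = 0),
               "positive")
})

test_that("practice phase has 32 trials, deterministic round first", {
  pr <- generate_practice_schedule(seed = 1)
  expect_equal(nrow(pr), 32)
  expect_true(all(table(pr$round, pr$cue) == 4))
  expect_true(all(pr$deterministic[pr$round == 1]))
  expect_false(any(pr$deterministic[pr$round == 2]))
})

test_that("feedback respects the 80/20 contingency and valence restrictions", {
  n <- 40000
  cues <- withr::with_seed(6, sample(c("G2W", "G2A", "N2W", "N2A"), n, replace = TRUE))
  correct <- correct_response(cues)
  wrong <- ifelse(correct == "go", "nogo", "go")
  desired_of <- function(cue) ifelse(cue_valence(cue) > 0, "reward", "neutral")

  out_c <- withr::with_seed(7, sample_outcomes(cues, correct))
  rate_c <- mean(out_c == desired_of(cues))
  se <- sqrt(0.8 * 0.2 / n)
  expect_lt(abs(rate_c - 0.8), 3 * se)

  out_w <- withr::with_seed(8, sample_outcomes(cues, wrong))
  rate_w <- mean(out_w == desired_of(cues))
  expect_lt(abs(rate_w - 0.2), 3 * se)

  # outcome sets respect valence exactly
  win <- cue_valence(cues) > 0
  expect_false(any(out_c[win] == "punishment") || any(out_w[win] == "punishment"))
  expect_false(any(out_c[!win] == "reward") || any(out_w[!win] == "reward"))

  # deterministic practice feedback
  det <- withr::with_seed(9, sample_outcomes(cues, correct, deterministic = TRUE))
  expect_true(all(det == desired_of(cues)))
  expect_error(sample_outcomes("G2W", "na"), "missing")
})

test_that("reward-signal coding is symmetric and drives learning in sign", {
  expect_equal(outcome_reward_signal(c("reward", "neutral", "punishment")),
               c(1, 0, -1))
  expect_true(is.na(outcome_reward_signal("na")))
  expect_error(outcome_reward_signal("win"), "unknown outcome")
  # rewarded Go raises Q(Go); punished Go lowers it
  expect_gt(q_update(0, 0.5, 2, outcome_reward_signal("reward")), 0)
  expect_lt(q_update(0, 0.5, 2, outcome_reward_signal("punishment")), 0)
})

test_that("trial CSV round-trips through write_trials/read_trials", {
  d <- make_trials(c("G2W", "N2A"), c("go", "na"), c("reward", "na"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials(d, path)
  back <- read_trials(path)
  expect_equal(back$cue, d$cue)
  expect_equal(back$response, c("go", "na"))
  expect_equal(back$outcome, c("reward", "na"))
  bad <- back
  bad$response[1] <- "press"
  path2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(as.data.frame(bad), path2, row.names = FALSE)
  expect_error(read_trials(path2), "response")
})
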