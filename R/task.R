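#' Cue conditions of the motivational Go/NoGo task
#'
#' The task crosses required action (Go/NoGo) with cue valence (Win/Avoid),
#' giving four cue conditions. Go2Win and NoGo2Avoid are bias-congruent: the
#' action they require coincides with the action the cue's valence prompts
#' (reward invigorates Go, threat of punishment suppresses it). Go2Avoid and
#' NoGo2Win are bias-incongruent.
#'
#' @return A tibble with one row per cue condition and columns `cue`
#'   (`"G2W"`, `"G2A"`, `"N2W"`, `"N2A"`), `required_action` (`"go"`/`"nogo"`),
#'   `valence` (`"win"`/`"avoid"`) and `congruent` (logical).
#' @export
#' @examples
#' cue_conditions()
cue_conditions <- function() {
  tibble::tibble(
    cue             = c("G2W", "G2A", "N2W", "N2A"),
    required_action = c("go", "go", "nogo", "nogo"),
    valence         = c("win", "avoid", "win", "avoid"),
    congruent       = c(TRUE, FALSE, FALSE, TRUE)
  )
}

.cue_codes <- c("G2W", "G2A", "N2W", "N2A")

check_cues <- function(cue) {
  bad <- setdiff(unique(cue), .cue_codes)
  if (length(bad) > 0) {
    stop("unknown cue code(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(cue)
}

#' Optimal response for a cue
#'
#' @param cue Character vector of cue codes (`"G2W"`, `"G2A"`, `"N2W"`, `"N2A"`).
#' @return Character vector, `"go"` or `"nogo"`.
#' @export
#' @examples
#' correct_response(c("G2W", "N2A"))
correct_response <- function(cue) {
  check_cues(cue)
  ifelse(substr(cue, 1, 1) == "G", "go", "nogo")
}

#' Cue valence as the signed prior used in the action weights
#'
#' Win cues carry V = +0.5, Avoid cues V = -0.5; the motivational-bias
#' parameter multiplies this value in the Go action weight.
#'
#' @param cue Character vector of cue codes.
#' @return Numeric vector of +0.5 / -0.5.
#' @export
cue_valence <- function(cue) {
  check_cues(cue)
  ifelse(substr(cue, 3, 3) == "W", 0.5, -0.5)
}

# Spread `n` draws as evenly as possible over `values`, remainder assigned by
# random draw without replacement, then shuffle. Exact balance is impossible
# when length(values) does not divide n (e.g. 40 presentations over 7 jitter
# steps); counts then differ by at most one.
balanced_jitter <- function(n, values) {
  base <- rep(values, floor(n / length(values)))
  rem <- n - length(base)
  extra <- if (rem > 0) sample(values, rem) else values[0]
  pool <- c(base, extra)
  pool[sample.int(length(pool))]
}

#' Generate a balanced session schedule
#'
#' Builds the trial sequence of one test session: `n_blocks` blocks in which
#' each of the four cue conditions appears exactly
#' `presentations_per_cue_per_block` times in seeded random order. Inter-trial
#' intervals (2200-3400 ms) and cue-feedback intervals (1400-2600 ms), both in
#' 200 ms steps, are balanced within each cue condition (counts per step value
#' differ by at most one) and shuffled within cue. Cue duration (1300 ms) and
#' feedback duration (750 ms) are attached as attributes `cue_ms` and
#' `feedback_ms`; they are metadata only.
#'
#' @param seed Integer seed; the schedule is fully reproducible given the seed.
#' @param n_blocks Number of blocks (default 2).
#' @param presentations_per_cue_per_block Presentations of each cue per block
#'   (default 20), i.e. the default session has 160 trials.
#' @return A tibble with columns `trial` (1-based across the session), `block`,
#'   `cue`, `iti_ms`, `cue_feedback_interval_ms`.
#' @export
#' @examples
#' sched <- generate_schedule(seed = 1)
#' table(sched$block, sched$cue)
generate_schedule <- function(seed, n_blocks = 2, presentations_per_cue_per_block = 20) {
  if (n_blocks < 1 || presentations_per_cue_per_block < 1) {
    stop("n_blocks and presentations_per_cue_per_block must be positive",
         call. = FALSE)
  }
  iti_steps <- seq(2200L, 3400L, by = 200L)
  cfi_steps <- seq(1400L, 2600L, by = 200L)
  withr::with_seed(seed, {
    cue <- unlist(lapply(seq_len(n_blocks), function(b) {
      sample(rep(.cue_codes, each = presentations_per_cue_per_block))
    }))
    n <- length(cue)
    iti <- integer(n)
    cfi <- integer(n)
    per_cue <- n_blocks * presentations_per_cue_per_block
    for (cc in .cue_codes) {
      idx <- which(cue == cc)
      iti[idx] <- balanced_jitter(per_cue, iti_steps)
      cfi[idx] <- balanced_jitter(per_cue, cfi_steps)
    }
    out <- tibble::tibble(
      trial = seq_len(n),
      block = rep(seq_len(n_blocks), each = 4L * presentations_per_cue_per_block),
      cue = cue,
      iti_ms = iti,
      cue_feedback_interval_ms = cfi
    )
  })
  attr(out, "cue_ms") <- 1300L
  attr(out, "feedback_ms") <- 750L
  out
}

#' Generate the practice schedule
#'
#' Two practice rounds of 4 presentations per cue (32 trials): deterministic
#' feedback in round 1, probabilistic in round 2. Practice trials are for task
#' familiarisation and are excluded from all model fits.
#'
#' @param seed Integer seed.
#' @return A tibble with columns `trial`, `round`, `cue`, `deterministic`.
#' @export
generate_practice_schedule <- function(seed) {
  withr::with_seed(seed, {
    cue <- unlist(lapply(1:2, function(r) sample(rep(.cue_codes, each = 4L))))
  })
  tibble::tibble(
    trial = seq_along(cue),
    round = rep(1:2, each = 16L),
    cue = cue,
    deterministic = rep(c(TRUE, FALSE), each = 16L)
  )
}

#' Sample probabilistic feedback
#'
#' A correct response (the cue's required action) yields the desired outcome
#' with probability `p_desired` (0.8 in the task), an incorrect response with
#' probability `1 - p_desired`. For Win cues the desired outcome is a reward
#' and the non-desired outcome neutral; for Avoid cues the desired outcome is
#' neutral and the non-desired a punishment. Win cues therefore never yield a
#' punishment and Avoid cues never a reward. Draws consume the current R
#' random number stream; seed the caller for reproducibility.
#'
#' @param cue Character vector of cue codes.
#' @param response Character vector, `"go"` or `"nogo"` (missing responses are
#'   an error: no outcome is defined for them).
#' @param p_desired Probability of the desired outcome after a correct
#'   response (default 0.8).
#' @param deterministic If `TRUE`, correct responses always get the desired
#'   outcome (practice round 1).
#' @return Character vector of outcomes: `"reward"`, `"neutral"`, `"punishment"`.
#' @export
#' @examples
#' withr::with_seed(1, sample_outcomes(c("G2W", "N2A"), c("go", "go")))
sample_outcomes <- function(cue, response, p_desired = 0.8, deterministic = FALSE) {
  check_cues(cue)
  if (!all(response %in% c("go", "nogo"))) {
    stop("response must be 'go' or 'nogo'; no outcome is defined for missing responses",
         call. = FALSE)
  }
  n <- length(cue)
  stopifnot(length(response) == n)
  correct <- response == correct_response(cue)
  p <- ifelse(correct, p_desired, 1 - p_desired)
  if (deterministic) p <- as.numeric(correct)
  desired <- runif(n) < p
  win <- cue_valence(cue) > 0
  out <- character(n)
  out[win & desired]   <- "reward"
  out[win & !desired]  <- "neutral"
  out[!win & desired]  <- "neutral"
  out[!win & !desired] <- "punishment"
  out
}

#' Numeric reward signal of an outcome
#'
#' Symmetric coding of the feedback entering the value update: reward +1,
#' neutral 0, punishment -1. The feedback-sensitivity parameter rho scales
#' this signal inside the Rescorla-Wagner update.
#'
#' @param outcome Character vector: `"reward"`, `"neutral"`, `"punishment"`
#'   (`"na"`/`NA` map to `NA`).
#' @param coding Named numeric vector giving the signal for each outcome;
#'   the symmetric default can be overridden.
#' @return Numeric vector in `{-1, 0, +1}` (or per `coding`).
#' @export
outcome_reward_signal <- function(outcome,
                                  coding = c(reward = 1, neutral = 0, punishment = -1)) {
  out <- rep(NA_real_, length(outcome))
  known <- outcome %in% names(coding)
  missing_ok <- is.na(outcome) | outcome == "na"
  if (!all(known | missing_ok)) {
    stop("unknown outcome code(s): ",
         paste(setdiff(unique(outcome), c(names(coding), "na")), collapse = ", "),
         call. = FALSE)
  }
  out[known] <- coding[outcome[known]]
  out
}
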