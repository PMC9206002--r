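#' @section Model family:
#' The package implements a nested family of Rescorla-Wagner models of
#' Go/NoGo choice. On every trial the value of the chosen action a for the
#' shown cue s is updated as
#' \deqn{Q_t(a,s) = Q_{t-1}(a,s) + \epsilon(\rho r_t - Q_{t-1}(a,s))}
#' with learning rate epsilon, feedback sensitivity rho and reward signal
#' r in {-1, 0, +1}. Action weights add a Go bias b and a motivational bias
#' pi acting through cue valence V (+0.5 Win / -0.5 Avoid) to the Go weight
#' only, and a softmax maps weights to choice probabilities.
#' M1 uses (rho, epsilon); M2 adds b; M3 adds pi; M4 duplicates the M3
#' parameter set per drug condition (placebo/drug).
#' @name mgng-models
NULL

.model_ids <- c("M1", "M2", "M3", "M4")

#' Number of free parameters of a model
#' @param model_id One of `"M1"`, `"M2"`, `"M3"`, `"M4"`.
#' @return Integer: 2, 3, 4 or 8.
#' @export
model_npar <- function(model_id) {
  c(M1 = 2L, M2 = 3L, M3 = 4L, M4 = 8L)[[match.arg(model_id, .model_ids)]]
}

#' Construct a parameter set
#'
#' @param rho Feedback sensitivity, > 0.
#' @param epsilon Learning rate in (0, 1).
#' @param b Go bias (0 in M1).
#' @param pi Motivational bias (0 in M1, M2).
#' @return A named list of class `gng_params`.
#' @export
param_set <- function(rho, epsilon, b = 0, pi = 0) {
  if (!is.finite(rho) || rho <= 0) stop("rho must be positive", call. = FALSE)
  if (!is.finite(epsilon) || epsilon <= 0 || epsilon >= 1) {
    stop("epsilon must lie in (0, 1)", call. = FALSE)
  }
  structure(list(rho = rho, epsilon = epsilon, b = b, pi = pi),
            class = "gng_params")
}

# zero out parameters a model does not contain
mask_params <- function(p, model_id) {
  if (model_id == "M1") { p$b <- 0; p$pi <- 0 }
  if (model_id == "M2") p$pi <- 0
  p
}

#' Rescorla-Wagner value update
#'
#' `q + epsilon * (rho * r - q)`: the learned value decays toward the scaled
#' reward signal. Only the (chosen action, shown cue) cell is updated on a
#' trial; this function is the scalar kernel.
#'
#' @param q Current value(s).
#' @param epsilon Learning rate (0 and 1 accepted for edge-case checks).
#' @param rho Feedback sensitivity, > 0.
#' @param r Reward signal, typically in `{-1, 0, +1}`.
#' @return Updated value(s).
#' @export
#' @examples
#' q_update(0, 0.5, 2, 1)  # 1
q_update <- function(q, epsilon, rho, r) {
  q + epsilon * (rho * r - q)
}

#' Action weights with Go and motivational bias
#'
#' The Go weight is `q_go + b + V * pi` where V is +0.5 for Win and -0.5 for
#' Avoid cues; the NoGo weight is the bare `q_nogo`. Pass `b = 0, pi = 0` for
#' M1 and `pi = 0` for M2.
#'
#' @param q_go,q_nogo Learned action values.
#' @param b Go bias.
#' @param pi Motivational bias.
#' @param valence `"win"`/`"avoid"`, or the numeric V itself (+0.5/-0.5).
#' @return A list with components `w_go` and `w_nogo`.
#' @export
action_weights <- function(q_go, q_nogo, b = 0, pi = 0, valence) {
  v <- if (is.character(valence)) {
    lv <- tolower(valence)
    if (!all(lv %in% c("win", "avoid"))) {
      stop("valence must be 'win' or 'avoid'", call. = FALSE)
    }
    ifelse(lv == "win", 0.5, -0.5)
  } else {
    valence
  }
  list(w_go = q_go + b + v * pi, w_nogo = q_nogo)
}

#' Softmax Go probability
#'
#' `p_go = exp(w_go) / (exp(w_go) + exp(w_nogo))`, computed by subtracting the
#' larger weight so that extreme weights saturate without overflow.
#'
#' @param w_go,w_nogo Finite action weights (vectorised).
#' @return `p_go` in (0, 1); `p_nogo` is `1 - p_go`.
#' @export
#' @examples
#' choice_probability(0.4, 0)  # 1 / (1 + exp(-0.4))
choice_probability <- function(w_go, w_nogo) {
  if (any(!is.finite(w_go)) || any(!is.finite(w_nogo))) {
    stop("action weights must be finite", call. = FALSE)
  }
  m <- pmax(w_go, w_nogo)
  eg <- exp(w_go - m)
  en <- exp(w_nogo - m)
  eg / (eg + en)
}

# Validate and encode a trial table into the numeric form the likelihood
# kernel consumes: cue index 1..4, valence, Go indicator (NA when missing),
# reward signal, session index in sorted-unique order.
encode_trials <- function(data) {
  req <- c("subject_id", "session", "trial", "cue", "response", "outcome")
  miss <- setdiff(req, names(data))
  if (length(miss) > 0) {
    stop("trial data lack column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(data) == 0) stop("empty trial dataset", call. = FALSE)
  check_cues(data$cue)
  if (!all(data$response %in% c("go", "nogo", "na") | is.na(data$response))) {
    stop("unknown response code(s): ",
         paste(setdiff(unique(data$response), c("go", "nogo", "na")), collapse = ", "),
         call. = FALSE)
  }
  sessions <- sort(unique(data$session))
  go <- ifelse(data$response == "go", 1L, ifelse(data$response == "nogo", 0L, NA_integer_))
  list(
    cue = match(data$cue, .cue_codes),
    valence = cue_valence(data$cue),
    go = go,
    r = outcome_reward_signal(data$outcome),
    session = match(data$session, sessions),
    sessions = sessions
  )
}

# expand ParamSet | DualParamSet into per-session parameter vectors
session_params <- function(params, sessions, model_id) {
  k <- length(sessions)
  if (model_id == "M4") {
    if (!all(c("placebo", "drug") %in% names(params))) {
      stop("M4 requires a dual parameter set with components 'placebo' and 'drug'",
           call. = FALSE)
    }
    if (!setequal(sessions, c("placebo", "drug"))) {
      stop("M4 requires both a 'placebo' and a 'drug' session in the data",
           call. = FALSE)
    }
    sets <- lapply(sessions, function(s) params[[s]])
  } else {
    if (all(c("placebo", "drug") %in% names(params))) {
      stop("models M1-M3 take a single parameter set", call. = FALSE)
    }
    sets <- rep(list(mask_params(params, model_id)), k)
  }
  list(
    rho = vapply(sets, `[[`, numeric(1), "rho"),
    epsilon = vapply(sets, `[[`, numeric(1), "epsilon"),
    b = vapply(sets, `[[`, numeric(1), "b"),
    pi = vapply(sets, `[[`, numeric(1), "pi")
  )
}

#' Negative log-likelihood of trial-level choices
#'
#' Replays the trials of each session in order (Q values reset to 0 at each
#' session start: the two test days use distinct cue sets, so learning does
#' not transfer), accumulating `-log p(chosen response)` over non-missing
#' trials. Only the chosen action's Q value is updated. For M1-M3 a single
#' parameter set applies to all sessions; M4 takes a dual set, one per drug
#' condition.
#'
#' @param params A `param_set()`, or for M4 `list(placebo = , drug = )`.
#' @param data Trial table with columns `subject_id`, `session`, `trial`,
#'   `cue`, `response`, `outcome` (one subject).
#' @param model_id `"M1"`..`"M4"`; parameters absent from the model are forced
#'   to 0.
#' @return Non-negative scalar, in nats.
#' @export
negative_log_likelihood <- function(params, data, model_id = "M3") {
  model_id <- match.arg(model_id, .model_ids)
  data <- data[order(data$session, data$trial), , drop = FALSE]
  enc <- encode_trials(data)
  if (all(is.na(enc$go))) stop("dataset contains no non-missing trials", call. = FALSE)
  sp <- session_params(params, enc$sessions, model_id)
  nll_replay_cpp(enc$cue, enc$valence, enc$go, enc$r, enc$session,
                 sp$rho, sp$epsilon, sp$b, sp$pi)
}

#' Simulate an agent on a schedule
#'
#' Plays the task trial by trial: Go sampled from the softmax probability,
#' feedback drawn from the 80/20 contingencies, Q updated online. With a
#' single parameter set and a single schedule, one session is simulated; with
#' a dual set (M4) supply `schedule = list(placebo = , drug = )` and both
#' sessions are simulated with independent learning.
#'
#' @param params A `param_set()` or, for M4, `list(placebo = , drug = )`.
#' @param schedule Output of [generate_schedule()], or a named list of two
#'   such schedules for a dual set.
#' @param model_id Model generating the choices; unused parameters forced to 0.
#' @param seed Integer seed; identical seeds and parameters give identical data.
#' @param subject_id Label stored in the output.
#' @param session Session label for a single-session simulation.
#' @param p_desired Feedback contingency (default 0.8).
#' @return Trial tibble with the standard columns plus `p_go` (the model's
#'   Go probability at the moment of choice, for debugging).
#' @export
simulate_agent <- function(params, schedule, model_id = "M3", seed = 1,
                           subject_id = "S01", session = "placebo",
                           p_desired = 0.8) {
  model_id <- match.arg(model_id, .model_ids)
  if (model_id == "M4" || all(c("placebo", "drug") %in% names(params))) {
    stopifnot(is.list(schedule), all(c("placebo", "drug") %in% names(schedule)))
    out <- lapply(seq_along(c("placebo", "drug")), function(i) {
      s <- c("placebo", "drug")[i]
      simulate_agent(params[[s]], schedule[[s]], model_id = "M3",
                     seed = seed + i - 1L, subject_id = subject_id,
                     session = s, p_desired = p_desired)
    })
    return(dplyr::bind_rows(out))
  }
  p <- mask_params(params, model_id)
  withr::with_seed(seed, {
    n <- nrow(schedule)
    q <- matrix(0, nrow = 2, ncol = 4)  # rows: go, nogo; cols: cues
    resp <- character(n); outc <- character(n); pgo <- numeric(n)
    cue_idx <- match(schedule$cue, .cue_codes)
    val <- cue_valence(schedule$cue)
    for (t in seq_len(n)) {
      ci <- cue_idx[t]
      w <- action_weights(q[1, ci], q[2, ci], p$b, p$pi, val[t])
      pg <- choice_probability(w$w_go, w$w_nogo)
      go <- runif(1) < pg
      resp[t] <- if (go) "go" else "nogo"
      outc[t] <- sample_outcomes(schedule$cue[t], resp[t], p_desired = p_desired)
      r <- outcome_reward_signal(outc[t])
      a <- if (go) 1 else 2
      q[a, ci] <- q_update(q[a, ci], p$epsilon, p$rho, r)
      pgo[t] <- pg
    }
  })
  tibble::tibble(
    subject_id = subject_id, session = session,
    block = schedule$block %||% 1L, trial = schedule$trial,
    cue = schedule$cue, response = resp, outcome = outc, p_go = pgo
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
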