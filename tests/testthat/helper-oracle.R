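# Pure-R trial-by-trial likelihood replay, independent of the package's
# compiled kernel. Takes full parameter lists (rho, epsilon, b, pi) per
# session; optionally returns the Q trace for bound checks.
r_nll_oracle <- function(params_by_session, data, return_q = FALSE) {
  data <- data[order(data$session, data$trial), ]
  cue_levels <- c("G2W", "G2A", "N2W", "N2A")
  val <- ifelse(substr(data$cue, 3, 3) == "W", 0.5, -0.5)
  rsig <- c(reward = 1, neutral = 0, punishment = -1)[data$outcome]
  nll <- 0
  qtrace <- numeric(0)
  for (sess in sort(unique(data$session))) {
    p <- params_by_session[[sess]]
    idx <- which(data$session == sess)
    q <- matrix(0, 2, 4)
    for (t in idx) {
      if (!data$response[t] %in% c("go", "nogo")) next
      ci <- match(data$cue[t], cue_levels)
      wg <- q[1, ci] + p$b + val[t] * p$pi
      wn <- q[2, ci]
      pgo <- 1 / (1 + exp(wn - wg))
      pr <- if (data$response[t] == "go") pgo else 1 - pgo
      nll <- nll - log(pr)
      a <- if (data$response[t] == "go") 1 else 2
      if (!is.na(rsig[t])) {
        q[a, ci] <- q[a, ci] + p$epsilon * (p$rho * rsig[t] - q[a, ci])
      }
      qtrace <- c(qtrace, q[a, ci])
    }
  }
  if (return_q) list(nll = nll, q = qtrace) else nll
}

# hand-built trial table
make_trials <- function(cue, response, outcome, session = "placebo",
                        subject_id = "T1") {
  tibble::tibble(subject_id = subject_id, session = session,
                 block = 1L, trial = seq_along(cue),
                 cue = cue, response = response, outcome = outcome)
}

# simulate one subject with two sessions from a single parameter set
sim_two_sessions <- function(p, seed, model_id = "M3", n_blocks = 2,
                             subject_id = "S01", pi_drug = NULL) {
  s1 <- generate_schedule(seed, n_blocks = n_blocks)
  s2 <- generate_schedule(seed + 1, n_blocks = n_blocks)
  pd <- if (is.null(pi_drug)) p else param_set(p$rho, p$epsilon, p$b, pi_drug)
  rbind(
    simulate_agent(p, s1, model_id, seed = seed + 2, subject_id = subject_id,
                   session = "placebo"),
    simulate_agent(pd, s2, model_id, seed = seed + 3, subject_id = subject_id,
                   session = "drug")
  )
}
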