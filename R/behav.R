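#' Condition-level behavioural summary
#'
#' Mean Go rate and accuracy per subject x session x cue condition (optionally
#' split by block). Accuracy equals the Go rate for Go cues and one minus the
#' Go rate for NoGo cues. Missing responses are excluded from denominators;
#' empty cells are kept with `n_trials = 0` and `NA` rates.
#'
#' @param data Trial table (columns `subject_id`, `session`, `block`, `trial`,
#'   `cue`, `response`).
#' @param by_block Also split by block.
#' @return Tibble: grouping columns plus `n_trials`, `p_go`, `accuracy`,
#'   `required_action`, `valence`, `congruent`.
#' @export
summarize_behaviour <- function(data, by_block = FALSE) {
  check_cues(data$cue)
  grp <- c("subject_id", "session", if (by_block) "block", "cue")
  full <- tidyr_complete_cells(data, grp)
  out <- dplyr::summarise(
    dplyr::group_by(full, dplyr::across(dplyr::all_of(grp))),
    n_trials = sum(.data$response %in% c("go", "nogo"), na.rm = TRUE),
    p_go = mean(.data$response[.data$response %in% c("go", "nogo")] == "go"),
    .groups = "drop"
  )
  out$p_go[out$n_trials == 0] <- NA_real_
  meta <- cue_conditions()
  out <- dplyr::left_join(out, meta, by = "cue")
  out$accuracy <- ifelse(out$required_action == "go", out$p_go, 1 - out$p_go)
  out
}

# make sure every subject x session (x block) x cue cell exists
tidyr_complete_cells <- function(data, grp) {
  cells <- unique(data[setdiff(grp, "cue")])
  grid <- merge(cells, data.frame(cue = .cue_codes), by = NULL)
  dplyr::left_join(tibble::as_tibble(grid), data, by = grp)
}

#' Motivational bias index
#'
#' `P(Go | Win cues) - P(Go | Avoid cues)` per subject and session, computed
#' from the cell means of [summarize_behaviour()] (balanced across cues by
#' design). Positive values mean reward invigorates and punishment suppresses
#' Go responding.
#'
#' @param data Trial table or the output of [summarize_behaviour()].
#' @return Tibble: `subject_id`, `session`, `bias_index` in `[-1, 1]`.
#' @export
bias_index <- function(data) {
  summ <- if ("p_go" %in% names(data)) data else summarize_behaviour(data)
  dplyr::summarise(
    dplyr::group_by(summ, .data$subject_id, .data$session),
    bias_index = mean(.data$p_go[.data$valence == "win"]) -
      mean(.data$p_go[.data$valence == "avoid"]),
    .groups = "drop"
  )
}

# centered moving average with shrinking windows at the edges
centered_moving_average <- function(x, window) {
  n <- length(x)
  if (window < 1) stop("window must be >= 1", call. = FALSE)
  if (window >= n) return(rep(mean(x), n))
  lo <- floor((window - 1) / 2)
  hi <- ceiling((window - 1) / 2)
  vapply(seq_len(n),
         function(i) mean(x[max(1, i - lo):min(n, i + hi)]),
         numeric(1))
}

#' Sliding-window Go-rate learning curves
#'
#' Centered moving average (default window 5 presentations, shorter at the
#' edges) of the Go indicator over each cue's presentation sequence, per
#' subject and session. A window at least as long as the series returns the
#' overall mean at every position.
#'
#' @param data Trial table.
#' @param window Window width in presentations of the same cue.
#' @return Tibble: `subject_id`, `session`, `cue`, `presentation` (1-based
#'   index within cue), `go_rate`.
#' @export
sliding_go_rate <- function(data, window = 5) {
  check_cues(data$cue)
  data <- data[data$response %in% c("go", "nogo"), , drop = FALSE]
  data <- data[order(data$subject_id, data$session, data$trial), , drop = FALSE]
  grp <- dplyr::group_by(data, .data$subject_id, .data$session, .data$cue)
  dplyr::reframe(
    grp,
    presentation = seq_along(.data$trial),
    go_rate = centered_moving_average(as.numeric(.data$response == "go"), window)
  )
}

#' Group-mean Go rates by cue condition
#'
#' Subject means with standard errors, ready for plotting in the conventional
#' four-bar layout (grouped by required action, coloured by valence).
#'
#' @param summary Output of [summarize_behaviour()].
#' @return Tibble: `session`, `cue`, `mean_p_go`, `sem`, `n`.
#' @export
group_go_rates <- function(summary) {
  dplyr::summarise(
    dplyr::group_by(summary, .data$session, .data$cue),
    mean_p_go = mean(.data$p_go, na.rm = TRUE),
    sem = sd(.data$p_go, na.rm = TRUE) / sqrt(sum(!is.na(.data$p_go))),
    n = sum(!is.na(.data$p_go)),
    .groups = "drop"
  )
}

#' Plot group Go rates per cue condition
#'
#' @param summary Output of [summarize_behaviour()].
#' @return A ggplot object (requires ggplot2).
#' @export
plot_go_rates <- function(summary) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  g <- group_go_rates(summary)
  g$cue <- factor(g$cue, levels = .cue_codes)
  ggplot2::ggplot(g, ggplot2::aes(x = .data$cue, y = .data$mean_p_go,
                                  fill = .data$cue)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_p_go - .data$sem,
                                        ymax = .data$mean_p_go + .data$sem),
                           width = 0.2) +
    ggplot2::facet_wrap(~session) +
    ggplot2::labs(x = NULL, y = "P(Go)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
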