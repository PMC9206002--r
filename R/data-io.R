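#' Write a trial-level dataset to CSV
#'
#' Canonical on-disk format: headered CSV with columns `subject_id`,
#' `session`, `block`, `trial`, `cue` (G2W|G2A|N2W|N2A), `response`
#' (go|nogo|na), `outcome` (reward|neutral|punishment|na); 1-based trial
#' indices within session.
#'
#' @param data Trial table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(data, path) {
  cols <- c("subject_id", "session", "block", "trial", "cue", "response", "outcome")
  if (!"block" %in% names(data)) data$block <- 1L
  miss <- setdiff(cols, names(data))
  if (length(miss) > 0) {
    stop("trial data lack column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  out <- as.data.frame(data[cols])
  out$response[is.na(out$response)] <- "na"
  out$outcome[is.na(out$outcome)] <- "na"
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trial-level dataset from CSV
#'
#' Validates the cue/response/outcome codes and the column set of the format
#' written by [write_trials()]. `"na"` codes are kept as the literal string
#' so that downstream code can distinguish a recorded missing response from
#' an absent field; the likelihood machinery skips such trials.
#'
#' @param path CSV file path.
#' @return Trial tibble.
#' @export
read_trials <- function(path) {
  df <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE,
                                   colClasses = c(subject_id = "character")))
  req <- c("subject_id", "session", "block", "trial", "cue", "response", "outcome")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) {
    stop("file lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  check_cues(df$cue)
  df$response[is.na(df$response)] <- "na"
  df$outcome[is.na(df$outcome)] <- "na"
  if (!all(df$response %in% c("go", "nogo", "na"))) {
    stop("unknown response code(s) in ", path, call. = FALSE)
  }
  if (!all(df$outcome %in% c("reward", "neutral", "punishment", "na"))) {
    stop("unknown outcome code(s) in ", path, call. = FALSE)
  }
  df
}
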