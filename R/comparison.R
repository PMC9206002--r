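#' Random-effects Bayesian model selection
#'
#' Treats the model identity of each subject as a random effect with a
#' Dirichlet population distribution over model frequencies and fits the
#' Dirichlet posterior by the usual variational scheme: subject
#' responsibilities `u_nk` proportional to
#' `exp(log_evidence_nk + digamma(alpha_k) - digamma(sum(alpha)))`, then
#' `alpha_k = alpha0 + sum_n u_nk`, iterated to convergence. Exceedance
#' probabilities (probability that each model is the most frequent) are
#' estimated by seeded Monte-Carlo sampling of the Dirichlet posterior. The
#' Bayes omnibus risk (BOR) is the posterior probability that all models are
#' equally frequent, computed from the free energies of the null
#' (equal-frequency) and the fitted random-effects model; protected
#' exceedance probabilities shrink XP toward uniformity:
#' `PXP = (1 - BOR) * XP + BOR / K`.
#'
#' @param log_evidence Numeric matrix, subjects x models (colnames used as
#'   model ids when present); all entries finite, at least 2 rows and 2
#'   columns.
#' @param alpha0 Dirichlet prior concentration (default 1: uniform prior over
#'   frequencies).
#' @param n_mc Monte-Carlo samples for the exceedance probabilities
#'   (default 1e6).
#' @param seed Integer seed for the Monte-Carlo draw.
#' @param tol Convergence tolerance on the change in alpha.
#' @return A `gng_bms` list: `model_ids`, `alpha`, `expected_frequency`,
#'   `xp`, `bor`, `pxp`, `n_mc`, `responsibilities`.
#' @export
#' @examples
#' L <- cbind(M2 = rep(0, 12), M3 = rep(3, 12))
#' run_bms(L, n_mc = 1e5, seed = 1)
run_bms <- function(log_evidence, alpha0 = 1, n_mc = 1e6, seed = 1,
                    tol = 1e-6) {
  L <- as.matrix(log_evidence)
  if (any(!is.finite(L))) stop("log evidences must be finite", call. = FALSE)
  n <- nrow(L); K <- ncol(L)
  if (K < 2) stop("need at least 2 models", call. = FALSE)
  if (n < 2) stop("need at least 2 subjects", call. = FALSE)
  if (alpha0 <= 0) stop("alpha0 must be positive", call. = FALSE)
  ids <- colnames(L) %||% paste0("model", seq_len(K))

  alpha <- rep(alpha0, K)
  u <- matrix(0, n, K)
  for (iter in seq_len(10000)) {
    lw <- sweep(L, 2, digamma(alpha) - digamma(sum(alpha)), `+`)
    lw <- lw - apply(lw, 1, max)
    u <- exp(lw)
    u <- u / rowSums(u)
    alpha_new <- alpha0 + colSums(u)
    if (max(abs(alpha_new - alpha)) < tol) { alpha <- alpha_new; break }
    alpha <- alpha_new
  }

  ef <- alpha / sum(alpha)
  xp <- dirichlet_exceedance(alpha, n_mc = n_mc, seed = seed)
  bor <- bms_bor(L, alpha, u, alpha0)
  pxp <- (1 - bor) * xp + bor / K

  structure(list(model_ids = ids,
                 alpha = setNames(alpha, ids),
                 expected_frequency = setNames(ef, ids),
                 xp = setNames(xp, ids),
                 bor = bor,
                 pxp = setNames(pxp, ids),
                 n_mc = n_mc,
                 responsibilities = u),
            class = "gng_bms")
}

#' Monte-Carlo exceedance probabilities of a Dirichlet distribution
#'
#' Probability, for each component, that it is the largest frequency under
#' `Dirichlet(alpha)`, estimated from `n_mc` seeded draws (gamma
#' representation).
#'
#' @param alpha Positive concentration vector (length >= 2).
#' @param n_mc Number of Monte-Carlo samples.
#' @param seed Integer seed.
#' @return Numeric vector summing to 1.
#' @export
dirichlet_exceedance <- function(alpha, n_mc = 1e6, seed = 1) {
  K <- length(alpha)
  stopifnot(K >= 2, all(alpha > 0))
  withr::with_seed(seed, {
    g <- matrix(rgamma(n_mc * K, shape = rep(alpha, each = n_mc)),
                nrow = n_mc, ncol = K)
  })
  win <- max.col(g, ties.method = "first")
  tabulate(win, nbins = K) / n_mc
}

# Free energy of the fitted random-effects model (variational bound) and of
# the null model in which all frequencies are fixed equal; BOR is the
# posterior probability of the null under equal model priors.
bms_bor <- function(L, alpha, u, alpha0) {
  K <- ncol(L)
  a0 <- rep(alpha0, K)
  dg <- digamma(alpha) - digamma(sum(alpha))
  elj <- lgamma(sum(a0)) - sum(lgamma(a0)) + sum((a0 - 1) * dg) +
    sum(u * (L + matrix(dg, nrow(L), K, byrow = TRUE)))
  sqf <- sum(lgamma(alpha)) - lgamma(sum(alpha)) - sum((alpha - 1) * dg)
  sqm <- -sum(ifelse(u > 0, u * log(u), 0))
  f1 <- elj + sqf + sqm
  # null: frequencies fixed at 1/K, subjects integrate over models exactly
  lse <- function(v) { m <- max(v); m + log(sum(exp(v - m))) }
  f0 <- sum(apply(L, 1, lse)) - nrow(L) * log(K)
  1 / (1 + exp(f1 - f0))
}

#' @export
print.gng_bms <- function(x, ...) {
  cat("<gng_bms> random-effects model selection over",
      length(x$model_ids), "models\n")
  print(frequency_report(x), digits = 3)
  invisible(x)
}

#' Model-selection summary table
#'
#' @param bms A `gng_bms` result.
#' @return Tibble with one row per model: `model_id`, `frequency_pct`
#'   (expected model frequency in percent), `frequency_label` (formatted
#'   string), `xp`, `pxp` and the shared `bor` column.
#' @export
frequency_report <- function(bms) {
  stopifnot(inherits(bms, "gng_bms"))
  tibble::tibble(
    model_id = bms$model_ids,
    frequency_pct = 100 * as.numeric(bms$expected_frequency),
    frequency_label = sprintf("%.1f%%", 100 * as.numeric(bms$expected_frequency)),
    xp = as.numeric(bms$xp),
    pxp = as.numeric(bms$pxp),
    bor = bms$bor
  )
}
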