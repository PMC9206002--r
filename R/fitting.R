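#' Default prior on the unconstrained parameter space
#'
#' Weakly-informative independent normals on the fitting coordinates:
#' `log(rho) ~ N(0, 1.5^2)`, `logit(epsilon) ~ N(0, 1.5^2)`,
#' `b ~ N(0, 2^2)`, `pi ~ N(0, 2^2)`. For M4 the same prior applies to both
#' drug-condition sets.
#'
#' @return List with numeric vectors `mean` and `sd` (length 4, named).
#' @export
default_prior <- function() {
  list(mean = c(x_rho = 0, x_eps = 0, b = 0, pi = 0),
       sd   = c(x_rho = 1.5, x_eps = 1.5, b = 2, pi = 2))
}

read_prior <- function(path) {
  y <- yaml::read_yaml(path)
  p <- default_prior()
  for (nm in names(p$mean)) {
    if (!is.null(y[[nm]])) {
      p$mean[[nm]] <- y[[nm]]$mean %||% p$mean[[nm]]
      p$sd[[nm]] <- y[[nm]]$sd %||% p$sd[[nm]]
    }
  }
  p
}

.EPS_CLIP <- 1e-12

#' Map an unconstrained vector to a parameter set
#'
#' `rho = exp(x)`, `epsilon = logistic(x)` (clipped away from 0/1), `b` and
#' `pi` untouched. M1 takes length 2, M2 length 3, M3 length 4; M4 takes
#' length 8 (placebo set then drug set).
#'
#' @param x Numeric vector in the fitting space.
#' @param model_id Model identifier.
#' @return A `gng_params` list, or for M4 `list(placebo = , drug = )`.
#' @seealso [untransform_params()] for the inverse.
#' @export
transform_params <- function(x, model_id = "M3") {
  model_id <- match.arg(model_id, .model_ids)
  d <- model_npar(model_id)
  if (length(x) != d) {
    stop("expected ", d, " unconstrained values for ", model_id,
         ", got ", length(x), call. = FALSE)
  }
  one <- function(v) {
    eps <- min(max(plogis(v[2]), .EPS_CLIP), 1 - .EPS_CLIP)
    structure(list(rho = exp(v[1]), epsilon = eps,
                   b = if (length(v) >= 3) v[3] else 0,
                   pi = if (length(v) >= 4) v[4] else 0),
              class = "gng_params")
  }
  if (model_id == "M4") {
    list(placebo = one(x[1:4]), drug = one(x[5:8]))
  } else {
    one(x)
  }
}

#' Inverse of [transform_params()]
#' @param params A `gng_params` or dual set.
#' @param model_id Model identifier.
#' @return Unconstrained numeric vector of length `model_npar(model_id)`.
#' @export
untransform_params <- function(params, model_id = "M3") {
  model_id <- match.arg(model_id, .model_ids)
  one <- function(p) c(log(p$rho), qlogis(p$epsilon), p$b, p$pi)
  x <- if (model_id == "M4") c(one(params$placebo), one(params$drug)) else one(params)
  x[seq_len(model_npar(model_id))]
}

# negative log prior in the unconstrained space
neg_log_prior <- function(x, model_id, prior) {
  if (model_id == "M4") {
    m <- c(prior$mean, prior$mean); s <- c(prior$sd, prior$sd)
  } else {
    d <- model_npar(model_id)
    m <- prior$mean[seq_len(d)]; s <- prior$sd[seq_len(d)]
  }
  -sum(dnorm(x, m, s, log = TRUE))
}

#' Fit one subject by maximum a posteriori estimation
#'
#' Minimises negative log-likelihood plus negative log-prior over the
#' unconstrained space with BFGS from `n_restarts` seeded starting points
#' (draws from the prior; an optional `init` — typically the optimum of the
#' nested simpler model — is prepended as an extra start). The log model
#' evidence is the Laplace approximation at the optimum,
#' `log p(y) ~ log p(y, theta*) + d/2 log(2 pi) - 1/2 log |H|`,
#' with H the finite-difference Hessian of the negative log posterior; when
#' H is not positive definite the function falls back to `-BIC/2` with a
#' warning.
#'
#' @param data Trial table of a single subject.
#' @param model_id `"M1"`..`"M4"`.
#' @param prior Prior specification, see [default_prior()].
#' @param n_restarts Number of random restarts (default 10).
#' @param seed Integer seed controlling the starting points.
#' @param init Optional unconstrained start vector prepended to the restarts.
#' @return A `gng_fit` list: `subject_id`, `model_id`, `estimates`, `par`
#'   (unconstrained optimum), `log_posterior`, `log_likelihood`,
#'   `log_evidence`, `n_restarts_converged`, `hessian_log_det`, `laplace_ok`,
#'   `converged`.
#' @export
fit_subject <- function(data, model_id = "M3", prior = default_prior(),
                        n_restarts = 10, seed = 1, init = NULL) {
  model_id <- match.arg(model_id, .model_ids)
  data <- data[order(data$session, data$trial), , drop = FALSE]
  enc <- encode_trials(data)
  if (all(is.na(enc$go))) stop("dataset contains no non-missing trials", call. = FALSE)
  if (model_id == "M4" && !setequal(enc$sessions, c("placebo", "drug"))) {
    stop("M4 requires both a 'placebo' and a 'drug' session", call. = FALSE)
  }
  d <- model_npar(model_id)
  nll_of <- function(x) {
    p <- transform_params(x, model_id)
    sp <- session_params(p, enc$sessions, model_id)
    nll_replay_cpp(enc$cue, enc$valence, enc$go, enc$r, enc$session,
                   sp$rho, sp$epsilon, sp$b, sp$pi)
  }
  objective <- function(x) nll_of(x) + neg_log_prior(x, model_id, prior)

  pm <- if (model_id == "M4") rep(prior$mean, 2) else prior$mean[seq_len(d)]
  ps <- if (model_id == "M4") rep(prior$sd, 2) else prior$sd[seq_len(d)]
  starts <- withr::with_seed(seed, {
    s <- matrix(rnorm(n_restarts * d, mean = rep(pm, each = n_restarts),
                      sd = rep(ps, each = n_restarts)),
                nrow = n_restarts, ncol = d)
    s[1, ] <- 0  # deterministic start at the prior mode's neighbourhood
    s
  })
  if (!is.null(init)) starts <- rbind(matrix(init, nrow = 1), starts)

  best <- NULL
  n_conv <- 0L
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      optim(starts[i, ], objective, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) NULL
    )
    if (is.null(res) || !is.finite(res$value)) next
    if (res$convergence == 0) n_conv <- n_conv + 1L
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    return(structure(list(subject_id = data$subject_id[1], model_id = model_id,
                          estimates = NULL, par = rep(NA_real_, d),
                          log_posterior = NA_real_, log_likelihood = NA_real_,
                          log_evidence = NA_real_, n_restarts_converged = 0L,
                          hessian_log_det = NA_real_, laplace_ok = FALSE,
                          converged = FALSE),
                     class = "gng_fit"))
  }
  par <- best$par
  log_post <- -best$value
  nll_hat <- nll_of(par)
  n_obs <- sum(!is.na(enc$go))

  H <- tryCatch(optimHess(par, objective), error = function(e) NULL)
  ch <- if (!is.null(H)) tryCatch(chol(H), error = function(e) NULL) else NULL
  if (!is.null(ch)) {
    hld <- 2 * sum(log(diag(ch)))
    log_ev <- log_post + d / 2 * log(2 * pi) - hld / 2
    laplace_ok <- TRUE
  } else {
    hld <- NA_real_
    log_ev <- -0.5 * (2 * nll_hat + d * log(n_obs))
    laplace_ok <- FALSE
    warning("Hessian not positive definite for ", data$subject_id[1], "/",
            model_id, "; using -BIC/2 as the evidence", call. = FALSE)
  }
  structure(list(
    subject_id = data$subject_id[1], model_id = model_id,
    estimates = transform_params(par, model_id), par = par,
    log_posterior = log_post, log_likelihood = -nll_hat,
    log_evidence = log_ev, n_restarts_converged = n_conv,
    hessian_log_det = hld, laplace_ok = laplace_ok, converged = TRUE
  ), class = "gng_fit")
}

#' @export
print.gng_fit <- function(x, ...) {
  cat("<gng_fit> subject", x$subject_id, "model", x$model_id, "\n")
  if (!x$converged) { cat("  fit failed: no restart converged\n"); return(invisible(x)) }
  est <- x$estimates
  fmt <- function(p) sprintf("rho=%.3f eps=%.3f b=%.3f pi=%.3f",
                             p$rho, p$epsilon, p$b, p$pi)
  if (x$model_id == "M4") {
    cat("  placebo:", fmt(est$placebo), "\n  drug:   ", fmt(est$drug), "\n")
  } else {
    cat(" ", fmt(est), "\n")
  }
  cat(sprintf("  log posterior %.3f, log evidence %.3f\n",
              x$log_posterior, x$log_evidence))
  invisible(x)
}

# unconstrained M(k) optimum -> start vector for the next model up
nested_init <- function(fit, target_model) {
  if (is.null(fit) || !fit$converged) return(NULL)
  switch(target_model,
         M2 = c(fit$par, 0),
         M3 = c(fit$par, 0),
         M4 = c(fit$par, fit$par),
         NULL)
}

#' Fit a set of models to every subject of a cohort
#'
#' Subjects are fitted independently; within a subject the models are fitted
#' in nesting order and each richer model receives the nested optimum as an
#' additional starting point, so the best negative log-likelihood is
#' monotone over M1 <= ... nesting. With `empirical_bayes = TRUE` the group
#' prior (mean/SD in the unconstrained space) is re-estimated from the
#' subject MAP estimates and the fits repeated, for `n_em` outer iterations.
#'
#' @param data Trial table with one or more subjects.
#' @param models Character vector of model ids in nesting order.
#' @param prior Prior specification.
#' @param n_restarts Restarts per subject and model.
#' @param seed Integer seed.
#' @param empirical_bayes Re-estimate the prior from the cohort (2 passes).
#' @param n_em Number of outer empirical-Bayes iterations.
#' @return A `gng_cohort_fit`: list of `gng_fit` objects plus the prior used.
#' @export
fit_cohort <- function(data, models = c("M1", "M2", "M3"),
                       prior = default_prior(), n_restarts = 10, seed = 1,
                       empirical_bayes = FALSE, n_em = 2) {
  models <- match.arg(models, .model_ids, several.ok = TRUE)
  subjects <- unique(data$subject_id)
  pass <- function(prior_k) {
    fits <- list()
    for (si in seq_along(subjects)) {
      sub <- data[data$subject_id == subjects[si], , drop = FALSE]
      prev <- NULL
      for (m in models) {
        f <- fit_subject(sub, m, prior = prior_k,
                         n_restarts = n_restarts,
                         seed = seed + 1000L * si + match(m, .model_ids),
                         init = nested_init(prev, m))
        fits[[paste(subjects[si], m, sep = ".")]] <- f
        prev <- f
      }
    }
    fits
  }
  fits <- pass(prior)
  if (empirical_bayes) {
    for (it in seq_len(n_em)) {
      # moment-match the unconstrained MAP estimates of the largest model
      m_top <- models[length(models)]
      X <- do.call(rbind, lapply(fits[grepl(paste0("\\.", m_top, "$"), names(fits))],
                                 `[[`, "par"))
      d <- min(ncol(X), 4L)
      prior$mean[seq_len(d)] <- colMeans(X)[seq_len(d)]
      prior$sd[seq_len(d)] <- pmax(apply(X, 2, sd)[seq_len(d)], 0.25)
      fits <- pass(prior)
    }
  }
  structure(list(fits = fits, models = models, subjects = subjects,
                 prior = prior), class = "gng_cohort_fit")
}

#' Tidy table of cohort fits
#' @param cohort_fit A `gng_cohort_fit`.
#' @return Tibble: subject_id, model_id, parameter, session, estimate,
#'   log_posterior, log_evidence.
#' @export
fits_table <- function(cohort_fit) {
  rows <- lapply(cohort_fit$fits, function(f) {
    if (!f$converged) return(NULL)
    one <- function(p, sess) {
      tibble::tibble(subject_id = f$subject_id, model_id = f$model_id,
                     session = sess,
                     parameter = c("rho", "epsilon", "b", "pi"),
                     estimate = c(p$rho, p$epsilon, p$b, p$pi),
                     log_posterior = f$log_posterior,
                     log_evidence = f$log_evidence)
    }
    if (f$model_id == "M4") {
      dplyr::bind_rows(one(f$estimates$placebo, "placebo"),
                       one(f$estimates$drug, "drug"))
    } else {
      one(f$estimates, "both")
    }
  })
  dplyr::bind_rows(rows)
}

#' Subject-by-model log-evidence matrix
#' @param cohort_fit A `gng_cohort_fit` (all fits must have converged).
#' @return Numeric matrix, rownames subjects, colnames models.
#' @export
evidence_matrix <- function(cohort_fit) {
  subj <- cohort_fit$subjects
  mods <- cohort_fit$models
  L <- matrix(NA_real_, length(subj), length(mods),
              dimnames = list(subj, mods))
  for (f in cohort_fit$fits) {
    L[f$subject_id, f$model_id] <- f$log_evidence
  }
  if (any(!is.finite(L))) {
    stop("non-finite log evidence for some subject/model; inspect the fits",
         call. = FALSE)
  }
  L
}

#' Paired drug contrast on each model parameter
#'
#' Two-sided paired Wilcoxon signed-rank test of the drug-session versus
#' placebo-session estimates from M4 fits, one test per parameter.
#'
#' @param cohort_fit A `gng_cohort_fit` containing M4 fits, or the output of
#'   [fits_table()] restricted to M4.
#' @return Tibble: parameter, mean_placebo, mean_drug, mean_diff
#'   (drug - placebo), statistic, p_value.
#' @export
drug_contrast <- function(cohort_fit) {
  tab <- if (inherits(cohort_fit, "gng_cohort_fit")) fits_table(cohort_fit) else cohort_fit
  tab <- tab[tab$model_id == "M4", , drop = FALSE]
  if (nrow(tab) == 0) stop("no M4 fits found", call. = FALSE)
  out <- lapply(c("rho", "epsilon", "b", "pi"), function(par) {
    w <- tab[tab$parameter == par, ]
    pla <- w$estimate[w$session == "placebo"][order(w$subject_id[w$session == "placebo"])]
    drg <- w$estimate[w$session == "drug"][order(w$subject_id[w$session == "drug"])]
    ht <- wilcox.test(drg, pla, paired = TRUE, exact = FALSE)
    tibble::tibble(parameter = par,
                   mean_placebo = mean(pla), mean_drug = mean(drg),
                   mean_diff = mean(drg - pla),
                   statistic = unname(ht$statistic), p_value = ht$p.value)
  })
  dplyr::bind_rows(out)
}
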