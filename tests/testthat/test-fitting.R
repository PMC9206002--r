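test_that("parameter transform is the documented bijection", {
  p <- transform_params(c(0, 0, 0, 0), "M3")
  expect_equal(p$rho, 1)
  expect_equal(p$epsilon, 0.5)
  expect_equal(p$b, 0)
  expect_equal(p$pi, 0)
  for (seed in 1:5) {
    x <- withr::with_seed(seed, rnorm(4, 0, 1.5))
    expect_equal(untransform_params(transform_params(x, "M3"), "M3"), x,
                 tolerance = 1e-12)
  }
  x8 <- withr::with_seed(6, rnorm(8))
  dual <- transform_params(x8, "M4")
  expect_named(dual, c("placebo", "drug"))
  expect_equal(untransform_params(dual, "M4"), x8, tolerance = 1e-12)
  # saturation guard keeps epsilon strictly inside (0, 1)
  expect_gt(transform_params(c(0, -40), "M1")$epsilon, 0)
  expect_lt(transform_params(c(0, 40), "M1")$epsilon, 1)
  expect_error(transform_params(c(0, 0), "M3"), "expected 4")
})

test_that("MAP fitting recovers generating M3 parameters within broad bounds", {
  truth <- param_set(2, 0.3, b = 0.3, pi = 0.8)
  fits <- lapply(c(100, 110, 120), function(s) {
    d <- sim_two_sessions(truth, s)
    fit_subject(d, "M3", n_restarts = 10, seed = 1)
  })
  expect_true(all(vapply(fits, `[[`, logical(1), "converged")))
  expect_true(all(vapply(fits, `[[`, integer(1), "n_restarts_converged") > 5))
  err <- function(par, true) mean(abs(vapply(fits, function(f)
    f$estimates[[par]], numeric(1)) - true))
  expect_lt(err("rho", truth$rho), 1.2)
  expect_lt(err("epsilon", truth$epsilon), 0.2)
  expect_lt(err("b", truth$b), 0.5)
  expect_lt(err("pi", truth$pi), 0.6)
  # optimizer dominance: fitted NLL no worse than at the generating values
  d <- sim_two_sessions(truth, 100)
  f <- fits[[1]]
  expect_lte(-f$log_likelihood, negative_log_likelihood(truth, d, "M3") + 1e-6)
  # deterministic given identical inputs
  f2 <- fit_subject(d, "M3", n_restarts = 10, seed = 1)
  expect_equal(f$par, f2$par)
  expect_equal(f$log_evidence, f2$log_evidence)
})

test_that("M4 fitted to drug-identical data gives matching parameter sets", {
  truth <- param_set(2.5, 0.25, 0.2, 0.6)
  d <- sim_two_sessions(truth, 200)
  f3 <- fit_subject(d, "M3", n_restarts = 5, seed = 2)
  f4 <- fit_subject(d, "M4", n_restarts = 5, seed = 2,
                    init = c(f3$par, f3$par))
  expect_lt(abs(f4$estimates$placebo$pi - f4$estimates$drug$pi), 0.5)
  expect_lt(abs(f4$estimates$placebo$b - f4$estimates$drug$b), 0.5)
  # degenerate split can only improve the likelihood
  expect_lte(-f4$log_likelihood, -f3$log_likelihood + 1e-4)
})

test_that("fit quality is monotone over the nested model chain", {
  truth <- param_set(3, 0.25, 0.3, 0.7)
  d <- sim_two_sessions(truth, 300)
  cf <- fit_cohort(d, models = c("M1", "M2", "M3", "M4"), n_restarts = 4,
                   seed = 3)
  nll <- vapply(cf$fits, function(f) -f$log_likelihood, numeric(1))
  ids <- vapply(cf$fits, `[[`, character(1), "model_id")
  expect_lte(nll[ids == "M2"], nll[ids == "M1"] + 1e-4)
  expect_lte(nll[ids == "M3"], nll[ids == "M2"] + 1e-4)
  expect_lte(nll[ids == "M4"], nll[ids == "M3"] + 1e-4)
})

test_that("Laplace evidence penalizes the superfluous bias parameter", {
  # data generated from M2 (pi = 0): M2 should usually beat M3 in evidence
  wins <- 0
  for (s in 1:8) {
    truth <- withr::with_seed(s, param_set(exp(rnorm(1, 1, 0.3)),
                                           plogis(rnorm(1, -1, 0.4)),
                                           rnorm(1, 0.2, 0.3)))
    d <- sim_two_sessions(truth, 400 + s, model_id = "M2")
    f2 <- fit_subject(d, "M2", n_restarts = 4, seed = s)
    f3 <- fit_subject(d, "M3", n_restarts = 4, seed = s, init = c(f2$par, 0))
    if (f2$log_evidence >= f3$log_evidence) wins <- wins + 1
  }
  expect_gte(wins, 5)
})

test_that("cohort fit table and evidence matrix are consistent", {
  truth <- param_set(2.5, 0.3, 0.2, 0.5)
  d <- rbind(sim_two_sessions(truth, 500, subject_id = "A"),
             sim_two_sessions(truth, 510, subject_id = "B"))
  cf <- fit_cohort(d, models = c("M1", "M2"), n_restarts = 3, seed = 4)
  tab <- fits_table(cf)
  expect_setequal(unique(tab$subject_id), c("A", "B"))
  expect_equal(nrow(tab), 2 * 2 * 4)  # 2 subjects x 2 models x 4 parameters
  L <- evidence_matrix(cf)
  expect_equal(dim(L), c(2, 2))
  expect_true(all(is.finite(L)))
  expect_equal(L["A", "M1"],
               tab$log_evidence[tab$subject_id == "A" & tab$model_id == "M1"][1])
})

test_that("drug contrast reports a paired Wilcoxon test per parameter", {
  truth <- param_set(2.5, 0.3, 0.2, 0.8)
  d <- dplyr::bind_rows(lapply(1:6, function(i) {
    sim_two_sessions(truth, 600 + 10 * i, subject_id = sprintf("S%02d", i),
                     pi_drug = 0.1)
  }))
  cf <- fit_cohort(d, models = c("M3", "M4"), n_restarts = 3, seed = 5)
  ct <- drug_contrast(cf)
  expect_setequal(ct$parameter, c("rho", "epsilon", "b", "pi"))
  expect_true(all(ct$p_value >= 0 & ct$p_value <= 1))
  expect_lt(ct$mean_diff[ct$parameter == "pi"], 0)
})
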