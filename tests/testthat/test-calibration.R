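# noise-free tables with an exact, known residual pattern on the objective
# (log10) scale: value = 10^(log10(pred + 1) + shift) - 1 gives residual
# -shift at every point
shifted_obs <- function(tissues, shift, design = study_design(cv = 0)) {
  design$tissues <- tissues
  obs <- generate_observations(p_sc, sched, design, seed = 1)
  obs$value <- 10^(log10(obs$value + 1) + shift) - 1
  obs
}

truth5 <- setNames(as.numeric(p_sc[c("k9", "k12", "k13", "kmat_3", "Vmax")]),
                   c("k9", "k12", "k13", "kmat_3", "Vmax"))

test_that("the objective matches its closed form for constant residuals", {
  r <- 0.4
  obs <- shifted_obs("spleen", -r)
  n <- nrow(obs)
  expect_equal(neg2ll(truth5, obs, p_sc, sched),
               n * (1 + log(2 * pi * r^2)), tolerance = 1e-10)
})

test_that("the objective is additive over observed variables", {
  r <- 0.25
  both <- shifted_obs(c("spleen", "blood"), -r)
  one <- shifted_obs("spleen", -r)
  expect_equal(neg2ll(truth5, both, p_sc, sched),
               2 * neg2ll(truth5, one, p_sc, sched), tolerance = 1e-8)
})

test_that("scaling one variable's residuals shifts the objective by n log c^2", {
  obs1 <- shifted_obs("spleen", -0.2)
  obs3 <- shifted_obs("spleen", -0.6) # residuals scaled by c = 3
  n <- nrow(obs1)
  expect_equal(neg2ll(truth5, obs3, p_sc, sched) -
                 neg2ll(truth5, obs1, p_sc, sched),
               n * log(9), tolerance = 1e-8)
})

test_that("the objective ignores the ordering of observations", {
  obs <- generate_observations(p_sc, sched, study_design(), seed = 5)
  perm <- obs[sample(nrow(obs)), ]
  expect_equal(neg2ll(truth5, perm, p_sc, sched),
               neg2ll(truth5, obs, p_sc, sched), tolerance = 1e-12)
})

test_that("unknown names in the value vector are rejected", {
  obs <- shifted_obs("spleen", -0.1)
  expect_error(neg2ll(c(bogus = 1), obs, p_sc, sched), "named")
})

test_that("an all-fixed fit returns the inits after one evaluation", {
  obs <- shifted_obs("spleen", -0.1)
  f <- fit_asc_model(obs, fixed = names(truth5), params = p_sc)
  expect_equal(f$estimates, truth5)
  expect_equal(f$evaluations, 1L)
  expect_length(f$fitted_names, 0)
})

test_that("noise-free data started at truth is recovered to 1e-3", {
  obs <- generate_observations(p_sc, sched, study_design(cv = 0), seed = 1)
  f <- fit_asc_model(obs, params = p_sc, hessian = FALSE)
  rel <- abs(f$estimates / truth5 - 1)
  expect_lt(max(rel), 1e-3)
})

test_that("a noisy fit recovers truth with finite identifiability metrics", {
  f <- noisy_fit7()$fit
  expect_equal(f$convergence, 0L)
  expect_true(all(abs(f$estimates / truth5 - 1) < 0.25))
  expect_true(all(is.finite(f$rse)) && all(f$rse > 0))
  # covariance symmetric PSD
  expect_equal(f$cov, t(f$cov))
  expect_true(all(eigen(f$cov, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-10))
  expect_output(print(f), "-2LL")
})

test_that("likelihood profile is minimal at the estimate and brackets it", {
  obs <- generate_observations(p_sc, sched, study_design(), seed = 11)
  f <- fit_asc_model(obs, params = p_sc, hessian = FALSE)
  pr <- profile_likelihood(f, obs, "Vmax", n_grid = 7, fold = 3)
  expect_equal(pr$grid[which.min(pr$minus2LL)], f$estimates[["Vmax"]],
               tolerance = 0.05)
  expect_gte(min(pr$minus2LL), f$minus2LL - 0.05)
  expect_true(pr$ci[1] <= f$estimates[["Vmax"]] &&
                f$estimates[["Vmax"]] <= pr$ci[2])
  expect_output(print(pr), "95% CI")
})

test_that("uncertainty bands collapse when the covariance is zero", {
  f0 <- noisy_fit7()$fit
  f0$cov <- matrix(0, 5, 5, dimnames = list(f0$fitted_names, f0$fitted_names))
  ub <- uncertainty_bands(f0, n_samples = 20, seed = 1, t_end = 50)
  expect_equal(ub$bands$ASCBone[, "lower"], ub$bands$ASCBone[, "upper"],
               ignore_attr = TRUE)
  expect_equal(ub$bands$ASCBone[, "median"], ub$point[, "ASCBone"],
               ignore_attr = TRUE)
})

test_that("uncertainty bands are seed-reproducible and centred", {
  f <- noisy_fit7()$fit
  u1 <- uncertainty_bands(f, n_samples = 60, seed = 3, t_end = 120, dt_out = 5)
  u2 <- uncertainty_bands(f, n_samples = 60, seed = 3, t_end = 120, dt_out = 5)
  expect_identical(u1$bands, u2$bands)
  # median trajectory tracks the point trajectory within Monte-Carlo error
  i200 <- length(u1$time)
  expect_equal(u1$bands$ASCBone[i200, "median"],
               u1$point[i200, "ASCBone"], tolerance = 0.1,
               ignore_attr = TRUE)
})

test_that("multi-start draws are seed-reproducible", {
  obs <- noisy_fit7()$obs
  m1 <- multistart_fit(obs, n_starts = 2, seed = 4, params = p_sc,
                       hessian = FALSE)
  m2 <- multistart_fit(obs, n_starts = 2, seed = 4, params = p_sc,
                       hessian = FALSE)
  expect_identical(m1$starts, m2$starts)
  expect_equal(m1$fits[[1]]$estimates, m2$fits[[1]]$estimates)
  m3 <- multistart_fit(obs, n_starts = 2, seed = 5, params = p_sc,
                       hessian = FALSE)
  expect_false(identical(m1$starts, m3$starts))
  expect_error(multistart_fit(obs, n_starts = 1), "n_starts")
})

test_that("degenerate bone-marrow data drives Vmax to the lower bound", {
  obs <- generate_observations(p_sc, sched,
                               study_design(tissues = "bone_marrow", cv = 0),
                               seed = 1)
  obs$value <- 0
  res <- fit_vmax_per_study(list(obs), params = p_sc)
  expect_true(res$at_bound[1])
  expect_lt(res$Vmax[1], 0.1)
})
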