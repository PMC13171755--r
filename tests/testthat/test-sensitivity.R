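test_that("eFAST recovers analytic variance shares of a linear function", {
  # y = 2 x1 + 1 x2 + 0.5 x3 (+ inert x4); Var share_i = a_i^2 / sum a^2
  a <- c(2, 1, 0.5, 0)
  fn <- function(X) X %*% a
  res <- efast_indices(fn, n_factors = 4, n_samples = 1000, seed = 2)
  shares <- a^2 / sum(a^2)
  expect_equal(res$first_order, shares, tolerance = 0.05)
  expect_equal(res$total_order, shares, tolerance = 0.05)
  # insensitivity control: inert factor has near-zero indices
  expect_lt(res$first_order[4], 0.01)
  expect_lt(res$total_order[4], 0.02)
  # total >= first within estimator noise
  expect_true(all(res$total_order >= res$first_order - 0.02))
})

test_that("eFAST rejects sample sizes below the method minimum", {
  expect_error(efast_indices(function(X) X[, 1], 2, n_samples = 30), "65")
})

test_that("eFAST runs are seed-reproducible", {
  fn <- function(X) X[, 1]^2 + X[, 2]
  r1 <- efast_indices(fn, 2, n_samples = 200, seed = 9)
  r2 <- efast_indices(fn, 2, n_samples = 200, seed = 9)
  expect_identical(r1, r2)
})

test_that("the unit multiplier of a local sweep reproduces the baseline", {
  sw <- local_sweep(p_sc, "Vmax", multipliers = c(0.8, 1, 1.2),
                    t_end = 120, dt_out = 2)
  base <- simulate_response(p_sc, sched, t_end = 120, dt_out = 2)
  expect_equal(sw$curves[, , 2], base$state[, colnames(sw$curves)])
  expect_error(local_sweep(p_sc, "k1"), "must be one of")
})

test_that("a Vmax sweep moves the bone-marrow plateau proportionally", {
  sw <- local_sweep(p_sc, "Vmax", multipliers = c(0.8, 1, 1.2),
                    t_end = 200, dt_out = 5)
  d200 <- sw$curves[dim(sw$curves)[1], "ASCBone", ]
  # day-200 level approximately linear in the multiplier
  expect_equal(unname(d200[3] / d200[2]), 1.2, tolerance = 0.02)
  expect_equal(unname(d200[1] / d200[2]), 0.8, tolerance = 0.02)
})

test_that("tornado with zero perturbation reports zero effects", {
  tor <- tornado(p_sc, metric = "day200", delta = 0, t_end = 150)
  expect_true(all(abs(tor$rel_low) < 1e-10))
  expect_true(all(abs(tor$rel_high) < 1e-10))
})

test_that("tornado endpoints agree with the sweep endpoints", {
  tor <- tornado(p_sc, metric = "day200", delta = 0.2, t_end = 200)
  sw <- local_sweep(p_sc, "kmat_3", multipliers = c(0.8, 1.2),
                    t_end = 200, dt_out = 1)
  i200 <- which(sw$time == 200)
  row <- tor[tor$parameter == "kmat_3" & tor$state == "ASCSpleen", ]
  expect_equal(row$low, unname(sw$curves[i200, "ASCSpleen", 1]),
               tolerance = 1e-8)
  expect_equal(row$high, unname(sw$curves[i200, "ASCSpleen", 2]),
               tolerance = 1e-8)
})

test_that("a dummy factor in the model eFAST is inert", {
  e <- efast(p_sc, parameters = c("Vmax", "k12", "dummy"), n_samples = 100,
             metrics = "day200", states = "ASCBone", t_end = 150, seed = 3)
  expect_lt(e$first_order[e$parameter == "dummy"], 0.03)
  expect_true(all(e$first_order >= 0 & e$first_order <= 1))
  expect_true(all(e$total_order >= -0.02 & e$total_order <= 1))
})
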