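test_that("initial state places homeostasis at the observed counts", {
  y <- initial_state(p_paper, 0)
  expect_equal(unname(y["NaiveSpleen"]), 24.30e6)
  expect_equal(unname(y["ASCBone"]), 0)
  expect_equal(unname(y["IgGBlood"]), 0)
  expect_equal(unname(initial_state(p_paper, 3.5)["Antigen0"]), 3.5)
  expect_length(y, 20)
  expect_error(initial_state(p_paper, -1), "antigen_dose")
})

test_that("the derivative vanishes at the self-consistent steady state", {
  d <- asc_rhs(0, initial_state(p_sc, 0), p_sc, zero_schedule())
  counts <- as.numeric(p_sc[ss_names])
  expect_true(all(abs(d[1:7]) < 1e-9 * counts))
  expect_true(all(d[8:20] == 0))
})

test_that("bone-marrow influx saturates at Vmax and halves at Khalf", {
  y <- initial_state(p_sc, 0)
  y["ASCBlood"] <- 1e6 * p_sc[["Khalf"]]
  d <- asc_rhs(0, y, p_sc, zero_schedule())
  influx <- d[["ASCBone"]]
  expect_equal(influx, p_sc[["Vmax"]], tolerance = 1e-5)
  y["ASCBlood"] <- p_sc[["Khalf"]]
  d <- asc_rhs(0, y, p_sc, zero_schedule())
  expect_equal(d[["ASCBone"]], p_sc[["Vmax"]] / 2, tolerance = 1e-12)
})

test_that("compiled and R right-hand sides agree along a trajectory", {
  tc <- simulate_response(p_sc, sched, t_end = 100, dt_out = 1)
  tr <- simulate_response(p_sc, sched, t_end = 100, dt_out = 1, engine = "r")
  expect_lt(max(abs(tc$state - tr$state) / (abs(tc$state) + 1)), 1e-6)
})

test_that("unstimulated simulation holds the steady state for 350 days", {
  tr <- simulate_response(p_sc, zero_schedule(), t_end = 350, dt_out = 5)
  drift <- abs(tr$state[nrow(tr$state), 1:7] / tr$state[1, 1:7] - 1)
  expect_lt(max(drift), 1e-3)
  expect_true(all(tr$state[, c("ASCSpleen", "ASCLN", "ASCBlood",
                               "ASCBone", "IgGBlood")] == 0))
})

test_that("states remain non-negative along the default response", {
  tr <- default_sim()
  # tiny solver-tolerance undershoots (~1e-5 cells) are acceptable
  expect_true(all(tr$state > -1e-3))
})

test_that("no niche influx means no bone-marrow ASC", {
  p <- build_parameters(list(Vmax = 0), mode = "self_consistent")
  tr <- simulate_response(p, sched, t_end = 100, dt_out = 1)
  expect_true(all(abs(tr$state[, "ASCBone"]) < 1e-6))
})

test_that("ASC mass is conserved: cumulative generation equals the pool", {
  tr <- default_sim()
  pf <- p_sc[["precursor_frequency"]]
  gen <- p_sc[["kmat_3"]] * pf *
    (tr$state[, "NaiveSpleen"] + tr$state[, "NaiveLN"]) * tr$state[, "Antigen"]
  cum <- cumsum((head(gen, -1) + tail(gen, -1)) / 2 * diff(tr$time))
  pool <- rowSums(tr$state[, c("ASCSpleen", "ASCLN", "ASCBlood",
                               "ASCBone", "ASCPeripheral")])
  expect_lt(max(abs(cum - pool[-1])) / max(pool), 1e-4)
})

test_that("bone-marrow ASC never exceed the saturated-influx envelope", {
  tr <- default_sim()
  k12 <- p_sc[["k12"]]
  cap <- p_sc[["Vmax"]] / k12 * (1 - exp(-k12 * tr$time))
  expect_true(all(tr$state[, "ASCBone"] <= cap * (1 + 1e-6) + 1e-6))
})

test_that("solver rejects bad grids and reports settings on failure", {
  expect_error(simulate_response(p_sc, sched, t_end = -1), "t_end")
  expect_error(simulate_response(p_sc, sched, times = c(1, 2)), "times")
  expect_error(simulate_response(p_sc, sched, times = c(0, 2, 2)), "times")
})

test_that("trajectories export to tidy long format and CSV", {
  tr <- simulate_response(p_sc, sched, t_end = 5, dt_out = 1)
  df <- as.data.frame(tr)
  expect_named(df, c("time", "state", "value"))
  expect_equal(nrow(df), length(tr$time) * 20)
  f <- tempfile(fileext = ".csv")
  write_trajectory(tr, f)
  back <- read.csv(f)
  expect_equal(nrow(back), nrow(df))
  unlink(f)
  expect_output(print(tr), "asc_trajectory")
})
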