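test_that("tissue scaling applies the whole-animal conventions", {
  expect_equal(apply_tissue_scaling(1000, "bone_marrow"), 7900)
  expect_equal(apply_tissue_scaling(1000, "lymph_nodes"), 22000)
  expect_equal(apply_tissue_scaling(1000, "spleen"), 1000)
  expect_error(apply_tissue_scaling(1, "kidney"), "unknown tissue")
  expect_error(apply_tissue_scaling(-1, "spleen"), ">= 0")
  # linear and invertible
  conv <- scaling_conventions()
  x <- c(0, 12.5, 1e5)
  expect_equal(apply_tissue_scaling(x, "bone_marrow", conv) /
                 conv$femur_factor, x)
})

test_that("peak summary takes the earliest maximum on the grid", {
  up <- fake_traj(0:350, 0:350)
  expect_equal(peak_summary(up, "ASCLN"), c(Cmax = 350, Tmax = 350))
  flat <- fake_traj(0:10, rep(4, 11))
  expect_equal(peak_summary(flat, "ASCLN"), c(Cmax = 4, Tmax = 0))
  expect_error(peak_summary(up, "NotAState"), "unknown state")
})

test_that("peak time is stable under grid refinement", {
  t1 <- simulate_response(p_sc, sched, t_end = 60, dt_out = 1)
  t2 <- simulate_response(p_sc, sched, t_end = 60, dt_out = 0.25)
  for (s in c("ASCSpleen", "ASCLN")) {
    expect_lte(abs(peak_summary(t1, s)[["Tmax"]] -
                     peak_summary(t2, s)[["Tmax"]]), 1)
  }
})

test_that("max-normalization is idempotent and scale-invariant", {
  expect_equal(normalize_to_max(c(2, 4, 8)), c(0.25, 0.5, 1))
  expect_equal(normalize_to_max(c(0.25, 0.5, 1)), c(0.25, 0.5, 1))
  expect_equal(normalize_to_max(5), 1)
  expect_equal(normalize_to_max(c(1, 3, 7) * 42), normalize_to_max(c(1, 3, 7)))
  expect_error(normalize_to_max(c(0, 0)), "maximum")
})

test_that("goodness-of-fit statistics follow the weighted-residual rules", {
  g <- gof_stats(c(2, 0), c(1, 1), sigma = 1)
  expect_equal(g$wres, c(1, -1))
  expect_equal(g$frac_wres_within_2, 1)
  expect_equal(gof_stats(1:5, 1:5, sigma = 1)$rmse, 0)
  expect_equal(gof_stats(3, 0, sigma = 1)$frac_wres_within_2, 0)
  expect_error(gof_stats(1, 0, sigma = 0), "sigma")
  expect_silent(gof_stats(1, 1, sigma = 0)) # zero residual is fine
})

test_that("observation tables are validated and round-trip via CSV", {
  obs <- data.frame(study = "s1", tissue = "spleen", day = c(7, 14),
                    value = c(10, 20))
  v <- as_observation_table(obs)
  expect_true(all(c("error", "scaled") %in% names(v)))
  expect_error(as_observation_table(data.frame(study = 1)), "columns")
  obs$tissue <- "brain"
  expect_error(as_observation_table(obs), "unknown tissue")
  obs$tissue <- "spleen"; obs$day <- c(-1, 1)
  expect_error(as_observation_table(obs), ">= 0")

  tab <- generate_observations(p_sc, sched, study_design(cv = 0.2), seed = 2)
  f <- tempfile(fileext = ".csv")
  write_observations(tab, f)
  back <- read_observations(f)
  expect_equal(back$value, tab$value)
  expect_equal(back$tissue, tab$tissue)
  unlink(f)
})
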