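test_that("zero-noise observations equal the model predictions exactly", {
  des <- study_design(cv = 0)
  obs <- generate_observations(p_sc, sched, des, seed = 1)
  tr <- simulate_response(p_sc, sched, times = sort(unique(c(0, des$days))))
  for (i in seq_len(nrow(obs))) {
    st <- switch(obs$tissue[i], spleen = "ASCSpleen",
                 lymph_nodes = "ASCLN", bone_marrow = "ASCBone",
                 blood = "ASCBlood")
    expect_equal(obs$value[i], state_at(tr, st, obs$day[i]), tolerance = 1e-12)
  }
  expect_true(all(obs$error == 0))
})

test_that("generation is reproducible under a fixed seed", {
  o1 <- generate_observations(p_sc, sched, study_design(), seed = 33)
  o2 <- generate_observations(p_sc, sched, study_design(), seed = 33)
  expect_identical(o1$value, o2$value)
  o3 <- generate_observations(p_sc, sched, study_design(), seed = 34)
  expect_false(identical(o1$value, o3$value))
})

test_that("replicate noise follows the delta-method standard error", {
  # SE of the mean of n lognormal replicates ~ cv * mu / sqrt(n)
  des <- study_design(days = seq(10, 200, by = 5), tissues = "lymph_nodes",
                      cv = 0.3, n_replicates = 5)
  obs <- generate_observations(p_sc, sched, des, seed = 21)
  keep <- obs$value > 0
  ratio <- obs$error[keep] / (0.3 * obs$value[keep] / sqrt(5))
  expect_gt(mean(ratio), 0.7)
  expect_lt(mean(ratio), 1.3)
})

test_that("ground truth is carried with the table and serializable", {
  obs <- generate_observations(p_sc, sched, study_design(), seed = 2)
  truth <- attr(obs, "truth")
  expect_equal(truth$params[["Vmax"]], p_sc[["Vmax"]])
  expect_equal(truth$seed, 2)
  f <- tempfile(fileext = ".json")
  write_ground_truth(obs, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$params[["Vmax"]], p_sc[["Vmax"]])
  unlink(f)
  expect_error(write_ground_truth(data.frame(), f), "no ground truth")
})

test_that("multi-study generation orders bone-marrow plateaus by Vmax", {
  studies <- generate_multistudy(c(26.66, 490.6, 836), p_sc, sched,
                                 study_design(cv = 0.1), seed = 5)
  d200 <- vapply(studies, function(s)
    s$value[s$tissue == "bone_marrow" & s$day == 200], numeric(1))
  expect_true(all(diff(d200) > 0))
  ids <- vapply(studies, function(s) s$study[1], character(1))
  expect_equal(ids, c("study_1", "study_2", "study_3"))
  expect_error(generate_multistudy(c(10, -1)), "> 0")
})

test_that("a single-study list reduces to the plain generator", {
  s1 <- generate_multistudy(p_sc[["Vmax"]], p_sc, sched,
                            study_design(), seed = 8)[[1]]
  s2 <- generate_observations(p_sc, sched, study_design(), seed = 8)
  expect_equal(s1$value, s2$value)
})

test_that("designs are validated", {
  expect_error(study_design(days = c(-1, 5)), "within")
  expect_error(study_design(days = 400), "within")
  expect_error(study_design(cv = -0.1), "magnitude")
  expect_error(study_design(tissues = "liver"), "unknown tissue")
})
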