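# shared fixtures, built once per test run

p_sc <- build_parameters(mode = "self_consistent")
p_paper <- build_parameters(mode = "paper")
sched <- antigen_schedule()

ss_names <- c("ImmBone_ss", "T1Bone_ss", "T1Blood_ss", "T1Spleen_ss",
              "NaiveSpleen_ss", "NaiveBlood_ss", "NaiveLN_ss")

# interpolate a trajectory state at arbitrary times (test-local copy)
state_at <- function(traj, state, at) {
  stats::approx(traj$time, traj$state[, state], xout = at, rule = 2)$y
}

# a small trajectory object with arbitrary content, for summary-statistic
# tests that do not need the solver
fake_traj <- function(time, values, state = "ASCLN") {
  m <- matrix(0, length(time), 20,
              dimnames = list(NULL, asc_state_names()))
  m[, state] <- values
  structure(list(time = time, state = m,
                 solver = list(engine = "none")),
            class = "asc_trajectory")
}

# a noisy synthetic study and its fit, cached (several tests reuse it)
noisy_fit7 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      obs <- generate_observations(p_sc, sched, study_design(), seed = 7)
      cache <<- list(obs = obs,
                     fit = fit_asc_model(obs, params = p_sc, seed = 7))
    }
    cache
  }
})

# default-forcing reference simulation, cached across test files
default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_response(p_sc, sched,
                                                    t_end = 350, dt_out = 0.1)
    cache
  }
})
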