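.activation_params <- c("k9", "k12", "k13", "kmat_3", "Vmax")
.asc_states <- c("ASCSpleen", "ASCLN", "ASCBlood", "ASCBone")

# metric of a trajectory for one state: peak count or the day-200 value
.traj_metric <- function(traj, state, metric) {
  switch(metric,
         Cmax = unname(peak_summary(traj, state)["Cmax"]),
         day200 = .state_at(traj, state, 200),
         stop("unknown metric: ", metric))
}

#' Local sensitivity sweep: family of curves for one parameter
#'
#' Simulates the model with the chosen parameter scaled by evenly spaced
#' multipliers in \code{[1 - span, 1 + span]} and returns the full ASC
#' trajectories of each curve.
#'
#' @param params baseline \code{asc_parameters}.
#' @param parameter one of the activation parameters
#'   (k9, k12, k13, kmat_3, Vmax).
#' @param span relative half-range (default 0.2, i.e. +/-20%).
#' @param n_curves number of curves (evenly spaced multipliers).
#' @param multipliers optional explicit multipliers (overrides
#'   \code{span}/\code{n_curves}).
#' @param t_end,dt_out simulation window, days.
#' @param schedule antigen schedule.
#' @param states states to keep.
#' @return list with \code{time}, \code{multipliers} and \code{curves}, an
#'   array time x state x curve.
#' @export
local_sweep <- function(params, parameter, span = 0.2, n_curves = 10,
                        multipliers = NULL, t_end = 350, dt_out = 1,
                        schedule = antigen_schedule(),
                        states = .asc_states) {
  if (!parameter %in% .activation_params)
    stop("parameter must be one of: ",
         paste(.activation_params, collapse = ", "))
  if (is.null(multipliers))
    multipliers <- seq(1 - span, 1 + span, length.out = n_curves)
  times <- seq(0, t_end, by = dt_out)
  curves <- array(
    NA_real_,
    dim = c(length(times), length(states), length(multipliers)),
    dimnames = list(NULL, states, paste0("x", signif(multipliers, 4))))
  for (j in seq_along(multipliers)) {
    p <- params
    p[[parameter]] <- params[[parameter]] * multipliers[j]
    tr <- simulate_response(p, schedule, times = times)
    curves[, , j] <- tr$state[, states]
  }
  list(time = times, parameter = parameter, multipliers = multipliers,
       curves = curves)
}

#' One-at-a-time tornado analysis
#'
#' For each activation parameter, the chosen metric (peak count or day-200
#' value) of each ASC state is computed at +delta and -delta relative
#' perturbations and compared with the baseline; parameters are ranked by
#' their largest absolute relative effect.
#'
#' @param params baseline \code{asc_parameters}.
#' @param metric \code{"Cmax"} or \code{"day200"}.
#' @param delta relative perturbation (default 0.2).
#' @param parameters parameters to perturb.
#' @param states states to report.
#' @param schedule,t_end,dt_out simulation settings.
#' @return data.frame with one row per state x parameter: baseline, low,
#'   high metric values, relative changes, and the per-state rank (1 = most
#'   influential).
#' @export
tornado <- function(params, metric = c("Cmax", "day200"), delta = 0.2,
                    parameters = .activation_params,
                    states = .asc_states,
                    schedule = antigen_schedule(), t_end = 350,
                    dt_out = 1) {
  metric <- match.arg(metric)
  times <- seq(0, t_end, by = dt_out)
  base_tr <- simulate_response(params, schedule, times = times)
  base <- vapply(states, function(s) .traj_metric(base_tr, s, metric),
                 numeric(1))
  rows <- list()
  for (pm in parameters) {
    vals <- lapply(c(low = 1 - delta, high = 1 + delta), function(m) {
      p <- params
      p[[pm]] <- params[[pm]] * m
      tr <- simulate_response(p, schedule, times = times)
      vapply(states, function(s) .traj_metric(tr, s, metric), numeric(1))
    })
    for (s in states) {
      b <- base[[s]]
      rel <- function(v) if (b > 0) (v - b) / b else 0
      rows[[length(rows) + 1L]] <- data.frame(
        state = s, parameter = pm, metric = metric, baseline = b,
        low = vals$low[[s]], high = vals$high[[s]],
        rel_low = rel(vals$low[[s]]), rel_high = rel(vals$high[[s]]))
    }
  }
  out <- do.call(rbind, rows)
  out$abs_effect <- pmax(abs(out$rel_low), abs(out$rel_high))
  out <- out[order(out$state, -out$abs_effect), ]
  out$rank <- stats::ave(-out$abs_effect, out$state, FUN = rank)
  rownames(out) <- NULL
  out
}

# ---- eFAST -------------------------------------------------------------

# complementary frequencies: spread k-1 integer frequencies over 1..wc_max
.efast_comp_freqs <- function(k_minus_1, wc_max) {
  if (k_minus_1 == 0) return(integer(0))
  if (wc_max >= k_minus_1)
    unique(round(seq(1, wc_max, length.out = k_minus_1)))[seq_len(k_minus_1)]
  else ((seq_len(k_minus_1) - 1) %% wc_max) + 1
}

#' Low-level eFAST estimator for an arbitrary function
#'
#' Extended Fourier Amplitude Sensitivity Test (interference factor
#' \code{M = 4}, one resampling curve per factor). For each factor a search
#' curve of \code{n_samples} points is generated with that factor assigned
#' the high driving frequency and the others low frequencies; first-order
#' indices come from the spectrum at the driving frequency's harmonics,
#' total-order indices from the complement of the low-frequency band.
#'
#' @param fn function taking a matrix in \code{[0,1]^k} (one row per run)
#'   and returning a numeric vector (one output per row) or a matrix (one
#'   column per output).
#' @param n_factors number of input factors k.
#' @param n_samples points per search curve (must be at least
#'   \code{4 M^2 + 1 = 65}).
#' @param M interference factor.
#' @param seed seed for the random phases.
#' @return data.frame with columns \code{factor}, \code{output},
#'   \code{first_order}, \code{total_order}, \code{n}, \code{seed}.
#' @export
efast_indices <- function(fn, n_factors, n_samples = 1000, M = 4,
                          seed = 1) {
  k <- n_factors
  Ns <- n_samples
  min_ns <- 4 * M^2 + 1
  if (Ns < min_ns)
    stop("n_samples below the eFAST minimum of ", min_ns)
  w_drive <- floor((Ns - 1) / (2 * M))
  wc_max <- max(1, floor(w_drive / (2 * M)))
  s <- pi * (2 * seq_len(Ns) - Ns - 1) / Ns

  set.seed(seed)
  rows <- list()
  for (i in seq_len(k)) {
    w <- numeric(k)
    w[i] <- w_drive
    w[-i] <- .efast_comp_freqs(k - 1, wc_max)
    phi <- stats::runif(k, 0, 2 * pi)
    X <- sapply(seq_len(k), function(j)
      0.5 + asin(sin(w[j] * s + phi[j])) / pi)
    Y <- fn(X)
    if (is.null(dim(Y))) Y <- matrix(Y, ncol = 1)
    if (is.null(colnames(Y)))
      colnames(Y) <- paste0("y", seq_len(ncol(Y)))
    for (out in colnames(Y)) {
      y <- Y[, out]
      m_max <- floor((Ns - 1) / 2)
      mm <- seq_len(m_max)
      A <- vapply(mm, function(m) mean(y * cos(m * s)), numeric(1))
      B <- vapply(mm, function(m) mean(y * sin(m * s)), numeric(1))
      lambda <- 2 * (A^2 + B^2)
      V <- sum(lambda)
      Vi <- sum(lambda[seq_len(M) * w_drive])
      Vci <- sum(lambda[seq_len(floor(w_drive / 2))])
      rows[[length(rows) + 1L]] <- data.frame(
        factor = i, output = out,
        first_order = if (V > 0) Vi / V else 0,
        total_order = if (V > 0) 1 - Vci / V else 0,
        n = Ns, seed = seed)
    }
  }
  do.call(rbind, rows)
}

#' eFAST global sensitivity of the ASC response
#'
#' Activation parameters are sampled from independent uniform distributions
#' within \code{+/- span} of their baseline values along eFAST search
#' curves; for every run the model is simulated over \code{t_end} days and
#' the peak count and day-200 value of each ASC state are recorded.
#'
#' The special factor name \code{"dummy"} adds an input with no effect on
#' the model (an insensitivity control).
#'
#' @param params baseline \code{asc_parameters}.
#' @param parameters factors to analyze (default the five activation
#'   parameters).
#' @param span relative half-range of the uniform ranges (default 0.2).
#' @param n_samples points per search curve (reference analysis: 1000).
#' @param metrics metrics to report.
#' @param states ASC states to report.
#' @param schedule,t_end,dt_out simulation settings.
#' @param M interference factor.
#' @param seed RNG seed for the search-curve phases.
#' @return tidy data.frame: \code{output} (state), \code{metric},
#'   \code{parameter}, \code{first_order}, \code{total_order}, \code{n},
#'   \code{seed}.
#' @export
efast <- function(params, parameters = .activation_params, span = 0.2,
                  n_samples = 1000, metrics = c("Cmax", "day200"),
                  states = .asc_states,
                  schedule = antigen_schedule(), t_end = 350, dt_out = 1,
                  M = 4, seed = 1) {
  times <- seq(0, t_end, by = dt_out)
  real <- setdiff(parameters, "dummy")
  ref <- setNames(as.numeric(params[real]), real)

  fn <- function(X) {
    out <- matrix(NA_real_, nrow(X), length(states) * length(metrics))
    colnames(out) <- as.vector(outer(states, metrics, paste, sep = "."))
    for (r in seq_len(nrow(X))) {
      p <- params
      for (j in seq_along(parameters)) {
        pm <- parameters[j]
        if (pm == "dummy") next
        p[[pm]] <- ref[[pm]] * (1 - span + 2 * span * X[r, j])
      }
      tr <- simulate_response(p, schedule, times = times)
      for (s in states) for (mt in metrics)
        out[r, paste(s, mt, sep = ".")] <- .traj_metric(tr, s, mt)
    }
    out
  }

  res <- efast_indices(fn, n_factors = length(parameters),
                       n_samples = n_samples, M = M, seed = seed)
  res$parameter <- parameters[res$factor]
  oc <- res$output
  res$output <- sub("\\..*$", "", oc)
  res$metric <- sub("^.*\\.", "", oc)
  res[, c("output", "metric", "parameter", "first_order", "total_order",
          "n", "seed")]
}
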