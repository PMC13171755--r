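# residual scale: log10(count + 1) for cell counts (the data span ~5 orders
# of magnitude across tissues), linear for max-normalized IgG
.to_obj_scale <- function(value, is_igg, scale) {
  if (scale == "linear") return(value)
  ifelse(is_igg, value, log10(value + 1))
}

.default_fit_params <- c("k9", "k12", "k13", "kmat_3", "Vmax")
.sigma2_floor <- 1e-20 # sigma floor 1e-10

# predictions matched to obs rows; igg rows are normalized per study to the
# maximum predicted value at that study's igg sampling days (mirroring the
# per-study max-normalization of the data)
.matched_predictions <- function(obs, traj) {
  pred <- .predict_observations(obs, traj)
  igg <- obs$tissue == "igg"
  if (any(igg)) {
    for (st in unique(obs$study[igg])) {
      idx <- igg & obs$study == st
      m <- max(pred[idx])
      if (m > 0) pred[idx] <- pred[idx] / m
    }
  }
  pred
}

# per-variable profiled residual variance and objective pieces
.obj_from_residuals <- function(r, tissue) {
  obj <- 0
  for (v in unique(tissue)) {
    idx <- tissue == v
    s2 <- max(mean(r[idx]^2), .sigma2_floor)
    obj <- obj + sum(r[idx]^2) / s2 + sum(idx) * log(2 * pi * s2)
  }
  obj
}

.sigma_per_variable <- function(r, tissue) {
  vapply(split(r, tissue), function(ri) sqrt(max(mean(ri^2), .sigma2_floor)),
         numeric(1))
}

# apply fitted values to a parameter set, honouring the structural
# assumption k14 == k12 (peripheral egress mirrors bone-marrow egress)
# whenever k12 moves and k14 is not itself being varied
.apply_fit_values <- function(params, values) {
  params[names(values)] <- values
  if ("k12" %in% names(values) && !"k14" %in% names(values))
    params[["k14"]] <- params[["k12"]]
  params
}

# closure evaluating -2LL at natural-scale values of the fitted parameters
.make_objective <- function(data, params, schedule, fitted,
                            scale = "log10") {
  obs <- as_observation_table(data)
  days <- sort(unique(c(0, obs$day)))
  is_igg <- obs$tissue == "igg"
  obs_scaled <- .to_obj_scale(obs$value, is_igg, scale)
  function(values) {
    p <- .apply_fit_values(params, setNames(values, fitted))
    traj <- tryCatch(
      simulate_response(p, schedule, times = days),
      error = function(e) NULL
    )
    if (is.null(traj)) return(list(value = 1e12, sigma = NULL))
    pred <- .matched_predictions(obs, traj)
    r <- obs_scaled - .to_obj_scale(pred, is_igg, scale)
    list(value = .obj_from_residuals(r, obs$tissue),
         sigma = .sigma_per_variable(r, obs$tissue),
         residuals = r)
  }
}

#' -2 log-likelihood with profiled residual variance
#'
#' Residuals are observed minus predicted on the configured scale
#' (log10(count + 1) for cell counts, linear for normalized IgG). The
#' residual SD of each observed variable is profiled out analytically,
#' \code{sigma_v^2 = sum(r^2)/n_v}, giving the objective
#' \code{sum_v [ sum(r^2)/sigma_v^2 + n_v log(2 pi sigma_v^2) ]}. A variance
#' floor of 1e-20 guards perfect fits.
#'
#' @param values named vector of natural-scale values for the fitted
#'   parameters (any subset of the parameter names).
#' @param data observation table (see \code{\link{as_observation_table}}).
#' @param params baseline \code{asc_parameters} supplying all non-fitted
#'   values.
#' @param schedule \code{antigen_schedule} used for the predictions.
#' @param scale \code{"log10"} (default) or \code{"linear"}.
#' @return the objective value (numeric scalar).
#' @examples
#' \donttest{
#' p <- build_parameters(mode = "self_consistent")
#' obs <- generate_observations(p, seed = 1)
#' neg2ll(c(Vmax = 490.6), obs, p)
#' }
#' @export
neg2ll <- function(values, data, params = build_parameters(mode = "self_consistent"),
                   schedule = antigen_schedule(), scale = c("log10", "linear")) {
  scale <- match.arg(scale)
  if (is.null(names(values)) || !all(names(values) %in% parameter_names()))
    stop("values must be named with known parameter names")
  f <- .make_objective(data, params, schedule, names(values), scale)
  f(values)$value
}

#' Maximum-likelihood fit of the activation parameters
#'
#' Nelder-Mead minimization of the profiled -2LL on log-transformed
#' parameters (guaranteeing positivity), with one restart from the
#' incumbent. Whenever \code{k12} is varied (and \code{k14} is not), the
#' structural assumption \code{k14 == k12} is maintained inside the
#' objective: the peripheral egress rate is defined by that equality, so it
#' must follow the estimate rather than stay at its tabulated value.
#' The covariance matrix of the log-scale estimates is the
#' inverse Hessian of the negative log-likelihood (one half the -2LL
#' Hessian), computed by central finite differences; RSE is reported per
#' parameter as 100 x SE(log estimate), the relative standard error of the
#' natural-scale estimate by the delta method.
#'
#' @param data observation table.
#' @param init named vector of natural-scale starting values; defaults to
#'   the baseline values of the five activation parameters
#'   (k9, k12, k13, kmat_3, Vmax).
#' @param fixed names among \code{init} to hold fixed (not fitted). If all
#'   are fixed the objective is evaluated once and \code{init} returned.
#' @param params,schedule,scale model context, as in \code{\link{neg2ll}}.
#' @param seed recorded in the result (the optimizer itself is
#'   deterministic).
#' @param maxit,reltol Nelder-Mead settings.
#' @param restart restart the search once from the incumbent with a fresh
#'   simplex (robust default; warm-started re-optimizations inside
#'   profiling skip it).
#' @param hessian compute the covariance/RSE (set FALSE to skip).
#' @return an \code{asc_fit} object: estimates (natural and log scale),
#'   \code{minus2LL}, \code{sigma} per observed variable, \code{cov}
#'   (log-scale), \code{rse} (%), convergence flag, evaluation count, and
#'   the model context needed to re-simulate.
#' @export
fit_asc_model <- function(data, init = NULL, fixed = character(),
                          params = build_parameters(mode = "self_consistent"),
                          schedule = antigen_schedule(),
                          scale = c("log10", "linear"), seed = NULL,
                          maxit = 2000, reltol = 1e-8, restart = TRUE,
                          hessian = TRUE) {
  scale <- match.arg(scale)
  if (is.null(init))
    init <- setNames(as.numeric(params[.default_fit_params]),
                     .default_fit_params)
  if (any(init <= 0)) stop("init values must be positive")
  free <- setdiff(names(init), fixed)

  base <- .apply_fit_values(params, init) # fixed ones pinned at their inits
  obs <- as_observation_table(data)

  f <- .make_objective(obs, base, schedule, free, scale)
  neval <- 0L
  fn <- function(theta_log) {
    neval <<- neval + 1L
    f(setNames(exp(theta_log), free))$value
  }

  if (!length(free)) {
    at <- f(setNames(numeric(0), character(0)))
    return(structure(
      list(estimates = init, log_estimates = log(init),
           minus2LL = at$value, sigma = at$sigma, cov = NULL, rse = NULL,
           convergence = 0L, evaluations = 1L, seed = seed,
           fitted_names = character(0), fixed = fixed, init = init,
           params = base, schedule = schedule, scale = scale),
      class = "asc_fit"))
  }

  theta0 <- log(init[free])
  opt <- optim(theta0, fn, method = "Nelder-Mead",
               control = list(maxit = maxit, reltol = reltol))
  convergence <- opt$convergence
  if (restart) {
    # one restart from the incumbent (fresh simplex); a degenerate restart
    # simplex (code 10) after a converged first pass still counts as
    # converged
    opt2 <- optim(opt$par, fn, method = "Nelder-Mead",
                  control = list(maxit = maxit, reltol = reltol))
    if (opt2$value < opt$value) opt <- opt2
    convergence <- if (convergence == 0L || opt2$convergence == 0L) 0L
                   else opt$convergence
  }

  est_log <- setNames(opt$par, free)
  est <- exp(est_log)
  at <- f(est)

  cov <- rse <- NULL
  if (hessian) {
    H <- .fd_hessian(fn, opt$par) # Hessian of -2LL on log scale
    cov <- tryCatch(2 * solve(H), error = function(e) NULL)
    if (!is.null(cov)) {
      cov <- (cov + t(cov)) / 2
      dimnames(cov) <- list(free, free)
      se_log <- suppressWarnings(sqrt(diag(cov)))
      rse <- setNames(100 * se_log, free)
    }
  }

  full_est <- init
  full_est[free] <- est
  structure(
    list(estimates = full_est, log_estimates = log(full_est),
         minus2LL = opt$value, sigma = at$sigma, cov = cov, rse = rse,
         convergence = convergence, evaluations = neval, seed = seed,
         fitted_names = free, fixed = fixed, init = init,
         params = base, schedule = schedule, scale = scale),
    class = "asc_fit")
}

#' @export
print.asc_fit <- function(x, ...) {
  cat("<asc_fit> -2LL =", format(x$minus2LL, digits = 8),
      if (x$convergence == 0) "(converged)" else "(NOT converged)", "\n")
  df <- data.frame(estimate = x$estimates)
  if (!is.null(x$rse))
    df$rse_pct <- signif(x$rse[rownames(df)], 4)
  print(df)
  if (length(x$sigma)) {
    cat("residual SD per variable:\n")
    print(signif(x$sigma, 4))
  }
  invisible(x)
}

# central finite-difference Hessian
.fd_hessian <- function(fn, x, h = 1e-4) {
  n <- length(x)
  H <- matrix(0, n, n)
  f0 <- fn(x)
  for (i in seq_len(n)) {
    for (j in i:n) {
      ei <- ej <- numeric(n); ei[i] <- h; ej[j] <- h
      if (i == j) {
        H[i, i] <- (fn(x + ei) - 2 * f0 + fn(x - ei)) / h^2
      } else {
        H[i, j] <- H[j, i] <-
          (fn(x + ei + ej) - fn(x + ei - ej) -
             fn(x - ei + ej) + fn(x - ei - ej)) / (4 * h^2)
      }
    }
  }
  H
}

#' Latin-hypercube multi-start fitting
#'
#' Starting points are drawn by Latin hypercube sampling within +/- a
#' relative spread (default 50%) of the reference values; each start is
#' fitted with \code{\link{fit_asc_model}} and the results are returned
#' sorted by objective, together with a dispersion summary of the optimized
#' values (max/min - 1 per parameter across converged starts).
#'
#' @param data observation table.
#' @param n_starts number of starts (>= 2).
#' @param reference named vector of reference values; default the baseline
#'   activation parameters.
#' @param spread relative half-width of the start hypercube (0.5 = +/-50%).
#' @param seed seed for the LHS draw.
#' @param ... passed to \code{\link{fit_asc_model}}.
#' @return list with \code{fits} (sorted by -2LL), \code{starts} (matrix),
#'   \code{dispersion} (per-parameter relative spread of optima) and
#'   \code{failures}.
#' @export
multistart_fit <- function(data, n_starts = 10, reference = NULL,
                           spread = 0.5, seed = 1,
                           params = build_parameters(mode = "self_consistent"),
                           ...) {
  if (n_starts < 2) stop("n_starts must be >= 2")
  if (is.null(reference))
    reference <- setNames(as.numeric(params[.default_fit_params]),
                          .default_fit_params)
  k <- length(reference)
  set.seed(seed)
  u <- lhs::randomLHS(n_starts, k)
  lower <- reference * (1 - spread)
  upper <- reference * (1 + spread)
  starts <- sweep(sweep(u, 2, upper - lower, `*`), 2, lower, `+`)
  colnames(starts) <- names(reference)

  fits <- vector("list", n_starts)
  failures <- list()
  for (i in seq_len(n_starts)) {
    fits[[i]] <- tryCatch(
      fit_asc_model(data, init = setNames(starts[i, ], names(reference)),
                    params = params, seed = seed, ...),
      error = function(e) e)
    if (inherits(fits[[i]], "error")) {
      failures[[length(failures) + 1L]] <-
        list(start = starts[i, ], message = conditionMessage(fits[[i]]))
      fits[[i]] <- NULL
    }
  }
  fits <- Filter(Negate(is.null), fits)
  ord <- order(vapply(fits, `[[`, numeric(1), "minus2LL"))
  fits <- fits[ord]
  conv <- Filter(function(f) f$convergence == 0, fits)
  if (!length(conv)) conv <- fits
  est <- do.call(rbind, lapply(conv, function(f)
    f$estimates[names(reference)]))
  dispersion <- apply(est, 2, function(v) max(v) / min(v) - 1)
  list(fits = fits, starts = starts, dispersion = dispersion,
       failures = failures, seed = seed)
}

# profiled objective: parameter pinned at `value`, others re-optimized
# (warm-started); returns the re-optimized -2LL
.profiled_value <- function(fit, parameter, value, warm = NULL,
                            maxit = 400, reltol = 1e-7) {
  others <- setdiff(fit$fitted_names, parameter)
  init <- fit$estimates[fit$fitted_names]
  init[parameter] <- value
  if (!is.null(warm)) init[others] <- warm
  fit_asc_model(
    data = fit$data_cache, init = init, fixed = c(fit$fixed, parameter),
    params = fit$params, schedule = fit$schedule, scale = fit$scale,
    maxit = maxit, reltol = reltol, restart = FALSE, hessian = FALSE)
}

#' Likelihood profile of one fitted parameter
#'
#' The parameter is fixed on a grid (by default 21 log-spaced points
#' spanning 1/5 to 5 times the estimate) and the remaining parameters are
#' re-optimized at each point. The 95% confidence interval is bounded where
#' the profiled -2LL exceeds its minimum by 3.84 (chi-squared, 1 df),
#' located by linear interpolation; a side whose bound is not bracketed
#' within the grid is flagged one-sided.
#'
#' @param fit an \code{asc_fit} (from \code{\link{fit_asc_model}}) — the
#'   fit must have been made on data passed as \code{data} here.
#' @param data the observation table the fit used.
#' @param parameter one of the fitted parameter names.
#' @param n_grid number of grid points.
#' @param fold half-range of the grid as a fold change.
#' @param maxit,reltol settings for the re-optimizations.
#' @return a \code{profile_result}: grid values, profiled -2LL, the CI, and
#'   flags.
#' @export
profile_likelihood <- function(fit, data, parameter, n_grid = 21, fold = 5,
                               maxit = 400, reltol = 1e-7) {
  stopifnot(inherits(fit, "asc_fit"))
  if (!parameter %in% fit$fitted_names) stop("not a fitted parameter")
  fit$data_cache <- as_observation_table(data)
  est <- fit$estimates[[parameter]]
  grid <- exp(seq(log(est / fold), log(est * fold), length.out = n_grid))
  # replace the nearest grid point with the estimate itself
  grid[which.min(abs(log(grid) - log(est)))] <- est
  obj <- numeric(n_grid)
  ctr <- which(grid == est)[1]
  warm <- NULL
  # march outward from the estimate so warm starts track the profile
  order_idx <- c(ctr, (ctr + 1):n_grid, (ctr - 1):1)
  order_idx <- order_idx[order_idx >= 1 & order_idx <= n_grid]
  order_idx <- unique(order_idx)
  others <- setdiff(fit$fitted_names, parameter)
  warm_up <- warm_dn <- fit$estimates[others]
  for (i in order_idx) {
    w <- if (i >= ctr) warm_up else warm_dn
    sub <- .profiled_value(fit, parameter, grid[i], warm = w,
                           maxit = maxit, reltol = reltol)
    obj[i] <- sub$minus2LL
    if (i >= ctr) warm_up <- sub$estimates[others] else
      warm_dn <- sub$estimates[others]
    if (i == ctr) warm_dn <- sub$estimates[others]
  }
  thr <- min(obj) + 3.84
  ci <- .interp_ci(grid, obj, thr, est)
  structure(list(parameter = parameter, grid = grid, minus2LL = obj,
                 estimate = est, threshold = thr,
                 ci = ci$ci, one_sided = ci$one_sided),
            class = "profile_result")
}

.interp_ci <- function(grid, obj, thr, est) {
  lg <- log(grid)
  below <- obj <= thr
  ci <- c(NA_real_, NA_real_)
  one_sided <- c(lower = FALSE, upper = FALSE)
  idx_est <- which.min(abs(grid - est))
  # lower bound: last upward crossing left of the estimate
  left <- seq_len(idx_est)
  if (all(below[left])) {
    ci[1] <- grid[1]; one_sided["lower"] <- TRUE
  } else {
    i <- max(which(!below[left]))
    x <- lg[i] + (thr - obj[i]) * (lg[i + 1] - lg[i]) / (obj[i + 1] - obj[i])
    ci[1] <- exp(x)
  }
  right <- idx_est:length(grid)
  if (all(below[right])) {
    ci[2] <- grid[length(grid)]; one_sided["upper"] <- TRUE
  } else {
    j <- right[min(which(!below[right]))]
    x <- lg[j - 1] + (thr - obj[j - 1]) * (lg[j] - lg[j - 1]) /
      (obj[j] - obj[j - 1])
    ci[2] <- exp(x)
  }
  list(ci = ci, one_sided = one_sided)
}

#' @export
print.profile_result <- function(x, ...) {
  cat("<profile_result>", x$parameter, " estimate", signif(x$estimate, 5),
      "\n95% CI: [", signif(x$ci[1], 5), ",", signif(x$ci[2], 5), "]",
      if (any(x$one_sided)) "(one-sided)" else "", "\n")
  invisible(x)
}

#' Fast profile-likelihood confidence bounds
#'
#' Locates the two 95% bounds (profiled -2LL rise of 3.84) by stepping
#' outward multiplicatively from the estimate and bisecting the bracketed
#' crossing, re-optimizing the remaining parameters at every evaluation.
#' Cheaper than a full grid profile; used in simulation studies.
#'
#' @inheritParams profile_likelihood
#' @param step multiplicative step-out factor.
#' @param max_fold give up (one-sided) beyond this fold change.
#' @param tol relative tolerance on the bound location.
#' @return named vector \code{c(lower =, upper =)} (NA with a warning if a
#'   side never crossed within \code{max_fold}).
#' @export
profile_ci <- function(fit, data, parameter, step = 1.6, max_fold = 25,
                       tol = 0.02, maxit = 300, reltol = 1e-6) {
  stopifnot(inherits(fit, "asc_fit"))
  fit$data_cache <- as_observation_table(data)
  est <- fit$estimates[[parameter]]
  thr <- fit$minus2LL + 3.84
  others <- setdiff(fit$fitted_names, parameter)

  bound <- function(direction) {
    warm <- fit$estimates[others]
    g <- function(v, w) {
      sub <- .profiled_value(fit, parameter, v, warm = w,
                             maxit = maxit, reltol = reltol)
      list(val = sub$minus2LL, warm = sub$estimates[others])
    }
    lo <- est; hi <- est
    f_lo <- fit$minus2LL
    repeat {
      cand <- if (direction > 0) hi * step else lo / step
      if (cand / est > max_fold || est / cand > max_fold)
        return(NA_real_)
      r <- g(cand, warm); warm <- r$warm
      if (r$val >= thr) {
        if (direction > 0) { lo <- hi; hi <- cand } else
          { hi <- lo; lo <- cand }
        break
      }
      if (direction > 0) hi <- cand else lo <- cand
    }
    # bisect on log scale
    while (log(hi / lo) > tol) {
      mid <- sqrt(lo * hi)
      r <- g(mid, warm); warm <- r$warm
      inside <- r$val < thr
      if (direction > 0) { if (inside) lo <- mid else hi <- mid }
      else { if (inside) hi <- mid else lo <- mid }
    }
    sqrt(lo * hi)
  }

  lower <- bound(-1)
  upper <- bound(+1)
  if (any(is.na(c(lower, upper))))
    warning("profile bound not bracketed within ", max_fold,
            "-fold; one-sided CI")
  c(lower = lower, upper = upper)
}

#' Parameter-uncertainty bands for model trajectories
#'
#' Parameter sets are sampled from a multivariate normal on the log scale
#' (mean = log estimates, covariance = the fit's log-scale covariance), the
#' model is simulated for each sample, and per-time-point 2.5/97.5
#' percentiles form 95% confidence envelopes. The bands represent parameter
#' uncertainty only, not biological variability or residual noise.
#'
#' @param fit an \code{asc_fit} with a valid covariance.
#' @param n_samples number of parameter draws (reference analysis: 1000).
#' @param seed RNG seed.
#' @param t_end,dt_out simulation window and output spacing (days).
#' @param states states to band (default the four ASC pools and IgG).
#' @return list with \code{time}, and per state a matrix with columns
#'   \code{lower}, \code{median}, \code{upper}, plus the point trajectory.
#' @export
uncertainty_bands <- function(fit, n_samples = 1000, seed = 1,
                              t_end = 350, dt_out = 1,
                              states = c("ASCSpleen", "ASCLN", "ASCBlood",
                                         "ASCBone", "IgGBlood")) {
  stopifnot(inherits(fit, "asc_fit"))
  if (is.null(fit$cov)) stop("fit has no covariance matrix")
  mu <- fit$log_estimates[fit$fitted_names]
  S <- fit$cov
  ev <- eigen(S, symmetric = TRUE)
  if (any(ev$values < -1e-12 * max(abs(ev$values)))) {
    warning("covariance not positive semi-definite; nearest-PSD repair")
    S <- ev$vectors %*% diag(pmax(ev$values, 0), nrow(S)) %*% t(ev$vectors)
  }
  set.seed(seed)
  draws <- MASS::mvrnorm(n_samples, mu = mu, Sigma = S)
  if (is.null(dim(draws))) draws <- matrix(draws, ncol = length(mu))
  colnames(draws) <- names(mu)

  times <- seq(0, t_end, by = dt_out)
  p_hat <- .apply_fit_values(fit$params, fit$estimates)
  point <- simulate_response(p_hat, fit$schedule, times = times)
  sims <- array(NA_real_, dim = c(n_samples, length(times), length(states)),
                dimnames = list(NULL, NULL, states))
  for (i in seq_len(n_samples)) {
    p <- .apply_fit_values(fit$params, exp(draws[i, ]))
    tr <- tryCatch(simulate_response(p, fit$schedule, times = times),
                   error = function(e) NULL)
    if (!is.null(tr)) sims[i, , ] <- tr$state[, states]
  }
  bands <- lapply(states, function(st) {
    q <- apply(sims[, , st], 2, quantile,
               probs = c(0.025, 0.5, 0.975), na.rm = TRUE)
    cbind(lower = q[1, ], median = q[2, ], upper = q[3, ])
  })
  names(bands) <- states
  list(time = times, bands = bands,
       point = point$state[, states, drop = FALSE],
       n_samples = n_samples, seed = seed)
}

#' Per-study survival-niche capacity refits
#'
#' Each study's observations are refitted estimating only \code{Vmax}
#' (one-dimensional profiled -2LL, golden-section search on the log scale)
#' with all other parameters held at the reference values, emulating the
#' exploration of between-study heterogeneity in bone-marrow ASC plateaus.
#' RSE is derived from the finite-difference curvature of the objective at
#' the optimum.
#'
#' @param studies list of observation tables (each needs at least one
#'   bone-marrow record).
#' @param params,schedule,scale reference model context (e.g. the global
#'   calibration result applied via overrides).
#' @param lower,upper search bounds for Vmax, cells/day.
#' @return data.frame with one row per study: \code{study}, \code{Vmax},
#'   \code{rse_pct}, \code{minus2LL}, \code{at_bound} flag.
#' @export
fit_vmax_per_study <- function(studies,
                               params = build_parameters(mode = "self_consistent"),
                               schedule = antigen_schedule(),
                               scale = "log10",
                               lower = 1e-2, upper = 1e5) {
  if (!is.list(studies) || inherits(studies, "data.frame"))
    studies <- list(studies)
  out <- lapply(seq_along(studies), function(i) {
    obs <- as_observation_table(studies[[i]])
    if (!any(obs$tissue == "bone_marrow"))
      stop("study ", i, " has no bone-marrow observations")
    f <- .make_objective(obs, params, schedule, "Vmax", scale)
    fn <- function(lv) f(c(Vmax = exp(lv)))$value
    op <- optimize(fn, interval = log(c(lower, upper)), tol = 1e-8)
    vhat <- exp(op$minimum)
    at_bound <- op$minimum < log(lower) + 1e-3 ||
      op$minimum > log(upper) - 1e-3
    h <- 1e-3
    d2 <- (fn(op$minimum + h) - 2 * op$objective + fn(op$minimum - h)) / h^2
    rse <- if (is.finite(d2) && d2 > 0) 100 * sqrt(2 / d2) else NA_real_
    st <- unique(obs$study)[1]
    data.frame(study = st, Vmax = vhat, rse_pct = rse,
               minus2LL = op$objective, at_bound = at_bound)
  })
  do.call(rbind, out)
}
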