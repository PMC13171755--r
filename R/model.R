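#' Names of the 20 model states
#'
#' Seven homeostatic B cell compartments, seven antigen-signal states
#' (exposure plus a six-stage transit chain), five ASC compartments and the
#' blood IgG pool.
#'
#' @return character vector of length 20 in state order.
#' @export
asc_state_names <- function() c(
  "ImmBone", "T1Bone", "T1Blood", "T1Spleen",
  "NaiveSpleen", "NaiveBlood", "NaiveLN",
  "Antigen0", "Antigen1", "Antigen2", "Antigen3", "Antigen4", "Antigen5",
  "Antigen",
  "ASCSpleen", "ASCLN", "ASCBlood", "ASCBone", "ASCPeripheral",
  "IgGBlood"
)

# order of the parameter vector handed to the compiled RHS; must match
# src/asc_model.c
.parms_order <- c(
  "ksyn_imm", "kmat_1", "kmat_2", "kmat_3",
  paste0("k", 1:14),
  "kdeg_spl", "kdeg_ln", "ksin_igg", "kdeg_igg",
  "Vmax", "Khalf", "precursor_frequency"
)

.c_parms <- function(params, schedule) {
  c(as.numeric(params[.parms_order]),
    schedule$amplitude, schedule$rise, schedule$decay, schedule$onset,
    schedule$ktr)
}

#' Model right-hand side
#'
#' Evaluates the 20 state derivatives (per day). The homeostatic submodel is
#' a linear lineage/trafficking network (bone marrow -> blood -> spleen
#' maturation, naive recirculation through blood, spleen and lymph nodes,
#' elimination in spleen and lymph nodes). Antigen exposure follows the
#' schedule's pulse in differential form and feeds a six-stage transit chain;
#' the terminal signal drives ASC generation at rate
#' \code{kmat_3 * (naive pool * precursor_frequency) * Antigen} in spleen and
#' lymph nodes. ASC exchange with blood (k8-k11), enter the bone-marrow
#' survival niche through the saturable flux
#' \code{Vmax * ASCBlood / (Khalf + ASCBlood)}, egress at k12, and exchange
#' with peripheral organs (k13/k14); there is no ASC elimination. IgG is
#' produced by spleen, lymph-node, blood and bone-marrow ASC (peripheral ASC
#' excluded) and cleared first-order.
#'
#' A pure R implementation, mirrored by the compiled version used by
#' \code{\link{simulate_response}}.
#'
#' @param t time, days.
#' @param state named (or ordered) numeric vector of the 20 states.
#' @param params an \code{asc_parameters} object.
#' @param schedule an \code{antigen_schedule}.
#' @return named numeric vector of 20 derivatives.
#' @export
asc_rhs <- function(t, state, params, schedule) {
  s <- setNames(as.numeric(state), asc_state_names())
  p <- params

  d <- numeric(20)
  names(d) <- asc_state_names()

  d["ImmBone"] <- p[["ksyn_imm"]] - p[["kmat_1"]] * s["ImmBone"]
  d["T1Bone"] <- p[["kmat_1"]] * s["ImmBone"] - p[["k1"]] * s["T1Bone"]
  d["T1Blood"] <- p[["k1"]] * s["T1Bone"] + p[["k2"]] * s["T1Spleen"] -
    p[["k3"]] * s["T1Blood"]
  d["T1Spleen"] <- p[["k3"]] * s["T1Blood"] -
    (p[["k2"]] + p[["kmat_2"]]) * s["T1Spleen"]
  d["NaiveSpleen"] <- p[["kmat_2"]] * s["T1Spleen"] +
    p[["k5"]] * s["NaiveBlood"] -
    (p[["k4"]] + p[["kdeg_spl"]]) * s["NaiveSpleen"]
  d["NaiveBlood"] <- p[["k4"]] * s["NaiveSpleen"] + p[["k7"]] * s["NaiveLN"] -
    (p[["k5"]] + p[["k6"]]) * s["NaiveBlood"]
  d["NaiveLN"] <- p[["k6"]] * s["NaiveBlood"] -
    (p[["k7"]] + p[["kdeg_ln"]]) * s["NaiveLN"]

  tt <- t - schedule$onset
  src <- if (tt >= 0)
    schedule$amplitude * (schedule$rise - schedule$decay) *
      exp(-schedule$rise * tt) else 0
  ktr <- schedule$ktr
  d["Antigen0"] <- src - schedule$decay * s["Antigen0"]
  chain <- c("Antigen0", "Antigen1", "Antigen2", "Antigen3", "Antigen4",
             "Antigen5", "Antigen")
  for (i in 2:7)
    d[chain[i]] <- ktr * (s[chain[i - 1]] - s[chain[i]])

  pf <- p[["precursor_frequency"]]
  gen_spl <- p[["kmat_3"]] * s["NaiveSpleen"] * pf * s["Antigen"]
  gen_ln <- p[["kmat_3"]] * s["NaiveLN"] * pf * s["Antigen"]
  ab <- max(s["ASCBlood"], 0)
  bone_in <- p[["Vmax"]] * ab / (p[["Khalf"]] + ab)

  d["ASCSpleen"] <- gen_spl + p[["k9"]] * s["ASCBlood"] -
    p[["k8"]] * s["ASCSpleen"]
  d["ASCLN"] <- gen_ln + p[["k10"]] * s["ASCBlood"] -
    p[["k11"]] * s["ASCLN"]
  d["ASCBlood"] <- p[["k8"]] * s["ASCSpleen"] + p[["k11"]] * s["ASCLN"] +
    p[["k12"]] * s["ASCBone"] + p[["k14"]] * s["ASCPeripheral"] -
    (p[["k9"]] + p[["k10"]] + p[["k13"]]) * s["ASCBlood"] - bone_in
  d["ASCBone"] <- bone_in - p[["k12"]] * s["ASCBone"]
  d["ASCPeripheral"] <- p[["k13"]] * s["ASCBlood"] -
    p[["k14"]] * s["ASCPeripheral"]
  d["IgGBlood"] <- p[["ksin_igg"]] *
    (s["ASCSpleen"] + s["ASCLN"] + s["ASCBlood"] + s["ASCBone"]) -
    p[["kdeg_igg"]] * s["IgGBlood"]

  d
}

#' Initial state for a response simulation
#'
#' Homeostatic compartments start at their steady-state counts; all antigen,
#' ASC and IgG states start at 0, except \code{Antigen0} which carries the
#' initial dose (the exposure pulse of the schedule, if any, is delivered
#' through the ODE source term on top of this).
#'
#' @param params an \code{asc_parameters} object.
#' @param antigen_dose initial value of \code{Antigen0}, antigen-signal
#'   units.
#' @return named numeric vector of 20 states.
#' @export
initial_state <- function(params, antigen_dose = 0) {
  .check_parameters(params)
  if (antigen_dose < 0) stop("antigen_dose must be >= 0")
  y <- setNames(numeric(20), asc_state_names())
  y["ImmBone"] <- params[["ImmBone_ss"]]
  y["T1Bone"] <- params[["T1Bone_ss"]]
  y["T1Blood"] <- params[["T1Blood_ss"]]
  y["T1Spleen"] <- params[["T1Spleen_ss"]]
  y["NaiveSpleen"] <- params[["NaiveSpleen_ss"]]
  y["NaiveBlood"] <- params[["NaiveBlood_ss"]]
  y["NaiveLN"] <- params[["NaiveLN_ss"]]
  y["Antigen0"] <- antigen_dose
  y
}

#' Integrate the model over time
#'
#' Stiff-capable integration (lsoda) of the 20-state system from
#' \code{\link{initial_state}}. The compiled right-hand side is used by
#' default; \code{engine = "r"} selects the pure R implementation
#' (\code{\link{asc_rhs}}) for cross-checking.
#'
#' @param params an \code{asc_parameters} object.
#' @param schedule an \code{antigen_schedule}; default the reference pulse.
#' @param t_end end of the simulation, days (> 0).
#' @param dt_out output grid spacing, days (> 0).
#' @param antigen_dose initial \code{Antigen0} dose.
#' @param times optional explicit output times (overrides \code{t_end} /
#'   \code{dt_out}); must start at 0 and be strictly increasing.
#' @param engine \code{"c"} (compiled) or \code{"r"}.
#' @param rtol,atol solver tolerances (defaults 1e-8 and 1e-6 cells; the
#'   rate constants span 0.02-6111 per day, so a stiff method and a tight
#'   relative tolerance are needed).
#' @return an \code{asc_trajectory}: list with \code{time}, \code{state}
#'   (matrix, one row per time point, 20 named columns) and metadata.
#' @examples
#' traj <- simulate_response(build_parameters(mode = "self_consistent"),
#'                           t_end = 50, dt_out = 1)
#' peak_summary(traj, "ASCLN")
#' @export
simulate_response <- function(params, schedule = antigen_schedule(),
                              t_end = 350, dt_out = 0.1, antigen_dose = 0,
                              times = NULL, engine = c("c", "r"),
                              rtol = 1e-8, atol = 1e-6) {
  engine <- match.arg(engine)
  .check_parameters(params)
  stopifnot(inherits(schedule, "antigen_schedule"))
  if (is.null(times)) {
    if (t_end <= 0 || dt_out <= 0) stop("t_end and dt_out must be > 0")
    times <- seq(0, t_end, by = dt_out)
    if (times[length(times)] < t_end) times <- c(times, t_end)
  } else {
    if (times[1] != 0 || any(diff(times) <= 0))
      stop("times must start at 0 and be strictly increasing")
  }
  y0 <- initial_state(params, antigen_dose)

  if (engine == "c") {
    out <- deSolve::lsoda(
      y = y0, times = times, func = "asc_derivs",
      parms = .c_parms(params, schedule),
      dllname = "bcellasc", initfunc = "asc_initmod",
      rtol = rtol, atol = atol, maxsteps = 50000
    )
  } else {
    out <- deSolve::lsoda(
      y = y0, times = times,
      func = function(t, y, parms) list(asc_rhs(t, y, params, schedule)),
      parms = NULL, rtol = rtol, atol = atol, maxsteps = 50000
    )
  }

  if (nrow(out) < length(times))
    stop("solver failed before t_end (rtol = ", rtol, ", atol = ", atol, ")")
  state <- out[, asc_state_names(), drop = FALSE]
  if (any(!is.finite(state)))
    stop("non-finite state encountered during integration")

  structure(
    list(time = out[, "time"], state = state,
         params = params, schedule = schedule,
         mode = attr(params, "mode"),
         solver = list(method = "lsoda", engine = engine,
                       rtol = rtol, atol = atol)),
    class = "asc_trajectory"
  )
}

#' @export
print.asc_trajectory <- function(x, ...) {
  cat(sprintf(
    "<asc_trajectory> %d time points over days %g-%g (closure: %s, engine: %s)\n",
    length(x$time), min(x$time), max(x$time),
    if (is.null(x$mode)) "?" else x$mode, x$solver$engine))
  fin <- x$state[nrow(x$state), c("ASCSpleen", "ASCLN", "ASCBlood",
                                  "ASCBone", "IgGBlood")]
  cat("final ASC/IgG values:\n")
  print(signif(fin, 4))
  invisible(x)
}

#' Tidy long-format view of a trajectory
#'
#' @param x an \code{asc_trajectory}.
#' @param row.names,optional,... ignored (S3 signature).
#' @return data.frame with columns \code{time}, \code{state}, \code{value}.
#' @export
as.data.frame.asc_trajectory <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  data.frame(
    time = rep(x$time, times = ncol(x$state)),
    state = rep(colnames(x$state), each = length(x$time)),
    value = as.vector(x$state)
  )
}

#' Write a trajectory as tidy CSV
#' @param traj an \code{asc_trajectory}.
#' @param path output CSV path (columns time, state, value).
#' @return the path, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

# interpolate a trajectory state at arbitrary times
.state_at <- function(traj, state, at) {
  stats::approx(traj$time, traj$state[, state], xout = at, rule = 2)$y
}
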