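#' Design of a synthetic immunization study
#'
#' Emulates the sparse multi-tissue sampling of published immunization
#' time courses: a handful of sampling days per tissue, a few replicate
#' animals per point, and multiplicative (lognormal) measurement noise.
#'
#' @param days sampling days (within 0-350).
#' @param tissues tissues measured (any of \code{"spleen"},
#'   \code{"lymph_nodes"}, \code{"bone_marrow"}, \code{"blood"},
#'   \code{"igg"}).
#' @param noise \code{"lognormal"} (multiplicative, mean-preserving) or
#'   \code{"additive"} (Gaussian).
#' @param cv noise magnitude: coefficient of variation per replicate
#'   (lognormal) or SD as a fraction of the value (additive).
#' @param n_replicates replicate animals per point.
#' @return a \code{study_design} list.
#' @export
study_design <- function(days = c(7, 14, 21, 28, 42, 60, 100, 200),
                         tissues = c("spleen", "lymph_nodes",
                                     "bone_marrow", "blood"),
                         noise = c("lognormal", "additive"),
                         cv = 0.3, n_replicates = 5) {
  noise <- match.arg(noise)
  if (any(days < 0 | days > 350)) stop("days must lie within [0, 350]")
  if (cv < 0) stop("noise magnitude must be >= 0")
  if (!all(tissues %in% .tissues)) stop("unknown tissue in design")
  structure(list(days = sort(unique(days)), tissues = tissues,
                 noise = noise, cv = cv,
                 n_replicates = as.integer(n_replicates)),
            class = "study_design")
}

#' Generate a synthetic observation table with known ground truth
#'
#' Simulates the model under the given (true) parameters, samples the
#' tissue time courses at the design days, draws \code{n_replicates} noisy
#' replicates per point and reports their mean and standard error. IgG
#' records, if requested, are max-normalized per study before noise.
#' Lognormal noise is mean-preserving
#' (\code{meanlog = log(pred) - sdlog^2/2}, \code{sdlog^2 = log(1 + cv^2)}).
#'
#' @param params true \code{asc_parameters}.
#' @param schedule antigen schedule.
#' @param design a \code{\link{study_design}}.
#' @param seed RNG seed.
#' @param study study identifier.
#' @return observation table (data.frame) with columns \code{study},
#'   \code{tissue}, \code{day}, \code{value}, \code{error}, \code{scaled};
#'   the ground truth (params, schedule, design, seed) is attached as
#'   \code{attr(, "truth")}.
#' @examples
#' p <- build_parameters(mode = "self_consistent")
#' obs <- generate_observations(p, seed = 42)
#' head(obs)
#' @export
generate_observations <- function(params, schedule = antigen_schedule(),
                                  design = study_design(), seed = 1,
                                  study = "study_1") {
  stopifnot(inherits(design, "study_design"))
  traj <- simulate_response(params, schedule,
                            times = sort(unique(c(0, design$days))))
  set.seed(seed)
  rows <- list()
  for (tis in design$tissues) {
    st <- .tissue_state[[tis]]
    pred <- .state_at(traj, st, design$days)
    if (tis == "igg") {
      m <- max(pred)
      if (m > 0) pred <- pred / m
    }
    for (i in seq_along(design$days)) {
      mu <- pred[i]
      reps <- if (design$cv == 0) rep(mu, design$n_replicates)
      else if (design$noise == "lognormal") {
        sdlog <- sqrt(log(1 + design$cv^2))
        stats::rlnorm(design$n_replicates,
                      meanlog = log(max(mu, 1e-12)) - sdlog^2 / 2,
                      sdlog = sdlog) * (mu > 0)
      } else {
        pmax(stats::rnorm(design$n_replicates, mu, design$cv * mu), 0)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        study = study, tissue = tis, day = design$days[i],
        value = mean(reps),
        error = stats::sd(reps) / sqrt(design$n_replicates),
        scaled = TRUE)
    }
  }
  obs <- do.call(rbind, rows)
  attr(obs, "truth") <- list(
    params = as.list(setNames(as.numeric(params), names(params))),
    schedule = unclass(schedule), design = unclass(design), seed = seed)
  as_observation_table(obs)
}

#' Generate a family of studies differing only in niche capacity
#'
#' One synthetic study per supplied \code{Vmax} value, all sharing the
#' remaining parameters — the testbed for per-study heterogeneity refits
#' (\code{\link{fit_vmax_per_study}}).
#'
#' @param vmax_values vector of true Vmax values, cells/day (> 0).
#' @param params shared \code{asc_parameters}.
#' @param schedule,design as in \code{\link{generate_observations}}.
#' @param seed base seed; study i uses \code{seed + i - 1}.
#' @return list of observation tables (study ids \code{study_1, ...}).
#' @export
generate_multistudy <- function(vmax_values,
                                params = build_parameters(mode = "self_consistent"),
                                schedule = antigen_schedule(),
                                design = study_design(), seed = 1) {
  if (any(vmax_values <= 0)) stop("all Vmax values must be > 0")
  lapply(seq_along(vmax_values), function(i) {
    p <- params
    p[["Vmax"]] <- vmax_values[i]
    generate_observations(p, schedule, design, seed = seed + i - 1,
                          study = paste0("study_", i))
  })
}

#' Write the ground truth of a synthetic table as a JSON sidecar
#' @param obs table from \code{\link{generate_observations}}.
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
write_ground_truth <- function(obs, path) {
  truth <- attr(obs, "truth")
  if (is.null(truth)) stop("no ground truth attached to this table")
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
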