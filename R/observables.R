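# tissues an observation table may contain; "igg" is max-normalized IgG,
# the others are whole-animal ASC counts
.tissues <- c("spleen", "lymph_nodes", "bone_marrow", "blood", "igg")

# model state observed for each tissue
.tissue_state <- c(spleen = "ASCSpleen", lymph_nodes = "ASCLN",
                   bone_marrow = "ASCBone", blood = "ASCBlood",
                   igg = "IgGBlood")

#' Whole-animal scaling conventions
#'
#' Literature ASC counts are typically reported per two femurs (about 12.7%
#' of total marrow; factor 7.9 to whole marrow) or per single lymph node
#' (22 nodes per mouse).
#'
#' @param femur_factor two-femur to whole-marrow factor.
#' @param ln_count number of lymph nodes per mouse.
#' @return a named list of the two factors.
#' @export
scaling_conventions <- function(femur_factor = 7.9, ln_count = 22) {
  if (femur_factor <= 0 || ln_count <= 0) stop("factors must be positive")
  list(femur_factor = femur_factor, ln_count = ln_count)
}

#' Scale raw tissue counts to whole-animal counts
#'
#' @param value raw count(s), cells (>= 0).
#' @param tissue one of \code{"spleen"}, \code{"lymph_nodes"},
#'   \code{"bone_marrow"}, \code{"blood"}, \code{"igg"}.
#' @param conventions see \code{\link{scaling_conventions}}.
#' @return whole-animal value(s); bone marrow multiplied by the femur
#'   factor, lymph nodes by the node count, others unchanged.
#' @examples
#' apply_tissue_scaling(1000, "bone_marrow") # 7900
#' @export
apply_tissue_scaling <- function(value, tissue,
                                 conventions = scaling_conventions()) {
  if (any(value < 0)) stop("raw values must be >= 0")
  if (!tissue %in% .tissues) stop("unknown tissue: ", tissue)
  switch(tissue,
         bone_marrow = value * conventions$femur_factor,
         lymph_nodes = value * conventions$ln_count,
         value)
}

#' Peak of a simulated time course
#'
#' @param traj an \code{asc_trajectory}.
#' @param state a state name, e.g. \code{"ASCLN"}.
#' @return named vector \code{c(Cmax =, Tmax =)}: the maximum over the
#'   output grid and the earliest grid time attaining it.
#' @export
peak_summary <- function(traj, state) {
  stopifnot(inherits(traj, "asc_trajectory"))
  if (!state %in% colnames(traj$state)) stop("unknown state: ", state)
  y <- traj$state[, state]
  if (!length(y)) stop("empty trajectory")
  i <- which.max(y) # earliest index on ties
  c(Cmax = unname(y[i]), Tmax = unname(traj$time[i]))
}

#' Normalize a series to its maximum
#'
#' Used to put IgG levels from different studies on a common unitless scale.
#'
#' @param x numeric series with max > 0.
#' @return \code{x / max(x)}; maximum of the output is 1.
#' @export
normalize_to_max <- function(x) {
  m <- max(x)
  if (!is.finite(m) || m <= 0) stop("series maximum must be > 0")
  x / m
}

#' Goodness-of-fit statistics
#'
#' Residuals are \code{observed - predicted} on whatever scale the caller
#' supplies (the calibration objective uses log10(count + 1) for cell counts
#' and the linear scale for normalized IgG). Weighted residuals divide by
#' the per-variable residual standard deviation.
#'
#' @param observed,predicted aligned numeric vectors.
#' @param sigma per-observation residual SD (scalar or vector; typically the
#'   profiled SD of the observation's variable from the fit).
#' @return list with \code{rmse}, \code{wres} (vector) and
#'   \code{frac_wres_within_2}.
#' @export
gof_stats <- function(observed, predicted, sigma) {
  if (length(observed) != length(predicted))
    stop("observed and predicted must be aligned 1:1")
  r <- observed - predicted
  if (any(sigma == 0) && any(r[rep_len(sigma, length(r)) == 0] != 0))
    stop("sigma is 0 with nonzero residuals")
  wres <- ifelse(rep_len(sigma, length(r)) == 0, 0, r / sigma)
  list(rmse = sqrt(mean(r^2)), wres = wres,
       frac_wres_within_2 = mean(abs(wres) <= 2))
}

# ---- observation tables -----------------------------------------------

#' Validate an observation table
#'
#' Multi-study tissue time-course records: columns \code{study},
#' \code{tissue}, \code{day}, \code{value} and optionally \code{error}
#' (same units as value) and \code{scaled} (whether whole-animal scaling has
#' been applied).
#'
#' @param obs data.frame.
#' @return the table, with missing \code{error}/\code{scaled} columns added
#'   (\code{NA} / \code{TRUE}).
#' @export
as_observation_table <- function(obs) {
  need <- c("study", "tissue", "day", "value")
  if (!all(need %in% names(obs)))
    stop("observation table needs columns: ", paste(need, collapse = ", "))
  if (!all(obs$tissue %in% .tissues))
    stop("unknown tissue(s): ",
         paste(setdiff(unique(obs$tissue), .tissues), collapse = ", "))
  if (any(obs$day < 0)) stop("times must be >= 0")
  if (any(obs$value < 0)) stop("values must be >= 0")
  if (!"error" %in% names(obs)) obs$error <- NA_real_
  if (!"scaled" %in% names(obs)) obs$scaled <- TRUE
  obs
}

#' Read / write observation tables
#'
#' CSV dialect: header \code{study,tissue,day,value,error,scaled}; missing
#' \code{error} allowed.
#'
#' @param path CSV path.
#' @return \code{read_observations}: validated data.frame.
#' @export
read_observations <- function(path) {
  as_observation_table(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_observations
#' @param obs observation table.
#' @export
write_observations <- function(obs, path) {
  write.csv(as_observation_table(obs), path, row.names = FALSE)
  invisible(path)
}

# model predictions matched to an observation table, by tissue and day
.predict_observations <- function(obs, traj) {
  vapply(seq_len(nrow(obs)), function(i) {
    st <- .tissue_state[[obs$tissue[i]]]
    .state_at(traj, st, obs$day[i])
  }, numeric(1))
}
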