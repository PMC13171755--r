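#' @useDynLib bcellasc
#' @importFrom stats optim setNames quantile median sd var optimize uniroot
#' @importFrom utils read.csv write.csv
NULL

# Reference parameter table: final estimates and steady-state cell counts of
# the murine B cell / ASC trafficking model. Units: cells for *_ss and Khalf,
# cells/day for ksyn_imm and Vmax, 1/day for rate constants, pg/cell/day for
# ksin_igg.
.table1 <- c(
  ImmBone_ss     = 1.97e6,
  T1Bone_ss      = 0.76e6,
  T1Blood_ss     = 0.004e6,
  T1Spleen_ss    = 4.40e6,
  NaiveSpleen_ss = 24.30e6,
  NaiveBlood_ss  = 4.64e6,
  NaiveLN_ss     = 1.90e6,
  k1             = 26.32,
  k2             = 1.01,
  k3             = 6111,
  k4             = 10.08,
  k5             = 73.53,
  k6             = 4.9,
  k7             = 62.62,
  ksyn_imm       = 20e6,
  kmat_1         = 10.15,
  kmat_2         = 4.55,
  kdeg_spl       = 4.78,
  kdeg_ln        = 0.05,
  k8             = 2.52,
  k9             = 8.53,
  k10            = 143.60,
  k11            = 2.72,
  k12            = 0.02,
  k13            = 16.26,
  k14            = 0.02,
  ksin_igg       = 22.00,
  kdeg_igg       = 0.12,
  kmat_3         = 294.19,
  Vmax           = 490.60,
  Khalf          = 0.10
)

# Fixed convention: frequency of antigen-specific naive B cells (about 1 in
# 10^6), scaling the activatable precursor pool.
.precursor_frequency <- 1e-6

.param_units <- c(
  ImmBone_ss = "cell", T1Bone_ss = "cell", T1Blood_ss = "cell",
  T1Spleen_ss = "cell", NaiveSpleen_ss = "cell", NaiveBlood_ss = "cell",
  NaiveLN_ss = "cell",
  k1 = "1/day", k2 = "1/day", k3 = "1/day", k4 = "1/day", k5 = "1/day",
  k6 = "1/day", k7 = "1/day", ksyn_imm = "cell/day", kmat_1 = "1/day",
  kmat_2 = "1/day", kdeg_spl = "1/day", kdeg_ln = "1/day", k8 = "1/day",
  k9 = "1/day", k10 = "1/day", k11 = "1/day", k12 = "1/day", k13 = "1/day",
  k14 = "1/day", ksin_igg = "pg/cell/day", kdeg_igg = "1/day",
  kmat_3 = "1/day", Vmax = "cell/day", Khalf = "cell",
  precursor_frequency = "dimensionless"
)

#' Build a model parameter set
#'
#' Returns the 31 named model constants (reference defaults) plus the fixed
#' precursor-frequency convention, with optional overrides. Two closure modes
#' are provided. In \code{"paper"} mode the printed reference values are used
#' verbatim (and \code{k14} tracks \code{k12} unless overridden, reflecting
#' the assumption that ASC egress from peripheral organs mirrors egress from
#' the bone marrow). In \code{"self_consistent"} mode the seven
#' steady-state-derived rates (\code{kmat_1, k1, k3, kmat_2, k7, k5,
#' kdeg_spl}) are re-derived from the steady-state cell counts via
#' \code{\link{derive_rates}} so that every homeostatic compartment is exactly
#' balanced. The two modes differ only in \code{k7}, \code{k5} and
#' \code{kdeg_spl}: the printed rates close the spleen and blood naive
#' balances but not the lymph-node balance.
#'
#' @param overrides named list or vector of parameter values to override.
#' @param mode closure mode, \code{"paper"} (default) or
#'   \code{"self_consistent"}.
#' @return an \code{asc_parameters} object: a named numeric vector with 32
#'   entries (31 model constants plus \code{precursor_frequency}) and a
#'   \code{mode} attribute.
#' @examples
#' p <- build_parameters()
#' p[["kmat_3"]]
#' build_parameters(list(Vmax = 100), mode = "self_consistent")[["Vmax"]]
#' @export
build_parameters <- function(overrides = list(),
                             mode = c("paper", "self_consistent")) {
  mode <- match.arg(mode)
  overrides <- unlist(overrides)
  p <- c(.table1, precursor_frequency = .precursor_frequency)

  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(p))
    if (length(bad))
      stop("unknown parameter name(s): ", paste(bad, collapse = ", "))
  }

  if (mode == "self_consistent") {
    counts <- p[grep("_ss$", names(p))]
    # overrides to counts or fixed rates must feed the derivation
    for (nm in intersect(names(overrides), names(p))) p[[nm]] <- overrides[[nm]]
    dr <- derive_rates(
      counts = p[grep("_ss$", names(p))],
      fixed = c(ksyn_imm = p[["ksyn_imm"]], k2 = p[["k2"]], k4 = p[["k4"]],
                k6 = p[["k6"]], kdeg_ln = p[["kdeg_ln"]]),
      mode = "self_consistent"
    )
    for (nm in names(dr$rates))
      if (!nm %in% names(overrides)) p[[nm]] <- dr$rates[[nm]]
  } else {
    if (!"k14" %in% names(overrides) && "k12" %in% names(overrides))
      p[["k14"]] <- overrides[["k12"]]
    for (nm in names(overrides)) p[[nm]] <- overrides[[nm]]
  }

  if (any(p < 0))
    stop("negative value for parameter(s): ",
         paste(names(p)[p < 0], collapse = ", "))

  structure(p, mode = mode, class = c("asc_parameters", class(p)))
}

#' @export
print.asc_parameters <- function(x, ...) {
  cat("<asc_parameters> 20-state B cell / ASC model,",
      length(x) - 1L, "constants + precursor frequency\n")
  cat("closure mode:", attr(x, "mode"), "\n")
  df <- data.frame(value = as.numeric(x),
                   units = unname(.param_units[names(x)]),
                   row.names = names(x))
  print(df, ...)
  invisible(x)
}

#' Names of the model parameters
#' @return character vector of the 32 parameter names.
#' @export
parameter_names <- function() c(names(.table1), "precursor_frequency")

# validity used by operations that accept raw vectors
.check_parameters <- function(params) {
  missing <- setdiff(parameter_names(), names(params))
  if (length(missing))
    stop("parameter set is missing: ", paste(missing, collapse = ", "))
  if (any(params[parameter_names()] < 0))
    stop("parameters must be non-negative")
  invisible(TRUE)
}

#' Write a parameter set to JSON or CSV
#'
#' JSON holds a flat name/value map (readable back by
#' \code{\link{read_parameters}}); CSV adds units.
#'
#' @param params an \code{asc_parameters} object.
#' @param path output file; format chosen from the extension
#'   (\code{.json}, \code{.yaml}/\code{.yml} or \code{.csv}).
#' @return the path, invisibly.
#' @export
write_parameters <- function(params, path) {
  ext <- tolower(tools::file_ext(path))
  vals <- as.list(setNames(as.numeric(params), names(params)))
  if (ext == "json") {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(vals, path)
  } else if (ext == "csv") {
    df <- data.frame(name = names(params), value = as.numeric(params),
                     units = unname(.param_units[names(params)]),
                     source = "reference table")
    write.csv(df, path, row.names = FALSE)
  } else stop("unsupported extension: ", ext)
  invisible(path)
}

#' Read a parameter set from JSON or YAML
#'
#' @param path file written by \code{\link{write_parameters}} (or any flat
#'   name/value map using the model's parameter names).
#' @param mode closure mode passed to \code{\link{build_parameters}}; entries
#'   present in the file are applied as overrides.
#' @return an \code{asc_parameters} object.
#' @export
read_parameters <- function(path, mode = "paper") {
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
          else yaml::read_yaml(path)
  build_parameters(vals[names(vals) %in% parameter_names()], mode = mode)
}
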