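#' Kinetic parameter set of the clock model
#'
#' A named numeric vector holding the 66 kinetic parameters in canonical
#' order (see \code{\link{clockParameterNames}}). Validity enforces
#' positivity, finiteness and the half-time bound on the degradation of
#' light-activated species.
#'
#' @slot .Data named numeric of length 66.
#' @export
setClass("ClockParameters", contains = "numeric", validity = function(object) {
  nm <- clockParameterNames()
  if (length(object) != length(nm))
    return(sprintf("expected %d kinetic parameters, got %d",
                   length(nm), length(object)))
  if (!identical(names(object), nm))
    return("parameter names/order do not match clockParameterNames()")
  # strict positivity everywhere except ktl_vvd, which the dvvd genotype zeroes
  bad <- !is.finite(object) | object < 0 |
    (object == 0 & nm != "ktl_vvd")
  if (any(bad))
    return(paste0("non-finite or non-positive parameter(s): ",
                  paste(nm[bad], collapse = ", ")))
  b <- lightSpeciesDegradationBound()
  viol <- object[names(b)] < b - 1e-12
  if (any(viol))
    return(paste0("half-time bound (<= 3 h) violated for: ",
                  paste(names(b)[viol], collapse = ", ")))
  TRUE
})

#' Construct a validated parameter set
#'
#' @param values named numeric vector covering all 66 kinetic parameters
#'   (any order; reordered canonically). Unknown names are an error.
#' @return A \code{ClockParameters} object.
#' @examples
#' p <- groundTruthParameters()
#' p["kd2"]
#' @export
clockParameters <- function(values) {
  nm <- clockParameterNames()
  if (is.null(names(values)) || any(names(values) == ""))
    stop("parameter values must be named")
  unknown <- setdiff(names(values), nm)
  if (length(unknown) > 0) {
    sug <- vapply(unknown, function(u) {
      d <- utils::adist(u, nm)
      nm[which.min(d)]
    }, "")
    stop("unknown parameter name(s): ",
         paste0(unknown, " (did you mean ", sug, "?)", collapse = ", "))
  }
  missing <- setdiff(nm, names(values))
  if (length(missing) > 0)
    stop("missing required parameter(s): ", paste(missing, collapse = ", "))
  new("ClockParameters", setNames(as.numeric(values[nm]), nm))
}

setMethod("show", "ClockParameters", function(object) {
  cat("ClockParameters:", length(object), "kinetic parameters (per-hour / a.u.)\n")
  cat(sprintf("  kd2 = %.4g, kmat_1 = %.4g, vmax_d_frq = %.4g, K_d_frq = %.4g\n",
              object[["kd2"]], object[["kmat_1"]],
              object[["vmax_d_frq"]], object[["K_d_frq"]]))
  cat("  (use as.numeric()/names() or [\"name\"] for full access)\n")
})

#' Piecewise-constant light protocol
#'
#' Contiguous, non-overlapping segments starting at 0 h with non-negative
#' light intensities in arbitrary units (the standard experimental light is
#' 1 a.u. by convention). Boundaries follow the half-open convention
#' \code{[start, end)}: the boundary instant belongs to the later segment.
#'
#' @slot start numeric, segment start times (h).
#' @slot end numeric, segment end times (h).
#' @slot intensity numeric, light intensity per segment (a.u.).
#' @export
setClass("LightProtocol",
  representation(start = "numeric", end = "numeric", intensity = "numeric"),
  validity = function(object) {
    n <- length(object@start)
    if (length(object@end) != n || length(object@intensity) != n)
      return("start, end, intensity must have equal length")
    if (n == 0) return("protocol must have at least one segment")
    if (abs(object@start[1]) > 1e-12) return("protocol must start at 0 h")
    if (any(object@end <= object@start)) return("segments must have positive duration")
    if (n > 1 && any(abs(object@start[-1] - object@end[-n]) > 1e-9))
      return("segments must be contiguous and non-overlapping")
    if (any(object@intensity < 0)) return("intensities must be >= 0")
    TRUE
  })

setMethod("show", "LightProtocol", function(object) {
  cat(sprintf("LightProtocol: %d segment(s), horizon %.4g h, light dose %.4g a.u.h\n",
              length(object@start), protocolHorizon(object),
              sum((object@end - object@start) * object@intensity)))
  for (i in seq_along(object@start))
    cat(sprintf("  [%7.2f, %7.2f) h  intensity %.4g\n",
                object@start[i], object@end[i], object@intensity[i]))
})

#' Simulated trajectory of the clock model
#'
#' @slot times numeric, strictly increasing grid (h).
#' @slot states matrix of non-negative concentrations, one column per species.
#' @slot protocol the \code{LightProtocol} used.
#' @slot genotype \code{"WT"} or \code{"dvvd"}.
#' @export
setClass("ClockTrajectory",
  representation(times = "numeric", states = "matrix",
                 protocol = "LightProtocol", genotype = "character"),
  validity = function(object) {
    if (ncol(object@states) != 18) return("states must have 18 columns")
    if (!identical(colnames(object@states), clockSpecies()))
      return("state columns must be named after clockSpecies()")
    if (nrow(object@states) != length(object@times))
      return("times and states disagree in length")
    if (any(diff(object@times) <= 0)) return("times must be strictly increasing")
    if (any(object@states < 0)) return("negative concentrations in trajectory")
    if (!object@genotype %in% c("WT", "dvvd")) return("unknown genotype")
    TRUE
  })

setMethod("show", "ClockTrajectory", function(object) {
  cat(sprintf("ClockTrajectory (%s): %d time points over [%.4g, %.4g] h, 18 species\n",
              object@genotype, length(object@times),
              min(object@times), max(object@times)))
})

#' Extract the time grid of a trajectory
#' @param trajectory a \code{ClockTrajectory}.
#' @return Numeric vector of hours.
#' @export
trajectoryTimes <- function(trajectory) trajectory@times

#' Extract one species' concentration time course
#' @param trajectory a \code{ClockTrajectory}.
#' @param species a species name from \code{\link{clockSpecies}}.
#' @return Numeric vector aligned with \code{\link{trajectoryTimes}}.
#' @export
stateSeries <- function(trajectory, species) {
  if (!species %in% clockSpecies()) stop("unknown species: ", species)
  trajectory@states[, species]
}
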