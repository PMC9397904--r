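#' Build a light protocol from segments
#'
#' @param start,end,intensity numeric vectors of equal length: contiguous
#'   half-open segments \code{[start, end)} in hours and their light
#'   intensities (a.u., >= 0).
#' @return A \code{\link{LightProtocol-class}} object.
#' @export
lightProtocol <- function(start, end, intensity) {
  new("LightProtocol", start = as.numeric(start), end = as.numeric(end),
      intensity = as.numeric(intensity))
}

#' Total time horizon of a protocol
#' @param protocol a \code{LightProtocol}.
#' @return Hours.
#' @export
protocolHorizon <- function(protocol) protocol@end[length(protocol@end)]

#' Light intensity at a time point
#'
#' Boundary instants belong to the later segment (half-open convention); the
#' final horizon returns the last segment's intensity.
#'
#' @param protocol a \code{LightProtocol}.
#' @param t time(s) in hours, within \code{[0, horizon]}.
#' @return Intensity (a.u.), vectorized over \code{t}.
#' @export
lightAt <- function(protocol, t) {
  h <- protocolHorizon(protocol)
  if (any(t < -1e-12 | t > h + 1e-12))
    stop("time outside protocol horizon [0, ", h, "]")
  idx <- findInterval(pmin(t, h - 1e-12), protocol@start)
  protocol@intensity[pmax(idx, 1L)]
}

#' Constant-darkness protocol
#' @param horizon hours of darkness.
#' @return A \code{LightProtocol}.
#' @export
darkProtocol <- function(horizon) lightProtocol(0, horizon, 0)

#' The standard 172 h measurement protocol
#'
#' Reporter recordings start (t = 0) after synchronization; cultures then sit
#' 72 h in constant darkness, are exposed to 12 h light, 12 h dark and 12 h
#' light, and are kept in the dark for another 64 h.
#'
#' @param light intensity of the light phases (a.u., default 1).
#' @return A 172 h \code{LightProtocol}.
#' @export
standardExperiment <- function(light = 1.0) {
  lightProtocol(start = c(0, 72, 84, 96, 108),
                end = c(72, 84, 96, 108, 172),
                intensity = c(0, light, 0, light, 0))
}

#' The synchronization protocol preceding t = 0
#'
#' 12 h light, 12 h dark, 12 h light, then 24 h dark (60 h total), the regime
#' used to synchronize cultures before measurements start.
#'
#' @param light intensity of the light phases (a.u., default 1).
#' @return A 60 h \code{LightProtocol}.
#' @export
synchronizationProtocol <- function(light = 1.0) {
  lightProtocol(start = c(0, 12, 24, 36),
                end = c(12, 24, 36, 60),
                intensity = c(light, 0, light, 0))
}

#' Repeated 12 h light : 12 h dark cycles
#' @param n_cycles number of 24 h cycles (>= 1).
#' @param light intensity of the light phases (a.u., default 1).
#' @return A \code{LightProtocol} of horizon \code{24 * n_cycles} h.
#' @export
repeatedLD <- function(n_cycles, light = 1.0) {
  if (n_cycles < 1) stop("n_cycles must be >= 1")
  s <- rep(seq_len(n_cycles) - 1, each = 2) * 24 + c(0, 12)
  lightProtocol(start = s, end = s + 12,
                intensity = rep(c(light, 0), n_cycles))
}

#' A single light pulse in otherwise constant darkness
#'
#' @param t_on pulse onset (h).
#' @param duration pulse length (h); default 0.25 h (15 min).
#' @param intensity pulse intensity (a.u.).
#' @param horizon total protocol length (h).
#' @return A \code{LightProtocol}.
#' @export
lightPulse <- function(t_on, duration = 0.25, intensity = 1.0, horizon = 48) {
  if (t_on < 0 || t_on + duration > horizon)
    stop("pulse [", t_on, ", ", t_on + duration, ") outside horizon")
  if (intensity == 0) return(darkProtocol(horizon))
  start <- unique(c(0, t_on, t_on + duration))
  segs <- data.frame(start = start,
                     end = c(start[-1], horizon),
                     intensity = c(if (t_on > 0) 0, intensity, 0))
  segs <- segs[segs$end > segs$start, ]
  lightProtocol(segs$start, segs$end, segs$intensity)
}

#' Concatenate two protocols in time
#' @param a,b \code{LightProtocol}s; \code{b} is shifted to start at the end
#'   of \code{a}.
#' @return A combined \code{LightProtocol}.
#' @export
concatProtocols <- function(a, b) {
  off <- protocolHorizon(a)
  lightProtocol(c(a@start, b@start + off), c(a@end, b@end + off),
                c(a@intensity, b@intensity))
}

#' Read/write protocols as delimited text
#'
#' Three-column tables \code{start,end,intensity} (hours, hours, a.u.).
#'
#' @param path file path.
#' @param protocol a \code{LightProtocol} (for writing).
#' @return \code{readProtocol} returns a \code{LightProtocol};
#'   \code{writeProtocol} invisibly returns the path.
#' @export
readProtocol <- function(path) {
  d <- utils::read.csv(path)
  need <- c("start", "end", "intensity")
  if (!all(need %in% names(d)))
    stop("protocol file must have columns: ", paste(need, collapse = ", "))
  lightProtocol(d$start, d$end, d$intensity)
}

#' @rdname readProtocol
#' @export
writeProtocol <- function(protocol, path) {
  utils::write.csv(data.frame(start = protocol@start, end = protocol@end,
                              intensity = protocol@intensity),
                   path, row.names = FALSE)
  invisible(path)
}
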