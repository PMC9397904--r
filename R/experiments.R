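#' Scan the length of the FRQ maturation chain
#'
#' Rebuilds the model with 1 to 6 maturation steps and reports, per step
#' count, rhythmicity of the frq observable and its mean level in constant
#' darkness. With \code{keep_total_delay = FALSE} (default) the per-step
#' rates are kept and removing steps shortens the transit delay; with
#' \code{TRUE} the remaining step rates are rescaled so the expected transit
#' time is preserved.
#'
#' A chain of s steps means: translation feeds pool 1, pools advance s-1
#' times, and the final advance produces the active FFC; s = 6 is the
#' unmodified model, s = 1 routes translation directly into the FFC.
#'
#' @param params a \code{ClockParameters} object or named vector.
#' @param steps integer vector, subset of 1:6 (default 6:1).
#' @param horizon DD simulation length in hours (default 240).
#' @param genotype genotype to simulate (default WT).
#' @param keep_total_delay see above.
#' @param rtol,atol integration tolerances.
#' @return A data.frame: \code{steps}, \code{rhythmic},
#'   \code{rel_amplitude}, \code{period}, \code{mean_frq}.
#' @export
maturationScan <- function(params, steps = 6:1, horizon = 240,
                           genotype = "WT", keep_total_delay = FALSE,
                           rtol = 1e-7, atol = 1e-9) {
  if (!all(steps %in% 1:6)) stop("steps must be a subset of 1:6")
  params <- .asParams(params)
  out <- lapply(steps, function(s) {
    p <- .chainVariant(params, s, keep_total_delay)
    x0 <- burnInState(p, genotype, rtol = rtol, atol = atol)
    dd <- simulateClock(p, genotype, darkProtocol(horizon), x0 = x0,
                        times = seq(0, horizon, 1 / 6),
                        rtol = rtol, atol = atol)
    y <- stateSeries(dd, "m_frq")
    ser <- data.frame(time_h = trajectoryTimes(dd), mean_cps = y,
                      sd_cps = 0, n = 1)
    # fit from 48 h so the rhythm call is not confounded by the relaxation
    # transient that reduced chains show after the synchronization burn-in
    f <- fitDampedCosine(ser, window = c(48, horizon))
    data.frame(steps = s, rhythmic = f$rhythmic,
               rel_amplitude = f$rel_amplitude, period = f$period,
               mean_frq = mean(y[trajectoryTimes(dd) >= 12]))
  })
  do.call(rbind, out)
}

# Reduce the 6-step chain to s steps. Steps are numbered translation = 1,
# pool advances 2..6. For s < 6 the surplus advances are made effectively
# instantaneous (very fast rates with no intermediate degradation), which is
# algebraically equivalent to deleting the pools while preserving state count.
.chainVariant <- function(params, s, keep_total_delay = FALSE) {
  p <- setNames(as.numeric(params), names(params))
  if (s == 6 && !keep_total_delay) return(.asParams(p))
  mat <- paste0("kmat_", 1:5)
  kdf <- paste0("kdf_", 1:5)
  keep <- s - 1 # pool advances retained
  if (keep_total_delay && keep > 0) {
    # preserve expected transit time: sum of 1/k over retained steps
    total <- sum(1 / p[mat])
    p[mat[seq_len(keep)]] <- keep / total
  }
  if (keep < 5) {
    fast <- mat[seq.int(keep + 1, 5)]
    # pass-through pools: ~1 min residence, negligible loss; equivalent to
    # deleting the step while keeping the state count (and integrator-friendly)
    p[fast] <- 50
    p[kdf[seq.int(keep + 1, 5)]] <- 1e-6
  }
  .asParams(p)
}

#' Delay and abundance ratio between new FRQ and active FFC
#'
#' Over one free-running cycle in darkness, measures the peak-time delay of
#' the assembled FFC relative to the first (newly translated) FRQ pool, and
#' the time-averaged ratio of all immature FRQ pools to the active complex.
#'
#' @param params a \code{ClockParameters} object or named vector.
#' @param protocol simulation protocol (default 240 h darkness).
#' @param genotype default WT.
#' @param rtol,atol integration tolerances.
#' @return A list with \code{delay_h} (> 0 when FFC lags) and
#'   \code{abundance_ratio} (immature / active, time-averaged).
#' @export
frqFfcDelay <- function(params, protocol = darkProtocol(240),
                        genotype = "WT", rtol = 1e-7, atol = 1e-9) {
  x0 <- burnInState(params, genotype, rtol = rtol, atol = atol)
  traj <- simulateClock(params, genotype, protocol, x0 = x0,
                        times = seq(0, protocolHorizon(protocol), 1 / 6),
                        rtol = rtol, atol = atol)
  t <- trajectoryTimes(traj)
  f1 <- stateSeries(traj, "F1")
  ffc <- stateSeries(traj, "FFC")
  w <- t >= 12
  s1 <- data.frame(time_h = t[w], mean_cps = f1[w], sd_cps = 0, n = 1)
  s2 <- data.frame(time_h = t[w], mean_cps = ffc[w], sd_cps = 0, n = 1)
  fit1 <- fitDampedCosine(s1); fit2 <- fitDampedCosine(s2)
  if (!fit1$rhythmic || !fit2$rhythmic)
    stop("frqFfcDelay requires a rhythmic regime")
  Tm <- mean(c(fit1$period, fit2$period))
  d <- (fit2$phase - fit1$phase) %% Tm
  immature <- rowSums(traj@states[w, paste0("F", 1:5)])
  list(delay_h = d, abundance_ratio = mean(immature / pmax(ffc[w], 1e-12)))
}

#' Light-pulse dose response of the frq and vvd promoters
#'
#' Applies a short light pulse at t = 7 min in otherwise constant darkness
#' and records the peak of each mRNA observable within a window after pulse
#' onset, per intensity and genotype.
#'
#' @param params a \code{ClockParameters} object or named vector.
#' @param intensities pulse intensities in a.u.
#'   (default \code{c(0, 0.005, 0.05, 0.5, 5)}).
#' @param genotypes default both WT and dvvd.
#' @param duration pulse length in hours (default 0.25).
#' @param peak_window hours after pulse onset searched for the peak
#'   (default 6).
#' @param horizon protocol length (default 24 h).
#' @param rtol,atol integration tolerances.
#' @return A data.frame: \code{genotype}, \code{intensity},
#'   \code{peak_frq}, \code{peak_vvd}.
#' @export
lightPulseResponse <- function(params, intensities = c(0, 0.005, 0.05, 0.5, 5),
                               genotypes = c("WT", "dvvd"), duration = 0.25,
                               peak_window = 6, horizon = 24,
                               rtol = 1e-7, atol = 1e-9) {
  if (any(intensities < 0)) stop("intensities must be >= 0")
  t_on <- 7 / 60
  rows <- list()
  for (g in genotypes) {
    x0 <- burnInState(params, g, rtol = rtol, atol = atol)
    for (I in intensities) {
      pr <- lightPulse(t_on, duration, I, horizon)
      traj <- simulateClock(params, g, pr, x0 = x0,
                            times = seq(0, horizon, 1 / 60),
                            rtol = rtol, atol = atol)
      t <- trajectoryTimes(traj)
      w <- t >= t_on & t <= t_on + peak_window
      rows[[length(rows) + 1]] <- data.frame(
        genotype = g, intensity = I,
        peak_frq = max(stateSeries(traj, "m_frq")[w]),
        peak_vvd = max(stateSeries(traj, "m_vvd")[w]))
    }
  }
  do.call(rbind, rows)
}

#' Scan the WCC reactivation rate kd2
#'
#' For each value of the dephosphorylation (reactivation) rate of P-WCC the
#' frq observable is simulated in constant darkness and its damping rate and
#' amplitude quantified with a damped-cosine fit.
#'
#' @param params a \code{ClockParameters} object or named vector.
#' @param kd2_values default \code{c(0.18, 0.14, 0.08)} per hour.
#' @param horizon DD length (default 400 h).
#' @param genotype default WT.
#' @param rtol,atol integration tolerances.
#' @return A data.frame: \code{kd2}, \code{damping}, \code{amplitude},
#'   \code{rel_amplitude}, \code{period}, \code{rhythmic}.
#' @export
kd2Scan <- function(params, kd2_values = c(0.18, 0.14, 0.08), horizon = 400,
                    genotype = "WT", rtol = 1e-7, atol = 1e-9) {
  if (any(kd2_values <= 0)) stop("kd2 values must be > 0")
  params <- .asParams(params)
  out <- lapply(kd2_values, function(k) {
    p <- params; p[["kd2"]] <- k
    x0 <- burnInState(p, genotype, rtol = rtol, atol = atol)
    dd <- simulateClock(p, genotype, darkProtocol(horizon), x0 = x0,
                        times = seq(0, horizon, 1 / 6),
                        rtol = rtol, atol = atol)
    ser <- data.frame(time_h = trajectoryTimes(dd),
                      mean_cps = stateSeries(dd, "m_frq"), sd_cps = 0, n = 1)
    f <- fitDampedCosine(ser, window = c(24, horizon))
    data.frame(kd2 = k, damping = f$damping, amplitude = f$amplitude,
               rel_amplitude = f$rel_amplitude, period = f$period,
               rhythmic = f$rhythmic)
  })
  do.call(rbind, out)
}

#' Cycle-to-cycle balance under repeated light-dark cycles
#'
#' Simulates n 12L:12D cycles and, for cycles \code{from} through n, computes
#' for every species the relative change of its cycle-mean level versus the
#' previous cycle. The system is balanced when the maximum deviation is
#' below 1 percent.
#'
#' @param params a \code{ClockParameters} object or named vector.
#' @param n_cycles number of LD cycles (default 10).
#' @param genotype default WT.
#' @param from first cycle entering the comparison (default 6, after the
#'   entrainment transient).
#' @param rtol,atol integration tolerances.
#' @return A list: \code{max_deviation} (scalar), \code{per_species} (named
#'   vector) and \code{balanced} (logical, deviation < 0.01).
#' @export
entrainmentBalance <- function(params, n_cycles = 10, genotype = "WT",
                               from = 6, rtol = 1e-7, atol = 1e-9) {
  if (n_cycles < 2) stop("n_cycles must be >= 2")
  x0 <- burnInState(params, genotype, rtol = rtol, atol = atol)
  traj <- simulateClock(params, genotype, repeatedLD(n_cycles), x0 = x0,
                        times = seq(0, 24 * n_cycles, 1 / 6),
                        rtol = rtol, atol = atol)
  t <- trajectoryTimes(traj)
  cyc <- pmin(floor(t / 24) + 1, n_cycles)
  means <- apply(traj@states, 2, function(y) tapply(y, cyc, mean))
  overall <- colMeans(traj@states)
  dev <- matrix(0, nrow = 0, ncol = ncol(means))
  for (i in seq(max(2, from), n_cycles)) {
    dev <- rbind(dev, abs(means[i, ] - means[i - 1, ]) / pmax(overall, 1e-12))
  }
  per_species <- apply(dev, 2, max)
  names(per_species) <- clockSpecies()
  # species absent in this genotype (identically ~0) are not informative
  per_species[overall < 1e-9] <- 0
  list(max_deviation = max(per_species), per_species = per_species,
       balanced = max(per_species) < 0.01)
}

#' Long free-run in darkness
#'
#' Simulates constant darkness (default 400 h) and quantifies period, phase,
#' amplitude and damping for each reporter observable.
#'
#' @param params a \code{ClockParameters} object or named vector.
#' @param horizon hours of darkness (default 400).
#' @param genotype default WT.
#' @param obs_params optional observation scales (default unit scales).
#' @param rtol,atol integration tolerances.
#' @return A data.frame with one row per reporter and the
#'   \code{\link{fitDampedCosine}} columns.
#' @export
longDarkRun <- function(params, horizon = 400, genotype = "WT",
                        obs_params = NULL, rtol = 1e-7, atol = 1e-9) {
  if (is.null(obs_params))
    obs_params <- observationParams(scale = c(frq = 1, vvd = 1, csp1 = 1,
                                              fam3 = 1))
  x0 <- burnInState(params, genotype, rtol = rtol, atol = atol)
  traj <- simulateClock(params, genotype, darkProtocol(horizon), x0 = x0,
                        times = seq(0, horizon, 1 / 6),
                        rtol = rtol, atol = atol)
  out <- lapply(names(.REPORTERS), function(r) {
    f <- fitDampedCosine(observe(traj, obs_params, r),
                         window = c(24, horizon))
    cbind(reporter = r, f)
  })
  do.call(rbind, out)
}
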