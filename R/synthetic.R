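#' The certified ground-truth kinetic parameters
#'
#' Loads the frozen synthetic ground-truth parameter set shipped with the
#' package. The values are \emph{not} experimentally fitted estimates;
#' they are a synthetic stand-in calibrated so
#' that the model reproduces the canonical qualitative and fold-change
#' phenotypes: ~22-24 h damped oscillations of all four reporters in
#' darkness with fam-3 in antiphase, entrainment balance under 12L:12D,
#' a positive phase delay of the vvd-knockout strain, lights-on induction of
#' ~18/~12-fold (frq), ~50/~10-fold (vvd) and ~6-fold (csp-1) in WT, an
#' approximately twofold higher vvd spike and ~5-fold higher adapted vvd
#' level in the knockout, and reduced damping as kd2 is lowered from 0.18
#' through 0.14 to 0.08 per hour.
#'
#' @return A \code{\link{ClockParameters-class}} object.
#' @seealso \code{\link{certifyGroundTruth}}, \code{\link{makeGroundTruth}}
#' @export
groundTruthParameters <- function() {
  path <- system.file("extdata", "ground_truth_params.tsv",
                      package = "neuroclock")
  readParams(path)
}

#' Observation scales used by the synthetic-data generator
#'
#' Arbitrary but fixed counts-per-second scales mapping each reporter's
#' mRNA to bioluminescence, of the magnitude of plate-reader counts.
#'
#' @return An \code{\link{observationParams}} object.
#' @export
groundTruthObservation <- function() {
  observationParams(scale = c(frq = 1500, vvd = 800, csp1 = 1200, fam3 = 400))
}

#' Certification checks for a ground-truth parameter set
#'
#' Runs the battery of phenotype checks that a parameter set must pass to
#' serve as the generator's ground truth. Each check row reports the
#' measured value, the admissible band and a pass flag.
#'
#' @param params a \code{ClockParameters} object or named vector.
#' @param rtol,atol integration tolerances.
#' @return A data.frame with columns \code{check}, \code{value},
#'   \code{lower}, \code{upper}, \code{pass}.
#' @export
certifyGroundTruth <- function(params, rtol = 1e-7, atol = 1e-9) {
  params <- .asParams(params)
  obs <- groundTruthObservation()
  rows <- list()
  add <- function(check, value, lower, upper)
    rows[[length(rows) + 1]] <<- data.frame(
      check = check, value = value, lower = lower, upper = upper,
      pass = is.finite(value) && value >= lower && value <= upper)

  dd <- list(); se <- list()
  for (g in c("WT", "dvvd")) {
    x0 <- burnInState(params, g, rtol = rtol, atol = atol)
    dd[[g]] <- simulateClock(params, g, darkProtocol(240), x0 = x0,
                             times = seq(0, 240, 1 / 6),
                             rtol = rtol, atol = atol)
    se[[g]] <- simulateClock(params, g, standardExperiment(), x0 = x0,
                             times = seq(0, 172, 1 / 6),
                             rtol = rtol, atol = atol)
  }
  fits <- list()
  for (g in c("WT", "dvvd")) for (r in names(.REPORTERS)) {
    s <- observe(dd[[g]], obs, r)
    f <- fitDampedCosine(s, window = c(12, 240))
    fits[[paste(g, r)]] <- f
    add(paste0("period_", g, "_", r), f$period, 20, 26)
    add(paste0("rel_amplitude_", g, "_", r), f$rel_amplitude, 0.05, Inf)
  }
  add("damping_WT_frq", fits[["WT frq"]]$damping, 1e-4, 0.02)
  # fam-3 is the evening (antiphasic) reporter
  pd_fam <- phaseDifference(observe(dd$WT, obs, "frq"),
                            observe(dd$WT, obs, "fam3"), window = c(12, 240))
  Tm <- fits[["WT frq"]]$period
  add("fam3_antiphase_offset_h", abs(pd_fam), Tm / 2 - 4.5, Tm / 2 + 4.5)
  for (r in names(.REPORTERS)) {
    pd <- phaseDifference(observe(dd$WT, obs, r), observe(dd$dvvd, obs, r),
                          window = c(12, 240))
    add(paste0("dvvd_phase_delay_", r), pd, 0.5, 8)
  }
  fi <- function(g, r) foldInduction(observe(se[[g]], obs, r), 72)
  f_frq <- fi("WT", "frq"); f_vvd <- fi("WT", "vvd"); f_csp <- fi("WT", "csp1")
  add("fold_peak_WT_frq", f_frq[1], 10, 50)
  add("fold_adapt_WT_frq", f_frq[2], 6, 24)
  add("fold_peak_WT_vvd", f_vvd[1], 25, 100)
  add("fold_adapt_WT_vvd", f_vvd[2], 5, 20)
  add("fold_peak_WT_csp1", f_csp[1], 3, 12)
  add("fold_adapt_WT_csp1", f_csp[2], 0.5, 2)
  fv_d <- fi("dvvd", "vvd")
  add("vvd_spike_ratio_dvvd_WT", fv_d[1] / f_vvd[1], 1.3, 3)
  add("vvd_adapt_ratio_dvvd_WT", fv_d[2] / f_vvd[2], 3, 8)
  # entrainment: observables must repeat cycle-to-cycle to < 1% of their
  # maximum after a 5-cycle transient; the stricter species-level cycle-mean
  # drift (see entrainmentBalance) is bounded at 5% and still converging,
  # reflecting the slow turnover of the stable P-WCC reservoir (vignette)
  add("entrainment_observable_repeatability",
      .ldRepeatability(params, obs, rtol = rtol, atol = atol), 0, 0.01)
  bal <- entrainmentBalance(params, 10, rtol = rtol, atol = atol)
  add("entrainment_species_mean_drift", bal$max_deviation, 0, 0.05)
  do.call(rbind, rows)
}

# worst-case |y(t+24) - y(t)| / max(y) over the reporter observables for
# cycles 6..9 of a 10-cycle 12L:12D run
.ldRepeatability <- function(params, obs, rtol = 1e-7, atol = 1e-9) {
  x0 <- burnInState(params, "WT", rtol = rtol, atol = atol)
  tr <- simulateClock(params, "WT", repeatedLD(10), x0 = x0,
                      times = seq(0, 240, 1 / 6), rtol = rtol, atol = atol)
  t <- trajectoryTimes(tr)
  i1 <- which(t >= 120 & t <= 216)
  i2 <- match(round(t[i1] + 24, 6), round(t, 6))
  max(vapply(names(.REPORTERS), function(r) {
    y <- observe(tr, obs, r)$mean_cps
    max(abs(y[i2] - y[i1])) / max(y)
  }, 0.0))
}

#' Obtain a certified ground truth
#'
#' Returns the frozen, certified parameter set; with \code{search = TRUE}
#' it instead perturbs the frozen set deterministically (log-normal jitter
#' of the non-structural parameters) and returns the first perturbation that
#' passes certification, which exercises the certification machinery itself.
#'
#' @param seed integer seed controlling the (optional) search.
#' @param search logical; default FALSE returns the frozen set.
#' @param max_tries search budget (default 20).
#' @param jitter_sd log-scale standard deviation of the perturbation
#'   (default 0.02).
#' @return A list with \code{params} (\code{ClockParameters}),
#'   \code{obs_params} and \code{certification} (the check table).
#' @export
makeGroundTruth <- function(seed = 1, search = FALSE, max_tries = 20,
                            jitter_sd = 0.02) {
  base <- groundTruthParameters()
  if (!search) {
    cert <- certifyGroundTruth(base)
    if (!all(cert$pass))
      warning("frozen ground truth failed certification check(s): ",
              paste(cert$check[!cert$pass], collapse = ", "))
    return(list(params = base, obs_params = groundTruthObservation(),
                certification = cert))
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  for (i in seq_len(max_tries)) {
    cand <- setNames(as.numeric(base) *
                       exp(rnorm(length(base), 0, jitter_sd)), names(base))
    b <- lightSpeciesDegradationBound()
    cand[names(b)] <- pmax(cand[names(b)], b)
    cand["kd2"] <- base[["kd2"]] # kd2 anchors the damping scan
    cert <- tryCatch(certifyGroundTruth(clockParameters(cand)),
                     error = function(e) NULL)
    if (!is.null(cert) && all(cert$pass))
      return(list(params = clockParameters(cand),
                  obs_params = groundTruthObservation(),
                  certification = cert))
  }
  stop("ground-truth search exhausted after ", max_tries,
       " tries; widen jitter or bounds")
}

#' Generate a synthetic reporter dataset
#'
#' Simulates each requested strain under the protocol, maps states onto the
#' reporter observables, and draws n replicate measurements per time point
#' from a truncated normal with mean-proportional noise:
#' signal ~ N(mean, (cv * mean + floor)^2), truncated at 0. The emitted table
#' reports the replicate mean, SD and n on a regular grid, emulating the
#' layout of plate-reader reporter tables.
#'
#' @param truth a \code{ClockParameters} object or named vector.
#' @param obs_params an \code{\link{observationParams}} object.
#' @param protocol a \code{LightProtocol} (default
#'   \code{standardExperiment()}).
#' @param cv coefficient of variation of the replicate noise (default 0.1).
#' @param floor additive noise floor in signal units (default 0).
#' @param n replicates per time point (default 30).
#' @param seed integer seed; the dataset is deterministic given it.
#' @param strains default both WT and dvvd.
#' @param reporters default all four.
#' @param dt sampling cadence in hours (default 1/6, i.e. 10 min).
#' @param rtol,atol integration tolerances.
#' @return Long-format data.frame: \code{strain}, \code{reporter},
#'   \code{time_h}, \code{mean_cps}, \code{sd_cps}, \code{n}.
#' @export
generateDataset <- function(truth, obs_params = groundTruthObservation(),
                            protocol = standardExperiment(),
                            cv = 0.1, floor = 0, n = 30, seed = 1,
                            strains = c("WT", "dvvd"),
                            reporters = names(.REPORTERS), dt = 1 / 6,
                            rtol = 1e-7, atol = 1e-9) {
  if (cv < 0 || floor < 0 || n < 1) stop("invalid noise model")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  times <- seq(0, protocolHorizon(protocol), by = dt)
  out <- list()
  for (g in strains) {
    x0 <- burnInState(truth, g, rtol = rtol, atol = atol)
    traj <- simulateClock(truth, g, protocol, x0 = x0, times = times,
                          rtol = rtol, atol = atol)
    for (r in reporters) {
      noiseless <- observe(traj, obs_params, r, strain = g)
      mu <- noiseless$mean_cps
      if (cv == 0 && floor == 0) {
        m <- mu; s <- rep(0, length(mu))
      } else {
        draws <- matrix(rnorm(length(mu) * n, mean = mu,
                              sd = cv * mu + floor),
                        nrow = length(mu))
        draws[draws < 0] <- 0
        m <- rowMeans(draws)
        s <- apply(draws, 1, sd)
      }
      out[[paste(g, r)]] <- data.frame(
        strain = g, reporter = r, time_h = times, mean_cps = m,
        sd_cps = s, n = as.integer(n), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
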