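# shared fixtures, built once per test run

gtParams <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- groundTruthParameters()
    cache
  }
})

gtObs <- function() groundTruthObservation()

# a valid but arbitrary random parameter set (not an oscillator)
randomParams <- function(seed = 1) {
  set.seed(seed)
  p <- setNames(exp(runif(66, log(0.05), log(3))), clockParameterNames())
  b <- lightSpeciesDegradationBound()
  p[names(b)] <- pmax(p[names(b)], b * 1.05)
  clockParameters(p)
}

randomState <- function(seed = 1, max = 3) {
  set.seed(seed)
  setNames(runif(18, 0, max), clockSpecies())
}

# integrate a raw parameter vector without ClockParameters validity checks
# (for structural experiments that switch rates off entirely)
rawIntegrate <- function(x0, pvec, u, horizon, rtol = 1e-10, atol = 1e-12) {
  st <- neuroclock:::.clockIntegrateCpp(
    as.numeric(x0[clockSpecies()]), as.numeric(pvec[clockParameterNames()]),
    0, horizon, u, horizon, rtol, atol, 5e6)
  setNames(st[1, ], clockSpecies())
}

# noiseless damped cosine reporter series
cosineSeries <- function(T = 22, lambda = 0.01, phi = 0, baseline = 100,
                         amp = 40, t = seq(0, 120, 1 / 6)) {
  data.frame(time_h = t,
             mean_cps = baseline + amp * exp(-lambda * t) *
               cos(2 * pi * t / T + phi),
             sd_cps = 0, n = 1L)
}

# cached WT dark trajectory of the ground truth (reused across tests)
gtDarkTrajectory <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      p <- gtParams()
      x0 <- burnInState(p, "WT", rtol = 1e-6, atol = 1e-8)
      cache <<- simulateClock(p, "WT", darkProtocol(240), x0 = x0,
                              times = seq(0, 240, 1 / 6),
                              rtol = 1e-6, atol = 1e-8)
    }
    cache
  }
})

gtDvvdDarkTrajectory <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      p <- gtParams()
      x0 <- burnInState(p, "dvvd", rtol = 1e-6, atol = 1e-8)
      cache <<- simulateClock(p, "dvvd", darkProtocol(240), x0 = x0,
                              times = seq(0, 240, 1 / 6),
                              rtol = 1e-6, atol = 1e-8)
    }
    cache
  }
})

gtStandardRun <- local({
  cache <- list()
  function(genotype = "WT") {
    if (is.null(cache[[genotype]])) {
      p <- gtParams()
      x0 <- burnInState(p, genotype, rtol = 1e-6, atol = 1e-8)
      cache[[genotype]] <<- simulateClock(p, genotype, standardExperiment(),
                                          x0 = x0, times = seq(0, 172, 1 / 6),
                                          rtol = 1e-6, atol = 1e-8)
    }
    cache[[genotype]]
  }
})
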