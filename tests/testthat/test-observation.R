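test_that("observe maps the cognate mRNA through scale and background", {
  tr <- gtDarkTrajectory()
  obs1 <- observationParams(scale = c(frq = 1, vvd = 1, csp1 = 1, fam3 = 1))
  s <- observe(tr, obs1, "frq")
  expect_equal(s$mean_cps, unname(stateSeries(tr, "m_frq")))
  expect_true(all(s$sd_cps == 0) && all(s$n == 1))
  obs2 <- observationParams(scale = c(frq = 2, vvd = 1, csp1 = 1, fam3 = 1),
                            background = c(frq = 5, vvd = 0, csp1 = 0, fam3 = 0))
  s2 <- observe(tr, obs2, "frq")
  expect_equal(s2$mean_cps - 5, 2 * s$mean_cps)
  expect_error(observe(tr, obs1, "wc1"), "reporter")
})

test_that("fold induction behaves on constructed series", {
  t <- seq(50, 96, 1 / 6)
  flat <- data.frame(time_h = t, mean_cps = 7, sd_cps = 0, n = 1L)
  expect_equal(unname(foldInduction(flat, 72)), c(1, 1))
  k <- 13
  step <- data.frame(time_h = t, mean_cps = ifelse(t > 72, 7 * k, 7),
                     sd_cps = 0, n = 1L)
  expect_equal(unname(foldInduction(step, 72)), c(k, k))
  # invariance under positive rescaling
  step2 <- step; step2$mean_cps <- step2$mean_cps * 37.5
  expect_equal(foldInduction(step2, 72), foldInduction(step, 72))
  zero <- flat; zero$mean_cps <- 0
  expect_error(foldInduction(zero, 72), "baseline")
})

test_that("damped cosine fits recover known parameters exactly", {
  s <- cosineSeries(T = 22, lambda = 0.01, phi = 0.8)
  f <- fitDampedCosine(s)
  expect_true(f$rhythmic)
  expect_equal(f$period, 22, tolerance = 0.01 / 22)
  expect_equal(f$damping, 0.01, tolerance = 0.01)
  # peak phase: cos peaks where 2 pi t / T + phi = 0
  expect_equal(f$phase, (-0.8 * 22 / (2 * pi)) %% 22, tolerance = 0.05)
})

test_that("constant and pure-noise series are called non-rhythmic", {
  t <- seq(0, 120, 1 / 6)
  flat <- data.frame(time_h = t, mean_cps = 50, sd_cps = 0, n = 1L)
  expect_false(fitDampedCosine(flat)$rhythmic)
  set.seed(1)
  noise <- data.frame(time_h = t, mean_cps = 50 + rnorm(length(t), 0, 0.5),
                      sd_cps = 0, n = 1L)
  r <- rhythmicity(noise)
  expect_false(r$rhythmic)
})

test_that("parameter recovery holds across 100 random damped cosines", {
  # property: at SNR >= 20, period, damping and phase recover within 1%
  set.seed(42)
  ok <- 0
  for (i in 1:100) {
    T <- runif(1, 18, 30)
    lam <- runif(1, 0.002, 0.018)
    phi <- runif(1, -pi, pi)
    base <- runif(1, 50, 200)
    amp <- base * runif(1, 0.2, 0.6)
    t <- seq(0, 140, 1 / 4)
    y <- base + amp * exp(-lam * t) * cos(2 * pi * t / T + phi) +
      rnorm(length(t), 0, amp / 20) # SNR 20 on the oscillatory part
    f <- fitDampedCosine(data.frame(time_h = t, mean_cps = y, sd_cps = 0,
                                    n = 1L))
    per_ok <- abs(f$period - T) / T < 0.01
    phase_true <- (-phi * T / (2 * pi)) %% T
    dphi <- min(abs(f$phase - phase_true), T - abs(f$phase - phase_true))
    ok <- ok + (f$rhythmic && per_ok && dphi < 0.01 * T + 0.15)
  }
  expect_gte(ok, 97)
})

test_that("phase differences are antisymmetric and recover known shifts", {
  s <- cosineSeries(T = 23, lambda = 0.005, phi = 0)
  shift <- 2
  s2 <- cosineSeries(T = 23, lambda = 0.005, phi = -2 * pi * shift / 23)
  expect_equal(phaseDifference(s, s), 0, tolerance = 1e-6)
  expect_equal(phaseDifference(s, s2), shift, tolerance = 0.05)
  expect_equal(phaseDifference(s2, s), -phaseDifference(s, s2),
               tolerance = 0.05)
  flat <- data.frame(time_h = s$time_h, mean_cps = 1, sd_cps = 0, n = 1L)
  expect_error(phaseDifference(s, flat), "rhythmic")
})

test_that("the observation model round-trips through the generator", {
  # noiseless synthetic data equals observe() of the same simulation
  p <- gtParams(); obs <- gtObs()
  d <- generateDataset(p, obs, protocol = darkProtocol(48), cv = 0, n = 1,
                       seed = 1, strains = "WT", reporters = "frq", dt = 0.5)
  x0 <- burnInState(p, "WT", rtol = 1e-7, atol = 1e-9)
  tr <- simulateClock(p, "WT", darkProtocol(48), x0 = x0,
                      times = seq(0, 48, 0.5), rtol = 1e-7, atol = 1e-9)
  s <- observe(tr, obs, "frq")
  expect_equal(d$mean_cps, s$mean_cps, tolerance = 1e-12)
})

test_that("the optional reporter-protein filter lags and smooths the mRNA", {
  tr <- gtDarkTrajectory()
  obs <- observationParams(scale = c(frq = 1, vvd = 1, csp1 = 1, fam3 = 1))
  direct <- observe(tr, obs, "frq")
  filt <- observe(tr, obs, "frq", luc_halflife = 1.5)
  # unit steady-state gain: time-averaged signal is preserved closely
  expect_equal(mean(filt$mean_cps), mean(direct$mean_cps), tolerance = 0.02)
  # the filtered rhythm peaks later and with smaller amplitude
  fd <- fitDampedCosine(direct, window = c(12, 240))
  ff <- fitDampedCosine(filt, window = c(12, 240))
  expect_lt(ff$amplitude, fd$amplitude)
  dphi <- (ff$phase - fd$phase) %% fd$period
  expect_gt(dphi, 0.2); expect_lt(dphi, 6)
  # a constant input passes through unchanged
  t <- seq(0, 10, 0.1)
  expect_equal(neuroclock:::.reporterFilter(t, rep(3, length(t)), 0.5),
               rep(3, length(t)), tolerance = 1e-12)
})
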