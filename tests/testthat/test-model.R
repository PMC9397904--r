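test_that("compiled derivatives match the stoichiometry-matrix oracle", {
  # 1000 random state/parameter/light points, 1e-12 relative agreement
  set.seed(100)
  worst <- 0
  for (i in 1:1000) {
    p <- randomParams(seed = i)
    x <- randomState(seed = i + 5000, max = 5)
    u <- runif(1, 0, 2)
    d_fast <- clockDerivatives(x, p, u)
    d_oracle <- neuroclock:::.derivOracle(x, p, u)
    # relative to the derivative scale: near-cancelled components only carry
    # summation-order noise, which is not a disagreement of the formulations
    den <- pmax(abs(d_oracle), 1e-3 * max(abs(d_oracle)))
    worst <- max(worst, max(abs(d_fast - d_oracle) / den))
  }
  expect_lt(worst, 1e-12)
})

test_that("darkness silences all photon-flux terms", {
  p <- randomParams(3)
  x <- randomState(3)
  d <- clockDerivatives(x, p, light = 0)
  # with no VVDs/WCCVVDs/WCC2s present, dark derivatives have no light terms:
  x0 <- x
  x0[c("WCCs", "WCC2s", "WCCVVDs", "VVDs")] <- 0
  d0 <- clockDerivatives(x0, p, light = 0)
  # VVDs production is zero in the dark
  expect_equal(d0[["VVDs"]], 0)
  expect_equal(d0[["WCCs"]], 0)
  # and raising light creates them
  dl <- clockDerivatives(x0, p, light = 1)
  expect_gt(dl[["WCCs"]], 0)
  expect_gt(dl[["VVDs"]], 0)
})

test_that("from an empty state only mRNAs are produced", {
  p <- randomParams(4)
  d <- clockDerivatives(setNames(numeric(18), clockSpecies()), p, light = 1)
  mrna <- grepl("^m_", clockSpecies())
  expect_true(all(d[mrna] > 0))
  expect_true(all(d[!mrna] == 0))
})

test_that("invalid inputs are rejected with the offending entry named", {
  p <- randomParams(5)
  x <- randomState(5)
  xb <- x; xb["FFC"] <- NaN
  expect_error(clockDerivatives(xb, p, 0), "FFC")
  pb <- setNames(as.numeric(p), names(p)); pb["kd2"] <- -1
  expect_error(clockParameters(pb), "kd2")
  pb2 <- setNames(as.numeric(p), names(p)); pb2["kdeg_wccs"] <- 0.1
  expect_error(clockParameters(pb2), "half-time")
  expect_error(clockDerivatives(x, p, -1), "light")
})

test_that("genotype handling zeroes VVD production and nothing else", {
  p <- randomParams(6)
  expect_equal(as.numeric(applyGenotype(p, "WT")), as.numeric(p))
  pd <- applyGenotype(p, "dvvd")
  expect_equal(pd[["ktl_vvd"]], 0)
  others <- setdiff(clockParameterNames(), "ktl_vvd")
  expect_equal(as.numeric(pd[others]), as.numeric(p[others]))
  expect_error(applyGenotype(p, "hettero"), "genotype")
})

test_that("the vvd knockout never produces VVD protein species", {
  p <- gtParams()
  x0 <- burnInState(p, "dvvd", rtol = 1e-6, atol = 1e-8)
  expect_equal(unname(x0[c("VVD", "VVDs", "WCCVVDs")]), c(0, 0, 0))
  tr <- gtDvvdDarkTrajectory()
  expect_equal(max(stateSeries(tr, "VVD")), 0)
  expect_equal(max(stateSeries(tr, "VVDs")), 0)
  expect_equal(max(stateSeries(tr, "WCCVVDs")), 0)
})

test_that("light-activated species decay away in darkness", {
  p <- randomParams(7)
  x0 <- randomState(7, max = 2) # includes light species
  tr <- simulateClock(p, "WT", darkProtocol(200), x0 = x0,
                      times = c(0, 100, 200))
  final <- tr@states[3, c("WCCs", "WCC2s", "WCCVVDs", "VVDs")]
  expect_true(all(final < 1e-6))
})

test_that("total WCC mass is conserved without synthesis and degradation", {
  # structural bookkeeping check: with all WCC synthesis and degradation
  # switched off (bypassing the half-time validity bound on purpose) and
  # light constant, WCC + P_WCC + WCCs + 2 WCC2s + WCCVVDs is invariant
  p <- setNames(as.numeric(randomParams(8)), clockParameterNames())
  p[c("ktl_wcc", "kdeg_wcc", "kdeg_pwcc", "kdeg_wccs", "kdeg_wcc2s",
      "kdeg_wccvvds")] <- 0
  x0 <- randomState(8, max = 2)
  mass <- function(x) unname(x["WCC"] + x["P_WCC"] + x["WCCs"] +
                               2 * x["WCC2s"] + x["WCCVVDs"])
  st <- rawIntegrate(x0, p, u = 0.5, horizon = 30)
  expect_equal(mass(st), mass(x0), tolerance = 1e-7)
  # VVD mass likewise (VVD + VVDs + WCCVVDs) once its sources/sinks are off
  p[c("ktl_vvd", "kdeg_vvd", "kdeg_vvds")] <- 0
  st <- rawIntegrate(x0, p, u = 0.5, horizon = 30)
  vmass <- function(x) unname(x["VVD"] + x["VVDs"] + x["WCCVVDs"])
  expect_equal(vmass(st), vmass(x0), tolerance = 1e-7)
})

test_that("maturation chain steady state matches the closed form", {
  # constant m_frq and frozen WCC variables: steady FFC inflow equals
  # translation flux times the product of kmat/(kmat + kdf) over the chain
  p <- setNames(as.numeric(randomParams(9)), clockParameterNames())
  kmat <- p[paste0("kmat_", 1:5)]
  kdf <- p[paste0("kdf_", 1:5)]
  m_frq <- 1.7
  flux_in <- p["ktl_frq"] * m_frq
  # closed form for the steady pools
  f <- numeric(5)
  inflow <- flux_in
  for (i in 1:5) {
    f[i] <- inflow / (kmat[i] + kdf[i])
    inflow <- kmat[i] * f[i]
  }
  ffc_inflow_expected <- unname(flux_in * prod(kmat / (kmat + kdf)))
  expect_equal(unname(inflow), ffc_inflow_expected, tolerance = 1e-12)
  # simulate the chain to steady state with mRNA and WCC frozen by zeroing
  # their couplings
  x0 <- setNames(numeric(18), clockSpecies())
  x0["m_frq"] <- m_frq
  pz <- p
  pz["kdm_frq"] <- 1e-12 # freeze m_frq (no transcription either)
  pz[c("bas_frq", "vmax_d_frq", "vmax_l_frq")] <- 1e-12
  pz["kdeg_ffc"] <- 0.5
  st <- rawIntegrate(x0, pz, u = 0, horizon = 400)
  expect_equal(unname(st[paste0("F", 1:5)]), unname(f), tolerance = 1e-5)
  expect_equal(unname(st["FFC"]), ffc_inflow_expected / 0.5, tolerance = 1e-5)
})

test_that("halving solver tolerances leaves states unchanged to 1e-4", {
  p <- gtParams()
  x0 <- burnInState(p, "WT", rtol = 1e-6, atol = 1e-8)
  a <- simulateClock(p, "WT", standardExperiment(), x0 = x0,
                     times = c(80, 120, 172), rtol = 1e-8, atol = 1e-10)
  b <- simulateClock(p, "WT", standardExperiment(), x0 = x0,
                     times = c(80, 120, 172), rtol = 5e-9, atol = 5e-11)
  rel <- abs(a@states - b@states) / pmax(abs(b@states), 1e-6)
  expect_lt(max(rel), 1e-4)
})

test_that("adaptive integration agrees with a fixed-step RK4 reference", {
  p <- randomParams(11)
  x0 <- randomState(11, max = 1)
  a <- simulateClock(p, "WT", lightProtocol(0, 2, 0.8), x0 = x0,
                     times = c(0, 2))@states[2, ]
  b <- neuroclock:::.clockRk4Cpp(as.numeric(x0), as.numeric(p), 0.8,
                                 0, 2, 1e-3)
  expect_lt(max(abs(a - b) / pmax(abs(b), 1e-8)), 1e-5)
})

test_that("trajectories stay non-negative for random valid inputs", {
  for (s in 1:5) {
    p <- randomParams(20 + s)
    x0 <- randomState(40 + s, max = 2)
    tr <- simulateClock(p, "WT", repeatedLD(2), x0 = x0,
                        times = seq(0, 48, 0.5), rtol = 1e-7, atol = 1e-9)
    expect_true(all(tr@states >= 0)) # post-clamp contract
  }
})

test_that("burn-in forgets its own starting guess", {
  p <- gtParams()
  a <- burnInState(p, "WT", x0_seed = setNames(rep(0.05, 18), clockSpecies()),
                   rtol = 1e-7, atol = 1e-9)
  b <- burnInState(p, "WT", x0_seed = setNames(rep(1.5, 18), clockSpecies()),
                   rtol = 1e-7, atol = 1e-9)
  rel <- abs(a - b) / pmax(pmax(abs(a), abs(b)), 1e-3)
  expect_lt(max(rel), 0.05)
})

test_that("dark-adapted burn-in state is nearly closed under one period", {
  # free-running limit set: re-simulating one full period from the burn-in
  # returns close to the same state (up to the slow damping)
  p <- gtParams()
  x0 <- burnInState(p, "WT", rtol = 1e-7, atol = 1e-9)
  dd <- gtDarkTrajectory()
  f <- fitDampedCosine(observe(dd, gtObs(), "frq"), window = c(12, 240))
  Tper <- f$period
  tr <- simulateClock(p, "WT", darkProtocol(3 * Tper), x0 = x0,
                      times = c(0, Tper, 2 * Tper), rtol = 1e-7, atol = 1e-9)
  s1 <- tr@states[2, ]; s2 <- tr@states[3, ]
  rel <- abs(s2 - s1) / pmax(pmax(s1, s2), 1e-2)
  # the certified truth is a damped oscillator, so closure is approximate:
  # one period shrinks the orbit by roughly exp(-lambda T) ~ 0.97 plus the
  # period-estimate error
  expect_lt(max(rel), 0.25)
})
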