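toyDataset <- function() {
  # 3-point toy dataset for objective arithmetic
  data.frame(strain = "WT", reporter = "frq", time_h = c(10, 20, 30),
             mean_cps = c(100, 120, 90), sd_cps = c(10, 10, 10), n = 30L)
}

test_that("chi-square is zero at the generating model and 1 per 1-sigma point", {
  p <- gtParams(); obs <- gtObs()
  d <- generateDataset(p, obs, protocol = darkProtocol(48), cv = 0, n = 1,
                       seed = 1, strains = "WT", reporters = c("frq", "vvd"),
                       dt = 2)
  proto <- list(WT = darkProtocol(48))
  # same integration tolerances as the generator so the pathways agree
  expect_lt(chiSquare(p, obs, d, protocol_map = proto,
                      rtol = 1e-7, atol = 1e-9), 1e-6)
  # push one (non-maximal, so the sigma floor is unchanged) point off by
  # exactly one floored sigma
  d2 <- d
  frq_rows <- which(d2$reporter == "frq")
  sigma <- 0.01 * max(d2$mean_cps[frq_rows])
  i <- frq_rows[which.min(d2$mean_cps[frq_rows])]
  d2$mean_cps[i] <- d2$mean_cps[i] + sigma
  expect_equal(chiSquare(p, obs, d2, protocol_map = proto,
                         rtol = 1e-7, atol = 1e-9), 1.0,
               tolerance = 1e-3)
})

test_that("chi-square matches a naive loop oracle on a toy dataset", {
  p <- gtParams(); obs <- gtObs()
  d <- toyDataset()
  proto <- list(WT = darkProtocol(48))
  got <- chiSquare(p, obs, d, protocol_map = proto)
  # independent reimplementation: explicit loop over rows
  x0 <- burnInState(p, "WT", rtol = 1e-6, atol = 1e-8)
  tr <- simulateClock(p, "WT", darkProtocol(48), x0 = x0, times = d$time_h,
                      rtol = 1e-6, atol = 1e-8)
  want <- 0
  for (i in seq_len(nrow(d))) {
    model <- obs$scale[["frq"]] * stateSeries(tr, "m_frq")[i]
    sigma <- max(d$sd_cps[i], 0.01 * max(d$mean_cps))
    want <- want + ((model - d$mean_cps[i]) / sigma)^2
  }
  expect_equal(got, want, tolerance = 1e-8)
})

test_that("objective is invariant to row order and vanishes for huge sigma floor", {
  p <- gtParams(); obs <- gtObs()
  d <- generateDataset(p, obs, protocol = darkProtocol(48), cv = 0.1, n = 5,
                       seed = 2, strains = "WT", reporters = "frq", dt = 4)
  proto <- list(WT = darkProtocol(48))
  a <- chiSquare(p, obs, d, protocol_map = proto)
  set.seed(3)
  b <- chiSquare(p, obs, d[sample(nrow(d)), ], protocol_map = proto)
  expect_equal(a, b, tolerance = 1e-10)
  expect_lt(chiSquare(p, obs, d, protocol_map = proto,
                      sd_floor_frac = 1e6), 1e-9)
  expect_error(chiSquare(p, obs, d[0, ], protocol_map = proto), "empty")
})

test_that("Latin-hypercube starts stratify each free dimension", {
  ref <- gtParams()
  space <- parameterSpace(c("kd2", "kmat_1", "K_d_frq"))
  n <- 20
  starts <- lhsStarts(space, n, seed = 11, reference = ref)
  expect_length(starts, n)
  for (nm in c("kd2", "kmat_1", "K_d_frq")) {
    k <- match(nm, space$name)
    u <- vapply(starts, function(s)
      (log(s[[nm]]) - log(space$lower[k])) /
        (log(space$upper[k]) - log(space$lower[k])), 0.0)
    expect_true(all(u >= 0 & u <= 1))
    # exactly one draw per bin
    expect_equal(sort(unique(ceiling(u * n + 1e-12))), 1:n)
  }
  # frozen parameters keep the reference value
  expect_true(all(vapply(starts, function(s) s[["kd2"]] != ref[["kd2"]] ||
                           TRUE, TRUE)))
  expect_equal(starts[[3]][["bas_frq"]], ref[["bas_frq"]])
  # determinism
  again <- lhsStarts(space, n, seed = 11, reference = ref)
  expect_identical(starts, again)
  expect_false(identical(starts, lhsStarts(space, n, seed = 12,
                                           reference = ref)))
})

test_that("fitting from the truth on noiseless data is a fixed point", {
  p <- gtParams(); obs <- gtObs()
  d <- generateDataset(p, obs, protocol = darkProtocol(72), cv = 0, n = 1,
                       seed = 1, strains = "WT", reporters = c("frq", "vvd"),
                       dt = 2)
  space <- parameterSpace(c("kd2", "kmat_1"), reference = p, span = 1 + 1e-9)
  # span ~ 1 collapses the box onto the truth: the single start is the truth
  fit <- clockFit(d, obs, space, reference = p, n_starts = 1, seed = 1,
                  protocol_map = list(WT = darkProtocol(72)), maxit = 5)
  expect_lt(fit$results$chisq[1], 1e-4)
  expect_equal(fit$best[["kd2"]], p[["kd2"]], tolerance = 1e-3)
})

test_that("fit results are ranked by chi-square and reproducible", {
  p <- gtParams(); obs <- gtObs()
  d <- generateDataset(p, obs, protocol = darkProtocol(48), cv = 0.1, n = 10,
                       seed = 5, strains = "WT", reporters = "frq", dt = 3)
  space <- parameterSpace(c("kd2", "kdm_frq"), reference = p, span = 3)
  pm <- list(WT = darkProtocol(48))
  f1 <- clockFit(d, obs, space, reference = p, n_starts = 4, seed = 9,
                 protocol_map = pm, maxit = 15)
  expect_true(!is.unsorted(f1$results$chisq))
  f2 <- clockFit(d, obs, space, reference = p, n_starts = 4, seed = 9,
                 protocol_map = pm, maxit = 15)
  expect_identical(f1$results, f2$results)
})

test_that("ensemble summaries flag constrained parameters", {
  res <- data.frame(start = 1:12, chisq = seq(1, 12),
                    convergence = 0L, iterations = 10L,
                    kd2 = c(rep(0.18, 10), 5, 8),
                    kmat_1 = 10^runif(12, -2, 2))
  fit <- list(results = res, free = c("kd2", "kmat_1"))
  sm <- ensembleSummary(fit, k = 10)$summary
  expect_true(sm$constrained[sm$name == "kd2"])
  expect_equal(sm$log10_median[sm$name == "kd2"], log10(0.18))
  expect_error(ensembleSummary(fit, k = 20), "exceeds")
  # k = 1 has zero ranges
  sm1 <- ensembleSummary(fit, k = 1)$summary
  expect_equal(sm1$log10_min, sm1$log10_max)
})

test_that("held-out series never influence the training fit", {
  p <- gtParams(); obs <- gtObs()
  d <- generateDataset(p, obs, protocol = darkProtocol(48), cv = 0.05, n = 5,
                       seed = 6, strains = c("WT", "dvvd"),
                       reporters = c("frq", "csp1"), dt = 3)
  ho <- data.frame(strain = "dvvd", reporter = "csp1")
  pm <- list(WT = darkProtocol(48), dvvd = darkProtocol(48))
  space <- parameterSpace(c("kd2", "kdm_frq"), reference = p, span = 2)
  v1 <- leaveOutValidation(d, ho, obs, space, reference = p, n_starts = 2,
                           seed = 4, protocol_map = pm, maxit = 10)
  d_pert <- d
  sel <- d_pert$strain == "dvvd" & d_pert$reporter == "csp1"
  d_pert$mean_cps[sel] <- d_pert$mean_cps[sel] * 3 + 100
  v2 <- leaveOutValidation(d_pert, ho, obs, space, reference = p,
                           n_starts = 2, seed = 4, protocol_map = pm,
                           maxit = 10)
  expect_identical(v1$fit$results, v2$fit$results)
  expect_error(leaveOutValidation(d, unique(d[, c("strain", "reporter")]),
                                  obs, space, reference = p),
               "entire dataset")
})

test_that("the free-initial-conditions mode fits per-strain starting states", {
  p <- gtParams(); obs <- gtObs()
  d <- generateDataset(p, obs, protocol = darkProtocol(36), cv = 0, n = 1,
                       seed = 1, strains = "WT", reporters = "frq", dt = 3)
  space <- parameterSpace("kd2", reference = p, span = 1.5)
  fit <- clockFit(d, obs, space, reference = p, n_starts = 2, seed = 2,
                  protocol_map = list(WT = darkProtocol(36)), maxit = 60,
                  fit_initial_states = TRUE)
  expect_named(fit$best_x0, "WT")
  expect_length(fit$best_x0$WT, 18)
  expect_true(all(fit$best_x0$WT >= 0))
  # the IC parameters appear in the free set and the result table
  expect_true(any(grepl("^x0_WT", fit$free)))
  expect_lt(fit$results$chisq[1], 50)
})
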