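.REPORTERS <- c(frq = "m_frq", vvd = "m_vvd", csp1 = "m_csp1", fam3 = "m_fam3")

#' Observation parameters for luciferase reporters
#'
#' Each reporter's bioluminescence is modeled as a positive scale factor times
#' the cognate mRNA plus an optional additive background: the destabilized
#' lucPEST reporter makes the signal track promoter activity closely enough
#' that a single proportionality constant per reporter suffices.
#'
#' @param scale named positive numeric, counts-per-second per mRNA a.u., one
#'   entry per reporter in \code{c("frq","vvd","csp1","fam3")}.
#' @param background named non-negative additive background (cps); default 0.
#' @return A list with class \code{"ObservationParams"}.
#' @export
observationParams <- function(scale, background = NULL) {
  rep_names <- names(.REPORTERS)
  if (is.null(names(scale)) || !setequal(names(scale), rep_names))
    stop("scale must be named for reporters: ", paste(rep_names, collapse = ", "))
  if (any(!is.finite(scale) | scale <= 0)) stop("scales must be positive")
  if (is.null(background)) background <- setNames(numeric(4), rep_names)
  background <- background[rep_names]
  if (any(!is.finite(background) | background < 0))
    stop("background must be >= 0")
  structure(list(scale = scale[rep_names], background = background),
            class = "ObservationParams")
}

#' Map a trajectory onto a reporter observable
#'
#' @param trajectory a \code{\link{ClockTrajectory-class}}.
#' @param obs_params an \code{\link{observationParams}} object.
#' @param reporter one of \code{"frq"}, \code{"vvd"}, \code{"csp1"},
#'   \code{"fam3"}.
#' @param strain strain label stored in the output (default the trajectory's
#'   genotype).
#' @param luc_halflife optional luciferase reporter-protein half-life in
#'   hours. \code{NULL} (default) reads the signal directly off the mRNA
#'   (the destabilized lucPEST justification); a finite value interposes a
#'   one-state first-order reporter-protein filter
#'   \code{dL/dt = m - log(2)/halflife * L}, normalized to unit steady-state
#'   gain, computed exactly on the trajectory grid for piecewise-linear mRNA.
#' @return A reporter series data.frame with columns \code{strain},
#'   \code{reporter}, \code{time_h}, \code{mean_cps}, \code{sd_cps}, \code{n}
#'   (SD 0 and n 1 for a noiseless model observable).
#' @export
observe <- function(trajectory, obs_params, reporter, strain = NULL,
                    luc_halflife = NULL) {
  if (!reporter %in% names(.REPORTERS)) stop("unknown reporter: ", reporter)
  if (is.null(strain)) strain <- trajectory@genotype
  m <- stateSeries(trajectory, .REPORTERS[[reporter]])
  if (!is.null(luc_halflife)) {
    if (luc_halflife <= 0) stop("luc_halflife must be positive")
    m <- .reporterFilter(trajectoryTimes(trajectory), m,
                         log(2) / luc_halflife)
  }
  sig <- obs_params$scale[[reporter]] * m + obs_params$background[[reporter]]
  data.frame(strain = strain, reporter = reporter,
             time_h = trajectoryTimes(trajectory),
             mean_cps = as.numeric(sig), sd_cps = 0, n = 1L,
             stringsAsFactors = FALSE)
}

# exact update of dL/dt = k (m(t) - L) for piecewise-linear m on the grid,
# initialized at quasi-steady state; unit steady-state gain
.reporterFilter <- function(t, m, k) {
  L <- numeric(length(m))
  L[1] <- m[1]
  for (i in seq_along(m)[-1]) {
    h <- t[i] - t[i - 1]
    a <- exp(-k * h)
    slope <- (m[i] - m[i - 1]) / h
    # convolution of the linear segment with the exponential kernel
    L[i] <- L[i - 1] * a + (m[i - 1] - slope / k) * (1 - a) +
      slope * h
  }
  L
}

.checkSeries <- function(series) {
  need <- c("time_h", "mean_cps", "sd_cps", "n")
  if (!all(need %in% names(series)))
    stop("reporter series must have columns: ", paste(need, collapse = ", "))
  if (any(diff(series$time_h) <= 0)) stop("time grid must be strictly increasing")
  if (any(series$sd_cps < 0)) stop("SD must be >= 0")
  series
}

#' Fold induction of a reporter after lights-on
#'
#' The peak fold is the maximum signal within \code{peak_window} hours after
#' the light transition divided by the mean dark baseline over the
#' \code{dark_window} hours preceding it; the adapted fold is the mean over
#' the last \code{adapt_window} hours of the light phase divided by the same
#' baseline. Both are invariant under positive rescaling of the series.
#'
#' @param series a reporter series data.frame.
#' @param t_light_on time of the dark-to-light transition (h).
#' @param dark_window baseline window before lights-on (h, default 22).
#' @param adapt_window averaging window at the end of the light phase
#'   (h, default 3).
#' @param light_duration length of the light phase (h, default 12).
#' @param peak_window peak search window after lights-on (h, default 2).
#' @return Named numeric \code{c(peak_fold, adapted_fold)}.
#' @export
foldInduction <- function(series, t_light_on, dark_window = 22,
                          adapt_window = 3, light_duration = 12,
                          peak_window = 2) {
  series <- .checkSeries(series)
  t <- series$time_h; y <- series$mean_cps
  base_idx <- t >= t_light_on - dark_window & t <= t_light_on
  if (!any(base_idx)) stop("no points in the dark baseline window")
  baseline <- mean(y[base_idx])
  if (baseline <= 0) stop("dark baseline is not positive")
  pk_idx <- t > t_light_on & t <= t_light_on + peak_window
  ad_idx <- t >= t_light_on + light_duration - adapt_window &
    t <= t_light_on + light_duration
  if (!any(pk_idx) || !any(ad_idx)) stop("windows outside the series grid")
  c(peak_fold = max(y[pk_idx]) / baseline,
    adapted_fold = mean(y[ad_idx]) / baseline)
}

#' Fit an exponentially damped cosine to a reporter series
#'
#' Least-squares fit of \code{b + A exp(-lambda t) cos(2 pi t / T + phi)}
#' after optional removal of a slow trend. Initialization uses the discrete
#' Fourier spectrum for the period and the analytic signal envelope for the
#' damping. The series is called rhythmic if the fitted relative amplitude
#' \code{A / b} exceeds 0.05 and the period falls in 15-35 h.
#'
#' @param series a reporter series data.frame.
#' @param window optional \code{c(t0, t1)} restricting the fit (h).
#' @param trend_removal subtract a linear trend of the baseline before fitting
#'   (refit as part of the model; default TRUE adds a linear baseline term).
#' @param period_range admissible period band in hours (default c(15, 35)).
#' @return A one-row data.frame: \code{period}, \code{phase} (peak time of the
#'   first cycle, h), \code{amplitude}, \code{baseline}, \code{damping} (per
#'   hour), \code{rel_amplitude}, \code{rhythmic}, \code{converged},
#'   \code{rss}.
#' @export
fitDampedCosine <- function(series, window = NULL, trend_removal = TRUE,
                            period_range = c(15, 35)) {
  series <- .checkSeries(series)
  t <- series$time_h; y <- series$mean_cps
  if (!is.null(window)) {
    keep <- t >= window[1] & t <= window[2]
    t <- t[keep]; y <- y[keep]
  }
  t0 <- t[1]; t <- t - t0
  out_fail <- data.frame(period = NA_real_, phase = NA_real_,
                         amplitude = NA_real_, baseline = mean(y),
                         damping = NA_real_, rel_amplitude = 0,
                         rhythmic = FALSE, converged = FALSE, rss = NA_real_)
  if (length(t) < 16 || diff(range(t)) < 2.5 * period_range[1] ||
      sd(y) == 0) return(out_fail)

  # regular resampling for the spectral period guess
  tg <- seq(min(t), max(t), length.out = max(length(t), 256))
  yg <- approx(t, y, tg)$y
  yg <- yg - mean(yg)
  spec <- Mod(fft(yg * (0.5 - 0.5 * cos(2 * pi * seq_along(yg) / length(yg)))))^2
  freq <- seq_along(yg) - 1
  per <- diff(range(tg)) / freq[-1]
  ok <- per >= period_range[1] & per <= period_range[2]
  T0 <- if (any(ok)) per[ok][which.max(spec[-1][ok])] else mean(period_range)

  # variable projection: for fixed (T, lambda) the model
  #   b0 + b1 t + exp(-lambda t) (B1 cos wt + B2 sin wt),  w = 2 pi / T
  # is linear in (b0, b1, B1, B2), solved exactly by least squares; only the
  # two nonlinear parameters are optimized
  design <- function(Tt, lam) {
    w <- 2 * pi / Tt
    e <- exp(-lam * t)
    X <- cbind(1, if (trend_removal) t, e * cos(w * t), e * sin(w * t))
    X
  }
  profiled <- function(par) {
    Tt <- par[1]; lam <- par[2]
    X <- design(Tt, lam)
    fit <- tryCatch(stats::lm.fit(X, y), error = function(e) NULL)
    if (is.null(fit)) return(list(rss = Inf))
    r <- y - X %*% fit$coefficients
    list(rss = sum(r * r), coef = fit$coefficients)
  }
  obj <- function(par) profiled(par)$rss
  best <- NULL
  for (Ts in unique(c(T0, 20, 24, 28))) for (lam0 in c(0.002, 0.02)) {
    f <- tryCatch(
      optim(c(Ts, lam0), obj, method = "L-BFGS-B",
            lower = c(period_range[1] + 1e-3, 0),
            upper = c(period_range[2] - 1e-3, 1),
            control = list(maxit = 500, factr = 1e5)),
      error = function(e) NULL)
    if (!is.null(f) && (is.null(best) || f$value < best$value)) best <- f
  }
  if (is.null(best)) return(out_fail)
  Tt <- best$par[1]; lam <- best$par[2]
  cf <- unname(profiled(best$par)$coef)
  nb <- if (trend_removal) 2 else 1
  B1 <- cf[nb + 1]; B2 <- cf[nb + 2]
  A <- sqrt(B1^2 + B2^2)
  phi <- atan2(-B2, B1)
  # peak time of the cosine: 2 pi t / T + phi = 0 (mod 2 pi), first t >= 0
  peak <- (-phi * Tt / (2 * pi)) %% Tt
  bl <- cf[1] + (if (trend_removal) cf[2] * mean(t) else 0)
  rel <- if (bl > 0) A / bl else Inf
  data.frame(period = Tt, phase = (t0 + peak) %% Tt, amplitude = A,
             baseline = bl, damping = lam, rel_amplitude = rel,
             rhythmic = is.finite(rel) && rel > 0.05 &&
               Tt > period_range[1] + 0.05 && Tt < period_range[2] - 0.05,
             converged = best$convergence == 0, rss = best$value)
}

#' Rhythmicity call for a reporter series
#'
#' @inheritParams fitDampedCosine
#' @return A one-row data.frame with \code{rhythmic} and
#'   \code{rel_amplitude}.
#' @export
rhythmicity <- function(series, window = NULL) {
  fit <- fitDampedCosine(series, window = window)
  fit[, c("rhythmic", "rel_amplitude")]
}

#' Circular phase difference between two rhythmic series
#'
#' Fits damped cosines to both series over a common window and returns the
#' circular difference of their peak phases, wrapped into
#' \code{(-period/2, period/2]}; positive values mean \code{series_b} peaks
#' later than \code{series_a}.
#'
#' @param series_a,series_b reporter series data.frames.
#' @param window optional common fitting window \code{c(t0, t1)} in hours.
#' @return Hours of phase delay of b relative to a.
#' @export
phaseDifference <- function(series_a, series_b, window = NULL) {
  fa <- fitDampedCosine(series_a, window = window)
  fb <- fitDampedCosine(series_b, window = window)
  if (!fa$rhythmic || !fb$rhythmic)
    stop("phaseDifference requires both series to be rhythmic")
  Tm <- mean(c(fa$period, fb$period))
  d <- (fb$phase - fa$phase) %% Tm
  if (d > Tm / 2) d <- d - Tm
  d
}
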