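#' Default parameter space for fitting
#'
#' Log-uniform bounds by parameter class: rates 1e-4 to 1e2 per hour,
#' Michaelis/repression constants 1e-3 to 1e3 a.u., maximal transcription
#' rates 1e-3 to 1e3 a.u. per hour. Degradation rates of light-activated
#' species have their lower bound raised to log(2)/3 per hour, imposing the
#' half-time <= 3 h constraint as a box bound.
#'
#' @param free character vector of parameter names to fit (default: a compact
#'   subset exercising the clock's core — see Details); all others are frozen
#'   at their reference value during fitting.
#' @return A data.frame with columns \code{name}, \code{lower}, \code{upper},
#'   \code{free} and attribute \code{log_scale = TRUE}.
#' @details The default free subset is
#'   \code{c("kd2", "kmat_1", "vmax_d_frq", "K_d_frq", "kdm_frq", "kdeg_ffc",
#'   "vmax_l_frq", "vmax_l_vvd")}: the reactivation rate, the maturation
#'   rate (applied to all five chain steps as one shared value when fit),
#'   the frq transcription parameters, and the dominant light drives.
#' @param reference optional \code{ClockParameters}; when supplied, the free
#'   parameters' bounds are tightened to \code{reference / span} and
#'   \code{reference * span}, the package's reading of restricting the fit
#'   to a biologically meaningful range around order-of-magnitude prior
#'   knowledge (clipped to the class-wide bounds above).
#' @param span multiplicative half-width of the reference-centred bounds
#'   (default 10, i.e. one decade each way).
#' @export
parameterSpace <- function(free = c("kd2", "kmat_1", "vmax_d_frq", "K_d_frq",
                                    "kdm_frq", "kdeg_ffc", "vmax_l_frq",
                                    "vmax_l_vvd"),
                           reference = NULL, span = 10) {
  nm <- clockParameterNames()
  unknown <- setdiff(free, nm)
  if (length(unknown) > 0)
    stop("unknown parameter(s) in free set: ", paste(unknown, collapse = ", "))
  is_conc <- grepl("^(K_|KMp_)", nm)
  lower <- ifelse(is_conc, 1e-3, 1e-4)
  upper <- ifelse(is_conc, 1e3, 1e2)
  vmax <- grepl("^(vmax_|bas_)", nm)
  lower[vmax] <- 1e-3; upper[vmax] <- 1e3
  if (!is.null(reference)) {
    reference <- .asParams(reference)
    i <- nm %in% free
    lower[i] <- pmax(lower[i], as.numeric(reference)[i] / span)
    upper[i] <- pmin(upper[i], as.numeric(reference)[i] * span)
  }
  b <- lightSpeciesDegradationBound()
  lower[match(names(b), nm)] <- pmax(lower[match(names(b), nm)], b)
  sp <- data.frame(name = nm, lower = lower, upper = upper,
                   free = nm %in% free, stringsAsFactors = FALSE)
  if (any(sp$lower >= sp$upper)) stop("invalid bounds: lower >= upper")
  attr(sp, "log_scale") <- TRUE
  sp
}

#' Weighted chi-square objective
#'
#' Sum over all data points of ((model - mean) / sigma)^2 where sigma is the
#' reported SD floored at \code{sd_floor_frac} times the series maximum.
#' Each strain is simulated once per evaluation: burn-in through the
#' synchronization protocol, then the protocol mapped to that strain.
#' Integration failures return a large finite penalty so optimizers can
#' retreat.
#'
#' @param params a \code{ClockParameters} object or named vector.
#' @param obs_params an \code{\link{observationParams}} object.
#' @param dataset long-format data.frame with columns \code{strain},
#'   \code{reporter}, \code{time_h}, \code{mean_cps}, \code{sd_cps}, \code{n}.
#' @param protocol_map named list mapping strain to its
#'   \code{LightProtocol}; default: \code{standardExperiment()} for every
#'   strain present.
#' @param sd_floor_frac noise floor as a fraction of each series' maximum
#'   signal (default 0.01).
#' @param x0_map optional named list mapping strain to an explicit initial
#'   state, bypassing the burn-in (used by the free-initial-conditions fit
#'   mode).
#' @param rtol,atol integration tolerances (looser than simulation defaults,
#'   for speed inside optimization loops).
#' @return Non-negative scalar.
#' @export
chiSquare <- function(params, obs_params, dataset,
                      protocol_map = NULL, sd_floor_frac = 0.01,
                      x0_map = NULL, rtol = 1e-6, atol = 1e-8) {
  if (nrow(dataset) == 0) stop("empty dataset")
  strains <- unique(dataset$strain)
  if (is.null(protocol_map))
    protocol_map <- setNames(rep(list(standardExperiment()), length(strains)),
                             strains)
  total <- 0
  for (g in strains) {
    d_g <- dataset[dataset$strain == g, ]
    times <- sort(unique(d_g$time_h))
    traj <- tryCatch({
      x0 <- if (!is.null(x0_map)) x0_map[[g]]
            else burnInState(params, g, rtol = rtol, atol = atol)
      simulateClock(params, g, protocol_map[[g]], x0 = x0, times = times,
                    rtol = rtol, atol = atol)
    }, error = function(e) NULL)
    if (is.null(traj)) return(1e12)
    for (r in unique(d_g$reporter)) {
      d <- d_g[d_g$reporter == r, ]
      mod <- observe(traj, obs_params, r)
      model_at <- mod$mean_cps[match(d$time_h, mod$time_h)]
      sigma <- pmax(d$sd_cps, sd_floor_frac * max(d$mean_cps))
      total <- total + sum(((model_at - d$mean_cps) / sigma)^2)
    }
  }
  total
}

#' Latin-hypercube starts in log-bounded parameter space
#'
#' Stratified sampling: each of the \code{n_starts} bins of every free
#' dimension holds exactly one draw; frozen parameters keep their reference
#' value. Deterministic given the seed.
#'
#' @param space a \code{\link{parameterSpace}} data.frame.
#' @param n_starts number of starts (>= 1).
#' @param seed integer RNG seed.
#' @param reference a \code{ClockParameters} object supplying frozen values.
#' @return A list of named parameter vectors.
#' @export
lhsStarts <- function(space, n_starts, seed, reference) {
  if (n_starts < 1) stop("n_starts must be >= 1")
  reference <- .asParams(reference)
  free <- space$name[space$free]
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  u <- vapply(free, function(.) (sample.int(n_starts) - runif(n_starts)) /
                n_starts, numeric(n_starts))
  if (n_starts == 1) u <- matrix(u, nrow = 1)
  lapply(seq_len(n_starts), function(i) {
    p <- setNames(as.numeric(reference), names(reference))
    for (j in seq_along(free)) {
      k <- match(free[j], space$name)
      p[free[j]] <- exp(log(space$lower[k]) +
                          u[i, j] * (log(space$upper[k]) - log(space$lower[k])))
    }
    p
  })
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Multi-start maximum-likelihood fit
#'
#' Bounded nonlinear optimization in log-parameter space: each
#' Latin-hypercube start is refined with a derivative-free bounded
#' trust-region method (BOBYQA) on the chi-square objective within the box
#' bounds of the parameter space (which encode the half-time constraint).
#' Results are ranked by final chi-square.
#'
#' @param dataset long-format reporter data (see \code{\link{chiSquare}}).
#' @param obs_params observation scales used for the fit (treated as known
#'   by default; see the vignette).
#' @param space a \code{\link{parameterSpace}}.
#' @param reference \code{ClockParameters} supplying frozen values.
#' @param n_starts number of LHS starts (default 50).
#' @param seed integer seed; fits are deterministic given it.
#' @param protocol_map see \code{\link{chiSquare}}.
#' @param maxit objective-evaluation cap per start (default 150).
#' @param mat_shared if TRUE (default) and any \code{kmat_i} is free, all
#'   five maturation rates are tied to a single shared value.
#' @param fit_initial_states if TRUE, the per-strain initial state at t = 0
#'   is fitted as 18 additional free parameters per strain (log-bounded,
#'   started from the reference burn-in) instead of being produced by the
#'   burn-in, mirroring designs in which initial conditions are part of the
#'   parameter vector. Default FALSE.
#' @return A list with \code{results} (data.frame: start, chisq, convergence,
#'   iterations, one column per free parameter) and \code{best} (the best-fit
#'   full \code{ClockParameters}).
#' @export
clockFit <- function(dataset, obs_params, space = parameterSpace(),
                     reference, n_starts = 50, seed = 1,
                     protocol_map = NULL, maxit = 150, mat_shared = TRUE,
                     fit_initial_states = FALSE) {
  reference <- .asParams(reference)
  free <- space$name[space$free]
  if (length(free) == 0) stop("no free parameters in space")
  mat_idx <- grepl("^kmat_", free)
  tie_mat <- mat_shared && any(mat_idx)
  if (tie_mat) free <- c(setdiff(free, free[mat_idx]), "kmat_1")
  ki <- match(free, space$name)
  lo <- log(space$lower[ki]); hi <- log(space$upper[ki])

  nkin <- length(free)
  ic_strains <- character(0); ic0 <- numeric(0)
  if (fit_initial_states) {
    ic_strains <- unique(dataset$strain)
    for (g in ic_strains) {
      bi <- burnInState(reference, g)
      ic0 <- c(ic0, setNames(log(pmax(bi, 1e-6)),
                             paste0("x0_", g, ".", clockSpecies())))
    }
    free <- c(free, names(ic0))
    lo <- c(lo, rep(log(1e-6), length(ic0)))
    hi <- c(hi, rep(log(1e3), length(ic0)))
  }

  expand <- function(lv) {
    p <- setNames(as.numeric(reference), names(reference))
    p[free[seq_len(nkin)]] <- exp(lv[seq_len(nkin)])
    if (tie_mat) p[paste0("kmat_", 1:5)] <- exp(lv[match("kmat_1", free)])
    p
  }
  expand_x0 <- function(lv) {
    if (!fit_initial_states) return(NULL)
    out <- list()
    for (g in ic_strains) {
      v <- exp(lv[paste0("x0_", g, ".", clockSpecies())])
      v[v < 2e-6] <- 0 # the lower bound stands in for exact zero
      out[[g]] <- setNames(v, clockSpecies())
    }
    out
  }
  objective <- function(lv) {
    chiSquare(expand(lv), obs_params, dataset, protocol_map = protocol_map,
              x0_map = expand_x0(lv))
  }

  starts <- lapply(lhsStarts(space, n_starts, seed, reference),
                   function(s) c(log(s[free[seq_len(nkin)]]), ic0))
  starts <- lapply(starts, setNames, free)
  rows <- vector("list", n_starts)
  for (i in seq_len(n_starts)) {
    lv0 <- pmin(pmax(starts[[i]][free], lo + 1e-9), hi - 1e-9)
    fit <- tryCatch(
      withCallingHandlers(
        minqa::bobyqa(lv0, objective, lower = lo, upper = hi,
                      control = list(maxfun = maxit, iprint = 0)),
        warning = function(w) {
          # minqa advises maxfun >= 10 n^2; a tighter evaluation budget is a
          # deliberate choice here
          if (grepl("maxfun|rhobeg", conditionMessage(w)))
            invokeRestart("muffleWarning")
        }),
      error = function(e) NULL)
    if (is.null(fit)) {
      rows[[i]] <- data.frame(start = i, chisq = Inf, convergence = -1L,
                              iterations = 0L,
                              t(setNames(rep(NA_real_, length(free)), free)))
    } else {
      rows[[i]] <- data.frame(start = i, chisq = fit$fval,
                              convergence = fit$ierr,
                              iterations = fit$feval,
                              t(setNames(exp(fit$par), free)))
    }
  }
  res <- do.call(rbind, rows)
  res <- res[order(res$chisq), ]
  rownames(res) <- NULL
  if (!is.finite(res$chisq[1])) stop("all optimization starts failed")
  best_lv <- setNames(log(as.numeric(res[1, free])), free)
  list(results = res, free = free,
       best = clockParameters(expand(best_lv)),
       best_x0 = expand_x0(best_lv))
}

#' Distribution of the top-k parameter sets
#'
#' Summarizes the ensemble of best fits: per free parameter the min, median
#' and max in log10 space over the k lowest-chi-square results, plus a
#' histogram of log10 values. A parameter is flagged \code{constrained} when
#' its top-k log10 range is below one decade.
#'
#' @param fit a \code{\link{clockFit}} result.
#' @param k ensemble size (default 10).
#' @param breaks histogram bin count.
#' @return A list with \code{summary} (data.frame) and \code{histograms}
#'   (named list of \code{hist} objects).
#' @export
ensembleSummary <- function(fit, k = 10, breaks = 10) {
  res <- fit$results[is.finite(fit$results$chisq), ]
  if (k > nrow(res)) stop("k exceeds the number of converged fits")
  top <- res[seq_len(k), , drop = FALSE]
  sm <- do.call(rbind, lapply(fit$free, function(nm) {
    v <- log10(top[[nm]])
    data.frame(name = nm, log10_min = min(v), log10_median = median(v),
               log10_max = max(v), constrained = (max(v) - min(v)) < 1)
  }))
  hs <- lapply(setNames(nm = fit$free), function(nm)
    hist(log10(top[[nm]]), breaks = breaks, plot = FALSE))
  list(summary = sm, histograms = hs)
}

#' Leave-out validation of the fitted model
#'
#' Fits on all (strain, reporter) series except the held-out keys, then
#' simulates the best fit and scores the held-out series with a normalized
#' RMSE (RMSE divided by the observed dynamic range).
#'
#' @param dataset long-format reporter data.
#' @param held_out data.frame with columns \code{strain}, \code{reporter}
#'   naming the held-out series.
#' @param obs_params,space,reference,n_starts,seed,protocol_map,maxit passed
#'   to \code{\link{clockFit}}.
#' @return A list: \code{fit} (training fit), \code{predictions} (long-format
#'   predicted series for held-out keys) and \code{nrmse} (named per key).
#' @export
leaveOutValidation <- function(dataset, held_out, obs_params,
                               space = parameterSpace(), reference,
                               n_starts = 50, seed = 1,
                               protocol_map = NULL, maxit = 150) {
  key <- paste(dataset$strain, dataset$reporter)
  ho_key <- paste(held_out$strain, held_out$reporter)
  if (!all(ho_key %in% key)) stop("held-out keys not present in dataset")
  train <- dataset[!key %in% ho_key, ]
  if (nrow(train) == 0) stop("cannot hold out the entire dataset")
  fit <- clockFit(train, obs_params, space, reference, n_starts = n_starts,
                  seed = seed, protocol_map = protocol_map, maxit = maxit)
  preds <- list(); scores <- c()
  strains <- unique(held_out$strain)
  if (is.null(protocol_map))
    protocol_map <- setNames(rep(list(standardExperiment()), length(strains)),
                             strains)
  for (i in seq_len(nrow(held_out))) {
    g <- held_out$strain[i]; r <- held_out$reporter[i]
    d <- dataset[dataset$strain == g & dataset$reporter == r, ]
    x0 <- burnInState(fit$best, g)
    traj <- simulateClock(fit$best, g, protocol_map[[g]], x0 = x0,
                          times = sort(unique(d$time_h)))
    pr <- observe(traj, obs_params, r, strain = g)
    preds[[paste(g, r)]] <- pr
    obs <- d$mean_cps[match(pr$time_h, d$time_h)]
    scores[paste(g, r)] <- sqrt(mean((pr$mean_cps - obs)^2)) / diff(range(obs))
  }
  list(fit = fit, predictions = do.call(rbind, preds), nrmse = scores)
}
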