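# Nonlinear least-squares estimation of kinetic parameters from
# fluorescence progress curves, mirroring a bounded lsqcurvefit-style
# procedure: minimize the Euclidean norm of (model - observed) over the
# free parameters, with the forward model an ODE or DDE solve.

fittableNames <- function() {
  c("k_on", "k_off", "k_act", "k_cat", "K_M", "tau", "alpha", "background")
}

#' Specify a kinetic fit
#'
#' Declares which parameters are free (those named in `start`), their
#' initial guesses and bounds, and the fixed values of everything else
#' (taken from `params` and `obs`). The default free set for progress-curve
#' fits is `k_act`, `k_cat`, `K_M` (plus `tau` for delayed fits); the
#' binding constants `k_on`/`k_off` stay fixed because single-trajectory
#' fluorescence data cannot resolve fast binding.
#'
#' @param start named numeric vector of initial guesses; names must be among
#'   `r paste(fittableNames(), collapse = ", ")`.
#' @param init the [speciesState] at t = 0 of the experiment being fitted.
#' @param params a [rateParameters] supplying fixed kinetic values.
#' @param obs an [observationModel] supplying fixed `alpha`/`background`
#'   (its noise and cadence fields are not used by the fit).
#' @param lower,upper optional named bounds for free parameters. Default
#'   lower bounds: 0 for rates and `tau`, small positive floors for `K_M`
#'   and `alpha`, `-Inf` for `background`. Default upper bounds are
#'   physically generous but finite for the kinetic constants (1 /nM/s for
#'   `k_on`, 10 /s for the first-order rates, 1e5 nM for `K_M`): an
#'   unbounded activation rate lets the optimizer wander onto the flat
#'   instant-activation manifold, where nothing distinguishes ever-larger
#'   `k_act`; the restart policy detects a parameter pinned at its bound
#'   and recovers instead.
#' @return An object of class `fitSpec`.
#' @export
fitSpec <- function(start, init, params = rateParameters(),
                    obs = observationModel(), lower = NULL, upper = NULL) {
  if (is.null(names(start)) || !all(names(start) %in% fittableNames()))
    stop("'start' must be named with parameters among: ",
         paste(fittableNames(), collapse = ", "), call. = FALSE)
  if (anyDuplicated(names(start)))
    stop("duplicated parameter in 'start'", call. = FALSE)
  init <- asSpeciesState(init)
  stopifnot(inherits(params, "rateParameters"),
            inherits(obs, "observationModel"))
  free <- names(start)
  lo <- setNames(rep(0, length(free)), free)
  lo[free %in% c("K_M", "alpha")] <- 1e-9
  lo["background" == free] <- -Inf
  hiDefault <- c(k_on = 1, k_off = 10, k_act = 10, k_cat = 10,
                 K_M = 1e5, tau = Inf, alpha = Inf, background = Inf)
  hi <- hiDefault[free]
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) hi[names(upper)] <- upper
  if (any(start < lo[free]) || any(start > hi[free]))
    stop("bounds must contain the initial guesses", call. = FALSE)
  structure(list(start = start, free = free, lower = lo, upper = hi,
                 init = init, params = params, obs = obs),
            class = "fitSpec")
}

# Full parameter vector (fixed values overridden by free values in `par`).
resolveParams <- function(spec, par) {
  full <- c(k_on = spec$params$k_on, k_off = spec$params$k_off,
            k_act = spec$params$k_act, k_cat = spec$params$k_cat,
            K_M = spec$params$K_M, tau = spec$params$tau,
            alpha = spec$obs$alpha, background = spec$obs$background)
  full[names(par)] <- par
  full
}

# Model fluorescence at the requested times. Bypasses the public output-grid
# guard of simulateDDE: dede interpolates its own dense internal history, so
# sparse output times are safe here.
forwardFluorescence <- function(times, full, init, model,
                                rtol = 1e-8, atol = 1e-10) {
  params <- rateParameters(k_on = full[["k_on"]], k_off = full[["k_off"]],
                           k_act = full[["k_act"]], k_cat = full[["k_cat"]],
                           K_M = full[["K_M"]], tau = full[["tau"]])
  grid <- sort(unique(c(0, times)))
  y0 <- setNames(as.numeric(init), speciesNames())
  # The RHS is inlined (no rhsCore call) because this function sits in the
  # optimizer's hot loop. maxsteps is kept deliberately low: pathological
  # trial parameters must fail fast (the caller maps failures to a penalty
  # residual) instead of grinding at collapsed step sizes.
  kon <- params$k_on; koff <- params$k_off; kact <- params$k_act
  kcat <- params$k_cat; KM <- params$K_M
  if (model == "ode" || params$tau == 0) {
    func <- function(t, y, p) {
      bind <- kon * y[1L] * y[2L] - koff * y[3L]
      v <- kcat * y[4L] * y[5L] / (KM + y[5L])
      list(c(-bind, -bind, bind - kact * y[3L], kact * y[3L], -v, v))
    }
    sol <- try(suppressWarnings(
      deSolve::ode(y = y0, times = grid, func = func, parms = NULL,
                   rtol = rtol, atol = atol, maxsteps = 2000)),
      silent = TRUE)
    if (inherits(sol, "try-error")) return(rep(NA_real_, length(times)))
  } else {
    tau <- params$tau
    rnpt0 <- y0[["RNPT"]]
    func <- function(t, y, p) {
      lag <- if (t <= tau) rnpt0 else deSolve::lagvalue(t - tau, 3L)
      bind <- kon * y[1L] * y[2L] - koff * y[3L]
      v <- kcat * y[4L] * y[5L] / (KM + y[5L])
      list(c(-bind, -bind, bind - kact * y[3L], kact * lag, -v, v))
    }
    sol <- try(suppressWarnings(
      deSolve::dede(y = y0, times = grid, func = func, parms = NULL,
                    rtol = rtol, atol = atol,
                    control = list(mxhist = 1e5), maxsteps = 2000)),
      silent = TRUE)
    if (inherits(sol, "try-error")) return(rep(NA_real_, length(times)))
  }
  P <- sol[match(times, sol[, 1L]), "P"]
  full[["background"]] + full[["alpha"]] * P
}

#' Fit kinetic parameters to a fluorescence progress curve
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt,
#' [minpack.lm::nls.lm]) minimizing the Euclidean norm of
#' `model fluorescence - observed fluorescence` over the free parameters of
#' `spec`. The forward model is the ODE realisation of the activation
#' scheme, or the delayed variant when `model = "dde"` (use [fitDelay] to
#' estimate the characteristic time `tau`). When the single start fails to
#' converge, five log-spaced restarts around it are tried and the best
#' converged solution is returned; a fit that never converges is flagged,
#' never silently returned as the guess.
#'
#' @param traj a trajectory with `time` and `fluorescence` columns.
#' @param spec a [fitSpec].
#' @param model `"ode"` or `"dde"`.
#' @param rtol,atol forward-solver tolerances.
#' @param maxIter maximum optimizer iterations per start.
#' @param multiStart number of log-spaced fallback starts.
#' @return An object of class `kinFit`: estimates, residual norm,
#'   convergence diagnostics, fitted curve and residuals.
#' @export
fitKinetics <- function(traj, spec, model = c("ode", "dde"),
                        rtol = 1e-8, atol = 1e-10,
                        maxIter = 100, multiStart = 5) {
  model <- match.arg(model)
  stopifnot(inherits(traj, "kinTrajectory"), inherits(spec, "fitSpec"))
  if (!("fluorescence" %in% names(traj)))
    stop("trajectory has no fluorescence column", call. = FALSE)
  y <- traj$fluorescence
  times <- traj$time
  if (any(!is.finite(y)))
    stop("non-finite fluorescence values in the data", call. = FALSE)
  if (length(y) < length(spec$start))
    stop("underdetermined: ", length(y), " observations for ",
         length(spec$start), " free parameters", call. = FALSE)
  if (model == "ode" && "tau" %in% spec$free)
    stop("'tau' can only be fitted with model = \"dde\" (see fitDelay)",
         call. = FALSE)

  # Strictly positive parameters are optimized on the log scale: the
  # k_cat/K_M-type compensation ridges of progress-curve objectives are
  # multiplicative, and log coordinates make them straight and scale-free.
  logged <- spec$free %in% c("k_on", "k_off", "k_act", "k_cat", "K_M",
                             "alpha") & spec$start > 0
  toTheta <- function(par) ifelse(logged, log(par), par)
  toPar <- function(th) setNames(ifelse(logged, exp(th), th), spec$free)
  # Logged parameters are left unbounded inside the optimizer (positivity
  # is structural in log coordinates, and minpack's bound projection can
  # wedge the search into a corner); user bounds are enforced by toPar on
  # the way out. Linear parameters (tau, background) keep real bounds.
  loTh <- ifelse(logged, -Inf, spec$lower[spec$free])
  hiTh <- ifelse(logged, Inf, spec$upper[spec$free])

  residFun <- function(th) {
    full <- resolveParams(spec, toPar(th))
    r <- forwardFluorescence(times, full, spec$init, model,
                             rtol = rtol, atol = atol) - y
    # A failed or truncated forward solve (pathological trial parameters)
    # is reported as a uniformly terrible residual so the optimizer backs
    # out of the region instead of crashing on NAs.
    if (any(!is.finite(r))) r <- rep(1e6, length(y))
    r
  }
  runOne <- function(start) {
    fit <- try(minpack.lm::nls.lm(
      par = toTheta(start), lower = loTh, upper = hiTh, fn = residFun,
      # epsfcn widens the finite-difference Jacobian step to ~1e-3
      # relative; the default machine-precision step is swamped by the
      # adaptive solver's acceptance noise and stalls the optimizer.
      control = minpack.lm::nls.lm.control(maxiter = maxIter,
                                           epsfcn = 1e-6)),
      silent = TRUE)
    if (inherits(fit, "try-error")) return(NULL)
    fit
  }
  best <- runOne(spec$start)
  okInfo <- c(1L, 2L, 3L, 4L, 6L, 7L)
  nStarts <- 1L
  if (is.null(best) || !(best$info %in% okInfo)) {
    factors <- 10^seq(-1, 1, length.out = multiStart)
    for (f in factors) {
      st <- pmin(pmax(spec$start * f, spec$lower[spec$free]),
                 spec$upper[spec$free])
      cand <- runOne(st)
      nStarts <- nStarts + 1L
      if (!is.null(cand) && cand$info %in% okInfo &&
          (is.null(best) || !(best$info %in% okInfo) ||
             cand$deviance < best$deviance))
        best <- cand
    }
  }
  if (is.null(best))
    stop("optimizer failed on all starts", call. = FALSE)
  # One chained restart from the endpoint: the damping parameter resets,
  # which recovers progress after a premature small-step stop.
  again <- runOne(toPar(unlist(best$par)))
  if (!is.null(again) && again$info %in% okInfo &&
      again$deviance < best$deviance)
    best <- again
  # Targeted restarts: a parameter that ran past its bounds (typically
  # k_act escaping onto the flat instant-activation manifold) is reset to
  # its starting guess while the others keep their fitted values.
  for (round in 1:2) {
    est <- toPar(unlist(best$par))
    atB <- which(est < spec$lower[spec$free] | est > spec$upper[spec$free])
    if (!length(atB)) break
    st <- pmin(pmax(est, spec$lower[spec$free]), spec$upper[spec$free])
    st[atB] <- spec$start[atB]
    cand <- runOne(st)
    nStarts <- nStarts + 1L
    if (!is.null(cand) && cand$deviance < best$deviance) best <- cand
    else break
  }
  est <- toPar(unlist(best$par))
  atBound <- est < spec$lower[spec$free] | est > spec$upper[spec$free]
  est <- pmin(pmax(est, spec$lower[spec$free]), spec$upper[spec$free])
  resid <- residFun(toTheta(est))
  structure(list(
    estimates = est,
    fixed = resolveParams(spec, est)[setdiff(fittableNames(), spec$free)],
    residualNorm = sqrt(sum(resid^2)),
    rss = sum(resid^2),
    converged = best$info %in% okInfo,
    info = best$info,
    message = best$message,
    iterations = best$niter,
    nStarts = nStarts,
    boundedAt = names(est)[atBound],
    model = model,
    tauAtZero = if ("tau" %in% spec$free) unname(est["tau"] <= 1e-8) else NA,
    spec = spec,
    times = times,
    observed = y,
    fitted = y + resid,
    residuals = resid,
    ci = NULL), class = "kinFit")
}

#' Fit the characteristic delay time together with the kinetic parameters
#'
#' As [fitKinetics] with the delayed forward model and `tau` in the free
#' set, bounded below by 0. A fitted `tau` at the zero boundary is reported
#' through the `tauAtZero` element ("no detectable lag").
#'
#' @inheritParams fitKinetics
#' @return A `kinFit`.
#' @export
fitDelay <- function(traj, spec, rtol = 1e-8, atol = 1e-10,
                     maxIter = 100, multiStart = 5) {
  if (!("tau" %in% spec$free))
    stop("fitDelay requires 'tau' among the free parameters", call. = FALSE)
  fitKinetics(traj, spec, model = "dde", rtol = rtol, atol = atol,
              maxIter = maxIter, multiStart = multiStart)
}

#' @export
print.kinFit <- function(x, ...) {
  cat(sprintf("Kinetic fit (%s model): %s after %d iteration(s)%s\n",
              x$model,
              if (x$converged) "converged" else "NOT converged",
              x$iterations,
              if (x$nStarts > 1L) sprintf(" (%d starts)", x$nStarts) else ""))
  cat("  estimates:\n")
  for (nm in names(x$estimates)) {
    ci <- if (!is.null(x$ci) && nm %in% rownames(x$ci))
      sprintf("  [%g, %g]", x$ci[nm, 1L], x$ci[nm, 2L]) else ""
    cat(sprintf("    %-10s %g%s\n", nm, x$estimates[[nm]], ci))
  }
  cat(sprintf("  residual norm: %g (n = %d)\n", x$residualNorm,
              length(x$observed)))
  if (isTRUE(x$tauAtZero))
    cat("  tau hit the zero boundary: no detectable lag\n")
  invisible(x)
}

#' Residual-resampling bootstrap intervals for a kinetic fit
#'
#' Refits the model on synthetic datasets formed by adding residuals
#' resampled with replacement to the fitted curve, and returns percentile
#' confidence intervals for each free parameter. Seeded and reproducible.
#'
#' @param traj,spec as in [fitKinetics].
#' @param fit a converged `kinFit`; computed from `traj`/`spec` when `NULL`.
#' @param nResamples number of bootstrap datasets (>= 10).
#' @param seed integer seed.
#' @param level interval coverage level.
#' @param model forward model kind, defaulting to the fit's.
#' @return The `kinFit` with `ci` (matrix, columns lower/upper) and
#'   `bootstrap` (matrix of resampled estimates) filled in.
#' @export
bootstrapFit <- function(traj, spec, fit = NULL, nResamples = 200,
                         seed = NULL, level = 0.95, model = NULL) {
  if (nResamples < 10)
    stop("'nResamples' must be >= 10", call. = FALSE)
  if (is.null(fit))
    fit <- fitKinetics(traj, spec, model = model %||% "ode")
  if (!fit$converged)
    stop("bootstrap requires a converged point fit", call. = FALSE)
  model <- model %||% fit$model
  spec2 <- spec
  spec2$start <- fit$estimates
  draws <- withLocalSeed(seed, {
    out <- matrix(NA_real_, nResamples, length(fit$estimates),
                  dimnames = list(NULL, names(fit$estimates)))
    for (b in seq_len(nResamples)) {
      tb <- traj
      tb$fluorescence <- fit$fitted +
        sample(fit$residuals, length(fit$residuals), replace = TRUE)
      fb <- try(fitKinetics(tb, spec2, model = model, multiStart = 0),
                silent = TRUE)
      if (!inherits(fb, "try-error") && fb$converged)
        out[b, ] <- fb$estimates
    }
    out
  })
  ok <- stats::complete.cases(draws)
  if (sum(ok) < 10)
    stop("too few converged bootstrap refits (", sum(ok), ")", call. = FALSE)
  a <- (1 - level) / 2
  ci <- t(apply(draws[ok, , drop = FALSE], 2L, stats::quantile,
                probs = c(a, 1 - a)))
  colnames(ci) <- c("lower", "upper")
  fit$ci <- ci
  fit$bootstrap <- draws[ok, , drop = FALSE]
  fit$bootstrapLevel <- level
  fit
}

#' Residual-norm profile of one parameter
#'
#' Refits all other free parameters at each grid value of `parameter` and
#' returns the profile of the residual norm. A flat profile — less than a
#' 2-fold change in residual norm across the grid — flags the parameter as
#' practically unidentifiable from the data (the classic example being
#' `alpha` and `k_cat` simultaneously free with no plateau: only their
#' product is constrained).
#'
#' @param traj,spec,model as in [fitKinetics].
#' @param parameter name of the free parameter to profile.
#' @param grid numeric values at which to pin it.
#' @return A data frame (`value`, `residualNorm`, `converged`) with
#'   attributes `unidentifiable` (logical) and `parameter`.
#' @export
profileFit <- function(traj, spec, parameter, grid, model = "ode") {
  if (!(parameter %in% spec$free))
    stop("'", parameter, "' is not a free parameter of the spec",
         call. = FALSE)
  if (length(grid) < 2L)
    warning("degenerate profile: grid of length ", length(grid))
  others <- setdiff(spec$free, parameter)
  if (!length(others))
    stop("no remaining free parameters to profile against", call. = FALSE)
  rn <- numeric(length(grid))
  cv <- logical(length(grid))
  for (i in seq_along(grid)) {
    sp <- spec
    sp$start <- spec$start[others]
    sp$free <- others
    sp$lower <- spec$lower[others]
    sp$upper <- spec$upper[others]
    if (parameter %in% c("alpha", "background")) {
      sp$obs[[parameter]] <- grid[i]
    } else {
      sp$params[[parameter]] <- grid[i]
    }
    f <- fitKinetics(traj, sp, model = model)
    rn[i] <- f$residualNorm
    cv[i] <- f$converged
  }
  out <- data.frame(value = grid, residualNorm = rn, converged = cv)
  attr(out, "parameter") <- parameter
  attr(out, "unidentifiable") <-
    max(rn) / max(min(rn), .Machine$double.eps) < 2
  out
}
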