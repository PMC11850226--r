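#' Right-hand side of the activation ODE system
#'
#' Instantaneous time derivatives of all six species under mass-action
#' binding/activation and Michaelis-Menten reporter turnover:
#' \deqn{d[RNP]/dt = -k_{on}[RNP][T] + k_{off}[RNPT]}
#' \deqn{d[T]/dt = -k_{on}[RNP][T] + k_{off}[RNPT]}
#' \deqn{d[RNPT]/dt = k_{on}[RNP][T] - k_{off}[RNPT] - k_{act}[RNPT]}
#' \deqn{d[RNPT^*]/dt = k_{act}[RNPT]}
#' \deqn{d[P]/dt = -d[Reporter]/dt = v =
#'       k_{cat}[RNPT^*][Reporter]/(K_M + [Reporter])}
#'
#' The derivatives of the enzyme moiety (RNP, RNPT, RNPT*) sum to zero, as
#' do those of the reporter moiety (Reporter, P).
#'
#' @param state a [speciesState] (all concentrations >= 0).
#' @param params a [rateParameters].
#' @return Named numeric vector of derivatives (nM/s) in species order, with
#'   attribute `"v"` holding the instantaneous product-formation rate.
#' @examples
#' s <- speciesState(RNP = 40, T = 250, Reporter = 250)
#' odeRates(s, rateParameters(k_on = 1e-3))
#' @export
odeRates <- function(state, params) {
  state <- asSpeciesState(state)
  stopifnot(inherits(params, "rateParameters"))
  d <- rhsCore(as.numeric(state), params, delayedRNPT = NULL)
  structure(setNames(d$deriv, speciesNames()), v = d$v)
}

#' Right-hand side of the delayed activation model
#'
#' Identical to [odeRates] except that production of the activated enzyme
#' uses the complex concentration a characteristic time tau in the past:
#' `d[RNPT*]/dt = k_act * [RNPT](t - tau)`. The consumption term of RNPT
#' itself (`-k_act [RNPT]`) stays at the current time, following the model
#' equation as written; consequence: the enzyme-moiety total dips
#' transiently by the amount "in transit" through the delay (bounded by
#' `k_act * max(RNPT) * tau`) and is restored asymptotically. See
#' [simulateDDE] for a transit-conserving alternative.
#'
#' @param state a [speciesState] at the current time.
#' @param delayedRNPT the RNPT concentration (nM, >= 0) at time `t - tau`.
#' @param params a [rateParameters].
#' @return As [odeRates].
#' @export
ddeRates <- function(state, delayedRNPT, params) {
  state <- asSpeciesState(state)
  stopifnot(inherits(params, "rateParameters"))
  if (!is.numeric(delayedRNPT) || length(delayedRNPT) != 1L ||
      !is.finite(delayedRNPT) || delayedRNPT < 0)
    stop("invalid history: 'delayedRNPT' must be a single number >= 0",
         call. = FALSE)
  d <- rhsCore(as.numeric(state), params, delayedRNPT = delayedRNPT)
  structure(setNames(d$deriv, speciesNames()), v = d$v)
}

asSpeciesState <- function(state) {
  if (inherits(state, "speciesState")) return(state)
  if (is.numeric(state) && !is.null(names(state)) &&
      all(speciesNames() %in% names(state)))
    return(do.call(speciesState, as.list(state[speciesNames()])))
  stop("'state' must be a speciesState or a named vector with fields ",
       paste(speciesNames(), collapse = ", "), call. = FALSE)
}

# Core arithmetic shared by exported RHS functions and the solvers.
# y: numeric length 6 (8 with inhibitor extension), order as speciesNames().
# delayedRNPT: NULL for the plain ODE; otherwise RNPT(t - tau).
# delayedForConsumption: when TRUE the -k_act term also uses the delayed
# value (transit-conserving variant).
rhsCore <- function(y, params, delayedRNPT = NULL,
                    delayedForConsumption = FALSE,
                    k_seq = 0, k_deact = 0) {
  RNP <- y[1L]; Tt <- y[2L]; RNPT <- y[3L]; RNPTs <- y[4L]
  Rep <- y[5L]
  bind <- params$k_on * RNP * Tt - params$k_off * RNPT
  prodRNPT <- if (is.null(delayedRNPT)) RNPT else delayedRNPT
  consRNPT <- if (delayedForConsumption && !is.null(delayedRNPT))
    delayedRNPT else RNPT
  v <- params$k_cat * RNPTs * Rep / (params$K_M + Rep)
  dRNP  <- -bind
  dT    <- -bind
  dRNPT <- bind - params$k_act * consRNPT
  dStar <- params$k_act * prodRNPT
  if (length(y) >= 8L) {       # staged system with inhibitor channels
    I <- y[7L]
    seq_  <- k_seq * Tt * I          # T + I -> TI
    deact <- k_deact * RNPTs * I     # RNPT* + I -> RNP + TI
    dT    <- dT - seq_
    dStar <- dStar - deact
    dRNP  <- dRNP + deact
    dI    <- -seq_ - deact
    dTI   <- seq_ + deact
    deriv <- c(dRNP, dT, dRNPT, dStar, -v, v, dI, dTI)
  } else {
    deriv <- c(dRNP, dT, dRNPT, dStar, -v, v)
  }
  list(deriv = deriv, v = v)
}

#' Mass-conservation drift of a closed simulated trajectory
#'
#' For a closed simulation (no addition events) the ODE model conserves the
#' enzyme moiety `RNP + RNPT + RNPT*` and the reporter moiety
#' `Reporter + P`. This returns the maximum relative drift of each total
#' over the trajectory, a direct check on integration quality. Delayed
#' trajectories integrated with the model equation as written show a
#' transient enzyme-moiety deficit (material in transit through the delay);
#' the reporter moiety is conserved in all variants.
#'
#' @param traj a trajectory from [simulateODE]/[simulateDDE] containing
#'   species columns and generated without events.
#' @return Named numeric vector `c(enzyme = , reporter = )` of maximum
#'   relative drifts.
#' @export
conservationResiduals <- function(traj) {
  stopifnot(inherits(traj, "kinTrajectory"))
  if (!all(speciesNames() %in% names(traj)))
    stop("unsupported input: trajectory has no species columns ",
         "(fluorescence-only)", call. = FALSE)
  ev <- attr(traj, "events")
  if (!is.null(ev) && nrow(ev) > 0L)
    stop("unsupported input: trajectory has addition events; ",
         "moiety totals are not conserved across additions", call. = FALSE)
  enz <- traj$RNP + traj$RNPT + traj$RNPT_star
  rep_ <- traj$Reporter + traj$P
  c(enzyme   = max(abs(enz - enz[1L])) / max(enz[1L], .Machine$double.eps),
    reporter = max(abs(rep_ - rep_[1L])) / max(rep_[1L], .Machine$double.eps))
}
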