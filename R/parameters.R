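#' Kinetic rate parameters for the three-step activation scheme
#'
#' Bundles the rate constants of the activation model: reversible binding of
#' the activator T to the ribonucleoprotein RNP (`k_on`, `k_off`),
#' irreversible conversion of the complex RNPT to the activated enzyme RNPT*
#' (`k_act`), and Michaelis-Menten turnover of the reporter by RNPT*
#' (`k_cat`, `K_M`). `tau` is the characteristic delay of the
#' delay-differential variant; `tau = 0` reduces it to the plain ODE model.
#'
#' Units are seconds and nanomolar throughout: `k_on` in /nM/s; `k_off`,
#' `k_act`, `k_cat` in /s; `K_M` in nM; `tau` in s.
#'
#' @param k_on association rate constant of RNP and T (/nM/s).
#' @param k_off dissociation rate constant of RNPT (/s).
#' @param k_act activation rate of RNPT (/s); small values manifest as a lag
#'   in the product curve.
#' @param k_cat turnover number of the activated enzyme (/s).
#' @param K_M Michaelis-Menten constant of reporter cleavage (nM).
#' @param tau characteristic delay time (s, >= 0).
#' @return An object of class `rateParameters` (a named list).
#' @examples
#' p <- rateParameters(k_act = 5e-3, k_cat = 0.05, K_M = 150)
#' dissociationConstant(p)
#' @export
rateParameters <- function(k_on = 1e-3, k_off = 1e-3, k_act = 5e-3,
                           k_cat = 0.05, K_M = 150, tau = 0) {
  p <- list(k_on = k_on, k_off = k_off, k_act = k_act,
            k_cat = k_cat, K_M = K_M, tau = tau)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("'", nm, "' must be a single finite number", call. = FALSE)
    if (v < 0)
      stop("'", nm, "' must be >= 0 (got ", v, ")", call. = FALSE)
  }
  if (p$K_M <= 0)
    stop("'K_M' must be > 0 (got ", p$K_M, ")", call. = FALSE)
  structure(p, class = "rateParameters")
}

#' @export
print.rateParameters <- function(x, ...) {
  cat("Kinetic rate parameters (s, nM):\n")
  cat(sprintf("  k_on  = %g /nM/s   k_off = %g /s\n", x$k_on, x$k_off))
  cat(sprintf("  k_act = %g /s      k_cat = %g /s\n", x$k_act, x$k_cat))
  cat(sprintf("  K_M   = %g nM      tau   = %g s\n", x$K_M, x$tau))
  if (x$k_on > 0)
    cat(sprintf("  K_d   = k_off/k_on = %g nM\n", x$k_off / x$k_on))
  invisible(x)
}

#' Species concentrations at one instant
#'
#' The six species of the activation scheme: free enzyme `RNP`, free
#' activator `T`, enzyme-activator complex `RNPT`, activated enzyme
#' `RNPT_star`, uncleaved `Reporter`, and cleaved product `P`. All in nM.
#' In a closed system (no additions) the enzyme moiety
#' `RNP + RNPT + RNPT_star` and the reporter moiety `Reporter + P` are
#' conserved by the ODE model.
#'
#' @param RNP free ribonucleoprotein (nM).
#' @param T free activator (nM).
#' @param RNPT enzyme-activator complex (nM).
#' @param RNPT_star activated enzyme (nM).
#' @param Reporter uncleaved substrate (nM).
#' @param P cleaved product (nM).
#' @return An object of class `speciesState` (a named numeric vector).
#' @export
speciesState <- function(RNP = 0, T = 0, RNPT = 0, RNPT_star = 0,
                         Reporter = 0, P = 0) {
  s <- c(RNP = RNP, T = T, RNPT = RNPT, RNPT_star = RNPT_star,
         Reporter = Reporter, P = P)
  if (!is.numeric(s) || any(!is.finite(s)))
    stop("species concentrations must be finite numbers", call. = FALSE)
  bad <- names(s)[s < 0]
  if (length(bad))
    stop("'", bad[1L], "' must be >= 0 (got ", s[[bad[1L]]], " nM)",
         call. = FALSE)
  structure(s, class = "speciesState")
}

#' @export
print.speciesState <- function(x, ...) {
  cat("Species state (nM):\n")
  print(setNames(as.numeric(x), names(x)))
  invisible(x)
}

speciesNames <- function() {
  c("RNP", "T", "RNPT", "RNPT_star", "Reporter", "P")
}

stagedSpeciesNames <- function() {
  c(speciesNames(), "I", "TI")
}

#' Fluorimeter observation model
#'
#' Maps simulated product concentration to an observed fluorescence signal:
#' `F = background + alpha * P`, sampled on the instrument cadence, with
#' additive homoscedastic Gaussian noise. Defaults emulate a real-time
#' fluorimeter reading every 60 s at 37 C.
#'
#' @param alpha fluorescence yield per nM of cleaved product (a.u./nM).
#' @param background baseline signal (a.u.).
#' @param noise_sd standard deviation of additive Gaussian noise (a.u.).
#' @param sampling_interval seconds between readings.
#' @return An object of class `observationModel`.
#' @export
observationModel <- function(alpha = 1, background = 50, noise_sd = 2.5,
                             sampling_interval = 60) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0)
    stop("'alpha' must be a single number > 0", call. = FALSE)
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0)
    stop("'noise_sd' must be >= 0", call. = FALSE)
  if (!is.numeric(sampling_interval) || length(sampling_interval) != 1L ||
      sampling_interval <= 0)
    stop("'sampling_interval' must be > 0", call. = FALSE)
  if (!is.numeric(background) || length(background) != 1L ||
      !is.finite(background))
    stop("'background' must be a single finite number", call. = FALSE)
  structure(list(alpha = alpha, background = background,
                 noise_sd = noise_sd,
                 sampling_interval = sampling_interval),
            class = "observationModel")
}

#' @export
print.observationModel <- function(x, ...) {
  cat(sprintf(
    "Observation model: F = %g + %g * [P], noise sd %g a.u., read every %g s\n",
    x$background, x$alpha, x$noise_sd, x$sampling_interval))
  invisible(x)
}

#' Timed concentration-addition schedule
#'
#' Ordered additions of activator (`"T"`) or inhibitor (`"I"`) during a
#' staged experiment. Each row steps the named species up by
#' `added_concentration` nM at `time` s (final-concentration increments;
#' volume changes are ignored).
#'
#' @param time event times in seconds (non-decreasing).
#' @param species character, each `"T"` or `"I"`.
#' @param added_concentration added amounts in nM (> 0).
#' @return An object of class `eventSchedule` (a data frame).
#' @export
eventSchedule <- function(time, species, added_concentration) {
  if (length(time) != length(species) ||
      length(time) != length(added_concentration))
    stop("event fields must have equal length", call. = FALSE)
  if (length(time) == 0L)
    return(structure(
      data.frame(time = numeric(0), species = character(0),
                 added_concentration = numeric(0)),
      class = c("eventSchedule", "data.frame")))
  if (!all(species %in% c("T", "I")))
    stop("event species must be 'T' (activator) or 'I' (inhibitor)",
         call. = FALSE)
  if (is.unsorted(time))
    stop("event times must be non-decreasing", call. = FALSE)
  if (any(added_concentration <= 0))
    stop("added concentrations must be > 0 nM", call. = FALSE)
  structure(
    data.frame(time = as.numeric(time), species = as.character(species),
               added_concentration = as.numeric(added_concentration),
               stringsAsFactors = FALSE),
    class = c("eventSchedule", "data.frame"))
}

#' Equilibrium dissociation constant of the RNP-activator complex
#'
#' Returns `K_d = k_off / k_on` in nM. With the activation and catalysis
#' channels switched off (`k_act = k_cat = 0`) the binding equilibrium
#' satisfies `[RNP][T]/[RNPT] = K_d`. Note the direction of the ratio: since
#' `k_on` is /nM/s and `k_off` is /s, only `k_off/k_on` carries
#' concentration units; the inverted ratio `k_on/k_off` sometimes quoted for
#' this quantity is dimensionally an association constant, not a `K_d`.
#'
#' @param params a [rateParameters] object with `k_on > 0`.
#' @return The dissociation constant in nM.
#' @examples
#' dissociationConstant(rateParameters(k_on = 1e-3, k_off = 1e-2)) # 10 nM
#' @export
dissociationConstant <- function(params) {
  stopifnot(inherits(params, "rateParameters"))
  if (params$k_on == 0)
    stop("affinity undefined: 'k_on' is 0", call. = FALSE)
  params$k_off / params$k_on
}
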