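# Curve-level summaries: empirical lag time (tangent method), apparent
# trans-cleavage rate (maximum slope), relative release percentages and
# logic-gate truth-table classification.

# Pull the observable from a trajectory: fluorescence if present, else the
# product concentration.
curveSignal <- function(traj) {
  stopifnot(inherits(traj, "kinTrajectory"))
  if ("fluorescence" %in% names(traj)) traj$fluorescence else traj$P
}

# Centered moving average, applied only when the signal looks noisy
# (a strictly non-decreasing product curve has no negative first
# differences; any appreciable negative step signals instrument noise).
maybeSmooth <- function(y, window = 5L) {
  d <- diff(y)
  tol <- 1e-9 * max(abs(y), 1)
  if (!any(d < -tol)) return(y)
  k <- rep(1 / window, window)
  ys <- stats::filter(y, k, sides = 2L)
  half <- window %/% 2L
  n <- length(y)
  ys[seq_len(half)] <- y[seq_len(half)]
  ys[seq(n - half + 1L, n)] <- y[seq(n - half + 1L, n)]
  as.numeric(ys)
}

centralSlopes <- function(t, y) {
  n <- length(y)
  (y[3:n] - y[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
}

#' Empirical lag time by the tangent method
#'
#' Draws the tangent at the point of maximum slope of the (smoothed)
#' signal and returns its intersection with the baseline (the first
#' sample's level), clipped to >= 0. This is the classic graphical lag-phase
#' estimator for sigmoidal progress curves, the empirical counterpart of the
#' fitted characteristic time `tau`. When the maximum slope occurs at the
#' first interior sample the curve rises immediately and 0 is returned. A
#' flat signal (range below the noise floor) yields `NA` — a distinguished
#' "no activation" value, not an error.
#'
#' @param traj a trajectory (noiseless or lightly noisy; noisy signals are
#'   smoothed with a centered moving average before differentiation).
#' @param window smoothing window (samples).
#' @return Lag time in seconds, or `NA_real_` for a flat signal.
#' @export
lagTimeTangent <- function(traj, window = 5L) {
  y <- curveSignal(traj)
  t <- traj$time
  if (length(y) < 3L)
    stop("need at least 3 samples for the tangent method", call. = FALSE)
  noiseFloor <- 6 * stats::mad(diff(y)) / sqrt(2)
  if (max(y) - min(y) <= max(noiseFloor, 1e-12))
    return(NA_real_)
  ys <- maybeSmooth(y, window)
  s <- centralSlopes(t, ys)
  i <- which.max(s)
  if (i == 1L) return(0)
  ti <- t[i + 1L]
  lag <- ti - (ys[i + 1L] - ys[1L]) / s[i]
  max(lag, 0)
}

#' Apparent trans-cleavage rate
#'
#' Maximum slope of the (smoothed) signal, estimated by central differences.
#' In fluorescence units per second; proportional to `alpha * v_max` for a
#' saturated reporter, so ratios of apparent rates between conditions track
#' ratios of catalytic activity.
#'
#' @inheritParams lagTimeTangent
#' @return Maximum slope (signal units per second); 0 for a flat signal.
#' @export
apparentRate <- function(traj, window = 5L) {
  y <- curveSignal(traj)
  t <- traj$time
  if (length(y) < window)
    stop("need at least ", window, " samples", call. = FALSE)
  noiseFloor <- 6 * stats::mad(diff(y)) / sqrt(2)
  if (max(y) - min(y) <= max(noiseFloor, 1e-12))
    return(0)
  ys <- maybeSmooth(y, window)
  max(centralSlopes(t, ys))
}

#' Endpoint signals as percentages of a reference condition
#'
#' Rescales a set of endpoint signals (all taken at the same endpoint time,
#' e.g. 45 min) so that the reference condition reads exactly 100%.
#'
#' @param values named numeric endpoint signals.
#' @param reference name of the reference entry.
#' @return Named numeric percentages; `values[reference]` maps to 100.
#' @examples
#' relativeRelease(c(short = 5, long = 2.5, none = 5), reference = "none")
#' @export
relativeRelease <- function(values, reference) {
  if (is.null(names(values)) || !(reference %in% names(values)))
    stop("'reference' must name an entry of 'values'", call. = FALSE)
  ref <- values[[reference]]
  if (!is.finite(ref) || ref <= 0)
    stop("degenerate reference: endpoint signal must be > 0 (got ",
         ref, ")", call. = FALSE)
  out <- 100 * values / ref
  out[reference] <- 100   # exact, immune to round-off
  out
}

canonicalGateTable <- function(gate) {
  switch(gate,
         AND = c(`00` = 0L, `01` = 0L, `10` = 0L, `11` = 1L),
         OR  = c(`00` = 0L, `01` = 1L, `10` = 1L, `11` = 1L),
         NOR = c(`00` = 1L, `01` = 0L, `10` = 0L, `11` = 0L))
}

#' Classify endpoint signals as a molecular logic gate
#'
#' Thresholds the endpoint signal of each input combination at a fraction of
#' the positive-control endpoint (output 1 iff
#' `endpoint >= threshold * positive_control`) and compares the resulting
#' truth table with the canonical AND / OR / NOR table. The classification
#' is invariant under uniform rescaling of all endpoints together with the
#' positive control (arbitrary fluorescence units carry no meaning).
#'
#' @param endpoints numeric endpoint signals named `"00"`, `"01"`, `"10"`,
#'   `"11"` (input combinations).
#' @param positiveControl endpoint signal of the positive control (> 0).
#' @param gate `"AND"`, `"OR"` or `"NOR"`.
#' @param threshold fraction of the positive control in (0, 1).
#' @return A list of class `gateResult`: `table` (observed outputs),
#'   `canonical`, `match` (logical), `mismatches` (combination names).
#' @export
classifyGate <- function(endpoints, positiveControl,
                         gate = c("AND", "OR", "NOR"), threshold = 0.5) {
  gate <- match.arg(gate)
  combos <- c("00", "01", "10", "11")
  if (is.null(names(endpoints)) || !all(combos %in% names(endpoints)))
    stop("incomplete input: endpoints must be named ",
         paste(combos, collapse = ", "), call. = FALSE)
  if (!is.numeric(positiveControl) || positiveControl <= 0)
    stop("'positiveControl' must be > 0", call. = FALSE)
  if (threshold <= 0 || threshold >= 1)
    stop("'threshold' must be strictly between 0 and 1", call. = FALSE)
  obs <- as.integer(endpoints[combos] >= threshold * positiveControl)
  names(obs) <- combos
  can <- canonicalGateTable(gate)
  structure(list(gate = gate, threshold = threshold, table = obs,
                 canonical = can, match = all(obs == can),
                 mismatches = combos[obs != can]),
            class = "gateResult")
}

#' @export
print.gateResult <- function(x, ...) {
  cat(sprintf("%s gate (threshold %g x positive control): %s\n", x$gate,
              x$threshold,
              if (x$match) "matches canonical truth table"
              else paste("MISMATCH at", paste(x$mismatches, collapse = ", "))))
  tab <- rbind(observed = x$table, canonical = x$canonical)
  print(tab)
  invisible(x)
}
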