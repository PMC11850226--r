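# Trajectory container: a data frame with a strictly increasing `time`
# column (s), optional species columns (nM) and/or a `fluorescence` column
# (a.u.), plus provenance attributes (model kind, parameters, events, seed).

newTrajectory <- function(df, model = "ode", params = NULL, events = NULL,
                          obs = NULL, seed = NULL) {
  stopifnot(is.data.frame(df), "time" %in% names(df))
  if (nrow(df) == 0L)
    stop("trajectory must contain at least one time point", call. = FALSE)
  if (any(diff(df$time) <= 0))
    stop("trajectory times must be strictly increasing", call. = FALSE)
  hasSpecies <- all(speciesNames() %in% names(df))
  if (!hasSpecies && !("fluorescence" %in% names(df)))
    stop("trajectory needs species columns and/or a fluorescence column",
         call. = FALSE)
  structure(df,
            class = c("kinTrajectory", "data.frame"),
            model = model, params = params, events = events,
            obs = obs, seed = seed)
}

#' @export
print.kinTrajectory <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("Kinetic trajectory: %d points, t = %g..%g s (%s model)\n",
              n, x$time[1L], x$time[n], attr(x, "model") %||% "?"))
  cols <- setdiff(names(x), "time")
  cat("  columns:", paste(cols, collapse = ", "), "\n")
  ev <- attr(x, "events")
  if (!is.null(ev) && nrow(ev) > 0L)
    cat(sprintf("  %d addition event(s) at t = %s s\n", nrow(ev),
                paste(ev$time, collapse = ", ")))
  utils::str(utils::head(as.data.frame(x), 3L), give.attr = FALSE)
  invisible(x)
}

#' Plot a kinetic trajectory
#'
#' Species concentrations and/or observed fluorescence against time.
#'
#' @param x a trajectory.
#' @param what `"species"` or `"fluorescence"`.
#' @param ... passed to [graphics::matplot] / [graphics::plot].
#' @return Invisibly, `x`.
#' @export
plot.kinTrajectory <- function(x, what = c("species", "fluorescence"), ...) {
  what <- match.arg(what)
  if (what == "fluorescence" && "fluorescence" %in% names(x)) {
    graphics::plot(x$time, x$fluorescence, type = "l",
                   xlab = "time (s)", ylab = "fluorescence (a.u.)", ...)
  } else {
    sp <- intersect(c(speciesNames(), "I", "TI"), names(x))
    if (!length(sp)) stop("no species columns to plot", call. = FALSE)
    graphics::matplot(x$time, as.matrix(as.data.frame(x)[sp]), type = "l",
                      lty = 1, xlab = "time (s)", ylab = "concentration (nM)",
                      ...)
    graphics::legend("right", legend = sp, lty = 1,
                     col = seq_along(sp), bty = "n")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
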