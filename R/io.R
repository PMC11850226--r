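# Delimited-text trajectory files and structured run configurations.
# Column units are encoded in the names (time_s, fluorescence_au, species
# in nM) to prevent silent unit mix-ups; there is no binary standard for
# plate-reader time courses, and CSV matches instrument exports.

#' Write a trajectory to CSV
#'
#' Deterministic column order: `time_s`, `fluorescence_au` (if present),
#' then species columns alphabetically with an `_nM` suffix. Values are
#' written at full double precision so a read-back reproduces the
#' trajectory exactly. Provenance (model kind, parameters, events, seed) is
#' written as a JSON sidecar at `<path>.meta.json`.
#'
#' @param traj a `kinTrajectory`.
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
writeTrajectory <- function(traj, path) {
  stopifnot(inherits(traj, "kinTrajectory"))
  if (nrow(traj) == 0L)
    stop("refusing to write an empty trajectory", call. = FALSE)
  df <- as.data.frame(traj)
  out <- data.frame(time_s = df$time)
  if ("fluorescence" %in% names(df))
    out$fluorescence_au <- df$fluorescence
  sp <- intersect(c(speciesNames(), "I", "TI"), names(df))
  sp <- sp[order(sp, method = "radix")]  # locale-independent order
  for (cn in sp) out[[paste0(cn, "_nM")]] <- df[[cn]]
  txt <- vapply(out, function(col) sprintf("%.17g", col), character(nrow(out)))
  if (nrow(out) == 1L) txt <- matrix(txt, nrow = 1L)
  lines <- c(paste(names(out), collapse = ","),
             apply(txt, 1L, paste, collapse = ","))
  writeLines(lines, path)
  meta <- list(model = attr(traj, "model"),
               params = unclass(attr(traj, "params")),
               seed = attr(traj, "seed"))
  ev <- attr(traj, "events")
  if (!is.null(ev) && nrow(ev) > 0L)
    meta$events <- as.data.frame(ev)
  ob <- attr(traj, "obs")
  if (!is.null(ob)) meta$obs <- unclass(ob)
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a trajectory from CSV
#'
#' Expects a header with a `time_s` column and at least one of
#' `fluorescence_au` or per-species `<name>_nM` columns. Times must be
#' strictly increasing; parse failures name the offending row. A
#' `<path>.meta.json` sidecar written by [writeTrajectory] is restored into
#' the trajectory's provenance attributes when present.
#'
#' @param path CSV path.
#' @return A `kinTrajectory`.
#' @export
readTrajectory <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!("time_s" %in% names(df)))
    stop("missing required column 'time_s'", call. = FALSE)
  for (cn in names(df)) {
    if (!is.numeric(df[[cn]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[cn]]))))[1L]
      stop("non-numeric value in column '", cn, "' at data row ",
           bad, call. = FALSE)
    }
  }
  tm <- df$time_s
  if (anyDuplicated(tm))
    stop("duplicate time at data row ",
         which(duplicated(tm))[1L], call. = FALSE)
  if (is.unsorted(tm))
    stop("non-monotone time at data row ",
         which(diff(tm) < 0)[1L] + 1L, call. = FALSE)
  out <- data.frame(time = tm)
  if ("fluorescence_au" %in% names(df))
    out$fluorescence <- df$fluorescence_au
  spCols <- grep("_nM$", names(df), value = TRUE)
  for (cn in spCols) out[[sub("_nM$", "", cn)]] <- df[[cn]]
  if (is.null(out$fluorescence) &&
      !all(speciesNames() %in% names(out)))
    stop("file has neither 'fluorescence_au' nor a full species set",
         call. = FALSE)
  meta <- NULL
  metaPath <- paste0(path, ".meta.json")
  if (file.exists(metaPath))
    meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
  params <- NULL
  if (!is.null(meta$params))
    params <- do.call(rateParameters, as.list(meta$params))
  events <- NULL
  if (!is.null(meta$events))
    events <- eventSchedule(meta$events$time, meta$events$species,
                            meta$events$added_concentration)
  newTrajectory(out, model = meta$model %||% "imported",
                params = params, events = events,
                seed = meta$seed)
}

#' Assemble a run configuration
#'
#' A fully-resolved description of one simulated experiment: scenario or
#' explicit initial state, kinetic parameters, observation model, event
#' schedule, solver tolerances and seed. Round-trips losslessly through
#' JSON via [writeRunConfig]/[readRunConfig], so every output can carry the
#' configuration sufficient to regenerate it.
#'
#' @param init a [speciesState].
#' @param params a [rateParameters].
#' @param obs an [observationModel].
#' @param events an [eventSchedule] or `NULL`.
#' @param scenario optional scenario name the configuration was derived
#'   from.
#' @param rtol,atol solver tolerances.
#' @param seed integer seed or `NULL`.
#' @return An object of class `runConfig`.
#' @export
runConfig <- function(init, params = rateParameters(),
                      obs = observationModel(), events = NULL,
                      scenario = NULL, rtol = 1e-8, atol = 1e-10,
                      seed = NULL) {
  init <- asSpeciesState(init)
  stopifnot(inherits(params, "rateParameters"),
            inherits(obs, "observationModel"))
  if (!is.null(events)) stopifnot(inherits(events, "eventSchedule"))
  structure(list(scenario = scenario, init = init, params = params,
                 obs = obs, events = events, rtol = rtol, atol = atol,
                 seed = seed),
            class = "runConfig")
}

#' @rdname runConfig
#' @param config a `runConfig`.
#' @param path JSON file path.
#' @export
writeRunConfig <- function(config, path) {
  stopifnot(inherits(config, "runConfig"))
  x <- list(scenario = config$scenario,
            init = as.list(setNames(as.numeric(config$init),
                                    names(config$init))),
            params = unclass(config$params),
            obs = unclass(config$obs),
            rtol = config$rtol, atol = config$atol, seed = config$seed)
  if (!is.null(config$events) && nrow(config$events) > 0L)
    x$events <- as.data.frame(config$events)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname runConfig
#' @export
readRunConfig <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  events <- NULL
  if (!is.null(x$events))
    events <- eventSchedule(x$events$time, x$events$species,
                            x$events$added_concentration)
  runConfig(init = do.call(speciesState, as.list(x$init)),
            params = do.call(rateParameters, as.list(x$params)),
            obs = do.call(observationModel, as.list(x$obs)),
            events = events, scenario = x$scenario,
            rtol = x$rtol, atol = x$atol, seed = x$seed)
}
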