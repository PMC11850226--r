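# Shared fixtures: canonical concentrations and a memoised cache so slow
# simulations are built once per test run.

standardInit <- function() speciesState(RNP = 40, T = 250, Reporter = 250)

defaultParams <- function(...) {
  args <- list(k_on = 1e-3, k_off = 1e-3, k_act = 5e-3, k_cat = 0.05,
               K_M = 150)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(rateParameters, args)
}

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixtureCache))
    assign(key, expr, envir = .fixtureCache)
  get(key, envir = .fixtureCache)
}

# Noiseless observed trajectory for a parameter set under the standard
# concentrations, 60 s cadence.
observedStandard <- function(params, span = 3600, noiseSd = 0, seed = 1L) {
  grid <- seq(0, span, by = 10)
  sim <- if (params$tau > 0) simulateDDE(standardInit(), params, grid)
         else simulateODE(standardInit(), params, grid)
  observeTrajectory(sim,
                    observationModel(alpha = 1, background = 50,
                                     noise_sd = noiseSd,
                                     sampling_interval = 60),
                    seed = seed)
}
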