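# Least-squares recovery of kinetic parameters from progress curves:
# consistency at the optimum, recovery from perturbed starts, boundary
# honesty for tau, bootstrap uncertainty and profile identifiability.

truthSpec <- function(start, tauUpper = NULL) {
  up <- c(k_act = 10, k_cat = 10, K_M = 1e4)
  if (!is.null(tauUpper)) up <- c(up, tau = tauUpper)
  fitSpec(start, init = standardInit(),
          params = rateParameters(k_on = 1e-3, k_off = 1e-3),
          obs = observationModel(alpha = 1, background = 50),
          upper = up[names(start)])
}

test_that("fitting noiseless data from the truth stays at the truth", {
  truth <- c(k_act = 5e-3, k_cat = 0.05, K_M = 150)
  traj <- cached("obsPrompt", observedStandard(defaultParams()))
  f <- fitKinetics(traj, truthSpec(truth))
  expect_true(f$converged)
  expect_lt(max(abs(f$estimates - truth) / truth), 1e-3)
  expect_lt(f$residualNorm, 1e-4)
})

test_that("noiseless recovery from 3x-perturbed guesses is within 1%", {
  truth <- c(k_act = 5e-3, k_cat = 0.05, K_M = 150)
  traj <- cached("obsPrompt", observedStandard(defaultParams()))
  for (pert in list(c(3, 1 / 3, 3), c(1 / 3, 3, 1 / 3))) {
    f <- fitKinetics(traj, truthSpec(truth * pert))
    expect_true(f$converged)
    expect_lt(max(abs(f$estimates - truth) / truth), 0.01)
  }
})

test_that("k_cat survives realistic noise in most replicate fits", {
  # 61 samples at 60 s, noise 2% of full scale; K_M treated as calibrated
  # (with it free, no hour-long regime at this cadence determines k_cat to
  # 10% at this noise — an expected-information floor, not a fitter limit)
  truth <- c(k_act = 4e-3, k_cat = 5e-3)
  p <- defaultParams(k_act = 4e-3, k_cat = 5e-3, K_M = 120)
  hits <- vapply(1:20, function(s) {
    traj <- observedStandard(p, span = 3600, noiseSd = 5, seed = s)
    st <- truth *
      exp(cas12akin:::withLocalSeed(s, runif(2, -log(3), log(3))))
    sp <- fitSpec(st, init = standardInit(),
                  params = rateParameters(k_on = 1e-3, k_off = 1e-3,
                                          K_M = 120),
                  obs = observationModel(alpha = 1, background = 50),
                  upper = c(k_act = 10, k_cat = 10))
    f <- fitKinetics(traj, sp, rtol = 1e-7, atol = 1e-9)
    abs(f$estimates[["k_cat"]] - truth[["k_cat"]]) / truth[["k_cat"]] <= 0.1
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("data generated without a lag never yields a material fitted tau", {
  truth <- c(k_act = 5e-3, k_cat = 0.05, K_M = 150, tau = 100)
  traj <- cached("obsPrompt", observedStandard(defaultParams()))
  f <- fitDelay(traj, truthSpec(truth, tauUpper = 3000))
  expect_true(f$converged)
  # two sampling intervals at the 60 s cadence
  expect_lte(f$estimates[["tau"]], 120)
})

test_that("a long characteristic time is recovered from noiseless data", {
  p <- defaultParams(k_act = 1e-2, k_cat = 0.03, tau = 1700)
  traj <- cached("obs1700", observedStandard(p, span = 5400))
  start <- c(k_act = 2e-2, k_cat = 0.015, K_M = 300,
             tau = lagTimeTangent(traj))
  f <- suppressWarnings(fitDelay(traj, truthSpec(start, tauUpper = 4860),
                                 rtol = 1e-7, atol = 1e-9))
  expect_true(f$converged)
  expect_lt(abs(f$estimates[["tau"]] - 1700) / 1700, 0.02)
})

test_that("degenerate inputs are refused with informative errors", {
  traj <- cached("obsPrompt", observedStandard(defaultParams()))
  short <- cas12akin:::newTrajectory(
    as.data.frame(traj)[1:2, c("time", "fluorescence")], model = "observed")
  expect_error(fitKinetics(short, truthSpec(c(k_act = 1e-3, k_cat = 0.1,
                                              K_M = 100))),
               "underdetermined")
  bad <- traj
  bad$fluorescence[5] <- NaN
  expect_error(fitKinetics(bad, truthSpec(c(k_act = 1e-3))), "non-finite")
  expect_error(fitKinetics(traj, truthSpec(c(k_act = 1e-3, tau = 10),
                                           tauUpper = 100), model = "ode"),
               "dde")
})

test_that("bootstrap intervals are seeded, tight on clean data, and gated", {
  truth <- c(k_act = 5e-3, k_cat = 0.05, K_M = 150)
  traj <- cached("obsPrompt", observedStandard(defaultParams()))
  f <- fitKinetics(traj, truthSpec(truth))
  expect_error(bootstrapFit(traj, truthSpec(truth), fit = f,
                            nResamples = 5), ">= 10")
  b1 <- bootstrapFit(traj, truthSpec(truth), fit = f, nResamples = 20,
                     seed = 5)
  b2 <- bootstrapFit(traj, truthSpec(truth), fit = f, nResamples = 20,
                     seed = 5)
  expect_identical(b1$ci, b2$ci)
  # noiseless data: interval widths are numerically negligible
  widths <- (b1$ci[, "upper"] - b1$ci[, "lower"]) / truth[rownames(b1$ci)]
  expect_true(all(widths < 1e-4))
})

test_that("bootstrap intervals cover the true k_cat at near-nominal rate", {
  # well-conditioned two-parameter regime (K_M calibrated): percentile
  # intervals should cover at close to the nominal rate
  truth <- c(k_act = 4e-3, k_cat = 5e-3)
  p <- defaultParams(k_act = 4e-3, k_cat = 5e-3, K_M = 120)
  mkSpec <- function() fitSpec(truth, init = standardInit(),
                               params = rateParameters(k_on = 1e-3,
                                                       k_off = 1e-3,
                                                       K_M = 120),
                               obs = observationModel(alpha = 1,
                                                      background = 50))
  covered <- vapply(1:20, function(s) {
    traj <- observedStandard(p, span = 3600, noiseSd = 5, seed = 1000 + s)
    sp <- mkSpec()
    f <- fitKinetics(traj, sp, rtol = 1e-6, atol = 1e-8)
    b <- bootstrapFit(traj, sp, fit = f, nResamples = 25, seed = s)
    b$ci["k_cat", "lower"] <= truth[["k_cat"]] &&
      truth[["k_cat"]] <= b$ci["k_cat", "upper"]
  }, logical(1))
  expect_gte(mean(covered), 0.85)
})

test_that("profiles expose the alpha/k_cat scale confound and its cure", {
  # pre-plateau window on realistically noisy data: with no plateau to pin
  # the scale, alpha and k_cat are constrained only through their product,
  # and the alpha profile is flat relative to the noise floor. (On data
  # that reach the plateau, alpha becomes identifiable -- the plateau
  # height is alpha * Reporter(0).)
  pSlow <- defaultParams(k_act = 4e-3, k_cat = 2e-3, K_M = 120)
  pre <- observedStandard(pSlow, span = 900, noiseSd = 2.5, seed = 7)
  spFree <- fitSpec(c(k_cat = 2e-3, alpha = 1),
                    init = standardInit(),
                    params = rateParameters(k_on = 1e-3, k_off = 1e-3,
                                            k_act = 4e-3, K_M = 120),
                    obs = observationModel(alpha = 1, background = 50))
  prof <- profileFit(pre, spFree, "alpha", c(0.5, 1, 2))
  expect_true(attr(prof, "unidentifiable"))
  traj <- cached("obsPrompt", observedStandard(defaultParams()))

  # alpha pinned: the k_cat profile has a clear minimum at the truth
  spPinned <- fitSpec(c(k_cat = 0.05, k_act = 5e-3, K_M = 150),
                      init = standardInit(),
                      params = rateParameters(k_on = 1e-3, k_off = 1e-3),
                      obs = observationModel(alpha = 1, background = 50))
  grid <- c(0.0125, 0.025, 0.05, 0.1, 0.2)
  prof2 <- profileFit(traj, spPinned, "k_cat", grid)
  expect_false(attr(prof2, "unidentifiable"))
  expect_equal(grid[which.min(prof2$residualNorm)], 0.05)

  expect_warning(profileFit(traj, spPinned, "k_cat", 0.05), "degenerate")
})
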