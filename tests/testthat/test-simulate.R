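# Simulators: adaptive ODE/DDE integration against a fixed-step reference,
# staged additions, the observation model and the scenario presets.

test_that("no activator means no product, ever", {
  traj <- simulateODE(speciesState(RNP = 40, Reporter = 250),
                      defaultParams(), seq(0, 3600, by = 60))
  expect_true(all(traj$P == 0))
  expect_true(all(traj$Reporter == 250))
})

test_that("product is monotone, bounded by the reporter pool, and positive", {
  traj <- cached("odeStandard",
                 simulateODE(standardInit(), defaultParams(),
                             seq(0, 3600, by = 10)))
  expect_true(all(diff(traj$P) >= -1e-9))
  expect_true(all(traj$P <= 250 + 1e-6))
  expect_true(all(as.matrix(as.data.frame(traj)[-1]) >= -1e-8))
})

test_that("adaptive ODE solution matches the fixed-step reference", {
  p <- defaultParams()
  ref <- referenceRK4(standardInit(), p, span = 120, dt = 1e-3,
                      outInterval = 5)
  tr <- simulateODE(standardInit(), p, seq(0, 120, by = 5))
  for (sp in c("RNP", "T", "RNPT", "RNPT_star", "Reporter", "P")) {
    scale <- max(abs(ref[[sp]]), 1e-12)
    expect_lt(max(abs(tr[[sp]] - ref[[sp]])) / scale, 1e-5)
  }
})

test_that("delayed integration matches a dense fixed-step delay reference", {
  p <- defaultParams(tau = 300)
  ref <- referenceRK4(standardInit(), p, span = 1800, dt = 0.05,
                      outInterval = 30)
  tr <- simulateDDE(standardInit(), p, seq(0, 1800, by = 30))
  for (sp in c("RNPT", "RNPT_star", "P")) {
    scale <- max(abs(ref[[sp]]), 1e-12)
    expect_lt(max(abs(tr[[sp]] - ref[[sp]])) / scale, 1e-5)
  }
})

test_that("zero delay dispatches to the ODE model exactly", {
  p <- defaultParams(tau = 0)
  grid <- seq(0, 1200, by = 20)
  expect_identical(as.data.frame(simulateDDE(standardInit(), p, grid)),
                   as.data.frame(simulateODE(standardInit(), p, grid)))
})

test_that("longer delays postpone product accumulation", {
  grid <- seq(0, 9000, by = 25)
  rise10 <- vapply(c(0, 100, 500, 1700, 5000), function(tau) {
    tr <- simulateDDE(standardInit(), defaultParams(k_act = 1e-2, tau = tau),
                      grid)
    grid[which(tr$P >= 0.1 * max(tr$P))[1]]
  }, numeric(1))
  expect_true(all(diff(rise10) > 0))
})

test_that("a long delay produces a flat lag phase then a sigmoidal rise", {
  p <- defaultParams(k_act = 1e-2, tau = 1700)
  tr <- cached("dde1700",
               simulateDDE(standardInit(), p, seq(0, 5400, by = 20)))
  plateau <- max(tr$P)
  expect_lt(max(tr$P[tr$time <= 1600]), 0.05 * plateau)
  expect_gt(max(tr$P), 0.9 * 250)
})

test_that("the delayed solver rejects an output grid coarser than tau/4", {
  expect_error(simulateDDE(standardInit(), defaultParams(tau = 100),
                           seq(0, 3600, by = 60)), "tau/4")
})

test_that("an empty schedule reproduces the closed simulation", {
  p <- defaultParams()
  grid <- seq(0, 1200, by = 10)
  closed <- simulateODE(standardInit(), p, grid)
  staged <- simulateStaged(standardInit(), p,
                           eventSchedule(numeric(0), character(0),
                                         numeric(0)), grid)
  expect_equal(staged$P, closed$P, tolerance = 1e-8)
})

test_that("events step the named species up and leave the rest untouched", {
  p <- defaultParams()
  grid <- sort(unique(c(seq(0, 1200, by = 10), 599.999, 600.001)))
  ev <- eventSchedule(600, "T", 77)
  tr <- simulateStaged(standardInit(), p, ev, grid)
  pre <- as.data.frame(tr)[tr$time == 599.999, ]
  post <- as.data.frame(tr)[tr$time == 600.001, ]
  expect_equal(post$T, pre$T + 77, tolerance = 1e-3)
  for (sp in c("RNP", "RNPT", "RNPT_star", "Reporter", "P", "I", "TI"))
    expect_equal(post[[sp]], pre[[sp]], tolerance = 1e-3)
})

test_that("an inert inhibitor leaves the trajectory unchanged", {
  p <- defaultParams(k_act = 2e-2)
  sc <- kineticScenario("dynamic")
  grid <- seq(0, 1500, by = 10)
  withI <- simulateStaged(sc$init, p, sc$events, grid,
                          k_seq = 0, k_deact = 0)
  onlyA <- simulateStaged(sc$init, p,
                          sc$events[sc$events$species == "T", ], grid)
  expect_equal(withI$P, onlyA$P, tolerance = 1e-6)
})

test_that("events outside the span are refused", {
  expect_error(simulateStaged(standardInit(), defaultParams(),
                              eventSchedule(9999, "T", 10),
                              seq(0, 1200, by = 10)),
               "outside")
})

test_that("observation maps product to signal exactly when noiseless", {
  traj <- cached("odeStandard",
                 simulateODE(standardInit(), defaultParams(),
                             seq(0, 3600, by = 10)))
  obs <- observationModel(alpha = 1, background = 0, noise_sd = 0,
                          sampling_interval = 60)
  o <- observeTrajectory(traj, obs)
  expect_equal(o$fluorescence, o$P)
  expect_equal(o$time, seq(0, 3600, by = 60))
  # signal is non-decreasing when noiseless: product is never destroyed
  expect_true(all(diff(o$fluorescence) >= -1e-9))
})

test_that("observation noise is seeded, reproducible and correctly scaled", {
  traj <- cached("odeStandard",
                 simulateODE(standardInit(), defaultParams(),
                             seq(0, 3600, by = 10)))
  obs <- observationModel(alpha = 1, background = 50, noise_sd = 3,
                          sampling_interval = 60)
  a <- observeTrajectory(traj, obs, seed = 99)
  b <- observeTrajectory(traj, obs, seed = 99)
  c_ <- observeTrajectory(traj, obs, seed = 100)
  expect_identical(a$fluorescence, b$fluorescence)
  expect_false(identical(a$fluorescence, c_$fluorescence))

  # empirical noise SD over many draws approaches the model SD
  clean <- observeTrajectory(traj, observationModel(
    alpha = 1, background = 50, noise_sd = 0, sampling_interval = 60))
  devs <- unlist(lapply(1:200, function(s)
    observeTrajectory(traj, obs, seed = s)$fluorescence -
      clean$fluorescence))
  expect_gt(length(devs), 10000)
  expect_lt(abs(sd(devs) - 3) / 3, 0.03)
})

test_that("scenario presets carry the canonical concentrations", {
  std <- kineticScenario("standard")
  expect_equal(unname(std$init[c("RNP", "T", "Reporter")]), c(40, 250, 250))

  dyn <- kineticScenario("dynamic")
  expect_equal(unname(dyn$init[["RNP"]]), 100)
  expect_equal(nrow(dyn$events), 5)
  expect_equal(dyn$events$added_concentration, c(10, 20, 50, 120, 250))
  expect_equal(diff(dyn$events$time), rep(240, 4))

  gate <- kineticScenario("gate")
  expect_equal(unname(gate$init[c("RNP", "T", "Reporter")]), c(40, 50, 250))

  expect_error(kineticScenario("nope"), "standard, dynamic, gate")
})
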