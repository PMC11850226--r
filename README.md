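# cas12akin

Kinetic modelling and parameter estimation for delayed CRISPR–Cas12a
trans-cleavage activation.

Cas12a ribonucleoprotein (RNP) switched on by a matching DNA activator
cleaves single-stranded reporter DNA indiscriminately, which is the signal
amplifier behind a large family of CRISPR diagnostics. Activators carrying
overhanging single-stranded extensions switch the enzyme on *late*: the
fluorescence time course shows a lag phase tunable from tens of seconds to
over an hour. This package is for people who model or analyse such
experiments — it simulates the activation kinetics, generates realistic
synthetic fluorimeter data, and estimates the kinetic constants and the
characteristic delay from measured progress curves.

## The model

A three-step scheme — reversible binding, irreversible activation,
Michaelis–Menten reporter turnover:

```
RNP + T  <=[k_on]/[k_off]=>  RNPT  --[k_act]-->  RNPT*
RNPT* + Reporter  --[k_cat, K_M]-->  RNPT* + P
```

with mass-action ODEs for the first two steps and

```
d[P]/dt = -d[Reporter]/dt = k_cat [RNPT*][Reporter] / (K_M + [Reporter]).
```

Delayed activation is modelled by a delay differential equation,
`d[RNPT*]/dt = k_act [RNPT](t − τ)`, with characteristic time τ. Units are
seconds and nanomolar throughout. Estimation is bounded nonlinear least
squares on the fluorescence residuals (Levenberg–Marquardt via
`minpack.lm`), with `k_act`, `k_cat`, `K_M` fitted on the ODE model and τ
on the DDE model; bootstrap intervals and profile-based identifiability
checks are built in. See the vignette
(`vignettes/cas12a-activation-kinetics.Rmd`) for the model assumptions,
numerical choices and limitations.

## Worked example

Simulate the canonical experiment (RNP 40 nM, activator 250 nM, reporter
250 nM) with a 1700 s activation delay, observe it through the fluorimeter
model, and fit the kinetic parameters back:

```r
library(cas12akin)

params <- rateParameters(k_on = 1e-3, k_off = 1e-3, k_act = 4e-3,
                         k_cat = 5e-3, K_M = 120, tau = 1700)
sc   <- kineticScenario("standard")
traj <- simulateDDE(sc$init, params, seq(0, 9000, by = 20))
obs  <- observeTrajectory(traj, observationModel(noise_sd = 2.5), seed = 1)

lagTimeTangent(obs)   # empirical tangent lag, s
#> [1] 1879.495

spec <- fitSpec(c(k_act = 8e-3, k_cat = 2.5e-3, K_M = 240,
                  tau = lagTimeTangent(obs)),
                init = sc$init,
                params = rateParameters(k_on = 1e-3, k_off = 1e-3),
                obs = observationModel(alpha = 1, background = 50))
fit <- fitDelay(obs, spec)
fit
#> Kinetic fit (dde model): converged after 6 iteration(s) (2 starts)
#>   estimates:
#>     k_act      0.00383821
#>     k_cat      0.00514361
#>     K_M        124.925
#>     tau        1696.93
#>   residual norm: 27.4609 (n = 151)
```

Starting two- to three-fold off truth, the fit recovers `k_act` within 4%,
`k_cat` within 3%, `K_M` within 4% and τ within 0.2% on this noisy (1% of
full scale) trajectory. The tangent lag (1879 s) overshoots τ because it
also absorbs the finite activation time — the fitted τ is the cleaner
estimate, the tangent lag the model-free one.

The staged protocol (alternating activator/inhibitor additions) and the
logic-gate classifier follow the same pattern:

```r
dyn <- kineticScenario("dynamic")
st  <- simulateStaged(dyn$init, rateParameters(k_act = 2e-2), dyn$events,
                      seq(0, 1500, by = 10))
classifyGate(c(`00` = 3, `01` = 5, `10` = 4, `11` = 180),
             positiveControl = 200, gate = "AND")
#> AND gate (threshold 0.5 x positive control): matches canonical truth table
#>           00 01 10 11
#> observed   0  0  0  1
#> canonical  0  0  0  1
```

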