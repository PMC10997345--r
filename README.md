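# larmex

Day-level dynamic networks of affect from ecological momentary assessment
(EMA) data, modeled as an exogenous linear autoregressive mixed-effects
(LARMEx) system: simulation, REML/ML estimation with BLUP prediction, and a
parameter-recovery evaluation suite.

## The model

EMA studies prompt a person several times a day (here, nominally 10 prompts
over N days) for a small set of mood ratings `m` and the intensity of
external events `e`. Within day `i` the moods follow a first-order vector
autoregression with a contemporaneous exogenous input,

    m[i,t] = B_ar[i] m[i,t-1] + B_e[i] e[i,t] + B_c[i] + eps[i,t],
    eps[i,t] ~ N(0, sigma^2 I),

where every coefficient splits into a subject-level *trait* and a day-level
*state*: `B[i] = beta + b[i]`, with `b[i] ~ N(0, G)` independent across
days. The autoregressive matrix carries the network's directed edges
(self-loops and cross-lagged couplings), the exogenous coefficients the
one-way influence of external events on each mood. Each day restarts from a
fresh initial value (overnight breaks are real discontinuities), so days
are exchangeable replicates nested in the person.

Stacking each day's transitions turns this into a standard linear
mixed-effects model `Y_i = X_i beta + Z_i b_i + eps_i` with `q = k^2 + 2k`
coefficients for `k` moods. The package estimates `beta`, `G` and `sigma^2`
by (restricted) maximum likelihood over a profiled, unconstrained
covariance parameterization, and predicts the realized day effects by the
best linear unbiased predictor `b_i = G Z_i' V_i^-1 (Y_i - X_i beta)`,
`V_i = Z_i G Z_i' + sigma^2 I`.

Because the day-level coefficients are the scientific quantity of interest
and EMA designs are short, the package ships a full simulation study:
stability-constrained day sampling, signal-to-noise calibration, missing
data (MCAR with listwise deletion of broken transition pairs), and relative
estimation error (REE) of fixed effects versus BLUPs across day counts,
noise levels, compliance rates and network sizes.

## Worked example

```r
library(larmex)

spec <- example_spec(2)                      # the canonical 2-mood network
cfg  <- sim_config(spec, n_days = 36, seed = 42)
data <- simulate_dataset(cfg)                # 360 rows, 36 days x 10 prompts
stk  <- stack_dataset(data)
fit  <- fit_larmex(stk)                      # REML, diagonal G
print(fit)
```

```
LARMEx fit (REML, G structure: diagonal)
  days: 36
  -2 logLik (constants excluded): -1574.0533
  converged: TRUE  iterations: 29  |grad|: 0.000426
       estimate     se  g_var
ar_1_1   0.3326 0.0404 0.0045
ar_1_2  -0.2865 0.0581 0.0650
ar_2_1  -0.2770 0.0521 0.0370
ar_2_2   0.2373 0.0504 0.0319
e_1      0.2791 0.0568 0.0000
e_2     -0.3131 0.0658 0.0332
c_1      0.0158 0.0403 0.0448
c_2     -0.0245 0.0385 0.0387
  sigma2_hat: 0.01897
```

The generating values were `+/-0.3` for the six network coefficients, zero
constants, `G = 0.03 I` and `sigma^2 = 0.02`: all fixed effects are
recovered within about one standard error, and the fitted day-level
variances scatter around 0.03. `blup(fit)` returns the predicted day
deviations; `compute_snr(spec)` reports the design's signal-to-noise ratio
(about 6 here).

A thin command-line wrapper covers the same workflows from a shell:

```sh
Rscript inst/cli/larmex.R simulate --config cfg.yaml --out out/
Rscript inst/cli/larmex.R fit --data out/ema.csv --out out/
Rscript inst/cli/larmex.R recover --config cfg.yaml --reps 100 --out out/
Rscript inst/cli/larmex.R snr --config cfg.yaml --out out/
```

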