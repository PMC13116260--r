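# Shared fixtures. Expensive objects (equilibrium replicate runs of the
# calibrated model) are computed once per test session and memoised.

.cache <- new.env(parent = emptyenv())

calibrated_model <- function() {
  if (is.null(.cache$model)) .cache$model <- channel_model()
  .cache$model
}

# three independent 400 ps equilibrium trajectories of the bound pair
equilibrium_replicates <- function() {
  if (is.null(.cache$eqreps))
    .cache$eqreps <- simulate(calibrated_model(), nsim = 3, seed = 21,
                              duration = 400e-12)
  .cache$eqreps
}

# SI shorthands used across tests
.kB <- 1.380649e-23
.eV <- 1.602176634e-19
.mCa <- 39.962590863 * 1.66053906660e-27
.h <- 6.62607015e-34
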