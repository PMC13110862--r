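# Shared fixtures, built in code at test time.

# the standard exposure design: 0/10/100/1000 nM x 4 replicates
stdConc <- function(nRep = 4L) rep(c(0, 10, 100, 1000), each = nRep)

# a small experiment wrapped around an explicit matrix
makeExperiment <- function(values, conc = stdConc()) {
  DoseResponseExperiment(values, conc)
}

# simulate one endpoint from a known curve
simulateEndpoint <- function(model, params, conc = stdConc(),
                             noiseSd = 0.25, seed = 1L) {
  withr::with_seed(seed, {
    evaluateModel(model, params, conc) + rnorm(length(conc), sd = noiseSd)
  })
}

# independent grid-search inversion of |f(d) - f(0)| = target, used as the
# brute-force oracle against closed-form BMCs (1e5-point dose grid)
gridSearchBMC <- function(model, params, target, maxDose,
                          nGrid = 1e5L) {
  d <- exp(seq(log(maxDose * 1e-7), log(maxDose), length.out = nGrid))
  f0 <- evaluateModel(model, params, 0)
  g <- abs(evaluateModel(model, params, d) - f0) - target
  i <- which(g >= 0)[1L]
  if (is.na(i)) return(NA_real_)
  if (i == 1L) return(d[1L])
  # linear interpolation of the crossing
  d[i - 1L] + (d[i] - d[i - 1L]) * (0 - g[i - 1L]) / (g[i] - g[i - 1L])
}
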