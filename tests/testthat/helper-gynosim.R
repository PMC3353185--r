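# Shared fixtures: small, fast configurations used across test files.

# A desk-scale coupled configuration: small censuses and capacity, default
# genetics. Keeps multi-generation tests cheap without changing the model.
smallConfig <- function(...) {
  args <- list(initialSize1 = 300, initialSize2 = 300, K0 = 1200,
               generations = 30, stabilityPeriod = 15, seed = 42)
  over <- list(...)
  args[names(over)] <- over
  do.call(simConfig, args)
}

# Combined census per generation from a trajectory.
combinedCensus <- function(tr) {
  stats::aggregate(cbind(census = census_F + census_M) ~ generation,
                   data = tr, FUN = sum)
}

# Exhaustive enumeration oracle for Mendelian segregation at one locus:
# distribution of the offspring state from the four equiprobable
# (maternal allele, paternal allele) draws.
segregationOracle <- function(motherState, fatherState) {
  mAlleles <- c(rep(0, 2 - motherState), rep(1, motherState))
  fAlleles <- c(rep(0, 2 - fatherState), rep(1, fatherState))
  states <- outer(mAlleles, fAlleles, `+`)
  p <- tabulate(as.vector(states) + 1L, nbins = 3L) / 4
  setNames(p, 0:2)
}
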