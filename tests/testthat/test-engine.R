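test_that("initialization sets all-heterozygous founders with the derived sex ratio", {
  st <- initializeSimulation(simConfig(alphaAsex1 = 0, alphaAsex2 = 1))
  expect_equal(femaleCount(st@pop1), 4500)
  expect_equal(maleCount(st@pop1), 4500)
  expect_equal(femaleCount(st@pop2), 9000)
  expect_equal(maleCount(st@pop2), 0)
  env <- st@env
  # all-het founders carry no fit genotype (lf = 0.729 < 0.8)
  expect_equal(fitFraction(st@pop1, env), 0)
  expect_equal(trajectory(runSimulation(
    simConfig(generations = 1, seed = 1)))$fit_count[1:2], c(0, 0))
  # remainder rounding goes to females
  st2 <- initializeSimulation(simConfig(initialSize1 = 9001, alphaAsex1 = 0))
  expect_equal(maleCount(st2@pop1), 4500)
  expect_equal(femaleCount(st2@pop1), 4501)
  # effective sigma is attached per population
  expect_equal(sigmaP(st@pop2), 0.2 * 0.7)
})

test_that("the environment flips exactly at multiples of the stability period", {
  cfg <- smallConfig(stabilityPeriod = 5, generations = 17, seed = 11)
  tr <- trajectory(runSimulation(cfg))
  expect_equal(tr$env_epoch[tr$pop == 1], (0:17) %/% 5)
  expect_equal(tr$env_epoch, tr$generation %/% 5)
  # stepping a state across the boundary complements the resources
  st <- initializeSimulation(simConfig(stabilityPeriod = 1, generations = 2))
  st1 <- stepGeneration(st, simConfig(stabilityPeriod = 1, generations = 2))
  expect_equal(resources(st1@env), 1L - st@env@resources)
  st2 <- stepGeneration(st1, simConfig(stabilityPeriod = 1, generations = 2))
  expect_equal(resources(st2@env), st@env@resources)
})

test_that("seeded runs are bit-reproducible and censuses stay non-negative", {
  cfg <- smallConfig(seed = 123)
  tr1 <- trajectory(runSimulation(cfg))
  tr2 <- trajectory(runSimulation(cfg))
  expect_identical(tr1, tr2)
  expect_true(all(tr1$census_F >= 0 & tr1$census_M >= 0))
  # and the individuals engine is reproducible too
  cfgI <- smallConfig(seed = 123, engineMode = "individuals",
                      generations = 8)
  expect_identical(trajectory(runSimulation(cfgI)),
                   trajectory(runSimulation(cfgI)))
})

test_that("a monomorphic fully-fit population equilibrates at K0", {
  cfg <- simConfig(initialSize1 = 500, initialSize2 = 0, K0 = 2000,
                   alphaAsex1 = 0.5, generations = 80,
                   stabilityPeriod = 100, seed = 21)
  st <- initializeSimulation(cfg, genotype = c(2, 2, 2))
  census <- numeric(80)
  for (g in 1:80) {
    st <- stepGeneration(st, cfg)
    census[g] <- census(st@pop1)
  }
  expect_equal(mean(census[50:80]), 2000, tolerance = 0.1)
})

test_that("density coupling: inflating one population depresses the other", {
  base <- simConfig(initialSize1 = 500, initialSize2 = 0, K0 = 3000,
                    generations = 40, stabilityPeriod = 100, seed = 5)
  alone <- runSimulation(base)
  crowded <- runSimulation(simConfig(initialSize1 = 500,
                                     initialSize2 = 2500, K0 = 3000,
                                     generations = 40,
                                     stabilityPeriod = 100, seed = 5))
  trA <- trajectory(alone); trC <- trajectory(crowded)
  cenA <- trA$census_F[trA$pop == 1] + trA$census_M[trA$pop == 1]
  cenC <- trC$census_F[trC$pop == 1] + trC$census_M[trC$pop == 1]
  expect_lt(mean(cenC[30:41]), mean(cenA[30:41]))
})

test_that("without mutation an all-asexual population never gains genotype classes", {
  cfg <- smallConfig(alphaAsex1 = 1, alphaAsex2 = 1, mutationRate = 0,
                     generations = 25, seed = 9)
  res <- runSimulation(cfg)
  final <- res@finalState
  present <- which(rowSums(final@pop1@counts[, , , drop = FALSE]) > 0)
  hetClass <- genotypeClassIndex(c(1L, 1L, 1L))
  expect_true(all(present %in% hetClass))
})

test_that("outcome classification covers the four cases and drives early exit", {
  mk <- function(n1, n2) {
    st <- initializeSimulation(simConfig(initialSize1 = n1,
                                         initialSize2 = n2))
    st
  }
  expect_equal(classifyOutcome(mk(100, 100)), "both_survive")
  expect_equal(classifyOutcome(mk(100, 0)), "pop1_only")
  expect_equal(classifyOutcome(mk(0, 100)), "pop2_only")
  expect_equal(classifyOutcome(mk(0, 0)), "both_extinct")
  expect_equal(classifyOutcome(mk(100, 100), extinctionThreshold = 100),
               "both_extinct")
  # an empty starting pair exits immediately as both_extinct
  res <- runSimulation(smallConfig(initialSize1 = 0, initialSize2 = 0,
                                   generations = 50))
  expect_equal(outcome(res), "both_extinct")
  expect_lt(max(trajectory(res)$generation), 50)
  # (9000, 0) ends pop1_only
  res2 <- runSimulation(simConfig(initialSize2 = 0, generations = 10,
                                  seed = 2))
  expect_equal(outcome(res2), "pop1_only")
})

test_that("fit fraction tracks the environment: a flip unfits a matched homozygote", {
  cfg <- simConfig(generations = 5)
  envA <- newEnvironment(L = 3)
  pop <- newPopulation(1000, alphaAsex = 0.5, genotype = c(2, 2, 2))
  expect_equal(fitFraction(pop, envA), 1)
  envB <- complementEnvironment(envA)
  expect_equal(fitFraction(pop, envB), 0)  # lf = 0.8^3 = 0.512 < 0.8
  empty <- newPopulation(0, alphaAsex = 0.5)
  ff <- fitFraction(empty, envA)
  expect_equal(as.numeric(ff), 0)
  expect_true(attr(ff, "empty"))
})

test_that("count engine and per-individual engine agree in distribution", {
  cfgC <- simConfig(initialSize1 = 120, initialSize2 = 120, K0 = 500,
                    alphaAsex1 = 0.3, alphaAsex2 = 0.7, generations = 12,
                    stabilityPeriod = 6, engineMode = "counts")
  cfgI <- simConfig(initialSize1 = 120, initialSize2 = 120, K0 = 500,
                    alphaAsex1 = 0.3, alphaAsex2 = 0.7, generations = 12,
                    stabilityPeriod = 6, engineMode = "individuals")
  nrep <- 24
  set.seed(314)
  run <- function(cfg) {
    res <- runSimulation(cfg)
    tr <- trajectory(res)
    last <- tr[tr$generation == max(tr$generation), ]
    c(c1 = last$census_F[1] + last$census_M[1],
      c2 = last$census_F[2] + last$census_M[2],
      fit = sum(last$fit_count))
  }
  mC <- t(replicate(nrep, run(cfgC)))
  mI <- t(replicate(nrep, run(cfgI)))
  # two-sample location tests on census and fit-count summaries
  expect_gt(stats::wilcox.test(mC[, "c1"], mI[, "c1"], exact = FALSE)$p.value,
            1e-3)
  expect_gt(stats::wilcox.test(mC[, "c2"], mI[, "c2"], exact = FALSE)$p.value,
            1e-3)
  expect_gt(stats::wilcox.test(mC[, "fit"], mI[, "fit"], exact = FALSE)$p.value,
            1e-3)
})

test_that("origin-specific selection mode penalizes asexually produced fish", {
  # with sigmaMode = "origin", a 100% asexual population faces mu * sigma
  # individually; censuses should fall below the population-mode run once
  # adaptation has not yet occurred (unfit genotypes, stronger selection)
  cfgP <- smallConfig(alphaAsex1 = 1, alphaAsex2 = 1, sigmaMode = "population",
                      generations = 10, seed = 77)
  cfgO <- smallConfig(alphaAsex1 = 1, alphaAsex2 = 1, sigmaMode = "origin",
                      generations = 10, seed = 77)
  trP <- combinedCensus(trajectory(runSimulation(cfgP)))
  trO <- combinedCensus(trajectory(runSimulation(cfgO)))
  # all-asexual: every newborn is asexual-origin, so the two modes coincide
  expect_identical(trP, trO)
})
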