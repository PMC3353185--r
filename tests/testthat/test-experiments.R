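test_that("seed derivation is stable, bounded and sensitive to its labels", {
  s1 <- deriveSeed(1, "grid", 2, 3, 1)
  expect_identical(s1, deriveSeed(1, "grid", 2, 3, 1))
  expect_false(s1 == deriveSeed(1, "grid", 2, 3, 2))
  expect_false(s1 == deriveSeed(2, "grid", 2, 3, 1))
  many <- vapply(1:200, function(i) deriveSeed(7, "x", i), integer(1))
  expect_true(all(many >= 1 & many < 2^31))
  expect_false(any(duplicated(many)))
})

test_that("tournament bookkeeping conserves replicates and is antisymmetric", {
  grid <- competitionGrid(alphas = c(0, 0.4, 0.8), reps = 2, sigma = 0.7,
                          stabilityPeriod = 15, generations = 40,
                          initialSize1 = 250, initialSize2 = 250, K0 = 1000,
                          seed = 3)
  expect_equal(nrow(grid), 9)
  # per-cell outcome counts sum to the replicate totals (2 on the
  # diagonal, 2 * 2 off it, both orderings aggregated)
  expect_equal(grid$n_pop1_only + grid$n_both + grid$n_pop2_only +
                 grid$n_both_extinct, grid$reps)
  expect_equal(grid$reps, ifelse(grid$alpha1 == grid$alpha2, 2L, 4L))
  # exact antisymmetry of the aggregated score up to joint extinctions
  for (k in seq_len(nrow(grid))) {
    mirror <- grid[grid$alpha1 == grid$alpha2[k] &
                     grid$alpha2 == grid$alpha1[k], ]
    expect_equal(grid$score[k] + mirror$score,
                 1 - grid$n_both_extinct[k] / grid$reps[k])
    expect_equal(grid$n_pop1_only[k], mirror$n_pop2_only)
  }
  # win totals cover every contested pairing
  sc <- winningScores(grid)
  expect_equal(sc$alpha, c(0, 0.4, 0.8))
  off <- grid$alpha1 != grid$alpha2
  expect_equal(sum(sc$wins),
               sum(grid$n_pop1_only[off] + 0.5 * grid$n_both[off]))
  expect_true(modalWinningAlpha(grid) %in% (100 * sc$alpha))
})

test_that("adaptation runs start unfit, fix no fluctuation, and report phases", {
  ad <- adaptationExperiment(alphaAsex = 0.5, sigma = 0.5,
                             generations = 60, size = 3000, K0 = 3000,
                             seed = 13)
  tr <- ad$trajectory
  expect_equal(tr$fit_count[tr$generation == 0], 0)
  expect_equal(unique(tr$env_epoch), 0)        # no fluctuation
  expect_true(is.na(ad$timeToAllFit) ||
                ad$timeToAllFit >= ad$timeToFirstFit)
  if (!is.na(ad$timeToAllFit)) {
    lastGen <- tr[tr$generation == ad$timeToAllFit, ]
    expect_equal(lastGen$fit_count, lastGen$census_F + lastGen$census_M)
    expect_equal(ad$amplificationTime,
                 ad$timeToAllFit - ad$timeToFirstFit)
  }
})

test_that("the asexuality sweep pairs stochastic and deterministic curves", {
  sw <- asexualitySweep(alphas = c(0, 0.8), sigmas = c(0.5),
                        generations = 25, size = 2500, K0 = 2500, seed = 5)
  expect_setequal(unique(sw$model), c("stochastic", "deterministic"))
  expect_setequal(unique(sw$alpha), c(0, 0.8))
  # every curve starts with zero fit genotypes
  expect_true(all(sw$fit_count[sw$generation == 0] == 0))
  # horizons match
  expect_equal(max(sw$generation), 25)
})

test_that("stability comparison couples the pair under each period", {
  st <- stabilityComparison(alphaPair = c(0.3, 0.5), sigma = 0.5,
                            periods = c(10, 5), generations = 20,
                            reps = 2, seed = 8,
                            initialSize1 = 400, initialSize2 = 400,
                            K0 = 1500)
  expect_setequal(unique(st$period), c(10, 5))
  expect_setequal(unique(st$rep), c(1, 2))
  expect_equal(unique(st$alpha[st$pop == 1]), 0.3)
  expect_equal(unique(st$alpha[st$pop == 2]), 0.5)
  # epochs advance with the period
  expect_equal(max(st$env_epoch[st$period == 5]), 4)
})

test_that("a census crash follows each environment fluctuation", {
  # sign test: the generation after a flip shows a census drop
  st <- stabilityComparison(alphaPair = c(0.3, 0.5), sigma = 0.5,
                            periods = 10, generations = 40, reps = 3,
                            seed = 4)
  drops <- 0; total <- 0
  for (r in unique(st$rep)) {
    tr <- st[st$rep == r, ]
    comb <- stats::aggregate(census ~ generation, tr, sum)
    for (flip in c(10, 20, 30)) {
      pre <- comb$census[comb$generation == flip]
      post <- comb$census[comb$generation == flip + 1]
      if (length(pre) && length(post)) {
        total <- total + 1
        if (post < pre) drops <- drops + 1
      }
    }
  }
  expect_gt(drops / total, 0.8)
})

test_that("configuration files round-trip with validation and defaults", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines("", f)
  cfg <- loadConfig(f)                      # empty file: full defaults
  expect_s4_class(cfg, "SimConfig")
  expect_equal(cfg@L, 3L)
  expect_equal(cfg@fitness@s, 0.2)
  expect_equal(cfg@demo@K0, 30000)
  writeLines(c("L: 5", "generations: 10"), f)
  cfg5 <- loadConfig(f)
  expect_equal(cfg5@fitness@s, 0.125)       # s keyed to L
  writeLines("bogusKey: 1", f)
  expect_error(loadConfig(f), "bogusKey")
  writeLines("sigma: 0.9", f)
  expect_warning(loadConfig(f), "sigma")
})

test_that("run artifacts (trajectory CSV, outcome JSON, manifest) are faithful", {
  res <- runSimulation(smallConfig(generations = 5, seed = 31))
  csv <- withr::local_tempfile(fileext = ".csv")
  writeTrajectory(res, csv)
  back <- utils::read.csv(csv)
  expect_equal(back, trajectory(res))
  js <- withr::local_tempfile(fileext = ".json")
  writeOutcome(res, js)
  rec <- jsonlite::read_json(js)
  expect_equal(rec$label, outcome(res))
  expect_equal(rec$finalCensus1, census(res@finalState@pop1))
  mf <- runManifest(res@config, masterSeed = 31,
                    derivedSeeds = c(a = 1L), outputs = csv)
  mj <- withr::local_tempfile(fileext = ".json")
  writeManifest(mf, mj)
  mrec <- jsonlite::read_json(mj)
  expect_equal(mrec$config$K0, 1200)
  expect_equal(mrec$masterSeed, 31)
})
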