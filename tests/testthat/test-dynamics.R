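test_that("reproduction-mode split is binomial with the population's asexual share", {
  set.seed(1)
  expect_equal(chooseReproductionModes(25, 1),
               c(asexual = 25L, sexual = 0L))
  expect_equal(chooseReproductionModes(25, 0),
               c(asexual = 0L, sexual = 25L))
  n <- 1e6
  m <- chooseReproductionModes(n, 0.5)
  expect_equal(sum(m), n)
  se <- sqrt(n * 0.25)
  expect_lt(abs(m[["asexual"]] - n / 2), 3 * se)
})

test_that("gynogenetic broods are all-female clonal copies of the mother", {
  mother <- c(0L, 1L, 2L)
  brood <- asexualBrood(mother, 10)
  expect_equal(nrow(brood), 10)
  expect_true(all(brood[, 4] == 1))                     # all female
  expect_true(all(brood[, 5] == 2))                     # asexual origin
  expect_equal(unique(brood[, 1:3]), matrix(mother, 1)) # exact clones
})

test_that("segregation matches the exhaustive per-locus enumeration oracle", {
  # degenerate crosses
  set.seed(2)
  expect_equal(segregate(c(0L, 0L), c(0L, 0L)), c(0L, 0L))
  expect_equal(segregate(c(0L, 2L), c(0L, 2L)), c(0L, 2L))  # hom x hom fixed
  expect_equal(segregate(0L, 2L), 1L)                       # forced het
  # het x het: 1/4 : 1/2 : 1/4 per the enumeration oracle
  oracle <- segregationOracle(1L, 1L)
  expect_equal(unname(oracle), c(0.25, 0.5, 0.25))
  draws <- replicate(2e4, segregate(1L, 1L))
  obs <- tabulate(draws + 1L, nbins = 3L)
  expect_gt(stats::chisq.test(obs, p = oracle)$p.value, 1e-3)
  # het x hom: oracle 1/2 : 1/2
  oracle2 <- segregationOracle(1L, 2L)
  draws2 <- replicate(2e4, segregate(1L, 2L))
  obs2 <- tabulate(draws2 + 1L, nbins = 3L)
  expect_gt(stats::chisq.test(obs2[2:3], p = oracle2[2:3])$p.value, 1e-3)
})

test_that("loci segregate independently (product measure over 27 classes)", {
  set.seed(3)
  n <- 3e4
  draws <- matrix(0L, n, 3)
  for (i in seq_len(n)) draws[i, ] <- segregate(c(1L, 1L, 1L), c(1L, 1L, 1L))
  idx <- genotypeClassIndex(draws)
  obs <- tabulate(idx, nbins = 27)
  perLocus <- segregationOracle(1L, 1L)
  classes <- enumerateGenotypeClasses(3)
  expProb <- apply(classes, 1, function(g) prod(perLocus[g + 1L]))
  expect_gt(stats::chisq.test(obs, p = expProb)$p.value, 1e-3)
})

test_that("sexual broods need conspecific males and sex offspring fairly", {
  set.seed(4)
  none <- sexualBrood(c(1L, 1L, 1L), matrix(integer(0), ncol = 3), 10)
  expect_equal(nrow(none), 0)
  males <- matrix(c(2L, 2L, 2L), 1)
  nF <- 0; total <- 0
  for (i in 1:500) {
    br <- sexualBrood(c(2L, 2L, 2L), males, 10)
    expect_equal(nrow(br), 10)
    expect_true(all(br[, 1:3] == 2L))  # monomorphic parents, identical kids
    nF <- nF + sum(br[, 4] == 1); total <- total + 10
  }
  se <- sqrt(total * 0.25)
  expect_lt(abs(nF - total / 2), 3 * se)
})

test_that("offspring alleles are conserved without mutation", {
  set.seed(5)
  for (rep in 1:50) {
    mother <- sample(0:2, 3, replace = TRUE)
    father <- sample(0:2, 3, replace = TRUE)
    kid <- segregate(mother, father)
    for (i in 1:3) {
      # transmitted allele pair must be drawable from the parents
      mA <- unique(c(if (mother[i] < 2) 0L, if (mother[i] > 0) 1L))
      fA <- unique(c(if (father[i] < 2) 0L, if (father[i] > 0) 1L))
      expect_true(kid[i] %in% unique(as.vector(outer(mA, fA, `+`))))
    }
  }
})

test_that("mutation flips exactly one uniformly chosen allele slot", {
  pool <- asexualBrood(c(0L, 0L, 0L), 1000)
  expect_identical(applyMutation(pool, 0, 3)[, 1:3], pool[, 1:3])
  expect_equal(attr(applyMutation(pool, 0, 3), "mutations"), 0L)
  set.seed(6)
  mut <- applyMutation(pool, 1, 3)  # every offspring mutates once
  expect_equal(attr(mut, "mutations"), 1000L)
  changed <- rowSums(mut[, 1:3] != 0L)
  expect_true(all(changed == 1))          # exactly one locus moved
  expect_true(all(mut[, 1:3] %in% c(0L, 1L)))  # hom 0 -> het only
  # het flips go to either homozygote
  hetPool <- asexualBrood(c(1L, 1L, 1L), 2000)
  mutHet <- applyMutation(hetPool, 1, 3)
  moved <- mutHet[, 1:3][mutHet[, 1:3] != 1L]
  expect_setequal(unique(moved), c(0L, 2L))
  expect_gt(stats::chisq.test(table(moved))$p.value, 1e-3)
})

test_that("a full season yields b offspring per mother with the zero-male rule", {
  L <- 3
  set.seed(7)
  # all-asexual: pure cloning, b * F female offspring
  females <- asexualBrood(c(1L, 1L, 1L), 40)  # 40 females, any origin
  pool <- reproducePopulation(females, alphaAsex = 1, b = 10,
                              mutationRate = 0, L = L)
  expect_equal(nrow(pool), 400)
  expect_true(all(pool[, 4] == 1))
  # fully sexual with zero males: no offspring at all
  pool0 <- reproducePopulation(females, alphaAsex = 0, b = 10,
                               mutationRate = 0, L = L)
  expect_equal(nrow(pool0), 0)
  # mixed: expected pool size b*F*(alpha + (1-alpha) * 1{males > 0})
  inds <- rbind(females[1:20, ],
                cbind(matrix(1L, 5, 3), 2L, 1L))  # add 5 males
  sizes <- replicate(40, nrow(reproducePopulation(inds, 0.5, 10, 0, L)))
  expect_equal(mean(sizes), 200, tolerance = 0.05)
})

test_that("Beverton-Holt survival matches worked values and decreases with density", {
  expect_equal(survivalProbability(30000, 10, 0.5, 0), 1)
  expect_equal(survivalProbability(30000, 10, 0.5, 30000), 1 / 6)
  p1 <- survivalProbability(1000, 10, 0.5, 5000)
  p2 <- survivalProbability(1000, 10, 0.5, 10000)
  expect_lt(p2, p1)
  expect_error(survivalProbability(0, 10, 0.5, 100), "K")
})

test_that("carrying capacity scales the maximum by genotype fitness", {
  env <- rep(1, 3)
  expect_equal(carryingCapacity(c(2, 2, 2), env, sigma = 0.5, K0 = 30000), 30000)
  Khet <- carryingCapacity(c(1, 1, 1), env, sigma = 0.5, K0 = 30000)
  expect_equal(Khet, 25901.9, tolerance = 1e-4)
  K <- carryingCapacity(enumerateGenotypeClasses(3), env, sigma = 0.5,
                        K0 = 30000)
  expect_true(all(K <= 30000))
})
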