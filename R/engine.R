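#' @include dynamics.R
NULL

## Internal: per-origin Gaussian fitness matrix (nC x 2) for one population
## under the current environment. In "population" mode both origin columns
## use the population-effective sigma_p; in "origin" mode asexually
## produced fish individually face the stronger selection mu * sigma.
.fitMatrix <- function(env, config, alphaAsex) {
  fp <- config@fitness
  lf <- lociFitness(enumerateGenotypeClasses(config@L), env, fp)
  sig <- if (config@sigmaMode == "population")
    rep(effectiveSigma(fp@sigma, alphaAsex, fp@mu), 2L)
  else c(fp@sigma, fp@mu * fp@sigma)
  cbind(sexual = exp(-(1 - lf)^2 / (2 * sig[1]^2)),
        asexual = exp(-(1 - lf)^2 / (2 * sig[2]^2)))
}

#' Initialize a simulation state
#'
#' Builds generation-0 state: both populations founded all-heterozygous at
#' every locus (intermediate fitness, no fit genotype under the default
#' threshold) with sex ratios from [initialSexFractions()], and the
#' environment set to the configured initial resource vector.
#'
#' @param config a [SimConfig-class].
#' @param genotype founder genotype passed to [newPopulation()]
#'   (default all-heterozygous).
#' @return a [SimState-class] at generation 0.
#' @export
#' @examples
#' st <- initializeSimulation(simConfig(generations = 10))
initializeSimulation <- function(config, genotype = "heterozygous") {
  validObject(config)
  fp <- config@fitness
  env <- newEnvironment(config@initialEnv, config@stabilityPeriod)
  pop <- function(size, alpha)
    newPopulation(size, L = config@L, alphaAsex = alpha,
                  sigma = fp@sigma, mu = fp@mu, genotype = genotype)
  new("SimState", generation = 0L, env = env,
      pop1 = pop(config@initialSize1, config@alphaAsex1),
      pop2 = pop(config@initialSize2, config@alphaAsex2))
}

## Internal: one generation on raw count arrays (used by the run loop,
## which caches the fitness matrices for the two alternating environments).
.stepCounts <- function(c1, c2, fit1, fit2, config) {
  d <- config@demo
  res <- cpp_step_generation(c1, c2,
                             enumerateGenotypeClasses(config@L), config@L,
                             fit1, fit2,
                             config@alphaAsex1, config@alphaAsex2,
                             d@b, d@K0, d@mutationRate,
                             config@broodModel == "poisson",
                             config@mutationModel == "per_allele")
  res
}

#' Advance the simulation by one generation
#'
#' Order of events: (1) every female in each population reproduces
#' (gynogenetic clones or Mendelian broods sired by a conspecific male);
#' (2) newborns are mutated and merged into their population; (3) coupled
#' Beverton-Holt viability selection thins every individual, with density
#' `N` and female fraction `phi` taken from the combined adult census of
#' both populations; (4) the generation counter advances; (5) if the new
#' generation index is a multiple of the stability period, the environment
#' is complemented.
#'
#' @param state a [SimState-class].
#' @param config the [SimConfig-class] governing the run.
#' @return the next [SimState-class]; attributes `mutations` and
#'   `offspring` report the allele flips and newborn totals of the season.
#' @export
stepGeneration <- function(state, config) {
  env <- state@env
  if (config@engineMode == "individuals") {
    res <- .stepIndividuals(state@pop1@counts, state@pop2@counts, env, config)
  } else {
    fit1 <- .fitMatrix(env, config, config@alphaAsex1)
    fit2 <- .fitMatrix(env, config, config@alphaAsex2)
    res <- .stepCounts(state@pop1@counts, state@pop2@counts, fit1, fit2, config)
  }
  gen <- state@generation + 1L
  if (gen %% config@stabilityPeriod == 0L)
    env <- complementEnvironment(env)
  dims <- dim(state@pop1@counts)
  dn <- dimnames(state@pop1@counts)
  out <- new("SimState", generation = gen, env = env,
             pop1 = initialize(state@pop1,
                               counts = array(res$counts1, dims, dn)),
             pop2 = initialize(state@pop2,
                               counts = array(res$counts2, dims, dn)))
  attr(out, "mutations") <- res$mutations
  attr(out, "offspring") <- c(res$offspring1, res$offspring2)
  out
}

#' Classify the outcome of a finished run
#'
#' A population is extinct when its census is at or below the extinction
#' threshold (default 0). The four outcomes are `pop1_only`,
#' `both_survive`, `pop2_only` and `both_extinct`.
#'
#' @param state the final [SimState-class].
#' @param extinctionThreshold census cutoff.
#' @return the outcome label (character).
#' @export
classifyOutcome <- function(state, extinctionThreshold = 0) {
  a1 <- census(state@pop1) > extinctionThreshold
  a2 <- census(state@pop2) > extinctionThreshold
  if (a1 && a2) "both_survive"
  else if (a1) "pop1_only"
  else if (a2) "pop2_only"
  else "both_extinct"
}

## Internal: trajectory rows for one generation.
.record <- function(gen, epoch, c1, c2, lf, fit, nMut) {
  rows <- lapply(list(c1, c2), function(cc) {
    dim(cc) <- c(length(lf), 4L)
    byClass <- rowSums(cc)
    n <- sum(byClass)
    c(censusF = sum(cc[, c(1L, 3L)]), censusM = sum(cc[, c(2L, 4L)]),
      fitCount = sum(byClass[fit]),
      meanLf = if (n > 0) sum(byClass * lf) / n else NA_real_)
  })
  data.frame(generation = gen, pop = 1:2,
             census_F = c(rows[[1]][1], rows[[2]][1]),
             census_M = c(rows[[1]][2], rows[[2]][2]),
             fit_count = c(rows[[1]][3], rows[[2]][3]),
             mean_lf = c(rows[[1]][4], rows[[2]][4]),
             env_epoch = epoch, mutations = nMut)
}

#' Run a full simulation
#'
#' Iterates [stepGeneration()] for the configured number of generations
#' (exiting early once both populations are extinct) and records a
#' per-generation, per-population trajectory: female/male census, number
#' of individuals carrying a fit genotype, mean loci fitness, environment
#' epoch (number of fluctuations so far) and allele flips that season
#' (reported on both rows of a generation).
#'
#' @param config a [SimConfig-class]; its `seed` slot (when not NA) seeds
#'   the RNG so runs are bit-reproducible.
#' @return a [SimResult-class].
#' @export
#' @examples
#' res <- runSimulation(simConfig(initialSize1 = 500, initialSize2 = 500,
#'                                K0 = 2000, generations = 20, seed = 1))
#' head(trajectory(res))
runSimulation <- function(config) {
  validObject(config)
  if (!is.na(config@seed)) set.seed(config@seed)
  state <- initializeSimulation(config)
  fp <- config@fitness

  envA <- state@env
  envB <- complementEnvironment(envA)
  classes <- enumerateGenotypeClasses(config@L)
  lfA <- lociFitness(classes, envA, fp); fitAcl <- lfA >= fp@fitThreshold
  lfB <- lociFitness(classes, envB, fp); fitBcl <- lfB >= fp@fitThreshold
  useCounts <- config@engineMode == "counts"
  if (useCounts) {
    f1A <- .fitMatrix(envA, config, config@alphaAsex1)
    f2A <- .fitMatrix(envA, config, config@alphaAsex2)
    f1B <- .fitMatrix(envB, config, config@alphaAsex1)
    f2B <- .fitMatrix(envB, config, config@alphaAsex2)
  }

  c1 <- state@pop1@counts; c2 <- state@pop2@counts
  dims <- dim(c1); dn <- dimnames(c1)
  recs <- vector("list", config@generations + 1L)
  recs[[1L]] <- .record(0L, 0L, c1, c2, lfA, fitAcl, 0L)
  lastGen <- 0L
  for (gen in seq_len(config@generations)) {
    epochPre <- (gen - 1L) %/% config@stabilityPeriod
    aEnv <- epochPre %% 2L == 0L
    if (useCounts) {
      res <- .stepCounts(c1, c2,
                         if (aEnv) f1A else f1B, if (aEnv) f2A else f2B,
                         config)
    } else {
      res <- .stepIndividuals(array(c1, dims, dn), array(c2, dims, dn),
                              if (aEnv) envA else envB, config)
    }
    c1 <- res$counts1; c2 <- res$counts2
    epoch <- gen %/% config@stabilityPeriod
    post <- epoch %% 2L == 0L
    recs[[gen + 1L]] <- .record(gen, epoch, c1, c2,
                                if (post) lfA else lfB,
                                if (post) fitAcl else fitBcl,
                                res$mutations)
    lastGen <- gen
    if (sum(c1) <= config@extinctionThreshold &&
        sum(c2) <= config@extinctionThreshold) break
  }
  traj <- do.call(rbind, recs[seq_len(lastGen + 1L)])
  rownames(traj) <- NULL
  final <- new("SimState",
               generation = lastGen,
               env = if ((lastGen %/% config@stabilityPeriod) %% 2L == 0L)
                 envA else envB,
               pop1 = initialize(state@pop1, counts = array(c1, dims, dn)),
               pop2 = initialize(state@pop2, counts = array(c2, dims, dn)))
  new("SimResult", trajectory = traj,
      outcome = classifyOutcome(final, config@extinctionThreshold),
      finalState = final, config = config)
}
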