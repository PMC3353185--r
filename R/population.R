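#' @include fitness.R
NULL

#' Construct a population
#'
#' Builds a genotype-class count [Population-class]. The default initial
#' composition is all-heterozygous at every locus (intermediate fitness, no
#' fit genotype under the default threshold), with sex counts given by
#' [initialSexFractions()]: males are rounded down and the remainder goes
#' to females. Initial individuals are attributed to reproductive origins
#' in proportion to the population's reproductive mix (males, being
#' products of syngamy, are always of sexual origin).
#'
#' @param size initial census.
#' @param L number of loci.
#' @param alphaAsex proportion of asexual (gynogenetic) reproduction.
#' @param sigma base selection strength.
#' @param mu asexual selection-increase factor.
#' @param genotype either `"heterozygous"` (default) or a state vector of
#'   length L in \{0,1,2\} used for every founder.
#' @return a [Population-class].
#' @export
#' @examples
#' p <- newPopulation(9000, L = 3, alphaAsex = 0.5)
#' census(p)
newPopulation <- function(size, L = 3, alphaAsex = 0, sigma = 0.7, mu = 0.2,
                          genotype = "heterozygous") {
  size <- as.integer(size)
  if (is.na(size) || size < 0) stop("'size' must be a non-negative integer")
  nC <- 3L^as.integer(L)
  counts <- array(0L, dim = c(nC, 2L, 2L),
                  dimnames = list(NULL, c("F", "M"), c("sexual", "asexual")))
  if (identical(genotype, "heterozygous")) genotype <- rep(1L, L)
  cls <- genotypeClassIndex(as.integer(genotype))
  fr <- initialSexFractions(alphaAsex)
  nM <- as.integer(floor(size * fr[["male"]]))
  nF <- size - nM
  nFasex <- as.integer(round(nF * alphaAsex))
  counts[cls, "F", "asexual"] <- nFasex
  counts[cls, "F", "sexual"] <- nF - nFasex
  counts[cls, "M", "sexual"] <- nM
  new("Population", counts = counts, alphaAsex = alphaAsex,
      sigmaP = effectiveSigma(sigma, alphaAsex, mu))
}

#' Genotype-specific carrying capacity
#'
#' `K(g, env) = F(g, env; sigma) * K0`: the maximum carrying capacity
#' scaled by the genotype's Gaussian fitness. Never exceeds `K0`.
#'
#' @inheritParams genotypeFitness
#' @param K0 maximum carrying capacity of the environment.
#' @return numeric carrying capacities in (0, K0].
#' @export
#' @examples
#' carryingCapacity(c(1, 1, 1), rep(1, 3), sigma = 0.5, K0 = 30000)
carryingCapacity <- function(g, env, params = fitnessParams(),
                             sigma = params@sigma, K0 = 30000) {
  genotypeFitness(g, env, params, sigma) * K0
}

#' Beverton-Holt survival probability
#'
#' Modified Beverton-Holt viability: `p = 1 / (1 + b * phi * N / K)`,
#' where `N` is the combined adult census of the two competing populations
#' and `phi` their female fraction. Equals 1 when there is no crowding and
#' decreases strictly with `N`. Selection is applied with this probability
#' to every individual, newborn or adult.
#'
#' @param K carrying capacity (vectorized, > 0).
#' @param b offspring per female.
#' @param phi female fraction of the combined adult census.
#' @param Ntotal combined adult census.
#' @return survival probabilities in (0, 1].
#' @export
#' @examples
#' survivalProbability(30000, b = 10, phi = 0.5, Ntotal = 30000)  # 1/6
survivalProbability <- function(K, b, phi, Ntotal) {
  if (any(K <= 0)) stop("'K' must be positive")
  if (any(phi < 0 | phi > 1)) stop("'phi' must be a proportion")
  if (any(Ntotal < 0)) stop("'Ntotal' must be non-negative")
  1 / (1 + b * phi * Ntotal / K)
}

#' Fraction of fit individuals in a population
#'
#' Share of the census whose genotype class has loci fitness at or above
#' the fit threshold in the current environment. An empty population
#' reports 0 with attribute `empty = TRUE`.
#'
#' @param pop a [Population-class].
#' @param env an [Environment-class] or resource vector.
#' @param params a [FitnessParams-class].
#' @return a proportion in [0, 1].
#' @export
fitFraction <- function(pop, env, params = fitnessParams()) {
  n <- census(pop)
  if (n == 0) return(structure(0, empty = TRUE))
  L <- round(log(dim(pop@counts)[1], 3))
  fit <- isFit(enumerateGenotypeClasses(L), env, params)
  sum(pop@counts[fit, , ]) / n
}
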