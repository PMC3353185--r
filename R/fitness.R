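#' @include AllClasses.R
NULL

## Internal: coerce Environment | 0/1 vector to a plain resource vector.
.resVec <- function(env) {
  if (is(env, "Environment")) env@resources else as.integer(env)
}

## Internal: coerce genotype input (state vector of length L, or an n x L
## matrix of states) to a matrix of per-locus states in {0,1,2}.
.stateMat <- function(g, L = NULL) {
  m <- if (is.matrix(g)) g else matrix(as.integer(g), nrow = 1L)
  if (!all(m %in% 0:2))
    stop("genotype states must be 0 (hom 0/0), 1 (het) or 2 (hom 1/1)")
  if (!is.null(L) && ncol(m) != L)
    stop("genotype has ", ncol(m), " loci but the environment has ", L)
  m
}

#' Collapse an allele pair to a locus state
#'
#' A diploid locus carries an unordered pair of 0/1 alleles; only the
#' number of `1` alleles matters for fitness, so the 4 ordered pairs
#' collapse to 3 states: 0 (homozygous 0/0), 1 (heterozygous), 2
#' (homozygous 1/1).
#'
#' @param alleleA,alleleB alleles in \{0, 1\} (vectorized).
#' @return integer state(s) in \{0, 1, 2\}.
#' @export
#' @examples locusState(0, 1)  # heterozygous -> 1
locusState <- function(alleleA, alleleB) {
  if (!all(c(alleleA, alleleB) %in% c(0, 1)))
    stop("alleles must be 0 or 1")
  as.integer(alleleA + alleleB)
}

#' Enumerate all unordered genotype classes
#'
#' Returns the canonical ordering of the 3^L unordered genotype classes
#' used throughout the count engine: class `k` (1-based) has per-locus
#' states equal to the base-3 digits of `k - 1`, locus 1 being the least
#' significant digit. The ordering is deterministic and stable.
#'
#' @param L number of loci (>= 1).
#' @return integer matrix of dimension (3^L, L) with entries in \{0, 1, 2\}.
#' @export
#' @examples
#' enumerateGenotypeClasses(1)  # the three states of a single locus
enumerateGenotypeClasses <- function(L) {
  L <- as.integer(L)
  if (is.na(L) || L < 1) stop("'L' must be a positive integer")
  nC <- 3L^L
  idx <- 0:(nC - 1L)
  m <- matrix(0L, nrow = nC, ncol = L)
  for (i in seq_len(L)) {
    m[, i] <- idx %% 3L
    idx <- idx %/% 3L
  }
  m
}

#' Index of a genotype class in the canonical ordering
#'
#' Inverse of [enumerateGenotypeClasses()]: maps per-locus states to the
#' 1-based row index.
#'
#' @param states integer vector (length L) or matrix (n x L) of states.
#' @return integer index (vector).
#' @export
genotypeClassIndex <- function(states) {
  m <- .stateMat(states)
  as.integer(m %*% 3L^(seq_len(ncol(m)) - 1L)) + 1L
}

#' Per-locus fitness
#'
#' Match score of one diploid locus against the corresponding binary
#' environmental resource: 1 when both alleles equal the resource,
#' `1 - delta * s` when heterozygous, `1 - s` when homozygous for the
#' wrong allele.
#'
#' @param state locus state in \{0, 1, 2\} (vectorized; see [locusState()]).
#' @param resource environmental resource bit (vectorized).
#' @param params a [FitnessParams-class].
#' @return numeric fitness value(s) in (0, 1].
#' @export
#' @examples
#' locusFitness(locusState(0, 1), 0, fitnessParams())  # 1 - 0.5 * 0.2 = 0.9
locusFitness <- function(state, resource, params = fitnessParams()) {
  validObject(params)
  state <- as.integer(state)
  resource <- as.integer(resource)
  if (!all(state %in% 0:2)) stop("locus state must be 0, 1 or 2")
  if (!all(resource %in% c(0L, 1L))) stop("resource must be 0 or 1")
  ifelse(state == 1L, 1 - params@delta * params@s,
         ifelse(state == 2L * resource, 1, 1 - params@s))
}

#' Loci fitness (lf)
#'
#' Multiplicative fitness of a genotype against the environment: the
#' product over loci of [locusFitness()]. Bounded in [(1-s)^L, 1].
#'
#' @param g genotype: state vector of length L or (n x L) state matrix.
#' @param env an [Environment-class] or 0/1 resource vector.
#' @param params a [FitnessParams-class].
#' @return numeric vector of loci-fitness values.
#' @export
#' @examples
#' lociFitness(c(1, 1, 1), rep(1, 3), fitnessParams())  # 0.9^3 = 0.729
lociFitness <- function(g, env, params = fitnessParams()) {
  r <- .resVec(env)
  m <- .stateMat(g, L = length(r))
  lf <- rep(1, nrow(m))
  for (i in seq_along(r))
    lf <- lf * locusFitness(m[, i], r[i], params)
  lf
}

#' Genotype fitness (Gaussian stabilizing selection)
#'
#' Maps the loci fitness `lf` through the Gaussian selection function
#' `exp(-(1 - lf)^2 / (2 sigma^2))`. Equals 1 exactly when every locus is
#' homozygous-matching; smaller `sigma` means a steeper (stronger)
#' selection gradient.
#'
#' @inheritParams lociFitness
#' @param sigma selection strength; defaults to `params@sigma`. The
#'   population-effective value from [effectiveSigma()] is passed here by
#'   the engine.
#' @return numeric vector of fitness values in (0, 1].
#' @export
#' @examples
#' genotypeFitness(c(1, 1, 1), rep(1, 3), fitnessParams(), sigma = 0.5)
genotypeFitness <- function(g, env, params = fitnessParams(),
                            sigma = params@sigma) {
  if (length(sigma) != 1 || is.na(sigma) || sigma <= 0)
    stop("'sigma' must be a single positive value")
  lf <- lociFitness(g, env, params)
  exp(-(1 - lf)^2 / (2 * sigma^2))
}

#' Is a genotype fit?
#'
#' A genotype is "fit" in the current environment when its loci fitness is
#' greater than or equal to the threshold (default 0.8; the comparison is
#' inclusive).
#'
#' @inheritParams lociFitness
#' @return logical vector.
#' @export
isFit <- function(g, env, params = fitnessParams()) {
  lociFitness(g, env, params) >= params@fitThreshold
}

#' Effective population selection strength
#'
#' Mixing the base selection strength by reproduction mode removes the
#' twofold demographic advantage of gynogenesis:
#' `sigma_p = sigma * alpha_sex + mu * sigma * alpha_asex`. With the
#' default mu = 0.2 a fully asexual population faces selection five times
#' as strong as a fully sexual one.
#'
#' @param sigma base selection strength.
#' @param alphaAsex proportion of asexual reproduction.
#' @param mu selection-increase factor in (0, 1].
#' @return effective sigma in [mu * sigma, sigma].
#' @export
#' @examples
#' effectiveSigma(0.5, 1, 0.2)  # 0.1
effectiveSigma <- function(sigma, alphaAsex, mu = 0.2) {
  if (any(mu <= 0 | mu > 1)) stop("'mu' must be in (0, 1]")
  if (any(alphaAsex < 0 | alphaAsex > 1)) stop("'alphaAsex' must be a proportion")
  if (any(sigma <= 0)) stop("'sigma' must be positive")
  sigma * (1 - alphaAsex) + mu * sigma * alphaAsex
}

#' Initial sex fractions of a population
#'
#' The initial sex ratio reflects the reproductive mix: gynogenetic
#' lineages are all-female, sexual lineages half-and-half, so a population
#' with asexual proportion `alpha_asex` starts with
#' `alpha_asex + alpha_sex / 2` females and `alpha_sex / 2` males. A male
#' fraction of 20% therefore corresponds to 40% sexual reproduction.
#'
#' @param alphaAsex proportion of asexual reproduction.
#' @return named numeric vector `c(female = , male = )`, summing to 1.
#' @export
#' @examples initialSexFractions(0.6)
initialSexFractions <- function(alphaAsex) {
  if (any(alphaAsex < 0 | alphaAsex > 1)) stop("'alphaAsex' must be a proportion")
  alphaSex <- 1 - alphaAsex
  c(female = alphaAsex + alphaSex / 2, male = alphaSex / 2)
}

#' Complement an environment (fluctuation)
#'
#' An environmental fluctuation complements every resource bit:
#' `r_i -> 1 - r_i`. Applying it twice restores the input.
#'
#' @param x an [Environment-class] or a 0/1 resource vector.
#' @return the complemented object, same type as the input.
#' @name complementEnvironment
#' @export
#' @examples
#' complementEnvironment(c(1, 1, 1))
setMethod("complementEnvironment", "Environment", function(x) {
  initialize(x, resources = 1L - x@resources)
})

#' @rdname complementEnvironment
#' @export
setMethod("complementEnvironment", "numeric", function(x) {
  if (!all(x %in% c(0, 1))) stop("resources must be 0/1")
  1 - x
})

#' @rdname complementEnvironment
#' @export
setMethod("complementEnvironment", "integer", function(x) {
  if (!all(x %in% c(0L, 1L))) stop("resources must be 0/1")
  1L - x
})

#' Complement a genotype
#'
#' Flips every allele of every locus (state 0 <-> 2; heterozygous loci are
#' self-complementary). Together with [complementEnvironment()] this is the
#' joint bit-flip symmetry of the fitness model:
#' `lf(g, env) == lf(complement(g), complement(env))`.
#'
#' @param g state vector or matrix of genotype classes.
#' @return the complemented states, same shape as the input.
#' @export
complementGenotype <- function(g) {
  m <- .stateMat(g)
  out <- 2L - m
  if (is.matrix(g)) out else as.integer(out)
}

#' Fitness of every genotype class
#'
#' Loci fitness, Gaussian fitness and fit classification for all 3^L
#' genotype classes in canonical order. Used by the count engine and the
#' deterministic companion model.
#'
#' @inheritParams genotypeFitness
#' @param L number of loci (defaults to the environment's length).
#' @return a data.frame with columns `class`, `lf`, `F`, `fit`.
#' @export
classFitnessTable <- function(env, params = fitnessParams(),
                              sigma = params@sigma,
                              L = length(.resVec(env))) {
  classes <- enumerateGenotypeClasses(L)
  lf <- lociFitness(classes, env, params)
  data.frame(class = seq_len(nrow(classes)), lf = lf,
             F = exp(-(1 - lf)^2 / (2 * sigma^2)),
             fit = lf >= params@fitThreshold)
}
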