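#' @include AllGenerics.R
NULL

## ---------------------------------------------------------------------------
## Parameter classes
## ---------------------------------------------------------------------------

#' Ecological fitness parameters
#'
#' Parameters of the multiplicative per-locus fitness model and of the
#' Gaussian stabilizing-selection map. `s` is the fitness decrement at a
#' single mismatched homozygous locus, `delta` the dominance factor applied
#' to heterozygous loci (0.5 means both alleles contribute equally),
#' `sigma` the strength of ecological selection (smaller values mean
#' stronger selection), `mu` the selection-increase factor applied to
#' asexually produced fish (removing the twofold advantage of gynogenesis),
#' and `fitThreshold` the loci-fitness cutoff above which a genotype counts
#' as "fit".
#'
#' @slot s numeric in (0,1).
#' @slot delta numeric in [0,1].
#' @slot sigma positive numeric.
#' @slot mu numeric in (0,1].
#' @slot fitThreshold numeric in (0,1].
#' @export
setClass("FitnessParams",
  representation(s = "numeric", delta = "numeric", sigma = "numeric",
                 mu = "numeric", fitThreshold = "numeric"),
  prototype(s = 0.2, delta = 0.5, sigma = 0.7, mu = 0.2, fitThreshold = 0.8))

setValidity("FitnessParams", function(object) {
  msg <- character()
  if (length(object@s) != 1 || is.na(object@s) || object@s <= 0 || object@s >= 1)
    msg <- c(msg, "'s' must be a single value in (0, 1)")
  if (length(object@delta) != 1 || is.na(object@delta) ||
      object@delta < 0 || object@delta > 1)
    msg <- c(msg, "'delta' must be a single value in [0, 1]")
  if (length(object@sigma) != 1 || is.na(object@sigma) || object@sigma <= 0)
    msg <- c(msg, "'sigma' must be a single positive value")
  if (length(object@mu) != 1 || is.na(object@mu) ||
      object@mu <= 0 || object@mu > 1)
    msg <- c(msg, "'mu' must be a single value in (0, 1]")
  if (length(object@fitThreshold) != 1 || is.na(object@fitThreshold) ||
      object@fitThreshold <= 0 || object@fitThreshold > 1)
    msg <- c(msg, "'fitThreshold' must be a single value in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Per-locus decrement paired to the number of loci
#'
#' The default fitness decrement keeps single-genotype loci-fitness values
#' roughly inside [0.5, 1] as the number of loci grows: s = 0.2 for L = 3,
#' 0.125 for L = 5 and 0.09 for L = 7.
#'
#' @param L number of loci (3, 5 or 7 have defaults).
#' @return the default `s` for `L`.
#' @export
#' @examples defaultDecrement(3)
defaultDecrement <- function(L) {
  tab <- c(`3` = 0.2, `5` = 0.125, `7` = 0.09)
  key <- as.character(L)
  if (!key %in% names(tab))
    stop("no default per-locus decrement for L = ", L, "; supply 's' explicitly")
  unname(tab[key])
}

#' Construct ecological fitness parameters
#'
#' @param L number of loci; used only to pick the default `s`.
#' @param s per-locus fitness decrement; defaults to [defaultDecrement()] of `L`.
#' @param delta dominance factor (default 0.5).
#' @param sigma selection strength (default 0.7, "weak"; 0.5 is "strong").
#' @param mu asexual selection-increase factor (default 0.2).
#' @param fitThreshold loci-fitness cutoff defining a fit genotype (default 0.8).
#' @return a [FitnessParams-class] object.
#' @export
#' @examples
#' fitnessParams(L = 5)
fitnessParams <- function(L = 3, s = defaultDecrement(L), delta = 0.5,
                          sigma = 0.7, mu = 0.2, fitThreshold = 0.8) {
  new("FitnessParams", s = s, delta = delta, sigma = sigma, mu = mu,
      fitThreshold = fitThreshold)
}

#' Demographic parameters
#'
#' `b` is the average number of offspring per female reaching the
#' free-swimming stage, `K0` the maximum carrying capacity of the
#' environment, and `mutationRate` the per-offspring probability that one
#' randomly chosen allele flips at birth.
#'
#' @slot b positive integer.
#' @slot K0 positive integer.
#' @slot mutationRate probability.
#' @export
setClass("DemographyParams",
  representation(b = "numeric", K0 = "numeric", mutationRate = "numeric"),
  prototype(b = 10, K0 = 30000, mutationRate = 1e-5))

setValidity("DemographyParams", function(object) {
  msg <- character()
  if (length(object@b) != 1 || is.na(object@b) || object@b < 1)
    msg <- c(msg, "'b' must be a single value >= 1")
  if (length(object@K0) != 1 || is.na(object@K0) || object@K0 < 1)
    msg <- c(msg, "'K0' must be a single value >= 1")
  if (length(object@mutationRate) != 1 || is.na(object@mutationRate) ||
      object@mutationRate < 0 || object@mutationRate > 1)
    msg <- c(msg, "'mutationRate' must be a probability")
  if (length(msg)) msg else TRUE
})

#' Construct demographic parameters
#'
#' @param b offspring per female reaching the first year (default 10).
#' @param K0 maximum carrying capacity (default 30000).
#' @param mutationRate per-offspring mutation probability (default 1e-5).
#' @return a [DemographyParams-class] object.
#' @export
demographyParams <- function(b = 10, K0 = 30000, mutationRate = 1e-5) {
  new("DemographyParams", b = b, K0 = K0, mutationRate = mutationRate)
}

## ---------------------------------------------------------------------------
## Environment
## ---------------------------------------------------------------------------

#' Binary resource environment
#'
#' The environment is a vector of L binary resources. Every
#' `stabilityPeriod` generations a fluctuation occurs and each resource bit
#' is complemented.
#'
#' @slot resources integer vector of 0/1 values, length L.
#' @slot stabilityPeriod positive integer number of generations between
#'   fluctuations.
#' @export
setClass("Environment",
  representation(resources = "integer", stabilityPeriod = "integer"),
  prototype(resources = c(1L, 1L, 1L), stabilityPeriod = 50L))

setValidity("Environment", function(object) {
  msg <- character()
  if (length(object@resources) < 1 || anyNA(object@resources) ||
      !all(object@resources %in% c(0L, 1L)))
    msg <- c(msg, "'resources' must be a non-empty 0/1 vector")
  if (length(object@stabilityPeriod) != 1 || is.na(object@stabilityPeriod) ||
      object@stabilityPeriod < 1)
    msg <- c(msg, "'stabilityPeriod' must be a positive integer")
  if (length(msg)) msg else TRUE
})

#' Construct an environment
#'
#' @param resources 0/1 vector of length L (default: all ones).
#' @param stabilityPeriod generations between fluctuations (default 50).
#' @param L used when `resources` is missing.
#' @return an [Environment-class] object.
#' @export
#' @examples
#' environment2 <- newEnvironment(L = 3, stabilityPeriod = 10)
newEnvironment <- function(resources = NULL, stabilityPeriod = 50L, L = 3L) {
  if (is.null(resources)) resources <- rep(1L, L)
  new("Environment", resources = as.integer(resources),
      stabilityPeriod = as.integer(stabilityPeriod))
}

#' @describeIn newEnvironment number of resources (loci).
#' @param x an `Environment`.
#' @export
setMethod("length", "Environment", function(x) length(x@resources))

#' @rdname accessors
#' @export
setMethod("resources", "Environment", function(x, ...) x@resources)

#' @rdname accessors
#' @export
setMethod("stabilityPeriod", "Environment", function(x, ...) x@stabilityPeriod)

setMethod("show", "Environment", function(object) {
  cat("Environment with", length(object@resources), "binary resources:",
      paste(object@resources, collapse = ""), "\n")
  cat("  stability period:", object@stabilityPeriod, "generations\n")
})

## ---------------------------------------------------------------------------
## Population
## ---------------------------------------------------------------------------

#' Genotype-class count population
#'
#' A population census indexed by (genotype class, sex, reproductive
#' origin). Genotype classes are the 3^L unordered per-locus allele pairs
#' (per locus: 0 = homozygous 0/0, 1 = heterozygous, 2 = homozygous 1/1) in
#' the canonical ordering of [enumerateGenotypeClasses()]. The origin
#' dimension records whether an individual was produced sexually or by
#' gynogenesis; it only affects selection when the per-origin selection
#' mode is enabled.
#'
#' @slot counts integer array of dimension (3^L, 2, 2) with dimnames
#'   sex = c("F","M") and origin = c("sexual","asexual").
#' @slot alphaAsex proportion of gynogenetic (asexual) reproduction.
#' @slot sigmaP effective population selection strength
#'   (see [effectiveSigma()]).
#' @export
setClass("Population",
  representation(counts = "array", alphaAsex = "numeric", sigmaP = "numeric"))

setValidity("Population", function(object) {
  msg <- character()
  d <- dim(object@counts)
  if (length(d) != 3 || d[2] != 2 || d[3] != 2)
    msg <- c(msg, "'counts' must be a (classes x 2 x 2) array")
  else {
    L <- round(log(d[1], 3))
    if (3^L != d[1]) msg <- c(msg, "first dimension of 'counts' must be 3^L")
    if (anyNA(object@counts) || any(object@counts < 0))
      msg <- c(msg, "counts must be non-negative")
  }
  if (length(object@alphaAsex) != 1 || is.na(object@alphaAsex) ||
      object@alphaAsex < 0 || object@alphaAsex > 1)
    msg <- c(msg, "'alphaAsex' must be a proportion")
  if (length(msg)) msg else TRUE
})

#' @rdname accessors
#' @export
setMethod("census", "Population", function(x, ...) sum(x@counts))

#' @rdname accessors
#' @export
setMethod("femaleCount", "Population", function(x, ...) sum(x@counts[, 1L, ]))

#' @rdname accessors
#' @export
setMethod("maleCount", "Population", function(x, ...) sum(x@counts[, 2L, ]))

#' @rdname accessors
#' @export
setMethod("alphaAsex", "Population", function(x, ...) x@alphaAsex)

#' @rdname accessors
#' @export
setMethod("sigmaP", "Population", function(x, ...) x@sigmaP)

setMethod("show", "Population", function(object) {
  nC <- dim(object@counts)[1]
  L <- round(log(nC, 3))
  cat("Population of", sum(object@counts), "individuals",
      sprintf("(%d F, %d M), L = %d\n",
              sum(object@counts[, 1, ]), sum(object@counts[, 2, ]), L))
  cat(sprintf("  asexual reproduction: %.0f%%; effective sigma: %.3f\n",
              100 * object@alphaAsex, object@sigmaP))
  cat("  genotype classes present:", sum(rowSums(object@counts) > 0),
      "of", nC, "\n")
})

## ---------------------------------------------------------------------------
## Simulation configuration and state
## ---------------------------------------------------------------------------

#' Simulation configuration
#'
#' Full parameter set for a coupled two-population run. See [simConfig()].
#'
#' @slot L integer number of loci.
#' @slot fitness a [FitnessParams-class].
#' @slot demo a [DemographyParams-class].
#' @slot alphaAsex1,alphaAsex2 asexual-reproduction proportions.
#' @slot initialSize1,initialSize2 initial census of each population.
#' @slot stabilityPeriod generations between environment fluctuations.
#' @slot generations number of generations to simulate.
#' @slot initialEnv initial 0/1 resource vector.
#' @slot seed integer seed (NA = leave the RNG stream alone).
#' @slot engineMode "counts" (exact genotype-class engine) or "individuals"
#'   (per-individual reference engine).
#' @slot sigmaMode "population" (one effective sigma per population, the
#'   default) or "origin" (asexually produced fish individually face the
#'   stronger selection mu*sigma).
#' @slot broodModel "fixed" (exactly b offspring) or "poisson".
#' @slot mutationModel "per_offspring" or "per_allele".
#' @slot extinctionThreshold census at or below which a population counts
#'   as extinct.
#' @export
setClass("SimConfig",
  representation(L = "integer", fitness = "FitnessParams",
                 demo = "DemographyParams",
                 alphaAsex1 = "numeric", alphaAsex2 = "numeric",
                 initialSize1 = "integer", initialSize2 = "integer",
                 stabilityPeriod = "integer", generations = "integer",
                 initialEnv = "integer", seed = "integer",
                 engineMode = "character", sigmaMode = "character",
                 broodModel = "character", mutationModel = "character",
                 extinctionThreshold = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@L < 1) msg <- c(msg, "'L' must be >= 1")
  if (length(object@initialEnv) != object@L ||
      !all(object@initialEnv %in% c(0L, 1L)))
    msg <- c(msg, "'initialEnv' must be a 0/1 vector of length L")
  for (a in c("alphaAsex1", "alphaAsex2")) {
    v <- slot(object, a)
    if (length(v) != 1 || is.na(v) || v < 0 || v > 1)
      msg <- c(msg, paste0("'", a, "' must be a proportion"))
  }
  if (object@generations < 1) msg <- c(msg, "'generations' must be >= 1")
  if (object@stabilityPeriod < 1) msg <- c(msg, "'stabilityPeriod' must be >= 1")
  if (any(c(object@initialSize1, object@initialSize2) < 0))
    msg <- c(msg, "initial sizes must be non-negative")
  if (!object@engineMode %in% c("counts", "individuals"))
    msg <- c(msg, "'engineMode' must be \"counts\" or \"individuals\"")
  if (!object@sigmaMode %in% c("population", "origin"))
    msg <- c(msg, "'sigmaMode' must be \"population\" or \"origin\"")
  if (!object@broodModel %in% c("fixed", "poisson"))
    msg <- c(msg, "'broodModel' must be \"fixed\" or \"poisson\"")
  if (!object@mutationModel %in% c("per_offspring", "per_allele"))
    msg <- c(msg, "'mutationModel' must be \"per_offspring\" or \"per_allele\"")
  if (length(msg)) msg else TRUE
})

#' Construct a simulation configuration
#'
#' Defaults reproduce the standard study conditions: two 9,000-individual
#' all-heterozygous populations with L = 3 loci (s = 0.2), weak selection
#' (sigma = 0.7), mu = 0.2, b = 10 offspring per female, maximum carrying
#' capacity 30,000, per-offspring mutation rate 1e-5, environment of all
#' ones complemented every 50 generations, 500 generations.
#'
#' @param L number of loci.
#' @param s per-locus decrement (default keyed to `L`).
#' @param delta dominance factor.
#' @param sigma selection strength.
#' @param mu asexual selection-increase factor.
#' @param fitThreshold fit-genotype loci-fitness cutoff.
#' @param b offspring per female.
#' @param K0 maximum carrying capacity.
#' @param mutationRate per-offspring mutation probability.
#' @param alphaAsex1,alphaAsex2 asexual proportions of the two populations.
#' @param initialSize1,initialSize2 initial censuses.
#' @param stabilityPeriod environment stability period (generations).
#' @param generations run length.
#' @param initialEnv initial resource vector (default all ones).
#' @param seed integer seed or NA.
#' @param engineMode,sigmaMode,broodModel,mutationModel engine switches,
#'   see [SimConfig-class].
#' @param extinctionThreshold extinction census cutoff (default 0).
#' @return a validated [SimConfig-class] object.
#' @export
#' @examples
#' cfg <- simConfig(alphaAsex1 = 0.3, alphaAsex2 = 0.5, generations = 50)
simConfig <- function(L = 3, s = defaultDecrement(L), delta = 0.5,
                      sigma = 0.7, mu = 0.2, fitThreshold = 0.8,
                      b = 10, K0 = 30000, mutationRate = 1e-5,
                      alphaAsex1 = 0.3, alphaAsex2 = 0.5,
                      initialSize1 = 9000, initialSize2 = 9000,
                      stabilityPeriod = 50, generations = 500,
                      initialEnv = rep(1L, L), seed = NA_integer_,
                      engineMode = "counts", sigmaMode = "population",
                      broodModel = "fixed", mutationModel = "per_offspring",
                      extinctionThreshold = 0) {
  new("SimConfig", L = as.integer(L),
      fitness = fitnessParams(L = L, s = s, delta = delta, sigma = sigma,
                              mu = mu, fitThreshold = fitThreshold),
      demo = demographyParams(b = b, K0 = K0, mutationRate = mutationRate),
      alphaAsex1 = alphaAsex1, alphaAsex2 = alphaAsex2,
      initialSize1 = as.integer(initialSize1),
      initialSize2 = as.integer(initialSize2),
      stabilityPeriod = as.integer(stabilityPeriod),
      generations = as.integer(generations),
      initialEnv = as.integer(initialEnv), seed = as.integer(seed),
      engineMode = engineMode, sigmaMode = sigmaMode,
      broodModel = broodModel, mutationModel = mutationModel,
      extinctionThreshold = as.integer(extinctionThreshold))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@L, "loci, s =", object@fitness@s,
      ", sigma =", object@fitness@sigma, ", mu =", object@fitness@mu, "\n")
  cat(sprintf("  populations: %d (%.0f%% asexual) vs %d (%.0f%% asexual)\n",
              object@initialSize1, 100 * object@alphaAsex1,
              object@initialSize2, 100 * object@alphaAsex2))
  cat("  b =", object@demo@b, ", K0 =", object@demo@K0,
      ", mutation rate =", object@demo@mutationRate, "\n")
  cat("  stability period =", object@stabilityPeriod, "; generations =",
      object@generations, "; engine =", object@engineMode, "\n")
})

#' Joint simulation state
#'
#' @slot generation non-negative integer.
#' @slot env an [Environment-class].
#' @slot pop1,pop2 [Population-class] objects.
#' @export
setClass("SimState",
  representation(generation = "integer", env = "Environment",
                 pop1 = "Population", pop2 = "Population"))

#' @rdname accessors
#' @export
setMethod("currentGeneration", "SimState", function(x, ...) x@generation)

setMethod("show", "SimState", function(object) {
  cat("SimState at generation", object@generation, "\n")
  cat("  environment:", paste(object@env@resources, collapse = ""), "\n")
  cat("  censuses:", census(object@pop1), "and", census(object@pop2), "\n")
})

#' Result of a simulation run
#'
#' @slot trajectory per-generation records (see [runSimulation()]).
#' @slot outcome one of "pop1_only", "both_survive", "pop2_only",
#'   "both_extinct".
#' @slot finalState the [SimState-class] at the end of the run.
#' @slot config the [SimConfig-class] used.
#' @export
setClass("SimResult",
  representation(trajectory = "data.frame", outcome = "character",
                 finalState = "SimState", config = "SimConfig"))

#' @rdname accessors
#' @export
setMethod("trajectory", "SimResult", function(x, ...) x@trajectory)

#' @rdname accessors
#' @export
setMethod("outcome", "SimResult", function(x, ...) x@outcome)

setMethod("show", "SimResult", function(object) {
  fs <- object@finalState
  cat("SimResult:", max(object@trajectory$generation), "generations;",
      "outcome:", object@outcome, "\n")
  cat("  final censuses:", census(fs@pop1), "and", census(fs@pop2), "\n")
})
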