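#' @include population.R
NULL

## Reference (per-individual) implementations of one reproductive season.
## Individuals are rows of an integer matrix: columns 1..L are per-locus
## states in {0,1,2}, column L+1 is sex (1 = F, 2 = M), column L+2 is
## reproductive origin (1 = sexual, 2 = asexual). The exact count engine in
## src/ is the production path; these functions define the model one
## individual at a time and back the distributional cross-checks.

#' Split females between reproductive modes
#'
#' Each female independently reproduces by gynogenesis with probability
#' `alphaAsex`, else sexually.
#'
#' @param nFemales number of reproducing females.
#' @param alphaAsex asexual proportion of the population.
#' @return named integer vector `c(asexual = , sexual = )`.
#' @export
chooseReproductionModes <- function(nFemales, alphaAsex) {
  nFemales <- as.integer(nFemales)
  if (is.na(nFemales) || nFemales < 0) stop("'nFemales' must be >= 0")
  nAsex <- stats::rbinom(1L, nFemales, alphaAsex)
  c(asexual = nAsex, sexual = nFemales - nAsex)
}

#' Gynogenetic brood
#'
#' A gynogenetic female produces exactly `b` all-female offspring copying
#' her genotype (sperm from the host species only triggers development and
#' contributes no DNA).
#'
#' @param mother state vector of the mother's genotype (length L).
#' @param b brood size.
#' @return offspring matrix in the individuals layout (all female,
#'   asexual origin).
#' @export
asexualBrood <- function(mother, b) {
  b <- as.integer(b)
  L <- length(mother)
  cbind(matrix(rep(as.integer(mother), each = b), nrow = b),
        rep(1L, b), rep(2L, b))
}

#' Mendelian segregation of one offspring genotype
#'
#' Each locus segregates independently: one allele is drawn uniformly from
#' the mother's pair and one from the father's. In the collapsed state
#' representation a parent of state `s` transmits a `1` allele with
#' probability `s / 2`.
#'
#' @param mother,father state vectors of equal length L.
#' @return an offspring state vector.
#' @export
segregate <- function(mother, father) {
  L <- length(mother)
  if (length(father) != L) stop("parent genotypes have different numbers of loci")
  fromMother <- stats::rbinom(L, 1L, as.integer(mother) / 2)
  fromFather <- stats::rbinom(L, 1L, as.integer(father) / 2)
  as.integer(fromMother + fromFather)
}

#' Sexual brood
#'
#' One father is chosen uniformly at random among the population's males
#' (with replacement across mothers); each of the `b` offspring gets an
#' independently segregated genotype and is male or female with
#' probability 1/2 each. With no conspecific males the brood is empty:
#' heterospecific sperm triggers gynogenesis but cannot fertilize.
#'
#' @param mother state vector of the mother's genotype.
#' @param males matrix of male state vectors (rows; may have 0 rows).
#' @param b brood size.
#' @return offspring matrix in the individuals layout (sexual origin),
#'   possibly with zero rows.
#' @export
sexualBrood <- function(mother, males, b) {
  L <- length(mother)
  if (is.null(dim(males))) males <- matrix(males, ncol = L)
  if (nrow(males) == 0L)
    return(matrix(integer(0), ncol = L + 2L))
  b <- as.integer(b)
  father <- males[sample.int(nrow(males), 1L), ]
  kids <- t(vapply(seq_len(b), function(i) segregate(mother, father),
                   integer(L)))
  sex <- stats::rbinom(b, 1L, 0.5) + 1L  # 1 = F, 2 = M
  cbind(kids, sex, rep(1L, b), deparse.level = 0)
}

#' Recurrent mutation on a newborn pool
#'
#' Under the default per-offspring model each newborn mutates with
#' probability `rate`; a mutating newborn has exactly one of its 2L allele
#' slots chosen uniformly and flipped (0 <-> 1). In the collapsed state
#' representation flipping one allele moves state 0 or 2 to 1, and state 1
#' to 0 or 2 with equal probability. The per-allele variant flips each of
#' the 2L slots independently with probability `rate`.
#'
#' @param pool offspring matrix in the individuals layout.
#' @param rate mutation probability.
#' @param L number of loci.
#' @param model `"per_offspring"` (default) or `"per_allele"`.
#' @return the mutated pool; attribute `mutations` counts allele flips.
#' @export
applyMutation <- function(pool, rate, L, model = c("per_offspring", "per_allele")) {
  model <- match.arg(model)
  n <- nrow(pool)
  if (n == 0L || rate == 0) return(structure(pool, mutations = 0L))
  nFlips <- if (model == "per_offspring") stats::rbinom(1L, n, rate)
            else stats::rbinom(1L, n * 2L * L, rate)
  if (nFlips > 0L) {
    who <- if (model == "per_offspring") sample.int(n, nFlips)
           else sample.int(n, nFlips, replace = TRUE)
    at <- sample.int(L, nFlips, replace = TRUE)
    for (k in seq_len(nFlips)) {
      s <- pool[who[k], at[k]]
      pool[who[k], at[k]] <- if (s == 1L) sample(c(0L, 2L), 1L) else 1L
    }
  }
  structure(pool, mutations = as.integer(nFlips))
}

#' One reproductive season of a population (reference engine)
#'
#' Every female reproduces once: her mode is drawn per
#' [chooseReproductionModes()], gynogenetic females produce clonal
#' all-female broods, sexual females require a conspecific male (the two
#' populations never interbreed). Mutation is applied to the merged pool.
#'
#' @param inds individuals matrix of the population.
#' @param alphaAsex asexual proportion.
#' @param b brood size.
#' @param mutationRate per-offspring mutation probability.
#' @param L number of loci.
#' @param broodModel `"fixed"` or `"poisson"`.
#' @param mutationModel `"per_offspring"` or `"per_allele"`.
#' @return offspring matrix; attribute `mutations` counts allele flips.
#' @export
reproducePopulation <- function(inds, alphaAsex, b, mutationRate, L,
                                broodModel = "fixed",
                                mutationModel = "per_offspring") {
  sexCol <- L + 1L
  females <- inds[inds[, sexCol] == 1L, seq_len(L), drop = FALSE]
  males <- inds[inds[, sexCol] == 2L, seq_len(L), drop = FALSE]
  nF <- nrow(females)
  pool <- matrix(integer(0), ncol = L + 2L)
  if (nF > 0L) {
    asexMode <- stats::rbinom(nF, 1L, alphaAsex) == 1L
    broods <- vector("list", nF)
    for (i in seq_len(nF)) {
      bi <- if (broodModel == "poisson") stats::rpois(1L, b) else as.integer(b)
      broods[[i]] <- if (bi == 0L) matrix(integer(0), ncol = L + 2L)
        else if (asexMode[i]) asexualBrood(females[i, ], bi)
        else sexualBrood(females[i, ], males, bi)
    }
    pool <- do.call(rbind, broods)
  }
  applyMutation(pool, mutationRate, L, mutationModel)
}
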