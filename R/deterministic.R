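#' @include experiments.R
NULL

#' Class-switching rates of the two-class model
#'
#' The deterministic companion model tracks only fit and unfit abundances;
#' recombination is summarized by two switching rates set a priori from
#' the number of loci: `delta_fu = 0.25 * (1 - 1/L)` is the approximate
#' fraction of unfit offspring produced by fit parents and
#' `delta_uf = 0.02 * (1 + 0.28/L)` the approximate fraction of fit
#' offspring produced by unfit parents.
#'
#' @param L number of loci (>= 1).
#' @return a probability.
#' @export
#' @examples
#' deltaFU(3)  # 1/6
#' deltaUF(3)  # 0.02187
deltaFU <- function(L) {
  if (any(L < 1)) stop("'L' must be >= 1")
  0.25 * (1 - 1 / L)
}

#' @rdname deltaFU
#' @export
deltaUF <- function(L) {
  if (any(L < 1)) stop("'L' must be >= 1")
  0.02 * (1 + 0.28 / L)
}

#' Average carrying capacities of fit and unfit genotypes
#'
#' `Kbar_f = Fbar_f * K0` and `Kbar_u = Fbar_u * K0`, where `Fbar_f` and
#' `Fbar_u` are the average Gaussian fitness of the fit and unfit genotype
#' classes in the current environment (unweighted means over classes by
#' default; `weighted = TRUE` weights each class by its multiplicity among
#' ordered genotypes, 2^heterozygous loci).
#'
#' @inheritParams classFitnessTable
#' @param K0 maximum carrying capacity.
#' @param weighted weight classes by ordered-genotype multiplicity.
#' @return named numeric vector `c(Kbar_f = , Kbar_u = )`.
#' @export
averageCarryingCapacities <- function(env, params = fitnessParams(),
                                      sigma = params@sigma, K0 = 30000,
                                      weighted = FALSE,
                                      L = length(.resVec(env))) {
  tab <- classFitnessTable(env, params, sigma, L)
  if (!any(tab$fit)) stop("no fit genotype class under this threshold")
  w <- if (weighted) 2^rowSums(enumerateGenotypeClasses(L) == 1L) else
    rep(1, nrow(tab))
  avg <- function(keep) sum(tab$F[keep] * w[keep]) / sum(w[keep])
  c(Kbar_f = avg(tab$fit) * K0,
    Kbar_u = if (all(tab$fit)) NA_real_ else avg(!tab$fit) * K0)
}

#' Parameters of the deterministic two-class recursion
#'
#' Bundles everything [deterministicStep()] needs. The female fraction
#' `phi` comes from [initialSexFractions()] and is held constant (the
#' deterministic model has no sex-count dynamics); the effective selection
#' strength and the average carrying capacities are derived from the
#' population's reproductive mix.
#'
#' @param L number of loci.
#' @param s per-locus decrement.
#' @param sigma selection strength.
#' @param alphaAsex asexual proportion.
#' @param mu asexual selection-increase factor.
#' @param b offspring per female.
#' @param K0 maximum carrying capacity.
#' @param env environment (default all ones).
#' @param delta dominance factor.
#' @param fitThreshold fit cutoff.
#' @param weighted multiplicity-weighted capacity averages.
#' @return a named list of recursion parameters.
#' @export
#' @examples
#' detParams(L = 3, sigma = 0.5, alphaAsex = 0.5)
detParams <- function(L = 3, s = defaultDecrement(L), sigma = 0.7,
                      alphaAsex = 0, mu = 0.2, b = 10, K0 = 30000,
                      env = rep(1L, L), delta = 0.5, fitThreshold = 0.8,
                      weighted = FALSE) {
  fp <- fitnessParams(L = L, s = s, delta = delta, sigma = sigma, mu = mu,
                      fitThreshold = fitThreshold)
  sigmaP <- effectiveSigma(sigma, alphaAsex, mu)
  Kbar <- averageCarryingCapacities(env, fp, sigmaP, K0, weighted, L)
  fr <- initialSexFractions(alphaAsex)
  list(b = b, phi = fr[["female"]], alphaAsex = alphaAsex,
       alphaSex = 1 - alphaAsex, deltaFU = deltaFU(L), deltaUF = deltaUF(L),
       KbarF = Kbar[["Kbar_f"]], KbarU = Kbar[["Kbar_u"]], K0 = K0,
       sigmaP = sigmaP)
}

#' One step of the deterministic fit/unfit recursion
#'
#' Non-overlapping-generations approximation of the stochastic engine.
#' Each class produces `b * phi` offspring per capita; clonal offspring
#' (`alpha_asex` share) retain their class, sexual offspring switch class
#' at rates `delta_fu` (fit to unfit, damped by `1 - N_f/N` because a
#' fully fit population carries almost no unfit alleles) and `delta_uf`
#' (unfit to fit). Beverton-Holt survival divides each class by
#' `1 + (b - 1) * phi * N / Kbar`.
#'
#' @param Nf,Nu fit and unfit abundances (non-negative reals).
#' @param p parameter list from [detParams()].
#' @return named numeric vector `c(Nf = , Nu = )`.
#' @export
deterministicStep <- function(Nf, Nu, p) {
  N <- Nf + Nu
  if (N <= 0) return(c(Nf = 0, Nu = 0))
  damp <- 1 - Nf / N
  bphi <- p$b * p$phi
  numF <- p$alphaAsex * bphi * Nf +
    p$alphaSex * bphi * Nf * (1 - p$deltaFU * damp) +
    p$alphaSex * bphi * Nu * p$deltaUF
  numU <- p$alphaAsex * bphi * Nu +
    p$alphaSex * bphi * Nu * (1 - p$deltaUF) +
    p$alphaSex * bphi * Nf * p$deltaFU * damp
  c(Nf = numF / (1 + (p$b - 1) * p$phi * N / p$KbarF),
    Nu = numU / (1 + (p$b - 1) * p$phi * N / p$KbarU))
}

#' Iterate the deterministic recursion
#'
#' @param initN initial total abundance.
#' @param params list from [detParams()].
#' @param generations number of steps.
#' @param initFitFraction share of the initial abundance that is fit
#'   (default 0: all-unfit start, as in the adaptation experiments).
#' @return data.frame with columns `generation`, `N_f`, `N_u`, `N`.
#' @export
#' @examples
#' dt <- deterministicTrajectory(28000, detParams(sigma = 0.5, alphaAsex = 0.5), 70)
deterministicTrajectory <- function(initN, params, generations,
                                    initFitFraction = 0) {
  stopifnot(generations >= 1, initN >= 0)
  Nf <- initN * initFitFraction
  Nu <- initN - Nf
  out <- matrix(0, nrow = generations + 1L, ncol = 2L)
  out[1L, ] <- c(Nf, Nu)
  for (g in seq_len(generations)) {
    st <- deterministicStep(out[g, 1L], out[g, 2L], params)
    out[g + 1L, ] <- st
  }
  data.frame(generation = 0:generations, N_f = out[, 1L], N_u = out[, 2L],
             N = out[, 1L] + out[, 2L])
}
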