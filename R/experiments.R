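#' @include individuals-engine.R
NULL

#' Derive a reproducible per-run seed
#'
#' Folds a master seed and an arbitrary sequence of labels (experiment
#' name, cell indices, replicate index, ...) into a stable 31-bit seed, so
#' that grids are reproducible and adding replicates never perturbs
#' existing runs.
#'
#' @param master integer master seed.
#' @param ... labels coerced to character and hashed.
#' @return a single integer seed in [1, 2^31 - 2].
#' @export
#' @examples deriveSeed(1, "grid", 3, 5, 2)
deriveSeed <- function(master, ...) {
  key <- paste(c(master, ...), collapse = "\r")
  h <- as.double(master %% 2147483647L)
  for (code in utf8ToInt(key))
    h <- (h * 31 + code) %% 2147483647
  as.integer(h %% 2147483645) + 1L
}

#' Round-robin competition tournament over asexuality percentages
#'
#' Runs the full grid of ordered pairs of asexual-reproduction proportions
#' for the two competing populations, with `reps` seeded replicates per
#' ordered pair, and scores every cell. The cell for (alpha1, alpha2)
#' aggregates the runs of both orderings (roles swapped), so off-diagonal
#' cells rest on `2 * reps` replicates. The score
#' `(n_pop1_only + 0.5 * n_both) / n` formalizes the grey scale of a
#' survival matrix: 1 means population 1 always prevailed.
#'
#' @param alphas asexual proportions on the grid (default 0, 0.1, ..., 1).
#' @param reps replicates per ordered pair (default 5).
#' @param sigma selection strength.
#' @param stabilityPeriod environment stability period.
#' @param generations run length (default 500).
#' @param L,s loci count and per-locus decrement.
#' @param seed master seed for [deriveSeed()].
#' @param ... further arguments passed to [simConfig()].
#' @return a data.frame with one row per (alpha1, alpha2) cell: outcome
#'   counts and `score`.
#' @export
competitionGrid <- function(alphas = seq(0, 1, by = 0.1), reps = 5,
                            sigma = 0.7, stabilityPeriod = 50,
                            generations = 500, L = 3,
                            s = defaultDecrement(L), seed = 1, ...) {
  nA <- length(alphas)
  labs <- c("pop1_only", "both_survive", "pop2_only", "both_extinct")
  tally <- array(0L, dim = c(nA, nA, 4L), dimnames = list(NULL, NULL, labs))
  for (i in seq_len(nA)) for (j in seq_len(nA)) for (r in seq_len(reps)) {
    cfg <- simConfig(L = L, s = s, sigma = sigma,
                     alphaAsex1 = alphas[i], alphaAsex2 = alphas[j],
                     stabilityPeriod = stabilityPeriod,
                     generations = generations,
                     seed = deriveSeed(seed, "grid", i, j, r), ...)
    out <- outcome(runSimulation(cfg))
    tally[i, j, out] <- tally[i, j, out] + 1L
  }
  cells <- expand.grid(i = seq_len(nA), j = seq_len(nA))
  res <- do.call(rbind, lapply(seq_len(nrow(cells)), function(k) {
    i <- cells$i[k]; j <- cells$j[k]
    # aggregate both orderings: runs (j, i) contribute with roles swapped
    n1 <- tally[i, j, "pop1_only"]
    n2 <- tally[i, j, "pop2_only"]
    nb <- tally[i, j, "both_survive"]
    ne <- tally[i, j, "both_extinct"]
    if (i != j) {
      n1 <- n1 + tally[j, i, "pop2_only"]
      n2 <- n2 + tally[j, i, "pop1_only"]
      nb <- nb + tally[j, i, "both_survive"]
      ne <- ne + tally[j, i, "both_extinct"]
    }
    n <- n1 + n2 + nb + ne
    data.frame(alpha1 = alphas[i], alpha2 = alphas[j], reps = n,
               n_pop1_only = n1, n_both = nb, n_pop2_only = n2,
               n_both_extinct = ne, score = (n1 + 0.5 * nb) / n)
  }))
  rownames(res) <- NULL
  class(res) <- c("gynosimGrid", class(res))
  res
}

#' Tournament win totals per asexuality percentage
#'
#' Sums, for each grid value of alpha, the wins collected against every
#' opponent (a win is surviving while the opponent goes extinct; both
#' surviving counts one half).
#'
#' @param grid a grid from [competitionGrid()].
#' @return data.frame with columns `alpha`, `wins`, `share` (wins over
#'   contested replicates), sorted by `alpha`.
#' @export
winningScores <- function(grid) {
  off <- grid[grid$alpha1 != grid$alpha2, , drop = FALSE]
  agg <- stats::aggregate(cbind(wins = n_pop1_only + 0.5 * n_both,
                                total = reps) ~ alpha1, data = off, FUN = sum)
  data.frame(alpha = agg$alpha1, wins = agg$wins,
             share = agg$wins / agg$total)
}

#' Modal winning asexuality percentage of a tournament
#'
#' @param grid a grid from [competitionGrid()].
#' @return the alpha (as a percentage, 0-100) with the most tournament
#'   wins.
#' @export
modalWinningAlpha <- function(grid) {
  sc <- winningScores(grid)
  100 * sc$alpha[which.max(sc$wins)]
}

#' Adaptation experiment: diffusion of fit genotypes
#'
#' A single population (the second population is empty) of `size`
#' all-heterozygous individuals - hence without any fit genotype - evolves
#' in a fixed environment (the stability period is pushed beyond the
#' horizon so no fluctuation occurs). Records the census and fit-genotype
#' trajectories and the two adaptation phases: the generation phase (first
#' appearance of a fit genotype, driven by recombination) and the
#' amplification phase (spread to 100% fit, driven by clonal
#' multiplication).
#'
#' @param alphaAsex asexual proportion.
#' @param sigma selection strength.
#' @param generations run length (default 100).
#' @param size initial census (default 28000).
#' @param L,s loci count and decrement.
#' @param seed integer seed.
#' @param ... passed to [simConfig()].
#' @return a list: `trajectory` (population-1 rows), `timeToFirstFit`,
#'   `timeToAllFit` (NA when censored), `amplificationTime` (their
#'   difference), `outcome`.
#' @export
adaptationExperiment <- function(alphaAsex, sigma = 0.7, generations = 100,
                                 size = 28000, L = 3, s = defaultDecrement(L),
                                 seed = NA_integer_, ...) {
  cfg <- simConfig(L = L, s = s, sigma = sigma,
                   alphaAsex1 = alphaAsex, alphaAsex2 = 0,
                   initialSize1 = size, initialSize2 = 0,
                   stabilityPeriod = generations + 1L,
                   generations = generations, seed = seed, ...)
  res <- runSimulation(cfg)
  tr <- trajectory(res)
  tr <- tr[tr$pop == 1L, , drop = FALSE]
  census <- tr$census_F + tr$census_M
  firstFit <- tr$generation[tr$fit_count > 0][1]
  allFit <- tr$generation[census > 0 & tr$fit_count == census &
                            tr$generation > 0][1]
  list(trajectory = tr,
       timeToFirstFit = firstFit,
       timeToAllFit = allFit,
       amplificationTime = allFit - firstFit,
       outcome = outcome(res))
}

#' Sweep of asexuality percentages with deterministic overlay
#'
#' Runs [adaptationExperiment()] for each (alpha, sigma) combination and
#' the matching two-class deterministic recursion, returning the
#' fit-genotype growth curves in long format for comparison.
#'
#' @param alphas asexual proportions (default 0, 0.5, 0.8).
#' @param sigmas selection strengths (default 0.7 and 0.5).
#' @param generations horizon (default 70, to show the initial growth).
#' @param size initial census.
#' @param L number of loci.
#' @param seed master seed.
#' @param ... passed to [adaptationExperiment()].
#' @return data.frame with columns `model` ("stochastic"/"deterministic"),
#'   `sigma`, `alpha`, `generation`, `census`, `fit_count`.
#' @export
asexualitySweep <- function(alphas = c(0, 0.5, 0.8), sigmas = c(0.7, 0.5),
                            generations = 70, size = 28000, L = 3,
                            seed = 1, ...) {
  out <- list()
  for (sg in sigmas) for (al in alphas) {
    ad <- adaptationExperiment(al, sigma = sg, generations = generations,
                               size = size, L = L,
                               seed = deriveSeed(seed, "sweep", sg, al), ...)
    tr <- ad$trajectory
    out[[length(out) + 1L]] <- data.frame(
      model = "stochastic", sigma = sg, alpha = al,
      generation = tr$generation,
      census = tr$census_F + tr$census_M, fit_count = tr$fit_count)
    dp <- detParams(L = L, sigma = sg, alphaAsex = al)
    dt <- deterministicTrajectory(initN = size, params = dp,
                                  generations = generations)
    out[[length(out) + 1L]] <- data.frame(
      model = "deterministic", sigma = sg, alpha = al,
      generation = dt$generation, census = dt$N, fit_count = dt$N_f)
  }
  do.call(rbind, out)
}

#' Census trajectories under different stability periods
#'
#' Couples two populations (default 30% vs 50% asexual reproduction,
#' strong selection) under each environment stability period and records
#' the census trajectories, optionally over several replicates.
#'
#' @param alphaPair the two asexual proportions (default c(0.3, 0.5)).
#' @param sigma selection strength (default 0.5).
#' @param periods stability periods (default 50, 20, 10).
#' @param generations horizon (default 70).
#' @param reps replicates per period.
#' @param seed master seed.
#' @param ... passed to [simConfig()].
#' @return data.frame with columns `period`, `rep`, `generation`, `pop`,
#'   `alpha`, `census`, `fit_count`, `env_epoch`.
#' @export
stabilityComparison <- function(alphaPair = c(0.3, 0.5), sigma = 0.5,
                                periods = c(50, 20, 10), generations = 70,
                                reps = 1, seed = 1, ...) {
  out <- list()
  for (p in periods) for (r in seq_len(reps)) {
    cfg <- simConfig(sigma = sigma, alphaAsex1 = alphaPair[1],
                     alphaAsex2 = alphaPair[2], stabilityPeriod = p,
                     generations = generations,
                     seed = deriveSeed(seed, "stability", p, r), ...)
    tr <- trajectory(runSimulation(cfg))
    out[[length(out) + 1L]] <- data.frame(
      period = p, rep = r, generation = tr$generation, pop = tr$pop,
      alpha = alphaPair[tr$pop], census = tr$census_F + tr$census_M,
      fit_count = tr$fit_count, env_epoch = tr$env_epoch)
  }
  do.call(rbind, out)
}
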