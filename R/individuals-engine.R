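#' @include engine.R
NULL

## Per-individual reference engine. Statistically equivalent to the count
## engine by construction; kept in plain R and used at small census sizes
## to cross-check the production path.

## counts array (nC x 2 x 2) -> individuals matrix (rows: L states, sex, origin)
.countsToInds <- function(counts, L) {
  cells <- which(counts > 0, arr.ind = TRUE)
  if (nrow(cells) == 0L) return(matrix(integer(0), ncol = L + 2L))
  classes <- enumerateGenotypeClasses(L)
  reps <- rep(seq_len(nrow(cells)), counts[cells])
  cbind(classes[cells[reps, 1L], , drop = FALSE],
        cells[reps, 2L], cells[reps, 3L], deparse.level = 0)
}

## individuals matrix -> counts array
.indsToCounts <- function(inds, L) {
  nC <- 3L^L
  arr <- array(0L, dim = c(nC, 2L, 2L),
               dimnames = list(NULL, c("F", "M"), c("sexual", "asexual")))
  if (nrow(inds) > 0L) {
    cls <- genotypeClassIndex(inds[, seq_len(L), drop = FALSE])
    flat <- cls + nC * (inds[, L + 1L] - 1L) + 2L * nC * (inds[, L + 2L] - 1L)
    arr[] <- tabulate(flat, nbins = 4L * nC)
  }
  arr
}

## One generation, per-individual; mirrors cpp_step_generation's contract.
.stepIndividuals <- function(c1, c2, env, config) {
  L <- config@L
  d <- config@demo
  Nadults <- sum(c1) + sum(c2)
  adultF <- sum(c1[, 1L, ]) + sum(c2[, 1L, ])
  phi <- if (Nadults > 0) adultF / Nadults else 0
  fits <- list(.fitMatrix(env, config, config@alphaAsex1),
               .fitMatrix(env, config, config@alphaAsex2))
  alphas <- c(config@alphaAsex1, config@alphaAsex2)

  one <- function(counts, alpha, fit) {
    inds <- .countsToInds(counts, L)
    pool <- reproducePopulation(inds, alpha, d@b, d@mutationRate, L,
                                config@broodModel, config@mutationModel)
    nMut <- attr(pool, "mutations")
    all <- rbind(inds, pool)
    if (nrow(all) > 0L) {
      cls <- genotypeClassIndex(all[, seq_len(L), drop = FALSE])
      K <- fit[cbind(cls, all[, L + 2L])] * d@K0
      p <- ifelse(K > 0, 1 / (1 + d@b * phi * Nadults / K), 0)
      all <- all[stats::runif(nrow(all)) < p, , drop = FALSE]
    }
    list(counts = .indsToCounts(all, L), mut = nMut, off = nrow(pool))
  }
  r1 <- one(c1, alphas[1L], fits[[1L]])
  r2 <- one(c2, alphas[2L], fits[[2L]])
  list(counts1 = r1$counts, counts2 = r2$counts,
       mutations = r1$mut + r2$mut,
       offspring1 = r1$off, offspring2 = r2$off)
}
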