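---
title: "Modelling mixed sexual/gynogenetic population dynamics in fluctuating environments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling mixed sexual/gynogenetic population dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gynosim)
```

## The biological question

Some fish — the gibel carp *Carassius gibelio* is the flagship case — carry
both reproductive modes at once: part of the females reproduce sexually,
part by gynogenesis, a sperm-dependent parthenogenesis in which sperm from a
host species triggers egg development but contributes no DNA, so offspring
are all-female maternal clones. Why would a *mixture* of the two modes be
advantageous? `gynosim` implements a forward-time model of two sympatric
populations with different asexuality percentages competing for the same
resources in a periodically changing environment, to ask which mixture wins
under which regime of selection strength and environmental stability.

## The model

**Genotypes and environment.** Individuals are diploid with `L` fitness
loci, each locus an unordered pair of 0/1 alleles; the environment is a
vector of `L` binary resources. Per locus the match score is

* 1 if both alleles equal the resource,
* `1 - delta * s` if heterozygous (`delta = 0.5`: both alleles contribute
  equally),
* `1 - s` if homozygous for the wrong allele.

The *loci fitness* `lf` is the product over loci, and the genotype fitness
is the Gaussian stabilizing-selection map

$$\mathcal{F}(g, env) = \exp\left(-\frac{(1 - lf)^2}{2\sigma^2}\right),$$

where smaller `sigma` means stronger ecological selection. A genotype is
*fit* when `lf >= 0.8` (the comparison is inclusive).

**Reproduction.** Once per generation every female reproduces: with
probability `alpha_asex` she clones herself into `b` all-female offspring
(gynogenesis; heterospecific sperm is assumed non-limiting), otherwise a
conspecific father is drawn uniformly among the males and each of the `b`
offspring receives an independently segregated genotype and a fair coin for
sex. The two populations never interbreed.

**Viability selection.** After newborns join their population, every
individual (newborn or adult — generations overlap) survives with the
modified Beverton–Holt probability

$$p_{surv} = \frac{1}{1 + b\,\phi\,N / K(g, env)}, \qquad
  K(g, env) = \mathcal{F}(g, env)\,K_0,$$

with `N` and `phi` the census and female fraction of the *combined adult*
(pre-reproduction) population of both competitors — this is what couples
them — and `K_0 = 30{,}000` the maximum carrying capacity. With these
conventions a monomorphic fully-fit population equilibrates at `K_0`
(the recursion `N' = N (1 + b\phi) / (1 + b\phi N / K_0)` has fixed point
`K_0`), which matches the observed rapid approach of the combined census to
roughly 30,000.

**Removing the twofold advantage.** An all-female clonal lineage would
otherwise trivially outgrow any sexual one. Coexistence is enforced by
strengthening selection in proportion to clonality:
`sigma_p = sigma * alpha_sex + mu * sigma * alpha_asex` with `mu = 0.2`,
i.e. fully asexual production faces fivefold selection. By default
`sigma_p` applies population-wide, exactly as this mixing formula states; a
per-origin alternative (`sigmaMode = "origin"`), in which only asexually
*produced* individuals face `mu * sigma`, is available because the verbal
description of the mechanism ("stronger selection on asexually produced
offspring") suggests it; the two coincide at the extremes
`alpha_asex` of 0 and 1.

**Fluctuation.** Every `pi` generations (at the *end* of generations `pi`,
`2 pi`, ...) the environment is complemented bit-wise. The model is exactly
symmetric under jointly flipping all genotype alleles and all resources, so
the choice of the all-ones initial environment is without loss of
generality (this symmetry is tested exhaustively at `L = 3`).

**Initial conditions.** Each population starts all-heterozygous at every
locus (intermediate fitness, zero fit genotypes) with sex fractions
`alpha_asex + alpha_sex/2` females and `alpha_sex/2` males; males are
rounded down, the remainder going to females. Equivalently, a population
with 20% males corresponds to 40% sexual reproduction.

## Parameters and defaults

| Parameter | Meaning | Default |
|---|---|---|
| `L` | number of selected loci | 3 (5 and 7 supported) |
| `s` | per-locus fitness decrement | 0.2 at `L = 3`, 0.125 at `L = 5`, 0.09 at `L = 7` (keeps `lf` in roughly [0.5, 1]) |
| `delta` | dominance factor | 0.5 |
| `sigma` | selection strength | 0.7 (weak) or 0.5 (strong) |
| `mu` | asexual selection increase | 0.2 |
| `b` | offspring per female reaching year 1 | 10 |
| `K0` | maximum carrying capacity | 30,000 |
| mutation rate | per offspring | 1e-5 (about 3 allele flips/generation at capacity) |
| `pi` | stability period | 50, 20 or 10 generations |
| initial sizes | per population | 9,000 |
| run length | generations | 500 |

## The two engines

The production engine tracks *census counts over the `3^L` unordered
genotype classes* (by sex and reproductive origin) rather than individual
fish: per-locus fitness depends only on the unordered allele pair, so the
`2^{2L}` ordered genotypes collapse to `3^L` classes without loss. One
generation is then an exact cascade of binomial/multinomial draws (mode
choice per female, father class, offspring class from the per-locus
transmission probabilities, offspring sex, mutation flips, survival
thinning), implemented in C++ on the R RNG stream. A deliberately naive
per-individual engine (`engineMode = "individuals"`, pure R) implements the
same season one fish at a time; the test suite checks the two produce
statistically indistinguishable census and fit-count distributions at small
census sizes. Fixed seed and fixed engine mode give bit-reproducible runs.

## Numerical and design choices

* **Where density is measured.** `N` and `phi` in `p_surv` are taken from
  the combined adult census before reproduction, while selection is applied
  to adults and newborns alike. Evaluating density after merging newborns
  would shift the equilibrium census down to about `K_0 / (1 + b\phi)`,
  contradicting the observed ~30,000 plateau.
* **Zero males.** A sexually-assigned female with no conspecific males
  produces nothing that season — heterospecific sperm triggers gynogenesis
  but cannot fertilize. No silent fallback to cloning.
* **Mutation.** Interpreted per offspring: each newborn flips one uniformly
  chosen allele slot with probability 1e-5, giving the expected ~3 flips
  per generation at 300,000 newborns. A per-allele variant
  (`mutationModel = "per_allele"`) is available. In the collapsed-state
  representation a heterozygous locus flips to either homozygote with equal
  probability.
* **Brood size.** Exactly `b` per female (it is defined as the number
  *reaching* the free-swimming stage); `broodModel = "poisson"` offers
  Poisson broods.
* **Fathers** are drawn uniformly with replacement (no mate choice); all of
  one mother's brood shares one father.
* **Seeds.** Experiment harnesses derive one seed per (experiment, cell,
  replicate) from the master seed with a stable string hash, so enlarging a
  grid never perturbs existing runs.
* **Extinction** means census at or below 0 by default (configurable); runs
  end early only when both populations are extinct.

## The deterministic companion model

Collapsing the genotype space to fit/unfit abundances `(N_f, N_u)` gives a
non-overlapping-generations recursion: per-capita production `b * phi`,
clonal offspring retain their class, sexual offspring switch fit→unfit at
rate `delta_fu = 0.25 (1 - 1/L)` damped by `(1 - N_f/N)` (an almost-fit
population carries almost no unfit alleles) and unfit→fit at
`delta_uf = 0.02 (1 + 0.28/L)`, and each class is divided by
`1 + (b-1) phi N / \bar K` with `\bar K_f, \bar K_u` the average
(unweighted over classes; multiplicity weighting optional) carrying
capacities of fit and unfit classes. The printed source for these
recursions is typographically corrupted; the implementation follows the
unique reading consistent with the surrounding description, and its all-fit
limit reproduces the closed-form fixed point
`N^* = \bar K_f (b\phi - 1) / ((b-1)\phi)` (tested numerically). The
deterministic curves are not expected to overlay the stochastic ones — they
are used for *trend* comparisons across `alpha` and `sigma`, which the test
suite checks by rank agreement of times-to-majority-fit.

## What the experiments emulate — and what they do not

All inputs here are synthetic by design: the model is the study object, and
the experiment harnesses generate their own populations under the standard
conditions above (9,000 + 9,000 all-heterozygous founders for competition;
a single 28,000-founder population without any fit genotype for the
adaptation experiments, run without fluctuation). Tournament grids run all
11×11 ordered pairs of asexuality percentages with 3 seeded replicates per
ordered pair (so 6 per unordered pair) over 500 generations — enough to
place the modal winning percentage reliably in its band, as the
near-monotone win profiles show, while keeping a full grid to a few
minutes on one core. Passing tests therefore demonstrate internal
consistency of the model and reproducibility of its qualitative claims
(optimal asexuality increasing with stability period, decreasing with
selection strength), not quantitative predictions for real *C. gibelio*
populations: real fish have triploid gynogens, sperm limitation, mate
choice, age structure, epistasis and continuous environments, all
deliberately outside this model.

## Known limitations

* No epistasis; loci contribute independently and multiplicatively.
* Two alleles per locus, binary resources, complete complementation at each
  fluctuation (no partial change).
* The per-origin selection switch tracks origin through an extra census
  dimension but founders must be attributed proportionally, which is a
  modelling convention.
* At `L = 7` the count engine is exact but the per-pair transmission
  computation grows with `3^L`; grids at `L = 5, 7` are supported but slow,
  matching the slower dynamics they exhibit.

## A worked call

```{r example, eval = FALSE}
cfg <- simConfig(alphaAsex1 = 0.3, alphaAsex2 = 0.5, sigma = 0.5,
                 stabilityPeriod = 50, generations = 500, seed = 1)
res <- runSimulation(cfg)
outcome(res)            # which mixture survived
head(trajectory(res))   # per-generation censuses, fit counts, mean lf
```
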