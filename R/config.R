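#' @include deterministic.R
NULL

## Internal: SimConfig -> plain named list (for manifests and JSON echoes)
.configAsList <- function(config) {
  fp <- config@fitness; d <- config@demo
  list(L = config@L, s = fp@s, delta = fp@delta, sigma = fp@sigma,
       mu = fp@mu, fitThreshold = fp@fitThreshold,
       b = d@b, K0 = d@K0, mutationRate = d@mutationRate,
       alphaAsex1 = config@alphaAsex1, alphaAsex2 = config@alphaAsex2,
       initialSize1 = config@initialSize1,
       initialSize2 = config@initialSize2,
       stabilityPeriod = config@stabilityPeriod,
       generations = config@generations,
       initialEnv = config@initialEnv,
       seed = config@seed, engineMode = config@engineMode,
       sigmaMode = config@sigmaMode, broodModel = config@broodModel,
       mutationModel = config@mutationModel,
       extinctionThreshold = config@extinctionThreshold)
}

#' Load a simulation configuration from a YAML file
#'
#' The file may set any argument of [simConfig()] by name; unset keys fall
#' back to the standard defaults (an empty file yields the default study
#' conditions). Unknown keys raise an error naming the field. When `L` is
#' given without `s`, the per-locus decrement defaults via
#' [defaultDecrement()]. Selection strengths other than the canonical
#' weak/strong pair (0.7 / 0.5) are accepted with a warning.
#'
#' @param path path to a YAML file (possibly empty).
#' @return a validated [SimConfig-class].
#' @export
loadConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- setdiff(names(formals(simConfig)), "initialEnv")
  known <- c(known, "initialEnv")
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  if (!is.null(vals$sigma) && !vals$sigma %in% c(0.7, 0.5))
    warning("sigma = ", vals$sigma,
            " is outside the canonical weak/strong pair (0.7, 0.5)")
  do.call(simConfig, vals)
}

#' Build a run manifest
#'
#' A manifest records everything needed to bit-reproduce a run: the full
#' configuration echo, the master seed and any derived seeds, the package
#' version, a timestamp and the output paths.
#'
#' @param config a [SimConfig-class].
#' @param masterSeed the master seed.
#' @param derivedSeeds optional named vector/list of derived seeds.
#' @param outputs optional character vector of output paths.
#' @param experiment optional experiment label.
#' @return a named list.
#' @export
runManifest <- function(config, masterSeed, derivedSeeds = NULL,
                        outputs = character(), experiment = "simulate") {
  list(experiment = experiment,
       config = .configAsList(config),
       masterSeed = masterSeed,
       derivedSeeds = derivedSeeds,
       version = as.character(utils::packageVersion("gynosim")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       outputs = outputs)
}

#' Write a trajectory, grid summary or manifest
#'
#' Tabular outputs are comma-separated with a header row, no index column
#' and '.' as decimal separator; manifests and outcome records are JSON.
#'
#' @param result a [SimResult-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeTrajectory <- function(result, path) {
  utils::write.csv(trajectory(result), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname writeTrajectory
#' @param grid a data.frame from [competitionGrid()].
#' @export
writeGridSummary <- function(grid, path) {
  utils::write.csv(as.data.frame(grid), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname writeTrajectory
#' @export
writeOutcome <- function(result, path) {
  fs <- result@finalState
  rec <- list(config = .configAsList(result@config),
              seed = result@config@seed,
              label = outcome(result),
              finalCensus1 = census(fs@pop1),
              finalCensus2 = census(fs@pop2),
              generations = fs@generation)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeTrajectory
#' @param manifest a list from [runManifest()].
#' @export
writeManifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
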