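## Scenario grid runner: every intervention is paired with the baseline
## through shared replicate seeds and a shared historical snapshot, so
## scenario contrasts are paired contrasts.

## Derive a scenario config from the base config and an intervention argument
## ("baseline", a policy object, or a full ScenarioConfig).
.scenarioFrom <- function(base, name, intervention) {
  if (is(intervention, "ScenarioConfig")) {
    cfg <- intervention
    cfg@name <- name
    return(cfg)
  }
  cfg <- base
  cfg@name <- name
  if (identical(intervention, "baseline")) {
    cfg@interventionType <- "baseline"
  } else if (is(intervention, "EditPolicy")) {
    cfg@interventionType <- "rage"
    cfg@editPolicy <- intervention
  } else if (is(intervention, "CarrierPolicy")) {
    cfg@interventionType <- "carriers"
    cfg@carrierPolicy <- intervention
  } else {
    stop("intervention '", name,
         "' must be 'baseline', an EditPolicy or a CarrierPolicy")
  }
  cfg
}

.resultFiles <- function(outDir, scenario, replicate) {
  stem <- file.path(outDir, sprintf("%s_rep%03d", scenario, replicate))
  c(records = paste0(stem, ".csv"), edits = paste0(stem, "_edits.csv"))
}

## Persist one replicate result as plain CSV (records + edit log).
.storeResult <- function(result, outDir) {
  f <- .resultFiles(outDir, result@scenario, result@replicate)
  rec <- cbind(scenario = result@scenario, replicate = result@replicate,
               seed = result@seed, result@records)
  data.table::fwrite(rec, f["records"])
  data.table::fwrite(result@editLog, f["edits"])
  invisible(f)
}

## Reconstruct a replicate result from its stored CSVs.
.loadResult <- function(outDir, scenario, replicate, config) {
  f <- .resultFiles(outDir, scenario, replicate)
  rec <- as.data.frame(data.table::fread(f["records"]))
  el <- as.data.frame(data.table::fread(
    f["edits"], colClasses = c(generation = "integer", sireId = "integer",
                               locus = "integer", isTrue = "logical",
                               s = "numeric", preDosage = "integer")))
  new("SimulationResult",
      records = rec[, setdiff(names(rec), c("scenario", "replicate", "seed"))],
      editLog = el,
      distinctEdited = sort(unique(el$locus)),
      scenario = scenario, replicate = as.integer(replicate),
      seed = as.integer(rec$seed[1]), config = configAsList(config))
}

#' Run a baseline-paired scenario grid
#'
#' Runs every intervention scenario and the shared baseline over
#' `nReplicates` replicates. Within a replicate all scenarios share the
#' replicate seed and the historical snapshot, so they are identical up to
#' the end of historical breeding and scenario contrasts are paired.
#' Results can be written incrementally to `outDir` as plain CSV and the
#' grid is then resumable by replicate.
#'
#' @param base a [ScenarioConfig-class] supplying genome, architecture and
#'   plan parameters (its own intervention slots are ignored).
#' @param interventions named list of scenario definitions: `"baseline"`, an
#'   [EditPolicy-class], a [CarrierPolicy-class], or a full
#'   [ScenarioConfig-class]. A baseline scenario is added automatically if
#'   none is given.
#' @param nReplicates,masterSeed replicate management (defaults from
#'   `base`).
#' @param outDir optional directory for incremental CSV results.
#' @param resume if TRUE, stored replicates are loaded instead of
#'   recomputed; if FALSE, existing result files are an error.
#' @param verbose log per-replicate progress to stderr.
#' @return a grid store: list with `results` (per scenario, a list of
#'   [SimulationResult-class] per replicate), `configs`, `seeds`.
#' @export
runScenarioGrid <- function(base, interventions = list(),
                            nReplicates = base@nReplicates,
                            masterSeed = base@masterSeed,
                            outDir = NULL, resume = FALSE,
                            verbose = FALSE) {
  if (!any(vapply(interventions, identical, TRUE, "baseline")))
    interventions <- c(list(baseline = "baseline"), interventions)
  if (is.null(names(interventions)) || any(names(interventions) == ""))
    stop("interventions must be a named list")
  configs <- mapply(.scenarioFrom, names(interventions), interventions,
                    MoreArgs = list(base = base), SIMPLIFY = FALSE)
  seeds <- replicateSeeds(masterSeed, nReplicates)

  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    existing <- unlist(lapply(names(configs), function(sc)
      vapply(seq_len(nReplicates),
             function(r) .resultFiles(outDir, sc, r)["records"], "")))
    present <- existing[file.exists(existing)]
    if (length(present) && !resume)
      stop("partial results already present in '", outDir,
           "' (", length(present), " files); use resume = TRUE")
  }

  results <- setNames(vector("list", length(configs)), names(configs))
  for (r in seq_len(nReplicates)) {
    done <- vapply(names(configs), function(sc) {
      !is.null(outDir) &&
        all(file.exists(.resultFiles(outDir, sc, r)))
    }, TRUE)
    snap <- NULL
    if (!all(done)) {
      if (verbose)
        message(sprintf("replicate %d/%d: historical snapshot (seed %d)",
                        r, nReplicates, seeds[r]))
      snap <- runHistoricalPhase(base, seeds[r])
    }
    for (sc in names(configs)) {
      if (done[[sc]]) {
        res <- .loadResult(outDir, sc, r, configs[[sc]])
      } else {
        if (verbose) message(sprintf("replicate %d/%d: scenario %s",
                                     r, nReplicates, sc))
        res <- runFuturePhase(snap, configs[[sc]])
        res@replicate <- r
        if (!is.null(outDir)) .storeResult(res, outDir)
      }
      results[[sc]][[r]] <- res
    }
  }
  list(results = results, configs = configs, seeds = seeds)
}

#' Summarize a scenario grid against its baseline
#'
#' For each non-baseline scenario computes the fitness change versus
#' baseline, the relative change in breeding-goal gain and the mean number
#' of distinct variants edited, with standard errors over replicates.
#'
#' @param store a grid store from [runScenarioGrid()].
#' @return data.frame, one row per non-baseline scenario.
#' @export
summarizeGrid <- function(store) {
  base <- store$results$baseline
  if (is.null(base)) stop("grid store has no baseline scenario")
  others <- setdiff(names(store$results), "baseline")
  rows <- lapply(others, function(sc) {
    res <- store$results[[sc]]
    fc <- fitnessChangeVsBaseline(res, base)
    rg <- relativeGainChange(res, base)
    de <- vapply(res, countDistinctEdits, 1L)
    data.frame(scenario = sc,
               fitnessChange = fc$mean, fitnessChangeSEM = fc$sem,
               relativeGainChange = rg$mean, relativeGainChangeSEM = rg$sem,
               meanDistinctEdits = mean(de),
               nReplicates = length(res))
  })
  do.call(rbind, rows)
}

#' Write a grid summary as JSON
#'
#' Scenario-level deltas, standard errors and distinct-edit counts.
#'
#' @param store a grid store from [runScenarioGrid()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writeGridSummary <- function(store, path) {
  s <- summarizeGrid(store)
  jsonlite::write_json(s, path, dataframe = "rows", digits = NA)
  invisible(path)
}
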