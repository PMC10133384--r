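## End-to-end orchestration: clean -> per-era grid/select/fit/evaluate ->
## era comparison -> scenario projections, driven by a single config.

#' Default pipeline configuration
#'
#' Returns the full set of configuration keys with their defaults: the
#' standard 0.08333-degree cell size, 350 km buffer, era windows 1961-1980
#' and 2001-2020, correlation threshold 0.8, FDR level 0.05, trim level
#' 0.05 and a 20% test split.  `occurrences` (CSV path) and `layers` (named
#' list: era label -> directory or named .asc paths) select the inputs;
#' when `occurrences` is NULL the pipeline simulates the bundled synthetic
#' study first.  `scenarios` (named list: scenario id -> directory or .asc
#' paths) enables projections.
#'
#' @return named list of defaults
#' @export
defaultConfig <- function() list(
  out_dir = "favshift_out",
  occurrences = NULL,
  layers = NULL,
  scenarios = NULL,
  cell_size = 0.08333,
  buffer_km = 350,
  eras = list(era1 = c(1961L, 1980L), era2 = c(2001L, 2020L)),
  lon_min = -Inf, lat_min = -Inf, allowed_countries = NULL,
  cor_threshold = 0.8, fdr_q = 0.05, trim_alpha = 0.05,
  test_frac = 0.2, seed = 1L)

#' Read a pipeline configuration file
#'
#' YAML or JSON; keys missing from the file take their [defaultConfig()]
#' values.
#'
#' @param path config file (.yaml/.yml/.json)
#' @return config list
#' @export
readPipelineConfig <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  utils::modifyList(defaultConfig(), cfg)
}

validateConfig <- function(config) {
  cfg <- utils::modifyList(defaultConfig(), as.list(config))
  need <- c("out_dir", "cell_size", "buffer_km", "eras", "cor_threshold",
            "fdr_q", "trim_alpha", "test_frac", "seed")
  miss <- need[vapply(need, function(k) is.null(cfg[[k]]), logical(1))]
  if (length(miss)) stop("missing config key(s): ", paste(miss, collapse = ", "))
  if (!(cfg$test_frac > 0 && cfg$test_frac < 1))
    stop("test_frac must lie strictly between 0 and 1")
  if (cfg$cor_threshold <= 0 || cfg$cor_threshold > 1)
    stop("cor_threshold must lie in (0, 1]")
  if (cfg$fdr_q <= 0 || cfg$fdr_q >= 1 || cfg$trim_alpha <= 0 || cfg$trim_alpha >= 1)
    stop("fdr_q and trim_alpha must lie in (0, 1)")
  if (cfg$buffer_km <= 0) stop("buffer_km must be positive")
  if (length(cfg$eras) < 1L) stop("at least one era window required")
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

configHash <- function(cfg) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(cfg[order(names(cfg))], tf, auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  unname(tools::md5sum(tf))
}

writeArtifact <- function(x, path, meta) {
  jsonlite::write_json(c(meta, x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", force = TRUE)
  invisible(path)
}

# write the two-era synthetic study (occurrence CSV, per-era .asc layers,
# scenario layer stacks, ground-truth JSON) under dir
simulateStudy <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  grid <- gridDefinition(west = -82, north = 47, cellSize = cfg$cell_size,
                         nRows = 60L, nCols = 60L)
  env1 <- generateEnvStack(grid, defaultLayerSpecs(), seed = cfg$seed)
  # the later era is the same climate warmed and translated northward
  env2 <- shiftClimate(env1, deltas = c(BIO1 = 0.8), translateCells = 2L)
  eras <- cfg$eras
  windows <- lapply(seq_along(eras), function(i) as.integer(eras[[i]]))
  sim1 <- simulateVirtualSpecies(env1, defaultSpeciesSpec(
    seed = cfg$seed + 101L, yearWindow = windows[[1]]))
  sim2 <- simulateVirtualSpecies(env2, defaultSpeciesSpec(
    seed = cfg$seed + 102L, yearWindow = windows[[min(2, length(windows))]]))
  occ <- rbind(sim1$occ, sim2$occ)
  occCsv <- file.path(dir, "occurrences.csv")
  gbif <- data.frame(gbifID = paste0(rep(c("a", "b"), c(nrow(sim1$occ), nrow(sim2$occ))),
                                     occ$recordId),
                     decimalLongitude = occ$lon, decimalLatitude = occ$lat,
                     year = occ$year, countryCode = occ$country,
                     occurrenceStatus = "PRESENT")
  write.csv(gbif, occCsv, row.names = FALSE, na = "")
  layerDirs <- list()
  for (i in seq_along(eras)) {
    d <- file.path(dir, "layers", names(eras)[i])
    writeSurfaces(if (i == 1L) env1 else env2, d)
    layerDirs[[names(eras)[i]]] <- d
  }
  scen <- list(
    WARM_MILD = shiftClimate(env2, deltas = c(BIO1 = 1.0), translateCells = 2L),
    WARM_SEVERE = shiftClimate(env2, deltas = c(BIO1 = 2.5), translateCells = 5L))
  scenDirs <- list()
  for (nm in names(scen)) {
    d <- file.path(dir, "scenarios", nm)
    writeSurfaces(scen[[nm]], d)
    scenDirs[[nm]] <- d
  }
  truth <- list(intercept = -1.6, betas = list(BIO1 = -0.5, BIO12 = 0.004),
                era1 = list(n1 = sim1$n1, n0 = sim1$n0,
                            injected = as.list(sim1$injected),
                            mean_P = mean(sim1$P, na.rm = TRUE),
                            mean_F = mean(sim1$F, na.rm = TRUE)),
                era2 = list(n1 = sim2$n1, n0 = sim2$n0,
                            injected = as.list(sim2$injected),
                            mean_P = mean(sim2$P, na.rm = TRUE),
                            mean_F = mean(sim2$F, na.rm = TRUE)))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(occurrences = occCsv, layers = layerDirs, scenarios = scenDirs)
}

#' Run the favorability pipeline
#'
#' Executes the workflow up to the requested command and writes its
#' artifacts (JSON reports, .asc surfaces, CSV tables and a parameter log)
#' under `config$out_dir`.  Commands: `"simulate"` writes the bundled
#' synthetic study (occurrence CSV, per-era and scenario layer stacks,
#' ground truth); `"clean"`, `"grid"`, `"select"`, `"fit"`, `"evaluate"`
#' stop after the named stage; `"compare-eras"` adds the fuzzy comparison of
#' the two era surfaces; `"project"` and `"all"` additionally project every
#' configured scenario against the later era's model and surface.  When
#' `config$occurrences` is NULL the synthetic study is simulated first and
#' used as input, so `runPipeline(command = "all")` is self-contained.
#'
#' Every JSON artifact embeds the config hash and seed; rerunning with an
#' identical config and seed reproduces the artifacts byte for byte.
#'
#' @param config a config list (see [defaultConfig()]) or a YAML/JSON path
#' @param command one of simulate, clean, grid, select, fit, evaluate,
#'   compare-eras, project, all
#' @return invisibly, a list with the computed objects (per-era frames,
#'   models, evaluations, surfaces, comparisons) and artifact paths
#' @examples
#' \donttest{
#' out <- runPipeline(list(out_dir = tempfile(), seed = 1,
#'                         eras = list(era1 = c(1961, 1980),
#'                                     era2 = c(2001, 2020))),
#'                    command = "all")
#' names(out$evaluations)
#' }
#' @export
runPipeline <- function(config = defaultConfig(), command = "all") {
  command <- match.arg(command, c("simulate", "clean", "grid", "select",
                                  "fit", "evaluate", "compare-eras",
                                  "project", "all"))
  if (is.character(config)) config <- readPipelineConfig(config)
  cfg <- validateConfig(config)
  level <- match(command, c("simulate", "clean", "grid", "select", "fit",
                            "evaluate", "compare-eras", "project", "all")) - 1L
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(config_hash = configHash(cfg), seed = cfg$seed)
  logLines <- c("favshift pipeline run",
                paste("package version:", as.character(utils::packageVersion("favshift"))),
                paste("R version:", R.version.string),
                paste("command:", command),
                paste("seed:", cfg$seed),
                paste("config hash:", meta$config_hash))
  state <- list(config = cfg, artifacts = character())

  if (is.null(cfg$occurrences)) {
    paths <- simulateStudy(cfg, file.path(cfg$out_dir, "synthetic"))
    cfg$occurrences <- paths$occurrences
    if (is.null(cfg$layers)) cfg$layers <- paths$layers
    if (is.null(cfg$scenarios)) cfg$scenarios <- paths$scenarios
    state$synthetic <- paths
    logLines <- c(logLines, "inputs: simulated synthetic study")
    if (command == "simulate") {
      writeLines(logLines, file.path(cfg$out_dir, "log.txt"))
      return(invisible(state))
    }
  } else if (command == "simulate") {
    stop("command 'simulate' needs occurrences unset (synthetic mode)")
  }
  if (is.null(cfg$layers)) stop("missing config key(s): layers")

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }

  ## clean ------------------------------------------------------------------
  raw <- stage("clean", readOccurrences(cfg$occurrences))
  cleaned <- stage("clean", cleanOccurrences(
    raw, lonMin = cfg$lon_min, latMin = cfg$lat_min,
    allowedCountries = cfg$allowed_countries))
  writeArtifact(list(removals = as.list(cleaned$log),
                     records_in = nrow(raw),
                     records_out = nrow(cleaned$records)),
                file.path(cfg$out_dir, "cleaning.json"), meta)
  state$clean <- cleaned
  if (level <= 1L) {
    writeLines(logLines, file.path(cfg$out_dir, "log.txt"))
    return(invisible(state))
  }

  ## per-era stages ---------------------------------------------------------
  eraNames <- names(cfg$eras)
  state$frames <- state$models <- state$evaluations <- state$surfaces <-
    stats::setNames(vector("list", length(eraNames)), eraNames)
  state$masks <- list()
  for (i in seq_along(eraNames)) {
    era <- eraNames[i]
    win <- as.integer(cfg$eras[[i]])
    occ <- stage("grid", subsetYears(cleaned$records, win[1L], win[2L]))
    env <- stage("grid", readEnvStack(unlist(cfg$layers[[era]])))
    mask <- stage("grid", buildStudyArea(occ, env@grid, radiusKm = cfg$buffer_km))
    frame <- stage("grid", gridRecords(occ, env, mask))
    state$frames[[era]] <- frame
    state$masks[[era]] <- mask
    if (level <= 2L) next
    split <- stage("fit", splitTrainTest(frame, testFrac = cfg$test_frac,
                                         seed = cfg$seed + i))
    sel <- stage("select", selectVariables(
      split$train, corThreshold = cfg$cor_threshold, fdrQ = cfg$fdr_q,
      trimAlpha = cfg$trim_alpha))
    writeArtifact(list(final_vars = sel$vars,
                       dropped_by_correlation = sel$trace$dropped_by_correlation,
                       dropped_by_fdr = sel$trace$dropped_by_fdr,
                       stepwise_path = sel$trace$stepwise_path,
                       trimmed = sel$trace$trimmed),
                  file.path(cfg$out_dir, paste0("selection_", era, ".json")),
                  meta)
    if (level <= 3L) next
    if (length(sel$vars) == 0L)
      stop("stage 'fit': no significant predictors remain for era ", era)
    model <- stage("fit", fitFavorabilityModel(split$train, sel$vars,
                                               trace = sel$trace,
                                               splitSeed = cfg$seed + i))
    state$models[[era]] <- model
    writeArtifact(list(intercept = model@intercept,
                       coefficients = as.list(model@coefficients),
                       summary = model@summary, aic = model@aic,
                       n1 = model@n1, n0 = model@n0,
                       split_seed = model@splitSeed),
                  file.path(cfg$out_dir, paste0("model_", era, ".json")), meta)
    surf <- stage("fit", predictSurface(model, env, mask))
    state$surfaces[[era]] <- surf
    writeSurfaces(surf, cfg$out_dir, prefix = paste0(era, "_"))
    if (level <= 4L) next
    ev <- stage("evaluate", evaluateModel(
      split$test@data$presence, predictProbability(model, split$test),
      prevalenceThreshold = prevalence(model)))
    state$evaluations[[era]] <- ev
    writeArtifact(ev, file.path(cfg$out_dir, paste0("evaluation_", era, ".json")),
                  meta)
  }
  if (level <= 5L) {
    writeLines(logLines, file.path(cfg$out_dir, "log.txt"))
    return(invisible(state))
  }

  ## era comparison ---------------------------------------------------------
  if (length(eraNames) >= 2L) {
    cmp <- stage("compare-eras", compareToBaseline(
      state$surfaces[[eraNames[1L]]], state$surfaces[[eraNames[2L]]]))
    state$eraComparison <- cmp
    writeArtifact(reportToList(cmp),
                  file.path(cfg$out_dir, "era_comparison.json"), meta)
    writeAsciiGrid(cmp@expansion, cmp@grid,
                   file.path(cfg$out_dir, "era_expansion.asc"))
    writeAsciiGrid(cmp@contraction, cmp@grid,
                   file.path(cfg$out_dir, "era_contraction.asc"))
  }
  if (level <= 6L) {
    writeLines(logLines, file.path(cfg$out_dir, "log.txt"))
    return(invisible(state))
  }

  ## scenario projections ---------------------------------------------------
  if (length(cfg$scenarios)) {
    baseEra <- eraNames[length(eraNames)]
    model <- state$models[[baseEra]]
    baseSurf <- state$surfaces[[baseEra]]
    mask <- state$masks[[baseEra]]
    rows <- list()
    state$projections <- list()
    for (nm in names(cfg$scenarios)) {
      scenSurf <- stage("project", projectScenario(
        model, readEnvStack(unlist(cfg$scenarios[[nm]])), mask = mask,
        scenarioId = nm))
      cmp <- stage("project", compareToBaseline(baseSurf, scenSurf))
      state$projections[[nm]] <- list(surface = scenSurf, comparison = cmp)
      writeSurfaces(scenSurf, cfg$out_dir, prefix = paste0("scenario_", nm, "_"))
      writeArtifact(reportToList(cmp),
                    file.path(cfg$out_dir, paste0("comparison_", nm, ".json")),
                    meta)
      rows[[nm]] <- data.frame(scenario = nm, t(cmp@indices), t(cmp@change),
                               centroid_shift_deg = cmp@centroids[["shift_deg"]])
    }
    summary <- do.call(rbind, rows)
    write.csv(summary, file.path(cfg$out_dir, "scenario_summary.csv"),
              row.names = FALSE)
    state$scenarioSummary <- summary
  }
  writeLines(logLines, file.path(cfg$out_dir, "log.txt"))
  invisible(state)
}
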