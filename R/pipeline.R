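# Pipeline orchestration: schema-checked run configurations, JSON reports
# with a reproducibility manifest, and a stable report writer.

pipeline_schema <- list(
  common = c("command", "output_dir", "seed", "log_level"),
  `fit-sec` = c("input", "inputs", "window", "molar_mass_kda",
                "concentrations_mg_ml", "concentrations_m"),
  `fit-reversion` = c("input", "window"),
  `fit-kinase` = c("input", "n_components", "constrain_baseline"),
  `compare-structures` = c("state_a", "state_b", "align_sel", "measure_sel",
                           "ring_sel", "distance_pairs", "domain_config"),
  simulate = c("stage", "noise", "k2", "n_concentrations", "truth"))

# Selections on configs/CLI are written "chain:start-end[:atom]".
parse_selection_string <- function(s) {
  parts <- strsplit(s, ":", fixed = TRUE)[[1]]
  if (length(parts) < 2) stop("selection must be 'chain:start-end[:atom]'")
  rng <- as.numeric(strsplit(parts[2], "-", fixed = TRUE)[[1]])
  if (length(rng) == 1) rng <- c(rng, rng)
  Selection(chain = parts[1], residueRange = rng,
            atomNames = if (length(parts) >= 3) parts[3] else "CA")
}

validate_config <- function(config) {
  if (is.null(config$command)) stop("config error: missing 'command'")
  cmd <- config$command
  if (!cmd %in% names(pipeline_schema)[-1])
    stop("config error: unknown command '", cmd, "'")
  allowed <- c(pipeline_schema$common, pipeline_schema[[cmd]])
  unknown <- setdiff(names(config), allowed)
  if (length(unknown))
    stop("config error: unknown key(s): ", paste(unknown, collapse = ", "))
  paths <- unlist(config[intersect(names(config),
                                   c("input", "inputs", "state_a", "state_b",
                                     "domain_config"))])
  missing <- if (length(paths)) paths[!file.exists(paths)] else character(0)
  if (length(missing))
    stop("config error: input path(s) do not exist: ",
         paste(missing, collapse = ", "))
  config
}

log_info <- function(config, ...) {
  if ((config$log_level %||% "INFO") != "QUIET")
    message("[INFO] ", ...)
}

default_of <- function(config, key, default) {
  if (is.null(config[[key]])) {
    log_info(config, "defaulted parameter ", key, " = ",
             paste(deparse(default), collapse = ""))
    default
  } else config[[key]]
}

#' Write a deterministic JSON report
#'
#' Keys are ordered stably (sorted recursively) and numbers serialized at
#' full precision, so identical results give byte-identical reports.
#'
#' @param results named list of stage outputs.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeReport <- function(results, path) {
  sort_rec <- function(x) {
    if (is.list(x) && !is.null(names(x)) && !is.data.frame(x))
      lapply(x[order(names(x))], sort_rec)
    else x
  }
  results$schema_version <- "1"
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(sort_rec(results), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "rows")
  invisible(path)
}

#' Read a JSON report back
#'
#' @param path report path.
#' @return the report as a list.
#' @export
readReport <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)

run_fit_sec <- function(config) {
  window <- config$window
  mm <- default_of(config, "molar_mass_kda", 165)
  inputs <- config$inputs %||% config$input
  chroms <- lapply(inputs, readChromatogramCsv)
  fits <- lapply(chroms, fitEMGMixture, window = window)
  per <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    tf <- tetramerFraction(f)
    p <- mixture_to_par(f@model)
    list(input = inputs[[i]], parameters = as.list(p),
         standard_errors = as.list(sqrt(pmax(diag(f@covariance), 0))),
         residual_rms = f@residualRMS, converged = f@converged,
         y_frac = tf$yFrac, y_frac_se = tf$se)
  })
  out <- list(fits = per,
              assumptions = list(
                fraction_definition = "area fraction ampT/(ampT+ampD), equal extinction per subunit, baseline excluded"))
  conc <- config$concentrations_m %||%
    if (!is.null(config$concentrations_mg_ml))
      mgPerMlToMolar(unlist(config$concentrations_mg_ml), mm) else NULL
  if (!is.null(conc)) {
    if (length(conc) != length(fits))
      stop("config error: concentrations must match inputs")
    y <- vapply(per, function(p) p$y_frac, numeric(1))
    af <- fitAssociationConstant(unlist(conc), y)
    out$association <- list(
      k2_per_m = af$k2, k2_se = af$se,
      note = "descriptive trendline: titration points need not be at equilibrium during elution",
      table = data.frame(c_tot_m = unlist(conc), y_frac = y))
  }
  out
}

run_fit_reversion <- function(config) {
  window <- default_of(config, "window", c(650, 785))
  series <- readSpectralSeriesCsv(config$input)
  fit <- fitGlobalBiexponential(series, window = as.numeric(unlist(window)))
  list(k1_per_s = fit@k1, k2_per_s = fit@k2,
       k_se = as.list(fit@kSE), degenerate = fit@degenerate,
       residual_rms = fit@residualRMS,
       window_nm = as.numeric(unlist(window)),
       amplitudes = data.frame(wavelength_nm = fit@wavelengths,
                               amp1 = fit@amp1, amp2 = fit@amp2,
                               abs0 = fit@abs0))
}

run_fit_kinase <- function(config) {
  ncomp <- default_of(config, "n_components", 1)
  constrain <- isTRUE(default_of(config, "constrain_baseline", FALSE))
  traces <- readKineticsCsv(config$input)
  fit <- fitSaturation(traces, nComponents = ncomp,
                       constrainBaseline = constrain)
  list(k_per_timeunit = fit@k,
       k2_per_timeunit = fit@k2, n_components = fit@nComponents,
       k_se = as.list(fit@kSE), residual_rms = fit@residualRMS,
       baseline_constrained = fit@baselineConstrained,
       units_note = "rate units are the reciprocal of the input time unit; units are echoed from input metadata, never assumed",
       replicates = data.frame(replicate_id = fit@replicateIds,
                               delta_s = fit@deltaS, s0 = fit@s0))
}

run_compare_structures <- function(config) {
  a <- readStructure(config$state_a)
  b <- readStructure(config$state_b)
  cfgfile <- config$domain_config %||%
    system.file("extdata", "psbphp1_domains.yaml", package = "bphptools")
  dom <- yaml::read_yaml(cfgfile)
  alignSel <- if (!is.null(config$align_sel))
    parse_selection_string(config$align_sel)
  else Selection(chain = dom$default_chain,
                 residueRange = unlist(dom$domains$GAF))
  measureSel <- if (!is.null(config$measure_sel))
    parse_selection_string(config$measure_sel)
  else Selection(chain = dom$default_chain,
                 residueRange = unlist(dom$domains$PHY))
  ringSel <- if (!is.null(config$ring_sel)) {
    if (is.character(config$ring_sel)) parse_selection_string(config$ring_sel)
    else Selection(chain = config$ring_sel$chain %||% NA,
                   atomNames = unlist(config$ring_sel$atoms),
                   ligand = config$ring_sel$ligand)
  } else NULL
  pairs <- lapply(config$distance_pairs %||% list(), function(p)
    list(a = p$a, b = p$b))
  metrics <- compareStructures(a, b, alignSel, measureSel, ringSel = ringSel,
                               distancePairs = pairs)
  list(metrics = metrics, domain_config = cfgfile)
}

run_simulate <- function(config) {
  stage <- config$stage %||% stop("config error: simulate needs 'stage'")
  seed <- default_of(config, "seed", 1)
  noise <- config$noise %||% list(type = "none")
  outdir <- config$output_dir
  sp <- generatorSpec(seed = seed, noise = noise)
  switch(stage,
    sec = {
      k2 <- default_of(config, "k2", 2e6)
      n <- default_of(config, "n_concentrations", 8)
      conc <- logspace(7.0909e-7, 7.0909e-6, n)
      series <- makeEquilibriumSeries(k2 = k2, concentrations = conc,
                                      template = sp)
      paths <- vapply(seq_along(series), function(i) {
        p <- file.path(outdir, sprintf("chromatogram_%02d.csv", i))
        writeChromatogramCsv(series[[i]], p)
      }, "")
      list(stage = "sec", files = paths, k2_true = k2,
           truth = data.frame(
             c_tot_m = conc,
             y_frac = vapply(series, function(s) s@truth$yFrac, numeric(1))))
    },
    reversion = {
      s <- makeReversionSeries(sp)
      p <- file.path(outdir, "reversion_series.csv")
      writeSpectralSeriesCsv(s, p)
      list(stage = "reversion", files = p,
           truth = list(k1 = s@truth$k1, k2 = s@truth$k2))
    },
    kinase = {
      tr <- makeKineticsTrace(sp)
      p <- file.path(outdir, "kinetics_traces.csv")
      writeKineticsCsv(tr, p)
      list(stage = "kinase", files = p,
           truth = list(k = tr[[1]]@truth$k))
    },
    structures = {
      pair <- makeRotatedPair(sp)
      pa <- file.path(outdir, "synthetic_state_a.pdb")
      pb <- file.path(outdir, "synthetic_state_b.pdb")
      writeStructurePdb(pair$stateA, pa)
      writeStructurePdb(pair$stateB, pb)
      list(stage = "structures", files = c(pa, pb),
           truth = list(angle = pair$truth$angle,
                        ring_flip = pair$truth$ringFlip))
    },
    stop("config error: unknown simulate stage '", stage, "'"))
}

#' Run one pipeline stage from a configuration
#'
#' The configuration is a named list (or the path of a YAML file) with a
#' `command` of `fit-sec`, `fit-reversion`, `fit-kinase`,
#' `compare-structures` or `simulate`, plus stage parameters. Unknown keys
#' are rejected and referenced input paths must exist before any computation
#' starts. Every defaulted parameter is logged and recorded in the manifest.
#' A JSON report and a run manifest (config echo, package version, input
#' checksums) are written to `output_dir`.
#'
#' @param config named list or YAML path.
#' @param overrides named list applied over the file/list values
#'   (precedence: overrides > config > defaults).
#' @return invisibly, a list with `report`, `manifest` and the output paths.
#' @export
runPipeline <- function(config, overrides = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (length(overrides)) {
    for (nm in names(overrides))
      log_info(config, "override: ", nm)
    config <- utils::modifyList(config, overrides)
  }
  config <- validate_config(config)
  outdir <- config$output_dir %||% "."
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  results <- switch(config$command,
    `fit-sec` = run_fit_sec(config),
    `fit-reversion` = run_fit_reversion(config),
    `fit-kinase` = run_fit_kinase(config),
    `compare-structures` = run_compare_structures(config),
    simulate = run_simulate(config))
  inputs <- unlist(config[intersect(names(config),
                                    c("input", "inputs", "state_a",
                                      "state_b"))])
  manifest <- list(
    config = config,
    package_version = as.character(utils::packageVersion("bphptools")),
    input_checksums = if (length(inputs))
      as.list(tools::md5sum(unlist(inputs))) else list())
  report_path <- file.path(outdir, paste0(config$command, "-report.json"))
  manifest_path <- file.path(outdir, paste0(config$command, "-manifest.json"))
  writeReport(results, report_path)
  writeReport(manifest, manifest_path)
  invisible(list(report = results, manifest = manifest,
                 report_path = report_path, manifest_path = manifest_path))
}
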