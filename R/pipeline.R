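# End-to-end orchestration: validated configuration, the
# simulate -> preprocess -> quantify -> classify -> stats pipeline, and a
# reproducibility manifest.

#' Default pipeline configuration
#'
#' Nested list of every tunable of the pipeline, fully serializable to JSON
#' so a run is reproducible from config + seed alone.
#'
#' @return named list; see the vignette for the meaning and units of each
#'   entry.
#' @export
defaultConfig <- function() {
  list(
    grid = list(start = 4000, end = 650, step = 1),
    design = list(cell_lines = "HCT116", doses = c(0, 0.1, 0.5, 1.0, 1.5),
                  bio_reps = 3, tech_reps = 3),
    preprocessing = list(sg_window = 9, sg_order = 3,
                         flatten_window = c(2200, 2050)),
    regions = list(whole = c(4000, 650), lipid = c(3030, 2830),
                   nucleic = c(1250, 1200)),
    chemometrics = list(region = "whole", k = 10, m = 10, kind = "linear",
                        split = 2 / 3, labels = "dose"),
    stats = list(variant = "student", aggregate_technical = TRUE),
    seed = 1)
}

# recursive unknown-key validation against the default skeleton
.validateConfig <- function(cfg, template = defaultConfig(), path = "") {
  if (!is.list(cfg)) stop("config element '", path, "' must be a list")
  unknown <- setdiff(names(cfg), names(template))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste0(sub("^\\.", "", paste0(path, ".", unknown)), collapse = ", "))
  for (nm in names(cfg))
    if (is.list(template[[nm]]) && !is.null(names(template[[nm]])))
      .validateConfig(cfg[[nm]], template[[nm]], paste0(path, ".", nm))
  invisible(TRUE)
}

# fill unset keys from the defaults
.mergeConfig <- function(cfg, template = defaultConfig()) {
  for (nm in names(template)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- template[[nm]]
    else if (is.list(template[[nm]]) && !is.null(names(template[[nm]])))
      cfg[[nm]] <- .mergeConfig(cfg[[nm]], template[[nm]])
  }
  cfg
}

#' Read and validate a pipeline configuration
#'
#' JSON configuration; unknown keys are rejected, unset keys take their
#' defaults, and the wavenumber regions are checked for validity before any
#' stage runs.
#'
#' @param path JSON file; `NULL` returns the validated defaults.
#' @return Validated config list.
#' @export
readConfig <- function(path = NULL) {
  cfg <- if (is.null(path)) list()
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
  .validateConfig(cfg)
  cfg <- .mergeConfig(cfg)
  g <- cfg$grid
  if (g$start <= g$end || g$step <= 0)
    stop("invalid grid: start must exceed end and step must be positive")
  for (nm in names(cfg$regions)) {
    r <- sort(as.numeric(cfg$regions[[nm]]))
    if (length(r) != 2 || r[1] >= r[2])
      stop("region '", nm, "' must be two distinct wavenumbers")
    if (r[2] > g$start || r[1] < g$end)
      stop("region '", nm, "' [", r[1], ", ", r[2],
           "] lies outside the grid [", g$end, ", ", g$start, "]")
  }
  if (!cfg$chemometrics$region %in% names(cfg$regions))
    stop("chemometrics region '", cfg$chemometrics$region,
         "' is not a configured region")
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes (optionally) simulate, then preprocess, quantify, classify and
#' summarize, writing tidy CSV outputs and a reproducibility manifest to
#' `outDir`. With `input = "simulate"` the spectra come from
#' [generateExperiment()] under the config's design and seed; otherwise
#' `input` is an [IRSpectraSet-class] (e.g. from [readSpectraCSV()]).
#' Identical config + seed produce an identical bundle (equal config and
#' result hashes in the manifest).
#'
#' @param config config list from [readConfig()] / [defaultConfig()].
#' @param input `"simulate"` or an [IRSpectraSet-class].
#' @param outDir output directory; created if needed. `NULL` skips writing.
#' @return list with `spectra`, `bandTable` (percent-scaled),
#'   `zdna`, `lipid`, `secondary`, `discrimination`, `stats`, `manifest`.
#' @export
runPipeline <- function(config = defaultConfig(), input = "simulate",
                        outDir = NULL) {
  .validateConfig(config)
  config <- .mergeConfig(config)
  if (identical(input, "simulate")) {
    grid <- wavenumberGrid(config$grid$start, config$grid$end, config$grid$step)
    des <- sampleDesign(config$design$cell_lines, config$design$doses,
                        config$design$bio_reps, config$design$tech_reps,
                        seed = config$seed)
    spectra <- generateExperiment(des, grid = grid)
  } else if (is(input, "IRSpectraSet")) {
    spectra <- input
  } else stop("input must be \"simulate\" or an IRSpectraSet")

  stage <- function(name, expr) tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
  pp <- config$preprocessing
  tbl <- stage("quantify",
    percentOfUntreated(quantifyBands(spectra,
      sgWindow = pp$sg_window, sgOrder = pp$sg_order)))
  zdna <- stage("zdna", zdnaEnhancementRatio(tbl))
  lipid <- stage("lipid", lipidUnsaturationSummary(tbl))
  secondary <- stage("secondary_structure", secondaryStructureSummary(tbl))
  ch <- config$chemometrics
  disc <- stage("classify", discriminateGroups(spectra,
    region = config$regions[[ch$region]], labels = ch$labels,
    k = min(ch$k, ncol(spectra) - 1), m = ch$m, kind = ch$kind,
    split = ch$split, seed = config$seed))
  statTables <- stage("stats", {
    bands <- unique(tbl$band)
    do.call(rbind, lapply(bands, function(b)
      cbind(band = b, groupSummary(tbl, b,
        aggregateTechnical = config$stats$aggregate_technical,
        variant = config$stats$variant))))
  })
  manifest <- list(
    package_version = as.character(utils::packageVersion("ftirQuant")),
    seed = config$seed,
    config_hash = .hashObject(config),
    n_samples = ncol(spectra),
    result_hash = .hashObject(list(tbl, zdna, lipid, secondary,
                                   disc$accuracyHeldout)))
  res <- list(spectra = spectra, bandTable = tbl, zdna = zdna, lipid = lipid,
              secondary = secondary, discrimination = disc,
              stats = statTables, manifest = manifest)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(d, f) utils::write.csv(d, file.path(outDir, f),
                                          row.names = FALSE)
    wr(tbl, "band_intensities.csv")
    wr(zdna, "zdna_ratio.csv")
    wr(lipid, "lipid_unsaturation.csv")
    wr(secondary, "secondary_structure.csv")
    wr(statTables, "group_statistics.csv")
    wr(disc$scoresTable, "pca_scores.csv")
    wr(as.data.frame(confusionMatrix(disc$lda, "heldout")),
       "confusion_heldout.csv")
    wr(as.data.frame(confusionMatrix(disc$lda, "all")), "confusion_all.csv")
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}

# md5 of the canonical JSON serialization (tools::md5sum needs a file)
.hashObject <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(x, f, auto_unbox = TRUE, digits = 15, force = TRUE)
  unname(tools::md5sum(f))
}
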