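.defaultRunConfig <- function() {
  list(seed = 1,
       shift = 100, min_score = 10,
       enrich = list(window = 600, alpha = 1e-4,
                     windows = seq(200, 4000, by = 200)),
       profile = list(flank = 2000, smooth = 200, orient = TRUE),
       stratify = list(proximal_bp = 1000, distal_bp = 10000),
       correlate = list(bin_size = 600, window = 600))
}

.mergeConfig <- function(base, user) {
  for (k in names(user)) {
    if (is.list(user[[k]]) && is.list(base[[k]]))
      base[[k]] <- .mergeConfig(base[[k]], user[[k]])
    else base[[k]] <- user[[k]]
  }
  base
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (optional) -> enrich -> stratify -> profile ->
#' correlate on one configuration and writes all result tables plus a
#' machine-readable JSON manifest (parameters, seed, package version,
#' clamped-tag counts) to `outDir`.  Two runs with the same configuration
#' produce identical files.
#'
#' The configuration is a nested list (or path to a YAML file with the same
#' structure).  Either a `simulate` block (arguments for [syntheticPreset()]
#' / [syntheticConfig()], e.g. `list(preset = "short_range_bimodal")`) or an
#' `inputs` block with file paths (`tags` named list, `control`, `sites`,
#' `site_mode`, `annotation`, `roles`, `chrom_sizes`) must be present.
#' Optional blocks `enrich` (`window`, `alpha`, `windows`), `profile`
#' (`flank`, `smooth`, `orient`), `stratify` (`proximal_bp`, `distal_bp`),
#' `correlate` (`bin_size`, `window`) and scalars `seed`, `shift`,
#' `min_score` override the defaults.
#'
#' @param config nested list or path to a YAML config file
#' @param outDir output directory (created if needed)
#' @return invisibly, the manifest list
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .mergeConfig(.defaultRunConfig(), config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  wt <- function(x, name) {
    p <- file.path(outDir, name)
    utils::write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs[[length(outputs) + 1L]] <<- name
    p
  }

  ## stage: simulate or load --------------------------------------------------
  if (!is.null(cfg$simulate)) {
    simArgs <- cfg$simulate
    simArgs$seed <- if (is.null(simArgs$seed)) cfg$seed else simArgs$seed
    sim <- tryCatch({
      if (!is.null(simArgs$preset)) {
        simArgs$name <- simArgs$preset
        simArgs$preset <- NULL
        do.call(syntheticPreset, simArgs)
      } else do.call(syntheticConfig, simArgs)
    }, error = function(e) stop("stage simulate: ", conditionMessage(e),
                                call. = FALSE))
    sim <- simulateDataset(sim)
    chromSizes <- sim$chromSizes
    tagsRaw <- sim$tags
    controlRaw <- sim$control
    sites <- sim$sites
    transcripts <- sim$transcripts
    roles <- sim$roles
  } else if (!is.null(cfg$inputs)) {
    inp <- cfg$inputs
    load1 <- function(expr, stage) tryCatch(expr, error = function(e)
      stop("stage load(", stage, "): ", conditionMessage(e), call. = FALSE))
    chromSizes <- load1(readChromSizes(inp$chrom_sizes), "chrom_sizes")
    tagsRaw <- load1(lapply(inp$tags, readTags, minScore = cfg$min_score),
                     "tags")
    controlRaw <- if (!is.null(inp$control))
      load1(readTags(inp$control, minScore = cfg$min_score), "control")
    sites <- load1(readSites(inp$sites,
                             mode = if (is.null(inp$site_mode)) "point"
                                    else inp$site_mode), "sites")
    transcripts <- if (!is.null(inp$annotation))
      load1(readAnnotation(inp$annotation), "annotation")
    roles <- if (!is.null(inp$roles)) load1(readRoles(inp$roles), "roles")
  } else stop("config needs a 'simulate' or an 'inputs' block")

  marks <- lapply(tagsRaw, shiftTags, chromSizes = chromSizes,
                  shift = cfg$shift, source = "mark")
  control <- if (!is.null(controlRaw))
    shiftTags(controlRaw, chromSizes, cfg$shift, source = "control")

  ## stage: stratify ----------------------------------------------------------
  strata <- NULL
  if (!is.null(transcripts)) {
    tx <- transcripts
    if (anyDuplicated(tx$gene_id) && !anyNA(tx$expression))
      tx <- selectRepresentative(tx)
    strata <- classifyDistance(sites, tx, cfg$stratify$proximal_bp,
                               cfg$stratify$distal_bp)
    if (!is.null(roles)) {
      ra <- assignRoles(sites, roles)
      strata$role <- ra$role[match(strata$site_id, ra$site_id)]
      strata$role[is.na(strata$role)] <- "excluded"
    }
    wt(strata, "strata.tsv")
  }

  ## stage: enrich ------------------------------------------------------------
  for (mk in names(marks)) {
    calls <- callEnrichment(marks[[mk]], sites, control,
                            window = cfg$enrich$window,
                            alpha = cfg$enrich$alpha)
    wt(calls, sprintf("calls_%s.tsv", mk))
    groups <- if (!is.null(strata))
      strata$distance_class[match(sites$site_id, strata$site_id)]
    curve <- enrichmentCurve(marks[[mk]], sites, control,
                             windows = cfg$enrich$windows,
                             alpha = cfg$enrich$alpha, groups = groups)
    wt(curve, sprintf("curve_%s.tsv", mk))
  }

  ## stage: profile -----------------------------------------------------------
  shapes <- NULL
  for (mk in names(marks)) {
    prof <- if (isTRUE(cfg$profile$orient) && !is.null(transcripts))
      orientByNearestGene(marks[[mk]], sites, transcripts, control,
                          flank = cfg$profile$flank)
    else netSignalProfile(marks[[mk]], sites, control,
                          flank = cfg$profile$flank)
    if (cfg$profile$smooth > 1)
      prof <- smoothProfile(prof, cfg$profile$smooth)
    writeProfile(prof, file.path(outDir, sprintf("profile_%s.tsv", mk)))
    outputs[[length(outputs) + 1L]] <- sprintf("profile_%s.tsv", mk)
    sh <- detectShape(prof)
    shapes <- rbind(shapes, data.frame(
      mark = mk, n_modes = sh@nModes,
      modes = paste(sh@modeOffsets, collapse = ","),
      inter_peak_distance = sh@interPeakDistance,
      asymmetry = sh@asymmetryIndex, min_offset = sh@minOffset))
  }
  wt(shapes, "shapes.tsv")

  ## stage: correlate ---------------------------------------------------------
  if (length(marks) >= 2) {
    bins <- lapply(marks, binCounts, binSize = cfg$correlate$bin_size)
    gc <- genomeCorrelation(bins)
    wt(as.data.frame(corMatrix(gc)), "correlation_genome.tsv")
    sc <- siteCorrelation(marks, sites, window = cfg$correlate$window)
    wt(as.data.frame(corMatrix(sc)), "correlation_sites.tsv")
  }

  manifest <- list(
    package = "siteMarks",
    version = as.character(utils::packageVersion("siteMarks")),
    seed = cfg$seed,
    parameters = cfg[c("shift", "min_score", "enrich", "profile",
                       "stratify", "correlate")],
    simulate = cfg$simulate,
    n_sites = nrow(sites),
    clamped_tags = c(lapply(marks, clampedCount),
                     list(control = if (is.null(control)) 0L
                          else clampedCount(control))),
    outputs = unlist(outputs))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
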