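#' Pipeline run configuration
#'
#' A single document (YAML/JSON file or R list) describing one analysis
#' run: input paths, the channel-role map (which TIFF page plays
#' cerulean / FlAsH / TMR / antibody / Hoechst), and the tunable constants
#' with their standard defaults — Otsu thresholding, zone fractions
#' `(0.5, 1)`, 110% boundary scaling, 25-px background circle, 20 x 4
#' log bins. Explicit arguments override file values.
#'
#' @param path optional YAML or JSON config file.
#' @param ... named overrides of config keys.
#' @return object of class `run_config`.
#' @export
run_config <- function(path = NULL, ...) {
  cfg <- list(
    inputs = list(),
    channel_roles = NULL,
    threshold_method = "otsu",
    zone_fractions = c(0.5, 1.0),
    scale_factor = 1.10,
    background_radius = 25,
    background_center = "auto-corner",
    n_cerulean_bins = 20L,
    n_tmr_bins = 4L,
    seed = 1L,
    out_dir = "."
  )
  if (!is.null(path)) {
    file_cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::fromJSON(path)
    } else {
      yaml::read_yaml(path)
    }
    cfg[names(file_cfg)] <- file_cfg
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  stopifnot(cfg$scale_factor > 0, cfg$background_radius > 0,
            cfg$n_cerulean_bins >= 2)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

.pipeline_stages <- c("simulate", "segment", "maturity", "zones", "frap",
                      "penetration", "cytometry", "stall")

.stage_warnings <- new.env(parent = emptyenv())

.collect_warnings <- function(expr) {
  warns <- character(0)
  val <- withCallingHandlers(expr, warning = function(w) {
    warns <<- c(warns, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  list(value = val, warnings = warns)
}

#' Run one pipeline stage
#'
#' Dispatches a configured analysis stage, writes its CSV/JSON outputs
#' under `config$out_dir`, and returns a run report (tool version, config
#' echo, input digests, per-stage record counts, warnings, output
#' manifest). Regenerating with identical config and inputs yields
#' identical outputs byte for byte; the report's timestamp is the only
#' run-varying field.
#'
#' Stages and their inputs:
#' * `simulate` — `config$simulate` holds `type` (`"scene"`, `"frap"` or
#'   `"population"`) plus spec arguments; writes TIFF + ground-truth JSON
#'   or an events CSV.
#' * `segment` — scene TIFFs in `inputs$scenes`; writes ROI JSONs.
#' * `maturity` — scene TIFFs; writes the per-inclusion maturity CSV.
#' * `zones` — scene TIFFs and `config$zone_channel`; writes the long
#'   per-zone CSV.
#' * `frap` — FRAP series TIFF in `inputs$frap`; writes trace CSV and
#'   mobility JSON.
#' * `penetration` — scene TIFFs with an antibody channel; writes the
#'   per-inclusion penetration CSV.
#' * `cytometry` — events CSV in `inputs$events`, calibration CSVs in
#'   `inputs$calibration_negative` / `_positive`; writes the tidy bin-grid
#'   CSV and JSON.
#' * `stall` — events CSV; writes the stall-ratio summary CSV.
#'
#' @param config a `run_config`.
#' @param stage one of the stage names above.
#' @return the `run_report` (list), invisibly; stage outputs are written
#'   to disk.
#' @export
run_pipeline <- function(config, stage) {
  if (!inherits(config, "run_config")) stop("expected a `run_config`")
  stage <- match.arg(stage, .pipeline_stages)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  run <- .collect_warnings(switch(stage,
    simulate = .stage_simulate(config),
    segment = .stage_segment(config),
    maturity = .stage_maturity(config),
    zones = .stage_zones(config),
    frap = .stage_frap(config),
    penetration = .stage_penetration(config),
    cytometry = .stage_cytometry(config),
    stall = .stage_stall(config)
  ))
  res <- run$value
  inputs <- as.character(unlist(config$inputs, use.names = FALSE))
  inputs <- inputs[!is.na(inputs) & file.exists(inputs)]
  report <- list(
    tool = "inclusionKit",
    version = as.character(utils::packageVersion("inclusionKit")),
    stage = stage,
    timestamp = format(Sys.time(), tz = "UTC"),
    config = unclass(config),
    input_digests = if (length(inputs)) {
      as.list(tools::md5sum(inputs))
    } else {
      list()
    },
    record_counts = res$counts,
    warnings = run$warnings,
    outputs = res$outputs
  )
  jsonlite::write_json(report,
                       file.path(config$out_dir,
                                 sprintf("report_%s.json", stage)),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE, force = TRUE)
  invisible(report)
}

.resolve_channel <- function(img, config, role) {
  nm <- if (!is.null(config$channel_roles)) {
    config$channel_roles[[role]]
  } else {
    role
  }
  if (is.null(nm) || !(nm %in% names(img$channels))) {
    stop(sprintf("channel-role error: no channel for role '%s' (have: %s)",
                 role, paste(names(img$channels), collapse = ", ")))
  }
  img$channels[[nm]]
}

.stage_simulate <- function(config) {
  sim <- config$simulate
  if (is.null(sim$type)) stop("config$simulate$type is required")
  out <- character(0)
  counts <- list()
  if (sim$type == "scene") {
    args <- sim[setdiff(names(sim), "type")]
    args$seed <- config$seed
    sc <- render_scene(do.call(scene_spec, args))
    p <- file.path(config$out_dir, "scene.tiff")
    write_scene(sc, p)
    out <- c(p, paste0(p, ".json"), paste0(p, ".truth.json"))
    counts$inclusion_px <- roi_size(sc$truth$inclusion_roi)
  } else if (sim$type == "frap") {
    args <- sim[setdiff(names(sim), "type")]
    args$seed <- config$seed
    fs <- simulate_frap(do.call(frap_spec, args))
    p <- file.path(config$out_dir, "frap.tiff")
    write_frap_series(fs, p)
    out <- c(p, paste0(p, ".json"))
    counts$n_frames <- length(fs$frames)
  } else if (sim$type == "population") {
    args <- sim[setdiff(names(sim), "type")]
    args$seed <- config$seed
    ev <- simulate_population(do.call(population_spec, args))
    p <- file.path(config$out_dir, "events.csv")
    write_events(ev, p)
    out <- p
    counts$n_events <- nrow(ev)
  } else {
    stop("unknown simulate type: ", sim$type)
  }
  list(outputs = out, counts = counts)
}

.load_scenes <- function(config) {
  paths <- config$inputs$scenes
  if (is.null(paths)) stop("config$inputs$scenes is required")
  lapply(paths, read_image_tiff)
}

.stage_segment <- function(config) {
  imgs <- .load_scenes(config)
  outs <- character(0)
  for (i in seq_along(imgs)) {
    roi <- largest_component(auto_threshold(
      .resolve_channel(imgs[[i]], config, "cerulean"),
      config$threshold_method))
    p <- file.path(config$out_dir, sprintf("roi_%03d.json", i))
    roi_to_json(roi, p)
    outs <- c(outs, p)
  }
  list(outputs = outs, counts = list(n_scenes = length(imgs)))
}

.stage_maturity <- function(config) {
  imgs <- .load_scenes(config)
  fm <- cm <- numeric(length(imgs))
  for (i in seq_along(imgs)) {
    cer <- .resolve_channel(imgs[[i]], config, "cerulean")
    fla <- .resolve_channel(imgs[[i]], config, "flash")
    roi <- largest_component(auto_threshold(cer, config$threshold_method))
    fm[i] <- mean_intensity(fla, roi)
    cm[i] <- mean_intensity(cer, roi)
  }
  thr <- if (!is.null(config$population_mean)) {
    maturity_thresholds(config$population_mean, config$population_sem)
  } else if (length(imgs) >= 2L) {
    NULL  # calibrate on this population
  } else {
    stop("maturity stage needs >= 2 scenes or explicit population_mean/population_sem")
  }
  tab <- maturity_table(fm, cm, thresholds = thr)
  if (any(tab$label == "INTERMEDIATE")) {
    warning(sprintf("%d inclusion(s) fall inside the +/-SEM band (INTERMEDIATE)",
                    sum(tab$label == "INTERMEDIATE")))
  }
  p <- file.path(config$out_dir, "maturity.csv")
  utils::write.csv(tab, p, row.names = FALSE)
  list(outputs = p, counts = list(n_inclusions = nrow(tab)))
}

.stage_zones <- function(config) {
  imgs <- .load_scenes(config)
  role <- if (is.null(config$zone_channel)) "tmr" else config$zone_channel
  rows <- list()
  for (i in seq_along(imgs)) {
    cer <- .resolve_channel(imgs[[i]], config, "cerulean")
    tgt <- .resolve_channel(imgs[[i]], config, role)
    roi <- largest_component(auto_threshold(cer, config$threshold_method))
    part <- partition_zones(roi, config$zone_fractions, config$scale_factor)
    pr <- zone_profile(tgt, part, channel_name = role)
    pr$inclusion_id <- i
    rows[[i]] <- pr
  }
  out <- do.call(rbind, rows)
  p <- file.path(config$out_dir, "zones.csv")
  utils::write.csv(out, p, row.names = FALSE)
  list(outputs = p, counts = list(n_inclusions = length(imgs)))
}

.stage_frap <- function(config) {
  path <- config$inputs$frap
  if (is.null(path)) stop("config$inputs$frap is required")
  series <- read_frap_series(path)
  res <- analyze_frap(series, background_center = config$background_center)
  p1 <- file.path(config$out_dir, "frap_recovery.csv")
  utils::write.csv(as.data.frame(res$curve), p1, row.names = FALSE)
  p2 <- file.path(config$out_dir, "frap_summary.json")
  jsonlite::write_json(res$summary, p2, auto_unbox = TRUE, digits = NA,
                       null = "null")
  list(outputs = c(p1, p2),
       counts = list(n_frames = length(series$frames),
                     n_postbleach = nrow(res$curve)))
}

.stage_penetration <- function(config) {
  imgs <- .load_scenes(config)
  rows <- lapply(seq_along(imgs), function(i) {
    cer <- .resolve_channel(imgs[[i]], config, "cerulean")
    ab <- .resolve_channel(imgs[[i]], config, "antibody")
    measure_penetration(cer, ab, config$scale_factor, inclusion_id = i)
  })
  out <- do.call(rbind, rows)
  p <- file.path(config$out_dir, "penetration.csv")
  utils::write.csv(out, p, row.names = FALSE)
  list(outputs = p, counts = list(n_inclusions = nrow(out)))
}

.stage_cytometry <- function(config) {
  ev <- read_events(config$inputs$events)
  calib <- list(negative = read_events(config$inputs$calibration_negative),
                positive = read_events(config$inputs$calibration_positive))
  flags <- pulsa_gate(ev, calib)
  grid <- make_bins(ev, config$n_cerulean_bins)
  bg <- inclusion_fraction(ev, flags, grid)
  tidy <- as.data.frame(bg)
  if (any(tidy$n == 0)) {
    warning(sprintf("%d empty bin(s) in the inclusion-fraction grid",
                    sum(tidy$n == 0)))
  }
  p1 <- file.path(config$out_dir, "inclusion_fraction.csv")
  utils::write.csv(tidy, p1, row.names = FALSE)
  p2 <- file.path(config$out_dir, "inclusion_fraction.json")
  jsonlite::write_json(tidy, p2, digits = NA, null = "null")
  list(outputs = c(p1, p2),
       counts = list(n_events = nrow(ev), n_gated = sum(flags)))
}

.stage_stall <- function(config) {
  ev <- read_events(config$inputs$events)
  ss <- stall_ratios(ev)
  p <- file.path(config$out_dir, "stall_ratios.csv")
  utils::write.csv(ss$summary, p, row.names = FALSE)
  list(outputs = p, counts = list(n_events = nrow(ev),
                                  n_constructs = nrow(ss$summary)))
}
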