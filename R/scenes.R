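#' Radial channel profiles for synthetic scenes
#'
#' Descriptors for how a channel's signal is laid out around an inclusion,
#' as a function of distance `d` from the inclusion center with radius `r`:
#'
#' * `profile_uniform(level, cytoplasm_level = level)` — constant `level`
#'   throughout the inclusion (`d <= r`) and `cytoplasm_level` in the
#'   surrounding cell. The default (equal levels) is the Rack1-like fully
#'   mixed pattern; `cytoplasm_level = 0` gives an inclusion-only signal
#'   such as the concentrated cerulean fusion used for segmentation.
#' * `profile_shell(inner_level, outer_level, shell_fraction)` — `inner_level`
#'   for `d/r < shell_fraction`, `outer_level` on the enriched surface
#'   shell from `shell_fraction * r` out to 110% of `r` (surface-coating
#'   proteins sit at and just beyond the segmented edge, which is what the
#'   outer-ring measurement captures). The Ltn1/Hspb1-like outer-layer
#'   pattern.
#' * `profile_coat(core_level, coat_level, coat_depth_px)` — `core_level`
#'   up to `r - coat_depth_px`, `coat_level` on the outermost
#'   `coat_depth_px` pixels of the inclusion. Models a stain (e.g.
#'   anti-GFP antibody) that penetrates only a known depth.
#' * `profile_excluded(level_outside)` — zero inside the inclusion,
#'   `level_outside` in the surrounding cytoplasm (Nacad-like exclusion).
#'
#' Profiles are defined on normalized distance `d/r` (except the coat
#' depth, which is a physical penetration in pixels) so one descriptor
#' serves any inclusion size.
#'
#' @param level,inner_level,outer_level,core_level,coat_level,level_outside
#'   non-negative intensity levels (a.u.) added on top of the scene
#'   background.
#' @param shell_fraction inner edge of the enriched shell on normalized
#'   radius, in (0, 1].
#' @param coat_depth_px coat thickness in pixels, `>= 0`.
#' @return a `radial_profile` descriptor.
#' @export
profile_uniform <- function(level, cytoplasm_level = level) {
  stopifnot(is.numeric(level), level >= 0, cytoplasm_level >= 0)
  structure(list(type = "uniform", level = level,
                 cytoplasm_level = cytoplasm_level),
            class = "radial_profile")
}

#' @rdname profile_uniform
#' @export
profile_shell <- function(inner_level, outer_level, shell_fraction) {
  stopifnot(inner_level >= 0, outer_level >= 0,
            shell_fraction > 0, shell_fraction <= 1)
  structure(list(type = "shell", inner_level = inner_level,
                 outer_level = outer_level, shell_fraction = shell_fraction),
            class = "radial_profile")
}

#' @rdname profile_uniform
#' @export
profile_coat <- function(core_level, coat_level, coat_depth_px) {
  stopifnot(core_level >= 0, coat_level >= 0, coat_depth_px >= 0)
  structure(list(type = "coat", core_level = core_level,
                 coat_level = coat_level, coat_depth_px = coat_depth_px),
            class = "radial_profile")
}

#' @rdname profile_uniform
#' @export
profile_excluded <- function(level_outside) {
  stopifnot(level_outside >= 0)
  structure(list(type = "excluded", level_outside = level_outside),
            class = "radial_profile")
}

# Evaluate a profile over pixel distances `d` from the inclusion center.
# `inside_cell` marks cytoplasm pixels (cell disk); returns the signal
# component (background excluded).
.profile_eval <- function(profile, d, r, inside_cell) {
  inside <- d <= r
  out <- numeric(length(d))
  switch(profile$type,
    uniform = {
      out[inside] <- profile$level
      cyt <- if (is.null(profile$cytoplasm_level)) profile$level else profile$cytoplasm_level
      out[!inside & inside_cell] <- cyt
    },
    shell = {
      core <- inside & (d / r < profile$shell_fraction)
      band <- !core & d <= 1.1 * r & (inside | inside_cell)
      out[core] <- profile$inner_level
      out[band] <- profile$outer_level
    },
    coat = {
      core <- d <= (r - profile$coat_depth_px)
      out[core] <- profile$core_level
      out[inside & !core] <- profile$coat_level
    },
    excluded = { out[!inside & inside_cell] <- profile$level_outside },
    stop("unknown profile type: ", profile$type)
  )
  out
}

#' Synthetic scene specification
#'
#' Declares one cell containing one circular inclusion, with per-channel
#' radial intensity profiles, additive Gaussian noise and a flat
#' background. Geometry is validated: the inclusion disk must lie fully
#' inside the cell disk, and the cell disk fully inside the image.
#'
#' @param image_shape `c(rows, cols)` in pixels.
#' @param cell_center,cell_radius cell disk geometry, pixels.
#' @param inclusion_center,inclusion_radius inclusion disk geometry, pixels.
#' @param channel_profiles named list of [radial profiles][profile_uniform]
#'   keyed by channel name.
#' @param flash_cerulean_ratio_target optional dimensionless target for the
#'   raw FlAsH:Cerulean mean-intensity ratio inside the inclusion. When set
#'   (and no explicit `flash` profile is given) the generator solves for a
#'   uniform `flash` level that realizes the target exactly in the
#'   noiseless limit, so classification can be tested against known truth.
#' @param noise_sigma Gaussian noise SD (a.u.), `>= 0`; intensities are
#'   clipped at zero.
#' @param background_level flat background (a.u.).
#' @param seed integer RNG seed; identical spec + seed renders
#'   bit-identical images.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(image_shape = c(128L, 128L),
                       cell_center = c(64, 64), cell_radius = 55,
                       inclusion_center = c(64, 64), inclusion_radius = 20,
                       channel_profiles = list(cerulean = profile_uniform(100, 0)),
                       flash_cerulean_ratio_target = NULL,
                       noise_sigma = 0, background_level = 10, seed = 1L) {
  stopifnot(noise_sigma >= 0, background_level >= 0,
            cell_radius > 0, inclusion_radius > 0)
  image_shape <- as.integer(image_shape)
  if (cell_center[1L] - cell_radius < 1 || cell_center[1L] + cell_radius > image_shape[1L] ||
      cell_center[2L] - cell_radius < 1 || cell_center[2L] + cell_radius > image_shape[2L]) {
    stop("geometry error: cell disk extends outside the image")
  }
  sep <- sqrt(sum((cell_center - inclusion_center)^2))
  if (sep + inclusion_radius > cell_radius) {
    stop("geometry error: inclusion disk extends outside the cell disk")
  }
  if (!length(channel_profiles) || is.null(names(channel_profiles))) {
    stop("`channel_profiles` must be a named list of radial profiles")
  }
  structure(list(
    image_shape = image_shape, cell_center = cell_center,
    cell_radius = cell_radius, inclusion_center = inclusion_center,
    inclusion_radius = inclusion_radius, channel_profiles = channel_profiles,
    flash_cerulean_ratio_target = flash_cerulean_ratio_target,
    noise_sigma = noise_sigma, background_level = background_level,
    seed = as.integer(seed)
  ), class = "scene_spec")
}

#' Render a synthetic scene
#'
#' Produces the multi-channel image described by a [scene_spec()] together
#' with its ground truth. Every pixel reads
#' `background + profile(distance from inclusion center) + N(0, noise_sigma)`,
#' clipped at zero. Ground truth (true inclusion and cell ROIs, the
#' profile per channel, the realized FlAsH:Cerulean ratio, any coat
#' penetration depth) is emitted alongside and is never consumed by the
#' analysis operations.
#'
#' @param spec a `scene_spec`.
#' @return list of class `scene` with elements `image`
#'   (`multichannel_image`) and `truth`.
#' @export
render_scene <- function(spec) {
  if (!inherits(spec, "scene_spec")) stop("expected a `scene_spec`")
  shp <- spec$image_shape
  rowi <- matrix(seq_len(shp[1L]), shp[1L], shp[2L])
  coli <- matrix(rep(seq_len(shp[2L]), each = shp[1L]), shp[1L], shp[2L])
  d_incl <- sqrt((rowi - spec$inclusion_center[1L])^2 +
                 (coli - spec$inclusion_center[2L])^2)
  d_cell <- sqrt((rowi - spec$cell_center[1L])^2 +
                 (coli - spec$cell_center[2L])^2)
  inside_cell <- d_cell <= spec$cell_radius
  inclusion_roi <- mask_roi(d_incl <= spec$inclusion_radius)
  cell_roi <- mask_roi(inside_cell)

  profiles <- spec$channel_profiles
  det <- lapply(profiles, function(p) {
    matrix(.profile_eval(p, as.vector(d_incl), spec$inclusion_radius,
                         as.vector(inside_cell)), shp[1L], shp[2L]) +
      spec$background_level
  })

  ratio_real <- NA_real_
  if (!is.null(spec$flash_cerulean_ratio_target) && is.null(det[["flash"]])) {
    if (is.null(det[["cerulean"]])) {
      stop("ratio target requires a 'cerulean' channel profile")
    }
    mc <- mean_intensity(det[["cerulean"]], inclusion_roi)
    lvl <- spec$flash_cerulean_ratio_target * mc - spec$background_level
    if (lvl < 0) {
      stop("ratio target unrealizable: implied FlAsH level below background")
    }
    pf <- profile_uniform(lvl)
    det[["flash"]] <- matrix(
      .profile_eval(pf, as.vector(d_incl), spec$inclusion_radius,
                    as.vector(inside_cell)), shp[1L], shp[2L]) +
      spec$background_level
    profiles[["flash"]] <- pf
  }
  if (!is.null(det[["flash"]]) && !is.null(det[["cerulean"]])) {
    ratio_real <- mean_intensity(det[["flash"]], inclusion_roi) /
      mean_intensity(det[["cerulean"]], inclusion_roi)
  }

  chans <- withr::with_seed(spec$seed, {
    lapply(det, function(ch) {
      if (spec$noise_sigma > 0) {
        ch <- ch + matrix(stats::rnorm(length(ch), 0, spec$noise_sigma),
                          nrow(ch), ncol(ch))
      } else {
        # keep the RNG stream aligned across noise settings per channel
        ch
      }
      pmax(ch, 0)
    })
  })

  depth <- NA_real_
  coats <- vapply(profiles, function(p) p$type == "coat", TRUE)
  if (any(coats)) depth <- profiles[[which(coats)[1L]]]$coat_depth_px

  structure(list(
    image = multichannel_image(chans),
    truth = list(
      inclusion_roi = inclusion_roi, cell_roi = cell_roi,
      channel_profiles = profiles,
      flash_cerulean_ratio = ratio_real,
      penetration_depth_px = depth,
      inclusion_center = spec$inclusion_center,
      inclusion_radius = spec$inclusion_radius,
      background_level = spec$background_level, seed = spec$seed
    ),
    spec = spec
  ), class = "scene")
}

#' Write a rendered scene to disk
#'
#' Multi-page TIFF (one page per channel) plus a ground-truth JSON sidecar
#' (`<path>.truth.json`) holding the inclusion/cell ROIs as run-length
#' encodings, the profile descriptors and the realized ratio.
#'
#' @param scene a `scene` from [render_scene()].
#' @param path TIFF output path.
#' @export
write_scene <- function(scene, path) {
  if (!inherits(scene, "scene")) stop("expected a `scene`")
  write_image_tiff(scene$image, path)
  tr <- scene$truth
  truth <- list(
    inclusion_roi = jsonlite::fromJSON(roi_to_json(tr$inclusion_roi)),
    cell_roi = jsonlite::fromJSON(roi_to_json(tr$cell_roi)),
    channel_profiles = lapply(tr$channel_profiles, unclass),
    flash_cerulean_ratio = tr$flash_cerulean_ratio,
    penetration_depth_px = tr$penetration_depth_px,
    inclusion_center = tr$inclusion_center,
    inclusion_radius = tr$inclusion_radius,
    background_level = tr$background_level,
    seed = tr$seed
  )
  jsonlite::write_json(truth, paste0(path, ".truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' FRAP simulation specification
#'
#' Kinetic parameters of a simulated half-inclusion photobleach: a
#' pre-bleach frame, an instantaneous bleach removing `bleach_depth` of the
#' signal in one half-disk, then single-exponential recovery of the mobile
#' pool with base-2 halftime `recovery_halftime`:
#' `recovered(t) = mobile_fraction * (1 - 2^(-t / halftime))` of the
#' bleached amount. At `t = halftime` exactly half of the mobile pool has
#' recovered.
#'
#' @param mobile_fraction fraction of the bleached signal that is mobile,
#'   in \[0, 1\].
#' @param recovery_halftime minutes, `> 0`.
#' @param bleach_depth fraction of the pre-bleach signal removed by the
#'   bleach, in (0, 1\].
#' @param n_postbleach_frames number of post-bleach frames (default 21,
#'   one per minute).
#' @param frame_interval minutes between frames (default 1).
#' @param noise_sigma Gaussian image noise SD (a.u.).
#' @param seed integer RNG seed.
#' @export
frap_spec <- function(mobile_fraction, recovery_halftime = 5,
                      bleach_depth = 0.5, n_postbleach_frames = 21L,
                      frame_interval = 1, noise_sigma = 0, seed = 1L) {
  stopifnot(mobile_fraction >= 0, mobile_fraction <= 1,
            bleach_depth > 0, bleach_depth <= 1,
            recovery_halftime > 0, n_postbleach_frames >= 2,
            frame_interval > 0, noise_sigma >= 0)
  structure(list(
    mobile_fraction = mobile_fraction, recovery_halftime = recovery_halftime,
    bleach_depth = bleach_depth,
    n_postbleach_frames = as.integer(n_postbleach_frames),
    frame_interval = frame_interval, noise_sigma = noise_sigma,
    seed = as.integer(seed)
  ), class = "frap_spec")
}

#' Default scene for FRAP simulations
#'
#' A single inclusion carrying a `fusion` channel (the Httex1 fluorescent
#' fusion used for the whole-inclusion ROI) and a `flash` channel (FlAsH,
#' which survives only in the unbleached half and therefore defines the
#' unbleached ROI).
#'
#' @param image_shape,inclusion_radius geometry (pixels).
#' @param fusion_level,flash_level signal levels above background (a.u.).
#' @param background_level,noise_sigma,seed as in [scene_spec()].
#' @export
frap_scene_spec <- function(image_shape = c(128L, 128L), inclusion_radius = 18,
                            fusion_level = 100, flash_level = 80,
                            background_level = 10, noise_sigma = 0, seed = 1L) {
  ctr <- (as.integer(image_shape) + 1) / 2
  scene_spec(
    image_shape = image_shape, cell_center = ctr,
    cell_radius = min(image_shape) / 2 - 2,
    inclusion_center = ctr, inclusion_radius = inclusion_radius,
    channel_profiles = list(fusion = profile_uniform(fusion_level, 0),
                            flash = profile_uniform(flash_level, 0)),
    noise_sigma = noise_sigma, background_level = background_level, seed = seed
  )
}

#' Simulate a FRAP image time series
#'
#' Renders a pre-bleach frame followed by `n_postbleach_frames` frames in
#' which the half of the inclusion on and right of the vertical diameter
#' through the inclusion center has been bleached. In the `fusion` channel
#' the bleached half loses `bleach_depth` of its signal at `t = 0` and
#' recovers per the kinetic model in [frap_spec()]; the unbleached half is
#' unchanged up to noise. In the `flash` channel the bleached half's dye is
#' destroyed and does not recover, which is what makes FlAsH the marker of
#' the unbleached region.
#'
#' @param fspec a `frap_spec`.
#' @param scene a `scene_spec` whose profiles include `fusion` and `flash`
#'   (default [frap_scene_spec()] with the frap spec's noise and seed).
#' @return object of class `frap_series`: `frames` (list of
#'   `multichannel_image`), `times` (minutes; the pre-bleach frame sits one
#'   frame interval before `t = 0`), and `truth` (bleached/unbleached/
#'   inclusion ROIs, kinetic parameters, and the noiseless per-frame mean
#'   trace).
#' @export
simulate_frap <- function(fspec, scene = NULL) {
  if (!inherits(fspec, "frap_spec")) stop("expected a `frap_spec`")
  if (is.null(scene)) {
    scene <- frap_scene_spec(noise_sigma = fspec$noise_sigma, seed = fspec$seed)
  }
  if (!inherits(scene, "scene_spec")) stop("expected a `scene_spec`")
  need <- c("fusion", "flash")
  if (!all(need %in% names(scene$channel_profiles))) {
    stop("FRAP scene must define 'fusion' and 'flash' channel profiles")
  }
  shp <- scene$image_shape
  rowi <- matrix(seq_len(shp[1L]), shp[1L], shp[2L])
  coli <- matrix(rep(seq_len(shp[2L]), each = shp[1L]), shp[1L], shp[2L])
  d_incl <- sqrt((rowi - scene$inclusion_center[1L])^2 +
                 (coli - scene$inclusion_center[2L])^2)
  d_cell <- sqrt((rowi - scene$cell_center[1L])^2 +
                 (coli - scene$cell_center[2L])^2)
  inside_cell <- d_cell <= scene$cell_radius
  incl_mask <- d_incl <= scene$inclusion_radius
  bleach_mask <- incl_mask & (coli >= scene$inclusion_center[2L])

  base <- lapply(scene$channel_profiles[need], function(p) {
    matrix(.profile_eval(p, as.vector(d_incl), scene$inclusion_radius,
                         as.vector(inside_cell)), shp[1L], shp[2L])
  })
  bg <- scene$background_level

  times <- c(-fspec$frame_interval,
             seq(0, by = fspec$frame_interval,
                 length.out = fspec$n_postbleach_frames))
  recovered <- function(t) {
    fspec$mobile_fraction * (1 - 2^(-t / fspec$recovery_halftime))
  }

  frame_det <- lapply(times, function(t) {
    fus <- base$fusion
    fla <- base$flash
    if (t >= 0) {
      fus[bleach_mask] <- fus[bleach_mask] *
        (1 - fspec$bleach_depth + fspec$bleach_depth * recovered(t))
      fla[bleach_mask] <- 0
    }
    list(fusion = fus + bg, flash = fla + bg)
  })

  frames <- withr::with_seed(fspec$seed, {
    lapply(frame_det, function(fr) {
      multichannel_image(lapply(fr, function(ch) {
        if (fspec$noise_sigma > 0) {
          ch <- ch + matrix(stats::rnorm(length(ch), 0, fspec$noise_sigma),
                            nrow(ch), ncol(ch))
        }
        pmax(ch, 0)
      }))
    })
  })

  bleached_roi <- mask_roi(bleach_mask)
  unbleached_roi <- mask_roi(incl_mask & !bleach_mask)
  true_trace <- data.frame(
    time = times,
    bleached = vapply(frame_det, function(fr) mean(fr$fusion[bleach_mask]), 0),
    unbleached = vapply(frame_det, function(fr) mean(fr$fusion[incl_mask & !bleach_mask]), 0)
  )

  structure(list(
    frames = frames, times = times, spec = fspec, scene_spec = scene,
    truth = list(
      mobile_fraction = fspec$mobile_fraction,
      recovery_halftime = fspec$recovery_halftime,
      bleach_depth = fspec$bleach_depth,
      inclusion_roi = mask_roi(incl_mask),
      bleached_roi = bleached_roi, unbleached_roi = unbleached_roi,
      background_level = bg, trace = true_trace
    )
  ), class = "frap_series")
}

#' Write a FRAP series to disk
#'
#' Multi-page TIFF with pages ordered frame-major (frame 1 fusion, frame 1
#' flash, frame 2 fusion, ...) and a JSON sidecar recording times, channel
#' order and ground truth.
#'
#' @param series a `frap_series`.
#' @param path TIFF output path.
#' @export
write_frap_series <- function(series, path) {
  if (!inherits(series, "frap_series")) stop("expected a `frap_series`")
  chn <- names(series$frames[[1L]]$channels)
  pages <- list()
  for (fr in series$frames) for (ch in chn) {
    pages[[length(pages) + 1L]] <- pmin(pmax(fr$channels[[ch]] / .TIFF_SCALE, 0), 1)
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  side <- list(
    layout = "frame_major", channels = chn, times = series$times,
    intensity_scale = .TIFF_SCALE,
    truth = list(
      mobile_fraction = series$truth$mobile_fraction,
      recovery_halftime = series$truth$recovery_halftime,
      bleach_depth = series$truth$bleach_depth,
      background_level = series$truth$background_level,
      bleached_roi = jsonlite::fromJSON(roi_to_json(series$truth$bleached_roi)),
      unbleached_roi = jsonlite::fromJSON(roi_to_json(series$truth$unbleached_roi))
    )
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_frap_series
#' @export
read_frap_series <- function(path) {
  side <- jsonlite::fromJSON(paste0(path, ".json"))
  pages <- tiff::readTIFF(path, all = TRUE)
  chn <- side$channels
  nch <- length(chn)
  nfr <- length(pages) / nch
  frames <- lapply(seq_len(nfr), function(i) {
    chans <- lapply(seq_len(nch), function(j) {
      p <- pages[[(i - 1L) * nch + j]]
      if (length(dim(p)) == 3L) p <- p[, , 1L]
      p * side$intensity_scale
    })
    names(chans) <- chn
    multichannel_image(chans)
  })
  structure(list(frames = frames, times = side$times, truth = side$truth),
            class = "frap_series")
}
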