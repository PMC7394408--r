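#' Assign FRAP analysis ROIs
#'
#' From the first post-bleach frame: the whole inclusion is segmented by
#' automatic thresholding of the fusion-protein channel; the unbleached
#' region by automatic thresholding of the FlAsH channel (the FlAsH dye in
#' the bleached half is destroyed, so FlAsH marks what was not bleached);
#' the bleached region is the set difference whole \ unbleached; and the
#' background is a fixed-radius circle (default 25 px) at a user-chosen
#' position, required to be disjoint from the inclusion.
#'
#' ROIs are fixed from this frame and reused across the whole series —
#' inclusions are treated as stationary over the recovery window.
#'
#' @param fusion_channel,flash_channel intensity matrices from the first
#'   post-bleach frame.
#' @param background_center `c(row, col)` center of the background circle,
#'   or `"auto-corner"` to pick the darkest 25-px corner circle of the
#'   fusion channel.
#' @param background_radius circle radius in pixels (default 25).
#' @param method thresholding method passed to [auto_threshold()].
#' @return object of class `frap_rois` with `whole_inclusion`,
#'   `unbleached`, `bleached`, `background`.
#' @export
assign_frap_rois <- function(fusion_channel, flash_channel,
                             background_center = "auto-corner",
                             background_radius = 25, method = "otsu") {
  whole <- largest_component(auto_threshold(fusion_channel, method))
  unbleached <- largest_component(auto_threshold(flash_channel, method))
  bleached <- roi_subtract(whole, unbleached)
  if (is_empty_roi(bleached)) {
    stop("empty bleached ROI: FlAsH threshold covers the whole inclusion (bleach failed?)")
  }
  shp <- dim(fusion_channel)
  if (identical(background_center, "auto-corner")) {
    off <- background_radius + 1
    corners <- list(c(off, off), c(off, shp[2L] - off),
                    c(shp[1L] - off, off), c(shp[1L] - off, shp[2L] - off))
    means <- vapply(corners, function(ctr) {
      mean_intensity(fusion_channel, circular_roi(ctr, background_radius, shp))
    }, 0)
    background_center <- corners[[which.min(means)]]
  }
  background <- circular_roi(background_center, background_radius, shp)
  if (!is_empty_roi(roi_intersect(background, whole))) {
    stop("background circle overlaps the inclusion ROI; move it")
  }
  structure(list(whole_inclusion = whole, unbleached = unbleached,
                 bleached = bleached, background = background),
            class = "frap_rois")
}

#' Extract a FRAP intensity trace
#'
#' Mean fusion-channel intensity of the bleached, unbleached and
#' background ROIs in every frame of a series.
#'
#' @param series a `frap_series` (from [simulate_frap()] or
#'   [read_frap_series()]).
#' @param rois a `frap_rois`.
#' @param channel channel to trace (default `"fusion"`).
#' @return object of class `frap_trace`: `data.frame` with columns `time`,
#'   `bleached`, `unbleached`, `background`; times strictly increasing,
#'   frame at the smallest (negative) time is the pre-bleach frame.
#' @export
frap_trace <- function(series, rois, channel = "fusion") {
  if (!inherits(rois, "frap_rois")) stop("expected `frap_rois`")
  frames <- series$frames
  times <- series$times
  if (length(frames) < 2L) stop("a trace needs at least 2 frames")
  if (any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  tr <- data.frame(
    time = times,
    bleached = vapply(frames, function(f) {
      mean_intensity(get_channel(f, channel), rois$bleached)
    }, 0),
    unbleached = vapply(frames, function(f) {
      mean_intensity(get_channel(f, channel), rois$unbleached)
    }, 0),
    background = vapply(frames, function(f) {
      mean_intensity(get_channel(f, channel), rois$background)
    }, 0)
  )
  class(tr) <- c("frap_trace", "data.frame")
  tr
}

#' Relative FRAP recovery
#'
#' For each post-bleach frame (`time >= 0`), the background-corrected
#' ratio of bleached to unbleached mean intensity:
#' `r(t) = (bleached(t) - background(t)) / (unbleached(t) - background(t))`.
#' Because both numerator and denominator are background-corrected means
#' from the same frame, `r(t)` is invariant under affine gain/offset
#' rescaling of the image and needs no further normalization. The
#' pre-bleach frame is retained as attribute `prebleach_recovery` for
#' reporting.
#'
#' @param trace a `frap_trace`.
#' @return object of class `recovery_curve`: `data.frame` with columns
#'   `time`, `recovery`; attribute `normalization` records the mode.
#' @export
relative_recovery <- function(trace) {
  if (!inherits(trace, "frap_trace")) stop("expected a `frap_trace`")
  denom <- trace$unbleached - trace$background
  if (any(denom <= 0)) {
    stop("non-positive corrected unbleached mean; background ROI brighter than signal")
  }
  r_all <- (trace$bleached - trace$background) / denom
  post <- trace$time >= 0
  if (sum(post) < 2L) stop("need at least 2 post-bleach frames")
  out <- data.frame(time = trace$time[post], recovery = r_all[post])
  attr(out, "normalization") <- "bleached_over_unbleached"
  attr(out, "prebleach_recovery") <- if (any(!post)) r_all[which(!post)[1L]] else NA_real_
  class(out) <- c("recovery_curve", "data.frame")
  out
}

#' Summarize mobility from a recovery curve
#'
#' Reports `end_recovery = r(t_end)`, `delta_recovery = r(t_end) - r(t0)`,
#' and estimates of the mobile fraction and recovery halftime from a
#' single-exponential fit `r(t) - r(t0) = A * (1 - 2^(-t / halftime))`
#' (Levenberg–Marquardt via [minpack.lm::nlsLM()]). The mobile fraction is
#' `A / (1 - r(t0))`: the fitted recovery amplitude as a fraction of the
#' bleach-induced drop. If the fit fails the summary carries the delta
#' only, flagged by `fit_ok = FALSE`.
#'
#' @param curve a `recovery_curve` with at least 3 post-bleach frames.
#' @return list with `end_recovery`, `delta_recovery`,
#'   `mobile_fraction_estimate`, `halftime_estimate`, `rmse`, `fit_ok`.
#' @export
mobility_summary <- function(curve) {
  if (!inherits(curve, "recovery_curve")) stop("expected a `recovery_curve`")
  if (nrow(curve) < 3L) stop("need at least 3 post-bleach frames")
  t <- curve$time - curve$time[1L]
  r0 <- curve$recovery[1L]
  y <- curve$recovery - r0
  delta <- y[length(y)]
  out <- list(end_recovery = curve$recovery[nrow(curve)],
              delta_recovery = delta,
              mobile_fraction_estimate = NA_real_,
              halftime_estimate = NA_real_, rmse = NA_real_, fit_ok = FALSE)
  drop0 <- 1 - r0
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A * (1 - 2^(-t / tau)),
      start = list(A = max(delta, 0.05), tau = max(t[length(t)] / 4, 1)),
      lower = c(A = 0, tau = 1e-3),
      upper = c(A = 2, tau = 1e4),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    out$rmse <- sqrt(mean(stats::residuals(fit)^2))
    out$halftime_estimate <- unname(cf["tau"])
    if (drop0 > 1e-6) {
      out$mobile_fraction_estimate <- unname(cf["A"]) / drop0
    }
    out$fit_ok <- TRUE
  } else if (drop0 > 1e-6) {
    # fit failure (e.g. an exactly flat curve): report the delta-based
    # estimate, flagged by fit_ok = FALSE
    out$mobile_fraction_estimate <- delta / drop0
  }
  out
}

#' One-call FRAP analysis of a series
#'
#' Convenience wrapper: assigns ROIs from the first post-bleach frame,
#' extracts the trace, computes relative recovery and the mobility
#' summary.
#'
#' @param series a `frap_series`.
#' @param background_center passed to [assign_frap_rois()].
#' @return list with `rois`, `trace`, `curve`, `summary`.
#' @export
analyze_frap <- function(series, background_center = "auto-corner") {
  i0 <- which(series$times >= 0)[1L]
  f0 <- series$frames[[i0]]
  rois <- assign_frap_rois(get_channel(f0, "fusion"),
                           get_channel(f0, "flash"),
                           background_center = background_center)
  tr <- frap_trace(series, rois)
  curve <- relative_recovery(tr)
  list(rois = rois, trace = tr, curve = curve,
       summary = mobility_summary(curve))
}
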