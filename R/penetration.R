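#' External inclusion boundary
#'
#' Segments the inclusion from the cerulean channel (automatic threshold,
#' largest component), scales the ROI by `scale_factor` (default 110%) to
#' obtain the external inclusion boundary, and returns that boundary with
#' the centroid of the scaled (outer) ROI. The scaled ROI is clipped at
#' the image edge; clipped pixels are simply absent from the boundary.
#'
#' @param cerulean_channel intensity matrix containing a segmentable
#'   inclusion.
#' @param scale_factor boundary expansion (default 1.10).
#' @param method thresholding method for [auto_threshold()].
#' @return list of class `external_boundary`: `boundary` (`pixel_roi`),
#'   `centroid`, `outer_roi`, `inclusion`.
#' @export
external_boundary <- function(cerulean_channel, scale_factor = 1.10,
                              method = "otsu") {
  inclusion <- largest_component(auto_threshold(cerulean_channel, method))
  outer <- scale_roi(inclusion, scale_factor)
  structure(list(
    boundary = roi_boundary(outer),
    centroid = roi_centroid(outer),
    outer_roi = outer,
    inclusion = inclusion
  ), class = "external_boundary")
}

#' Internal (antibody-front) boundary
#'
#' Finds the unstained core of an inclusion: antibody intensities within
#' the inclusion region are inverted and automatically thresholded, the
#' bright (i.e. antibody-poor) component is kept, and its boundary is the
#' internal boundary — the front to which antibody penetrated.
#'
#' Degenerate cases follow explicit conventions: if the antibody signal is
#' flat across the region, a flat-low region (no staining anywhere) means
#' the core is the whole inclusion (zero penetration), while a flat-high
#' region (stain fills the inclusion) means an empty core (full
#' penetration). The two are told apart by comparing the region's level
#' against the rest of the image.
#'
#' @param antibody_channel intensity matrix of the antibody stain.
#' @param inclusion `pixel_roi` of the segmented (unscaled) inclusion.
#' @param method thresholding method.
#' @return list of class `internal_boundary`: `core` (`pixel_roi`,
#'   possibly empty), `boundary` (`pixel_roi`, empty iff core is empty),
#'   `empty_core` flag.
#' @export
internal_boundary <- function(antibody_channel, inclusion, method = "otsu") {
  .assert_roi(inclusion)
  if (is_empty_roi(inclusion)) stop("inclusion ROI is empty")
  vals <- antibody_channel[inclusion$coords]
  flat_tol <- 1e-9 * max(1, max(abs(vals)))
  if (diff(range(vals)) <= flat_tol) {
    outside <- antibody_channel[-((inclusion$coords[, 2L] - 1L) *
                                    nrow(antibody_channel) + inclusion$coords[, 1L])]
    filled <- length(outside) > 0 && mean(vals) > mean(outside) +
      stats::sd(outside) + flat_tol
    if (filled) {
      empty <- pixel_roi(NULL, inclusion$image_shape)
      return(structure(list(core = empty, boundary = empty, empty_core = TRUE),
                       class = "internal_boundary"))
    }
    return(structure(list(core = inclusion,
                          boundary = roi_boundary(inclusion),
                          empty_core = FALSE),
                     class = "internal_boundary"))
  }
  # invert within the inclusion's region and threshold the antibody-poor core
  inv <- matrix(0, nrow(antibody_channel), ncol(antibody_channel))
  inv[inclusion$coords] <- max(vals) - vals
  core_all <- tryCatch(auto_threshold(inv, method), error = function(e) NULL)
  if (is.null(core_all)) {
    core <- pixel_roi(NULL, inclusion$image_shape)
  } else {
    core <- roi_intersect(core_all, inclusion)
  }
  if (is_empty_roi(core)) {
    empty <- pixel_roi(NULL, inclusion$image_shape)
    return(structure(list(core = empty, boundary = empty, empty_core = TRUE),
                     class = "internal_boundary"))
  }
  core <- largest_component(core)
  structure(list(core = core, boundary = roi_boundary(core),
                 empty_core = FALSE),
            class = "internal_boundary")
}

#' Antibody penetration depth
#'
#' The penetration of the stain into the inclusion, in pixels: mean
#' Euclidean distance from the outer-ROI centroid to the external boundary
#' pixels, minus the mean distance from the same centroid to the internal
#' boundary pixels. An empty internal boundary (stain filled the
#' inclusion) is reported by convention as full penetration, i.e.
#' `penetration = external_mean_distance` — the limit of the formula as
#' the unstained core shrinks onto the centroid.
#'
#' Note the geometric floor: because the external boundary comes from the
#' 110%-scaled ROI, even a zero-depth surface stain measures a penetration
#' of about 10% of the inclusion radius. Both raw distances are always
#' reported so the floor can be subtracted.
#'
#' @param outer an `external_boundary`.
#' @param internal an `internal_boundary`.
#' @param inclusion_id optional identifier.
#' @param ratio optional FlAsH:Cerulean maturity ratio for pairing.
#' @return one-row `data.frame` of class `penetration_measurement`:
#'   `inclusion_id`, `ratio`, `external_mean_distance`,
#'   `internal_mean_distance`, `penetration`, `full_penetration`.
#' @export
penetration <- function(outer, internal, inclusion_id = NA, ratio = NA_real_) {
  if (!inherits(outer, "external_boundary")) stop("expected `external_boundary`")
  if (!inherits(internal, "internal_boundary")) stop("expected `internal_boundary`")
  if (is_empty_roi(outer$boundary)) stop("empty external boundary")
  ctr <- outer$centroid
  dist_to <- function(roi) {
    mean(sqrt((roi$coords[, 1L] - ctr[1L])^2 + (roi$coords[, 2L] - ctr[2L])^2))
  }
  ext <- dist_to(outer$boundary)
  if (internal$empty_core || is_empty_roi(internal$boundary)) {
    int <- 0
    pen <- ext
    full <- TRUE
  } else {
    int <- dist_to(internal$boundary)
    pen <- ext - int
    full <- FALSE
  }
  out <- data.frame(inclusion_id = inclusion_id, ratio = ratio,
                    external_mean_distance = ext,
                    internal_mean_distance = int,
                    penetration = pen, full_penetration = full,
                    stringsAsFactors = FALSE)
  class(out) <- c("penetration_measurement", "data.frame")
  out
}

#' One-call penetration measurement on a scene
#'
#' Segments the inclusion from the cerulean channel, finds the internal
#' antibody front, and measures penetration.
#'
#' @param cerulean_channel,antibody_channel intensity matrices.
#' @param scale_factor external-boundary expansion (default 1.10).
#' @param inclusion_id,ratio carried into the measurement row.
#' @return `penetration_measurement` row.
#' @export
measure_penetration <- function(cerulean_channel, antibody_channel,
                                scale_factor = 1.10,
                                inclusion_id = NA, ratio = NA_real_) {
  outer <- external_boundary(cerulean_channel, scale_factor)
  inner <- internal_boundary(antibody_channel, outer$inclusion)
  penetration(outer, inner, inclusion_id = inclusion_id, ratio = ratio)
}
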