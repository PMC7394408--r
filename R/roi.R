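#' Pixel-set regions of interest
#'
#' A `pixel_roi` is a finite set of integer pixel coordinates inside an image
#' of known size. It is the unit every image analysis in this package
#' consumes: inclusions segmented from the cerulean channel, bleached and
#' unbleached FRAP regions, background circles, radial zones. Coordinates are
#' 1-based `(row, col)` pairs with the origin at the top-left, matching R's
#' matrix indexing; ROIs are sets of pixel centers (no sub-pixel contours),
#' which keeps the set algebra exact.
#'
#' @param coords two-column integer matrix (or data.frame) of `(row, col)`
#'   pixel coordinates. Duplicates are removed; rows are stored sorted by
#'   `(row, col)` so equal sets have identical representations.
#' @param image_shape integer vector `c(rows, cols)` of the parent image.
#' @param metadata named list of provenance fields (e.g. the threshold
#'   method that produced the ROI).
#' @return an object of class `pixel_roi`.
#' @examples
#' r <- pixel_roi(cbind(c(2, 2, 3), c(2, 3, 2)), image_shape = c(8, 8))
#' roi_size(r)
#' @export
pixel_roi <- function(coords, image_shape, metadata = list()) {
  if (is.data.frame(coords)) coords <- as.matrix(coords)
  if (is.null(coords) || length(coords) == 0L) {
    coords <- matrix(integer(0), ncol = 2L)
  }
  if (ncol(coords) != 2L) stop("`coords` must have two columns (row, col)")
  storage.mode(coords) <- "integer"
  image_shape <- as.integer(image_shape)
  if (length(image_shape) != 2L || any(image_shape < 1L)) {
    stop("`image_shape` must be c(rows, cols), both >= 1")
  }
  if (nrow(coords)) {
    bad <- coords[, 1L] < 1L | coords[, 1L] > image_shape[1L] |
      coords[, 2L] < 1L | coords[, 2L] > image_shape[2L]
    if (any(bad)) stop("ROI coordinates fall outside the image")
    o <- order(coords[, 1L], coords[, 2L])
    coords <- coords[o, , drop = FALSE]
    coords <- coords[!duplicated(coords), , drop = FALSE]
  }
  dimnames(coords) <- list(NULL, c("row", "col"))
  structure(
    list(coords = coords, image_shape = image_shape, metadata = metadata),
    class = "pixel_roi"
  )
}

#' @export
print.pixel_roi <- function(x, ...) {
  cat(sprintf(
    "<pixel_roi> %d px in %d x %d image\n",
    nrow(x$coords), x$image_shape[1L], x$image_shape[2L]
  ))
  if (length(x$metadata)) {
    cat("  metadata:", paste(names(x$metadata), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname pixel_roi
#' @param roi a `pixel_roi`.
#' @export
roi_size <- function(roi) nrow(roi$coords)

#' @rdname pixel_roi
#' @export
is_empty_roi <- function(roi) nrow(roi$coords) == 0L

.assert_roi <- function(roi) {
  if (!inherits(roi, "pixel_roi")) stop("expected a `pixel_roi`")
  invisible(roi)
}

.assert_same_shape <- function(a, b) {
  if (!identical(a$image_shape, b$image_shape)) {
    stop("ROIs come from images of different shapes")
  }
}

# linear (column-major) pixel index; the canonical set key
.roi_index <- function(roi) {
  (roi$coords[, 2L] - 1L) * roi$image_shape[1L] + roi$coords[, 1L]
}

.index_to_roi <- function(idx, image_shape, metadata = list()) {
  idx <- sort(unique(as.integer(idx)))
  nr <- image_shape[1L]
  pixel_roi(
    cbind(((idx - 1L) %% nr) + 1L, ((idx - 1L) %/% nr) + 1L),
    image_shape, metadata
  )
}

#' Convert between ROIs and logical masks
#'
#' @param roi a `pixel_roi`.
#' @return `roi_mask()` returns a logical matrix of the image shape with
#'   `TRUE` at ROI pixels; `mask_roi()` builds a `pixel_roi` from such a
#'   mask.
#' @export
roi_mask <- function(roi) {
  .assert_roi(roi)
  m <- matrix(FALSE, roi$image_shape[1L], roi$image_shape[2L])
  m[roi$coords] <- TRUE
  m
}

#' @rdname roi_mask
#' @param mask logical matrix.
#' @param metadata provenance list.
#' @export
mask_roi <- function(mask, metadata = list()) {
  pixel_roi(which(mask, arr.ind = TRUE), dim(mask), metadata)
}

#' ROI set algebra
#'
#' Exact set operations on pixel coordinate sets. `roi_subtract()` is the
#' difference `a \ b` used to derive the bleached FRAP region by removing
#' the unbleached pixel coordinates from the whole-inclusion ROI;
#' `roi_union()` and `roi_intersect()` complete the algebra so that
#' `roi_union(roi_subtract(a, b), roi_intersect(a, b))` always recovers `a`.
#'
#' @param a,b `pixel_roi` objects sharing one image shape.
#' @return a `pixel_roi` (possibly empty; emptiness is visible via
#'   [is_empty_roi()]).
#' @export
roi_subtract <- function(a, b) {
  .assert_roi(a); .assert_roi(b); .assert_same_shape(a, b)
  .index_to_roi(setdiff(.roi_index(a), .roi_index(b)), a$image_shape)
}

#' @rdname roi_subtract
#' @export
roi_union <- function(a, b) {
  .assert_roi(a); .assert_roi(b); .assert_same_shape(a, b)
  .index_to_roi(union(.roi_index(a), .roi_index(b)), a$image_shape)
}

#' @rdname roi_subtract
#' @export
roi_intersect <- function(a, b) {
  .assert_roi(a); .assert_roi(b); .assert_same_shape(a, b)
  .index_to_roi(intersect(.roi_index(a), .roi_index(b)), a$image_shape)
}

#' @rdname roi_subtract
#' @export
roi_equal <- function(a, b) {
  identical(a$image_shape, b$image_shape) && identical(a$coords, b$coords)
}

#' Automatic intensity thresholding
#'
#' Segments the bright pixels of a single intensity channel, the way
#' inclusions are identified from cerulean fluorescence. The default method
#' is Otsu's between-class variance criterion (computed by
#' [EBImage::otsu()] on the intensity histogram); the method used is
#' recorded in the returned ROI's metadata together with the threshold on
#' the original intensity scale. Pixels strictly above the threshold are
#' returned.
#'
#' @param channel numeric matrix of intensities.
#' @param method `"otsu"` (default) or `"mean"` (threshold at the image
#'   mean, a deliberately crude fallback for diagnostics).
#' @return `pixel_roi` with `metadata$threshold_method` and
#'   `metadata$threshold`.
#' @details A constant image carries no threshold information and raises an
#'   error rather than returning an arbitrary segmentation.
#' @export
auto_threshold <- function(channel, method = c("otsu", "mean")) {
  method <- match.arg(method)
  if (!is.matrix(channel) || !is.numeric(channel)) {
    stop("`channel` must be a numeric matrix")
  }
  rng <- range(channel)
  if (!is.finite(diff(rng)) || diff(rng) <= 0) {
    stop("cannot threshold a constant image (degenerate input)")
  }
  thr <- switch(method,
    otsu = {
      norm <- (channel - rng[1L]) / diff(rng)
      t01 <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1), levels = 256)
      rng[1L] + t01 * diff(rng)
    },
    mean = mean(channel)
  )
  mask <- channel > thr
  if (!any(mask)) stop("threshold selected no pixels (degenerate input)")
  mask_roi(mask, metadata = list(threshold_method = method, threshold = thr))
}

# 8-connected component labels by iterative min-label propagation.
# Returns an integer matrix, 0 = background; labels are renumbered so that
# label order follows the component's smallest linear index.
.label_components8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  lab[mask] <- which(mask)          # unique seed labels (column-major index)
  big <- .Machine$integer.max
  shift <- function(m, dr, dc) {
    out <- matrix(big, nr, nc)
    rs <- max(1L, 1L + dr):min(nr, nr + dr)
    cs <- max(1L, 1L + dc):min(nc, nc + dc)
    out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
    out
  }
  repeat {
    cur <- lab
    cur[!mask] <- big
    nb <- cur
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      nb <- pmin(nb, shift(cur, dr, dc))
    }
    nb[!mask] <- 0L
    nb[mask] <- pmin(nb[mask], lab[mask])
    if (identical(nb, lab)) break
    lab <- nb
  }
  lab
}

#' Largest connected component of an ROI
#'
#' Thresholding can return satellite specks alongside the inclusion of
#' interest; this keeps only the largest 8-connected component. An exact
#' area tie is broken in favor of the component containing the
#' lexicographically smallest `(row, col)` pixel, so the result is
#' deterministic.
#'
#' @param roi non-empty `pixel_roi`.
#' @return `pixel_roi` of the winning component (metadata preserved).
#' @export
largest_component <- function(roi) {
  .assert_roi(roi)
  if (is_empty_roi(roi)) stop("cannot take the largest component of an empty ROI")
  lab <- .label_components8(roi_mask(roi))
  labs <- lab[roi$coords]
  sizes <- table(labs)
  best <- as.integer(names(sizes)[sizes == max(sizes)])
  if (length(best) > 1L) {
    # coords are sorted by (row, col): first hit of a tied label wins
    labs_in_order <- labs[labs %in% best]
    best <- labs_in_order[[1L]]
  }
  keep <- roi$coords[labs == best, , drop = FALSE]
  pixel_roi(keep, roi$image_shape, roi$metadata)
}

#' ROI centroid
#'
#' Arithmetic mean of the member pixel coordinates, in fractional pixels.
#'
#' @param roi non-empty `pixel_roi`.
#' @return named numeric `c(row, col)`.
#' @export
roi_centroid <- function(roi) {
  .assert_roi(roi)
  if (is_empty_roi(roi)) stop("centroid of an empty ROI is undefined")
  c(row = mean(roi$coords[, 1L]), col = mean(roi$coords[, 2L]))
}

#' ROI boundary
#'
#' The boundary of an ROI is the subset of its pixels having at least one
#' 4-neighbor (up/down/left/right) outside the ROI; positions beyond the
#' image edge count as outside. Paired with 8-connected components this is
#' the standard combination that keeps boundaries closed.
#'
#' @param roi non-empty `pixel_roi`.
#' @return `pixel_roi` of boundary pixels (always non-empty for a non-empty
#'   input).
#' @export
roi_boundary <- function(roi) {
  .assert_roi(roi)
  if (is_empty_roi(roi)) stop("boundary of an empty ROI is undefined")
  m <- roi_mask(roi)
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- m
  interior <- pad[1:nr, 2:(nc + 1L)] & pad[3:(nr + 2L), 2:(nc + 1L)] &
    pad[2:(nr + 1L), 1:nc] & pad[2:(nr + 1L), 3:(nc + 2L)]
  mask_roi(m & !interior, metadata = roi$metadata)
}

#' Geometric scaling of an ROI about its centroid
#'
#' Scales the region by `factor` about its own centroid, the operation used
#' to expand a segmented inclusion by 110% to obtain its external boundary.
#' The scaled region is produced by inverse mapping: a candidate pixel
#' belongs to the scaled ROI when its pre-image under the scaling (rounded
#' to the nearest pixel center) belongs to the original ROI. This
#' re-rasterizes the filled scaled shape exactly, rather than approximating
#' it with morphological dilation, and clips the result to the image.
#'
#' @param roi non-empty `pixel_roi`.
#' @param factor positive scale factor (1.10 expands by 10%).
#' @return `pixel_roi`; `factor = 1` returns the input set unchanged.
#' @export
scale_roi <- function(roi, factor) {
  .assert_roi(roi)
  if (is_empty_roi(roi)) stop("cannot scale an empty ROI")
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0) {
    stop("`factor` must be a positive scalar")
  }
  if (factor == 1) return(roi)
  ctr <- roi_centroid(roi)
  m <- roi_mask(roi)
  rr <- range(roi$coords[, 1L]); cr <- range(roi$coords[, 2L])
  r0 <- floor(ctr[1L] + (rr[1L] - ctr[1L]) * factor) - 1L
  r1 <- ceiling(ctr[1L] + (rr[2L] - ctr[1L]) * factor) + 1L
  c0 <- floor(ctr[2L] + (cr[1L] - ctr[2L]) * factor) - 1L
  c1 <- ceiling(ctr[2L] + (cr[2L] - ctr[2L]) * factor) + 1L
  rows <- max(1L, r0):min(roi$image_shape[1L], r1)
  cols <- max(1L, c0):min(roi$image_shape[2L], c1)
  g <- expand.grid(row = rows, col = cols)
  pr <- round(ctr[1L] + (g$row - ctr[1L]) / factor)
  pc <- round(ctr[2L] + (g$col - ctr[2L]) / factor)
  ok <- pr >= 1L & pr <= roi$image_shape[1L] & pc >= 1L & pc <= roi$image_shape[2L]
  ok[ok] <- m[cbind(pr[ok], pc[ok])]
  if (!any(ok)) stop("scaled ROI falls entirely outside the image")
  pixel_roi(cbind(g$row[ok], g$col[ok]), roi$image_shape, roi$metadata)
}

#' Mean intensity within an ROI
#'
#' The per-region readout everything downstream consumes: the arithmetic
#' mean of the channel values over the ROI coordinates.
#'
#' @param channel numeric intensity matrix with the ROI's image shape.
#' @param roi non-empty `pixel_roi`.
#' @return scalar mean intensity (a.u.).
#' @export
mean_intensity <- function(channel, roi) {
  .assert_roi(roi)
  if (is_empty_roi(roi)) stop("mean intensity of an empty ROI is undefined")
  if (!identical(dim(channel), as.integer(roi$image_shape))) {
    stop("channel dimensions do not match the ROI's image shape")
  }
  mean(channel[roi$coords])
}

#' Circular ROI
#'
#' Rasterized disk: all pixels whose center lies within `radius` of
#' `center`, clipped to the image. Used for the fixed-radius (default 25
#' px) background circle in FRAP normalization.
#'
#' @param center numeric `c(row, col)` center (fractional allowed).
#' @param radius positive radius in pixels.
#' @param image_shape `c(rows, cols)`.
#' @return `pixel_roi`; errors if the disk lies entirely outside the image.
#' @export
circular_roi <- function(center, radius, image_shape) {
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0) {
    stop("`radius` must be a positive scalar")
  }
  image_shape <- as.integer(image_shape)
  rows <- max(1L, floor(center[1L] - radius)):min(image_shape[1L], ceiling(center[1L] + radius))
  cols <- max(1L, floor(center[2L] - radius)):min(image_shape[2L], ceiling(center[2L] + radius))
  if (!length(rows) || !length(cols) || rows[1L] > rows[length(rows)] ||
      cols[1L] > cols[length(cols)]) {
    stop("circular ROI lies entirely outside the image")
  }
  g <- expand.grid(row = rows, col = cols)
  keep <- (g$row - center[1L])^2 + (g$col - center[2L])^2 <= radius^2
  if (!any(keep)) stop("circular ROI lies entirely outside the image")
  pixel_roi(cbind(g$row[keep], g$col[keep]), image_shape,
            metadata = list(center = as.numeric(center), radius = radius))
}

#' Serialize ROIs as run-length encodings
#'
#' `roi_to_json()` writes a compact row-wise run-length encoding
#' (`row`, `col_start`, `length` triples plus the image shape);
#' `roi_from_json()` inverts it. The encoding is stable across platforms,
#' so serialized ROIs are byte-reproducible.
#'
#' @param roi a `pixel_roi`.
#' @param path optional file path; if omitted the JSON string is returned.
#' @export
roi_to_json <- function(roi, path = NULL) {
  .assert_roi(roi)
  runs <- if (nrow(roi$coords)) {
    co <- roi$coords
    brk <- c(TRUE, diff(co[, 1L]) != 0L | diff(co[, 2L]) != 1L)
    grp <- cumsum(brk)
    starts <- which(brk)
    data.frame(
      row = co[starts, 1L],
      col_start = co[starts, 2L],
      length = as.integer(tabulate(grp))
    )
  } else {
    data.frame(row = integer(0), col_start = integer(0), length = integer(0))
  }
  obj <- list(image_shape = roi$image_shape, rle = runs, metadata = roi$metadata)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' @rdname roi_to_json
#' @param json JSON string or path to a JSON file produced by
#'   [roi_to_json()].
#' @export
roi_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  runs <- obj$rle
  coords <- if (length(runs) && nrow(runs)) {
    do.call(rbind, lapply(seq_len(nrow(runs)), function(i) {
      cbind(runs$row[i], runs$col_start[i] + seq_len(runs$length[i]) - 1L)
    }))
  } else {
    matrix(integer(0), ncol = 2L)
  }
  md <- obj$metadata
  pixel_roi(coords, obj$image_shape, if (is.null(md)) list() else as.list(md))
}

#' Import an ROI from a label-mask TIFF
#'
#' Reads a single-page TIFF whose pixel values are integer labels and
#' returns the pixels carrying `label` (after rescaling from the TIFF's
#' unit range back to integers).
#'
#' @param path TIFF file path.
#' @param label integer label to extract (default: every non-zero pixel).
#' @export
roi_from_labelmask <- function(path, label = NULL) {
  img <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  mask <- if (is.null(label)) img != 0 else img == label
  if (!any(mask)) stop("label mask contains no matching pixels")
  mask_roi(mask, metadata = list(source = path, label = label))
}
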