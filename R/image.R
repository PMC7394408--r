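#' Multi-channel image container
#'
#' A named list of equally sized numeric matrices, one per fluorescence
#' channel (e.g. `cerulean`, `flash`, `tmr`, `antibody`, `hoechst`).
#' Channel names carry the biological role; the container enforces only
#' shared dimensions and numeric intensities.
#'
#' @param channels named list of numeric matrices with identical
#'   dimensions.
#' @return object of class `multichannel_image`.
#' @export
multichannel_image <- function(channels) {
  if (!is.list(channels) || is.null(names(channels)) ||
      any(!nzchar(names(channels)))) {
    stop("`channels` must be a named list of matrices")
  }
  dims <- lapply(channels, dim)
  if (any(vapply(channels, function(ch) !is.matrix(ch) || !is.numeric(ch), TRUE))) {
    stop("every channel must be a numeric matrix")
  }
  if (length(unique(dims)) != 1L) stop("all channels must share one shape")
  structure(list(channels = channels, shape = as.integer(dims[[1L]])),
            class = "multichannel_image")
}

#' @export
print.multichannel_image <- function(x, ...) {
  cat(sprintf("<multichannel_image> %d x %d px, channels: %s\n",
              x$shape[1L], x$shape[2L],
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' @rdname multichannel_image
#' @param img a `multichannel_image`.
#' @param name channel name.
#' @export
get_channel <- function(img, name) {
  if (!inherits(img, "multichannel_image")) stop("expected a `multichannel_image`")
  ch <- img$channels[[name]]
  if (is.null(ch)) stop(sprintf("channel '%s' not present (have: %s)",
                                name, paste(names(img$channels), collapse = ", ")))
  ch
}

# Intensities are written as 16-bit TIFF pages scaled by `scale`; the scale
# and the channel order travel in the JSON sidecar so reads invert exactly.
.TIFF_SCALE <- 65535

#' Write / read multi-channel images as multi-page TIFF
#'
#' One TIFF page per channel, 16-bit, with a JSON sidecar (`<path>.json`)
#' recording channel names and the intensity scale. [read_image_tiff()]
#' restores the `multichannel_image`; without a sidecar, channel names must
#' be supplied.
#'
#' @param img `multichannel_image`.
#' @param path output TIFF path.
#' @export
write_image_tiff <- function(img, path) {
  if (!inherits(img, "multichannel_image")) stop("expected a `multichannel_image`")
  pages <- lapply(img$channels, function(ch) {
    pmin(pmax(ch / .TIFF_SCALE, 0), 1)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  sidecar <- list(channels = names(img$channels), intensity_scale = .TIFF_SCALE)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_image_tiff
#' @param channel_names optional character vector naming the pages when no
#'   sidecar exists.
#' @export
read_image_tiff <- function(path, channel_names = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  side <- paste0(path, ".json")
  scale <- .TIFF_SCALE
  if (file.exists(side)) {
    sc <- jsonlite::fromJSON(side)
    if (is.null(channel_names)) channel_names <- sc$channels
    if (!is.null(sc$intensity_scale)) scale <- sc$intensity_scale
  }
  if (is.null(channel_names)) {
    stop("no sidecar found; supply `channel_names` for the TIFF pages")
  }
  if (length(channel_names) != length(pages)) {
    stop("number of channel names does not match TIFF pages")
  }
  chans <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]
    p * scale
  })
  names(chans) <- channel_names
  multichannel_image(chans)
}
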