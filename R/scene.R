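#' Multichannel scene container
#'
#' A `multichannel_scene` holds a set of named intensity channels sharing one
#' pixel grid, together with the physical pixel size in micrometres. Channels
#' are numeric matrices (rows = image rows, columns = image columns) for 2D
#' scenes, or 3D arrays (`row x col x slice`) for z-stacks. Pixel `(i, j)`
#' (1-based) has its centre at physical position
#' `x = (j - 0.5) * pixel_size`, `y = (i - 0.5) * pixel_size`.
#'
#' @param channels Named list of numeric matrices (or 3D arrays, all of equal
#'   dimension).
#' @param pixel_size Pixel edge length in micrometres per pixel.
#' @return An object of class `multichannel_scene`.
#' @export
new_scene <- function(channels, pixel_size = 1) {
  if (length(channels) == 0 || is.null(names(channels)) || any(names(channels) == "")) {
    abort("`channels` must be a non-empty named list of matrices or arrays.")
  }
  check_number(pixel_size, "pixel_size", min = 0, strict_min = TRUE)
  dims <- unique(lapply(channels, dim))
  if (length(dims) != 1) abort("all channels must share one pixel grid.")
  structure(
    list(channels = channels, pixel_size = pixel_size),
    class = "multichannel_scene"
  )
}

#' @export
print.multichannel_scene <- function(x, ...) {
  d <- dim(x$channels[[1]])
  kind <- if (length(d) == 3) sprintf("z-stack (%d slices)", d[3]) else "2D scene"
  cat(sprintf(
    "<multichannel_scene> %s, %d x %d px @ %g um/px\n  channels: %s\n",
    kind, d[1], d[2], x$pixel_size, paste(names(x$channels), collapse = ", ")
  ))
  invisible(x)
}

#' @export
dim.multichannel_scene <- function(x) dim(x$channels[[1]])

#' Extract one channel of a scene
#'
#' @param scene A `multichannel_scene`.
#' @param channel Channel name.
#' @return The channel's matrix or array.
#' @export
scene_channel <- function(scene, channel) {
  stopifnot(inherits(scene, "multichannel_scene"))
  if (!channel %in% names(scene$channels)) {
    abort(sprintf(
      "channel '%s' not present in scene (available: %s).",
      channel, paste(names(scene$channels), collapse = ", ")
    ))
  }
  scene$channels[[channel]]
}

scene_is_stack <- function(scene) length(dim(scene$channels[[1]])) == 3

#' Write a scene to multi-page TIFF plus a JSON channel map
#'
#' Intensities are stored as 16-bit TIFF pages; each channel is scaled by the
#' scene-wide maximum, which is recorded in the channel map so that
#' [read_scene()] restores the original arbitrary-unit floats (up to 16-bit
#' quantization). For z-stacks, pages are ordered channel-major
#' (all slices of channel 1, then channel 2, ...).
#'
#' @param scene A `multichannel_scene`.
#' @param tiff_path Output TIFF path.
#' @param map_path Output JSON channel-map path.
#' @return Invisibly, the channel map list.
#' @export
write_scene <- function(scene, tiff_path, map_path) {
  stopifnot(inherits(scene, "multichannel_scene"))
  scale <- max(1e-12, max(vapply(scene$channels, max, numeric(1))))
  pages <- list()
  entries <- list()
  for (nm in names(scene$channels)) {
    ch <- scene$channels[[nm]]
    if (length(dim(ch)) == 3) {
      for (s in seq_len(dim(ch)[3])) pages[[length(pages) + 1L]] <- ch[, , s] / scale
      entries[[nm]] <- list(first_page = length(pages) - dim(ch)[3] + 1L, n_slices = dim(ch)[3])
    } else {
      pages[[length(pages) + 1L]] <- ch / scale
      entries[[nm]] <- list(first_page = length(pages), n_slices = 1L)
    }
  }
  tiff::writeTIFF(pages, tiff_path, bits.per.sample = 16L)
  channel_map <- list(
    pixel_size = scene$pixel_size,
    intensity_scale = scale,
    channels = entries
  )
  jsonlite::write_json(channel_map, map_path, auto_unbox = TRUE, digits = NA)
  invisible(channel_map)
}

#' Read a scene written by [write_scene()]
#'
#' @param tiff_path TIFF path.
#' @param map_path JSON channel-map path.
#' @return A `multichannel_scene`.
#' @export
read_scene <- function(tiff_path, map_path) {
  channel_map <- jsonlite::read_json(map_path)
  pages <- tiff::readTIFF(tiff_path, all = TRUE)
  scale <- channel_map$intensity_scale
  channels <- lapply(channel_map$channels, function(e) {
    n <- as.integer(e$n_slices)
    first <- as.integer(e$first_page)
    if (n == 1L) {
      pages[[first]] * scale
    } else {
      arr <- array(0, c(dim(pages[[first]]), n))
      for (s in seq_len(n)) arr[, , s] <- pages[[first + s - 1L]] * scale
      arr
    }
  })
  new_scene(channels, pixel_size = as.numeric(channel_map$pixel_size))
}
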