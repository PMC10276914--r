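# image_stack: the in-memory raster container used by every imaging stage.
# Pixels are stored as a numeric array [row, col, channel, z] with the origin
# at the top-left corner and 0-based coordinates in all emitted tables.

#' Construct a multi-channel image stack
#'
#' @param data Numeric array. Accepted shapes: `h x w` (one channel, one z),
#'   `h x w x c` (one z) or `h x w x c x z`. Intensities must be finite and
#'   non-negative.
#' @param pixel_size_um Physical size of one pixel side in micrometres.
#' @param channels Character vector of channel role labels, one per channel.
#'   Conventional roles: `"nuclei"`, `"marker"`, `"deposit"`, `"yfp"`,
#'   `"membrane"`.
#' @return An `image_stack` object.
#' @export
#' @examples
#' st <- image_stack(array(0, c(32, 32, 2)), pixel_size_um = 0.3,
#'                   channels = c("nuclei", "deposit"))
#' dim(st)
image_stack <- function(data, pixel_size_um, channels = NULL) {
  check_scalar(pixel_size_um, "pixel_size_um", min = 0, strict = TRUE)
  if (is.matrix(data)) dim(data) <- c(dim(data), 1L, 1L)
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 4L)
    abort("`data` must have 2, 3 or 4 dimensions (h, w, channel, z).")
  if (any(!is.finite(data)) || any(data < 0))
    abort("image intensities must be finite and >= 0.")
  n_ch <- dim(data)[3]
  if (is.null(channels)) channels <- paste0("ch", seq_len(n_ch))
  if (length(channels) != n_ch)
    abort("`channels` must name every channel once.")
  structure(data,
    pixel_size_um = pixel_size_um,
    channels = as.character(channels),
    class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<image_stack> %d x %d px, %d channel(s) [%s], %d z-slice(s), %.4g um/px\n",
              d[1], d[2], d[3], paste(attr(x, "channels"), collapse = ", "),
              d[4], attr(x, "pixel_size_um")))
  invisible(x)
}

#' Channel role labels of an image stack
#' @param stack An `image_stack`.
#' @return Character vector of channel roles.
#' @export
channel_roles <- function(stack) attr(stack, "channels")

#' Pixel size of an image stack
#' @param stack An `image_stack`.
#' @return Micrometres per pixel side.
#' @export
pixel_size <- function(stack) attr(stack, "pixel_size_um")

#' Extract one 2-D plane from a stack
#'
#' @param stack An `image_stack`.
#' @param channel Channel role label or integer index.
#' @param z Z-slice index (default 1).
#' @return A numeric matrix.
#' @export
get_plane <- function(stack, channel = 1L, z = 1L) {
  ci <- resolve_channel(stack, channel)
  if (z < 1 || z > dim(stack)[4]) abort("`z` out of range.")
  unclass(stack)[, , ci, z, drop = TRUE][, , drop = TRUE]
}

resolve_channel <- function(stack, channel) {
  if (is.character(channel)) {
    ci <- match(channel, attr(stack, "channels"))
    if (is.na(ci))
      abort(sprintf("no channel with role '%s' (available: %s).", channel,
                    paste(attr(stack, "channels"), collapse = ", ")))
    return(ci)
  }
  if (channel < 1 || channel > dim(stack)[3]) abort("channel index out of range.")
  as.integer(channel)
}

#' Maximum-intensity projection across z
#'
#' Collapses a z-stack to a single plane by the per-pixel maximum, the
#' composite used before quantification of confocal stacks. With a single
#' z-slice this is the identity.
#'
#' @param x An `image_stack` or an `h x w x z` numeric array or a matrix.
#' @param channel For stacks, which channel to project (role or index).
#' @return A numeric matrix.
#' @export
max_project <- function(x, channel = 1L) {
  if (inherits(x, "image_stack")) {
    ci <- resolve_channel(x, channel)
    arr <- unclass(x)[, , ci, , drop = FALSE]
    dim(arr) <- dim(arr)[c(1, 2, 4)]
  } else if (is.matrix(x)) {
    return(x)
  } else if (length(dim(x)) == 3L) {
    arr <- x
  } else {
    abort("`x` must be an image_stack, a matrix or an h x w x z array.")
  }
  apply(arr, c(1, 2), max)
}
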