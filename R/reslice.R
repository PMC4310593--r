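#' Two-channel image stack container
#'
#' An acquisition stack of en-face frames: each channel is a 3-D array with
#' dimensions (y, x, z), frames stacked along the third dimension at `z_step`
#' um intervals.
#'
#' @param channel_af,channel_shg 3-D arrays of identical dimensions.
#' @param px_lateral In-plane pixel size (um/px, both x and y).
#' @param z_step Axial step between frames (um).
#' @return An object of class `ecti_stack`.
#' @export
ecti_stack <- function(channel_af, channel_shg, px_lateral, z_step) {
  stopifnot(length(dim(channel_af)) == 3L,
            identical(dim(channel_af), dim(channel_shg)),
            px_lateral > 0, z_step > 0)
  structure(list(channel_af = channel_af, channel_shg = channel_shg,
                 px_lateral = px_lateral, z_step = z_step),
            class = "ecti_stack")
}

#' Reslice an image stack into a cross-sectional view
#'
#' Extracts the x-z plane at a given y index (or the y-z plane at a given x
#' index) from a two-channel stack, producing the depth-vs-lateral
#' [cross_section()] on which all interface measurements are made. The axial
#' pixel size of the result is the stack's z-step.
#'
#' @param volume An [ecti_stack()].
#' @param plane `"xz"` or `"yz"`.
#' @param index 1-based index of the fixed coordinate (y for `"xz"`,
#'   x for `"yz"`).
#' @return A [cross_section()] with rows = depth, columns = lateral position.
#' @export
reslice_stack <- function(volume, plane = c("xz", "yz"), index) {
  stopifnot(inherits(volume, "ecti_stack"))
  plane <- match.arg(plane)
  d <- dim(volume$channel_af)   # (y, x, z)
  pick <- function(arr) {
    if (plane == "xz") {
      if (index < 1 || index > d[1]) {
        stop("y index ", index, " out of bounds [1, ", d[1], "]")
      }
      t(arr[index, , ])         # (x, z) -> (z, x)
    } else {
      if (index < 1 || index > d[2]) {
        stop("x index ", index, " out of bounds [1, ", d[2], "]")
      }
      t(arr[, index, ])         # (y, z) -> (z, y)
    }
  }
  cross_section(pick(volume$channel_af), pick(volume$channel_shg),
                px_lateral = volume$px_lateral, px_axial = volume$z_step)
}
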