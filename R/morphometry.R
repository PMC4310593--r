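#' Detect the epithelial surface in the autofluorescence channel
#'
#' Finds, per lateral column, the smallest depth at which autofluorescence
#' exceeds a fraction of the channel's robust maximum (its 99th percentile),
#' then median-filters the surface over 5 columns. The surface includes the
#' keratinized band: it is the top of all autofluorescent signal. Columns
#' without suprathreshold signal are interpolated from their neighbors; if
#' more than half the columns are empty a detection error is raised.
#'
#' @param section A [cross_section()].
#' @param threshold_frac Detection fraction of the robust maximum
#'   (default 0.2).
#' @return An object of class `surface_line`: list with `depth_um`
#'   (per-column surface depth), `x_um`, and the intensity `level` used.
#' @export
detect_surface <- function(section, threshold_frac = 0.2) {
  stopifnot(inherits(section, "cross_section"),
            threshold_frac > 0, threshold_frac < 1)
  af <- section$channel_af
  if (diff(range(af)) < .Machine$double.eps) {
    stop("detection error: autofluorescence channel is constant")
  }
  level <- threshold_frac * quantile(af, 0.99, names = FALSE)
  first_row <- apply(af >= level, 2, function(col) {
    w <- which(col)
    if (length(w) == 0L) NA_integer_ else w[1]
  })
  if (mean(is.na(first_row)) > 0.5) {
    stop("detection error: no suprathreshold surface pixel in more than ",
         "half of the columns")
  }
  nx <- length(first_row)
  xs <- (seq_len(nx) - 1) * section$px_lateral
  if (anyNA(first_row)) {
    nn <- which(!is.na(first_row))
    first_row <- round(approx(nn, first_row[nn], xout = seq_len(nx),
                              rule = 2)$y)
  }
  if (nx >= 5) first_row <- runmed(first_row, 5, endrule = "median")
  structure(list(depth_um = (first_row - 1) * section$px_axial,
                 x_um = xs, level = level),
            class = "surface_line")
}

#' Epithelial thickness at fixed lateral sampling positions
#'
#' Measures the vertical distance between the epithelial surface and the
#' traced interface at `n_sites` equally spaced lateral positions, at
#' fractions (2k-1)/(2 n_sites) of the lateral extent (for the default 4
#' sites: 1/8, 3/8, 5/8, 7/8 of the width), and averages them -- an
#' automated, reproducible version of repeated manual line-tool
#' measurements. Surface and boundary depths are linearly interpolated at
#' the sampling positions.
#'
#' @param surface A `surface_line` from [detect_surface()].
#' @param trace A `boundary_trace` from [trace_boundary()].
#' @param n_sites Number of sampling positions (default 4).
#' @return An object of class `thickness_result`: list with `positions_um`,
#'   `thickness_um` (per position) and `mean_um`.
#' @export
epithelial_thickness <- function(surface, trace, n_sites = 4L) {
  stopifnot(inherits(surface, "surface_line"),
            inherits(trace, "boundary_trace"), n_sites >= 1)
  lo <- max(min(surface$x_um), min(trace$points$x_um))
  hi <- min(max(surface$x_um), max(trace$points$x_um))
  if (hi <= lo) stop("surface and trace do not share a lateral extent")
  frac <- (2 * seq_len(n_sites) - 1) / (2 * n_sites)
  xq <- lo + frac * (hi - lo)
  s <- approx(surface$x_um, surface$depth_um, xout = xq)$y
  b <- approx(trace$points$x_um, trace$points$z_um, xout = xq)$y
  thick <- b - s
  if (any(thick <= 0)) {
    stop("geometry error: boundary lies at or above the surface at a ",
         "sampling position")
  }
  structure(list(positions_um = xq, thickness_um = thick,
                 mean_um = mean(thick)),
            class = "thickness_result")
}

# scale-normalized negative Laplacian-of-Gaussian response stack
log_response <- function(img, sigmas) {
  lap <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  out <- vector("list", length(sigmas))
  for (k in seq_along(sigmas)) {
    sm <- gaussian_smooth(img, sigmas[k])
    out[[k]] <- -sigmas[k]^2 *
      EBImage::filter2(sm, lap, boundary = "replicate")
  }
  out
}

#' Nuclear density from an en-face frame
#'
#' Counts dark nuclei on a bright cytoplasm background by multi-scale
#' Laplacian-of-Gaussian blob detection on the inverted image: the
#' scale-normalized response is maximized over space (3x3 neighborhood) and
#' scale, thresholded relative to the image contrast (making the estimate
#' invariant to global intensity scaling), and greedily non-maximum
#' suppressed so that no two detections lie closer than the smaller blob
#' radius. The density is reported per 100 um^2 of imaged area.
#'
#' @param raster Numeric matrix (en-face autofluorescence frame, rows = y).
#' @param px_lateral Pixel size (um/px, both directions).
#' @param scale_range Nucleus diameter search range (um), e.g. `c(7, 19)`.
#' @param n_scales Number of LoG scales spanning the range.
#' @param threshold_rel Detection threshold as a fraction of the image
#'   intensity range (contrast-relative).
#' @return List of class `density_result`: `density_per_100um2`, `count`,
#'   and `blobs` (data frame `x_um`, `y_um`, `radius_um`, `response`).
#' @export
nuclear_density <- function(raster, px_lateral, scale_range = c(7, 19),
                            n_scales = 6L, threshold_rel = 0.15) {
  raster <- as.matrix(raster)
  stopifnot(px_lateral > 0, length(scale_range) == 2L,
            scale_range[1] > 0, scale_range[2] > scale_range[1])
  r_px <- scale_range / 2 / px_lateral
  if (r_px[1] <= 1 || r_px[2] > min(dim(raster)) / 2) {
    stop("parameter error: nucleus scale range must lie within ",
         "(2 px, half the field)")
  }
  area_100 <- nrow(raster) * ncol(raster) * px_lateral^2 / 100
  contrast <- diff(range(raster))
  empty <- list(density_per_100um2 = 0, count = 0L,
                blobs = data.frame(x_um = numeric(0), y_um = numeric(0),
                                   radius_um = numeric(0),
                                   response = numeric(0)))
  class(empty) <- "density_result"
  if (contrast < .Machine$double.eps) return(empty)

  inv <- max(raster) - raster
  # pad the scale axis so accepted maxima are interior in scale: a peak must
  # dominate both a smaller and a larger scale, which suppresses broad
  # background structure that would otherwise saturate the largest scale
  sigmas <- exp(seq(log(r_px[1] / sqrt(2)) - 0.35,
                    log(r_px[2] / sqrt(2)) + 0.35,
                    length.out = n_scales + 2L))
  resp <- log_response(inv, sigmas)
  thr <- threshold_rel * contrast
  peaks <- NULL
  for (k in seq(2L, length(sigmas) - 1L)) {
    r <- resp[[k]]
    is_max <- r >= thr
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      is_max <- is_max & (r >= shift_mat(r, di, dj))
    }
    is_max <- is_max & (r >= resp[[k - 1]]) & (r >= resp[[k + 1]])
    # the outermost pixels carry replicate-boundary filter artifacts
    is_max[c(1:2, nrow(r) - 1:0), ] <- FALSE
    is_max[, c(1:2, ncol(r) - 1:0)] <- FALSE
    w <- which(is_max)
    if (length(w)) {
      peaks <- rbind(peaks, cbind(row = (w - 1) %% nrow(r) + 1,
                                  col = (w - 1) %/% nrow(r) + 1,
                                  sigma = sigmas[k], response = r[w]))
    }
  }
  if (is.null(peaks)) return(empty)

  # greedy spatial suppression, strongest response first
  o <- order(-peaks[, "response"])
  peaks <- peaks[o, , drop = FALSE]
  kept <- logical(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    if (i == 1L) { kept[1] <- TRUE; next }
    prev <- peaks[kept, , drop = FALSE]
    d <- sqrt((prev[, "row"] - peaks[i, "row"])^2 +
                (prev[, "col"] - peaks[i, "col"])^2)
    minsep <- pmin(prev[, "sigma"], peaks[i, "sigma"]) * sqrt(2)
    if (all(d >= minsep)) kept[i] <- TRUE
  }
  blobs <- peaks[kept, , drop = FALSE]
  out <- list(
    density_per_100um2 = nrow(blobs) / area_100,
    count = nrow(blobs),
    blobs = data.frame(
      x_um = (blobs[, "col"] - 1) * px_lateral,
      y_um = (blobs[, "row"] - 1) * px_lateral,
      radius_um = blobs[, "sigma"] * sqrt(2) * px_lateral,
      response = blobs[, "response"])
  )
  class(out) <- "density_result"
  out
}
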