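# Gaussian smoothing that tolerates rasters smaller than the default
# brush of EBImage::gblur (kernel must not exceed the image).
gaussian_smooth <- function(img, sigma) {
  if (sigma <= 0) return(img)
  radius <- 2 * ceiling(3 * sigma) + 1
  limit <- min(dim(img))
  if (radius > limit) {
    radius <- if (limit %% 2 == 1) limit else limit - 1
    if (radius < 3) return(img)
  }
  EBImage::gblur(img, sigma = sigma, radius = radius, boundary = "replicate")
}

# shift a matrix by (di, dj), replicating the edge rows/columns
shift_mat <- function(m, di, dj) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) - di, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) - dj, 1L), nc)
  m[ri, ci, drop = FALSE]
}

#' Threshold the SHG channel
#'
#' Binarizes the SHG channel, the first step of interface extraction: the
#' lamina propria produces SHG signal while the epithelium produces none, so
#' suprathreshold pixels lie at and below the interface. The automatic level
#' maximizes between-class variance (Otsu's method) on the SHG histogram.
#'
#' @param section A [cross_section()].
#' @param method `"otsu"` (automatic) or `"manual"`.
#' @param manual_level Threshold level (intensity units) when
#'   `method = "manual"`.
#' @return A logical matrix (`TRUE` where `SHG >= level`) with the chosen
#'   level in attribute `"level"`.
#' @export
threshold_shg <- function(section, method = c("otsu", "manual"),
                          manual_level = NULL) {
  stopifnot(inherits(section, "cross_section"))
  method <- match.arg(method)
  shg <- section$channel_shg
  if (method == "otsu") {
    rng <- range(shg)
    if (diff(rng) < .Machine$double.eps) {
      stop("degenerate histogram: SHG channel is constant, ",
           "automatic thresholding impossible")
    }
    level <- EBImage::otsu(shg, range = rng, levels = 256L)
  } else {
    if (is.null(manual_level)) stop("`manual_level` required")
    level <- manual_level
  }
  mask <- shg >= level
  attr(mask, "level") <- level
  mask
}

#' Canny-style edge detection
#'
#' Extracts thin edges from a raster by the classic chain: Gaussian
#' smoothing, Sobel gradient, non-maximum suppression across the local
#' gradient direction, and hysteresis linking (8-connected) between the low
#' and high thresholds, both expressed as fractions of the maximum gradient
#' magnitude. Applied to the SHG channel this isolates the
#' epithelium-lamina propria transition.
#'
#' @param raster Numeric matrix.
#' @param sigma Smoothing scale (px), > 0.
#' @param low,high Hysteresis thresholds as fractions of the maximum
#'   gradient magnitude, `0 <= low <= high <= 1`.
#' @return An object of class `edge_map`: list with logical `edges`, the
#'   `gradient` magnitude raster, and the parameters used.
#' @export
detect_edges <- function(raster, sigma = 1.5, low = 0.2, high = 0.5) {
  raster <- as.matrix(raster)
  stopifnot(sigma > 0, low >= 0, low <= high, high <= 1)
  sm <- gaussian_smooth(raster, sigma)
  gx <- (shift_mat(sm, 0, -1) - shift_mat(sm, 0, 1)) / 2   # d/dx (columns)
  gz <- (shift_mat(sm, -1, 0) - shift_mat(sm, 1, 0)) / 2   # d/dz (rows)
  g <- sqrt(gx^2 + gz^2)
  gmax <- max(g)
  # FFT-based smoothing leaves ~1e-13 ripple on constant rasters
  if (gmax <= 1e-9 * max(1, max(abs(raster)))) {
    edges <- matrix(FALSE, nrow(raster), ncol(raster))
    return(structure(list(edges = edges, gradient = g, sigma = sigma,
                          low = low, high = high), class = "edge_map"))
  }

  # non-maximum suppression: quantize the gradient direction into four
  # sectors and keep pixels that dominate both neighbors along it
  ang <- atan2(gz, gx)
  sector <- (round(ang / (pi / 4)) %% 4)   # 0: x, 1: diag, 2: z, 3: anti-diag
  keep <- matrix(FALSE, nrow(g), ncol(g))
  nbrs <- list(`0` = c(0, 1), `1` = c(1, 1), `2` = c(1, 0), `3` = c(1, -1))
  for (s in 0:3) {
    d <- nbrs[[as.character(s)]]
    sel <- sector == s
    keep[sel] <- g[sel] >= shift_mat(g, d[1], d[2])[sel] &
      g[sel] > shift_mat(g, -d[1], -d[2])[sel]
  }
  weak <- keep & g >= low * gmax
  strong <- keep & g >= high * gmax

  edges <- hysteresis_link(weak, strong)
  structure(list(edges = edges, gradient = g, sigma = sigma,
                 low = low, high = high),
            class = "edge_map")
}

# keep weak-edge components (8-connected) that contain a strong pixel
hysteresis_link <- function(weak, strong) {
  idx <- which(weak)
  if (length(idx) == 0L) return(weak & FALSE)
  nr <- nrow(weak)
  id_of <- integer(length(weak))
  id_of[idx] <- seq_along(idx)
  offs <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1))
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  from <- integer(0); to <- integer(0)
  nc <- ncol(weak)
  for (k in seq_len(nrow(offs))) {
    r2 <- rows + offs[k, 1]; c2 <- cols + offs[k, 2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nid <- id_of[(c2[ok] - 1L) * nr + r2[ok]]
    has <- nid > 0L
    from <- c(from, id_of[idx[ok]][has])
    to <- c(to, nid[has])
  }
  g <- igraph::make_graph(as.vector(rbind(from, to)), n = length(idx),
                          directed = FALSE)
  comp <- igraph::components(g)$membership
  strong_comps <- unique(comp[strong[idx]])
  out <- weak & FALSE
  out[idx[comp %in% strong_comps]] <- TRUE
  out
}

#' Per-column topmost boundary candidates
#'
#' For each lateral column, returns the smallest depth (row index) carrying
#' a suprathreshold or edge pixel -- the "topmost border" interpretation of
#' the interface in SHG cross-sections -- with `NA` marking columns without
#' any candidate. Isolated candidates more than `jump` rows away from both
#' flanking candidates are rejected as speckle.
#'
#' @param x A logical mask (e.g. from [threshold_shg()]) or an `edge_map`.
#' @param jump Speckle rejection threshold (px, default 15).
#' @return Integer vector of row indices (length = number of columns), with
#'   `NA` gap markers.
#' @export
topmost_candidates <- function(x, jump = 15) {
  mask <- if (inherits(x, "edge_map")) x$edges else x
  stopifnot(is.matrix(mask))
  if (!any(mask)) stop("empty mask: no candidates in any column")
  cand <- apply(mask, 2, function(col) {
    w <- which(col)
    if (length(w) == 0L) NA_integer_ else w[1]
  })
  nn <- which(!is.na(cand))
  if (length(nn) >= 2L) {
    keep <- cand
    for (j in nn) {
      pos <- match(j, nn)
      prev <- if (pos > 1L) cand[nn[pos - 1L]] else NA_integer_
      nxt <- if (pos < length(nn)) cand[nn[pos + 1L]] else NA_integer_
      far_prev <- !is.na(prev) && abs(cand[j] - prev) > jump
      far_next <- !is.na(nxt) && abs(cand[j] - nxt) > jump
      # interior: isolated from both sides; ends: isolated from the only side
      isolated <- if (is.na(prev)) far_next
                  else if (is.na(nxt)) far_prev
                  else far_prev && far_next
      if (isolated) keep[j] <- NA_integer_
    }
    cand <- keep
  }
  if (mean(is.na(cand)) > 0.5) {
    stop("extraction failure: more than 50% of columns have no boundary ",
         "candidate")
  }
  cand
}
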