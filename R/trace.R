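#' Arc length of a polyline in physical units
#'
#' Sum of Euclidean segment lengths of an ordered point set, in the same
#' units as the coordinates (um throughout the package; pixel anisotropy is
#' applied before points reach this function).
#'
#' @param points Two-column matrix or data frame of (x, z) coordinates (um).
#' @return Arc length (um).
#' @examples
#' arc_length(rbind(c(0, 0), c(3, 4)))  # 5
#' @export
arc_length <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 2L) stop("degenerate trace: need at least 2 points")
  sum(sqrt(diff(points[, 1])^2 + diff(points[, 2])^2))
}

#' Deviation of a traced boundary from linearity
#'
#' The shape statistic at the heart of the package: the arc length `l` of
#' the traced interface is compared with the chord `L` joining its first and
#' last points, giving `delta_L = l - L` and the dimensionless
#' `delta_L_norm = (l - L)/L`. A flat interface scores 0; rete-ridge
#' undulation increases the score. Because the chord joins the trace's own
#' endpoints, `l >= L` and the statistic is non-negative for every valid
#' trace.
#'
#' @param points Two-column matrix or data frame of ordered (x, z)
#'   coordinates (um).
#' @return List with `l_um`, `L_um`, `delta_L_um`, `delta_L_norm`.
#' @examples
#' th <- seq(0, pi, length.out = 1000)
#' semi <- cbind(50 - 50 * cos(th), 50 * sin(th))
#' delta_linearity(semi)$delta_L_norm  # ~ pi/2 - 1
#' @export
delta_linearity <- function(points) {
  points <- as.matrix(points)
  l <- arc_length(points)
  n <- nrow(points)
  L <- sqrt(sum((points[n, ] - points[1, ])^2))
  if (L < .Machine$double.eps) {
    stop("degenerate geometry: zero chord between trace endpoints")
  }
  list(l_um = l, L_um = L, delta_L_um = l - L, delta_L_norm = (l - L) / L)
}

# Minimal-cost 8-connected path across a per-pixel cost grid (uniform-cost
# search via igraph's Dijkstra). Path cost is the sum of per-pixel costs of
# every pixel on the path, including the start. A tiny depth bias
# (1e-9 per row) breaks cost ties in favour of shallower pixels; it is
# removed from the reported cost.
dijkstra_grid <- function(cost, start, end) {
  nr <- nrow(cost); nc <- ncol(cost)
  stopifnot(start[1] >= 1, start[1] <= nr, start[2] >= 1, start[2] <= nc,
            end[1] >= 1, end[1] <= nr, end[2] >= 1, end[2] <= nc)
  biased <- cost + (seq_len(nr) - 1) * 1e-9
  id <- function(r, c) (c - 1L) * nr + r
  offs <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
                c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  rows <- rep(seq_len(nr), nc)
  cols <- rep(seq_len(nc), each = nr)
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (k in seq_len(nrow(offs))) {
    r2 <- rows + offs[k, 1]; c2 <- cols + offs[k, 2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    from <- c(from, id(rows[ok], cols[ok]))
    tid <- id(r2[ok], c2[ok])
    to <- c(to, tid)
    w <- c(w, biased[tid])
  }
  g <- igraph::make_graph(as.vector(rbind(from, to)), n = nr * nc,
                          directed = TRUE)
  sp <- igraph::shortest_paths(g, from = id(start[1], start[2]),
                               to = id(end[1], end[2]),
                               mode = "out", weights = w,
                               output = "vpath")
  v <- as.integer(sp$vpath[[1]])
  if (length(v) == 0L) stop("tracing error: no path between seeds")
  path <- cbind(row = (v - 1L) %% nr + 1L, col = (v - 1L) %/% nr + 1L)
  list(path = path, cost = sum(cost[path]))
}

#' Trace the interface as a minimal-cost path through an edge map
#'
#' Traces the ECTI between seed points in the leftmost and rightmost image
#' columns as the minimal-cost 8-connected path (uniform-cost / Dijkstra
#' search), where each pixel costs `epsilon + 1/(1 + gradient magnitude)`:
#' the path hugs strong edges but can bridge short gradient gaps at finite
#' cost. The pixel path is reduced to one depth per column (keeping the
#' topmost path pixel, consistent with the topmost-border reading of the
#' interface), converted to um, optionally smoothed with a moving average to
#' suppress pixel staircase inflation of the arc length, and measured.
#'
#' @param edges An `edge_map` from [detect_edges()].
#' @param px_lateral,px_axial Pixel sizes (um/px).
#' @param start,end Optional `c(row, col)` seeds; when omitted they are
#'   derived from [topmost_candidates()] of the edge map (or of `candidates`
#'   if supplied) at the extreme columns.
#' @param candidates Optional per-column candidate depths (row indices, NA
#'   gaps) used for seeding and for restricting the search band.
#' @param epsilon Constant per-pixel cost floor enabling gap bridging.
#' @param max_gap Band margin (px) added around the candidate depth range
#'   when restricting the search grid; caps how far the path may stray.
#' @param smooth Apply the moving-average smoother to z(x) before measuring.
#' @param smooth_halfwidth Half-width (samples) of the moving average.
#' @return An object of class `boundary_trace`: list with `points` (data
#'   frame `x_um`, `z_um`, strictly increasing in x), the measures `l_um`,
#'   `L_um`, `delta_L_um`, `delta_L_norm`, the raw `path_cost`, and
#'   `params`.
#' @export
trace_boundary <- function(edges, px_lateral, px_axial,
                           start = NULL, end = NULL, candidates = NULL,
                           epsilon = 0.01, max_gap = 20,
                           smooth = TRUE, smooth_halfwidth = 1) {
  stopifnot(inherits(edges, "edge_map"), px_lateral > 0, px_axial > 0)
  g <- edges$gradient
  nr <- nrow(g); nc <- ncol(g)
  if (is.null(candidates) && (is.null(start) || is.null(end))) {
    candidates <- topmost_candidates(edges)
  }
  if (is.null(start) || is.null(end)) {
    nn <- which(!is.na(candidates))
    if (length(nn) == 0L) stop("tracing error: no seed candidates")
    # a single edge-column candidate can be speckle the jump rule cannot
    # veto (it has only one neighbor); the median over the outermost
    # candidate columns is robust
    seed_row <- function(cols) {
      as.integer(round(median(candidates[cols], na.rm = TRUE)))
    }
    start <- c(seed_row(head(nn, 15)), 1L)
    end <- c(seed_row(tail(nn, 15)), nc)
  }
  if (start[2] != 1L || end[2] != nc) {
    stop("seeds must lie in the leftmost and rightmost columns")
  }

  # restrict the search to a band around the candidate depths
  r0 <- 1L; r1 <- nr
  if (!is.null(candidates) && any(!is.na(candidates))) {
    r0 <- max(1L, min(candidates, na.rm = TRUE) - as.integer(max_gap))
    r1 <- min(nr, max(candidates, na.rm = TRUE) + as.integer(max_gap))
    r0 <- min(r0, start[1], end[1])
    r1 <- max(r1, start[1], end[1])
  }
  band <- g[r0:r1, , drop = FALSE]
  cost <- epsilon + 1 / (1 + band)
  sp <- dijkstra_grid(cost, c(start[1] - r0 + 1L, start[2]),
                      c(end[1] - r0 + 1L, end[2]))
  path <- sp$path
  path[, "row"] <- path[, "row"] + r0 - 1L

  # one depth per column: keep the topmost (smallest z) path pixel
  top <- tapply(path[, "row"], path[, "col"], min)
  colv <- as.integer(names(top))
  o <- order(colv)
  colv <- colv[o]; zrow <- as.integer(top[o])
  # sub-pixel refinement: parabolic interpolation of the gradient
  # magnitude across the edge removes most of the staircase quantization
  dz <- vapply(seq_along(colv), function(i) {
    r <- zrow[i]; cc <- colv[i]
    if (r <= 1L || r >= nr) return(0)
    gm <- g[r - 1L, cc]; g0 <- g[r, cc]; gp <- g[r + 1L, cc]
    den <- gm - 2 * g0 + gp
    if (abs(den) < .Machine$double.eps) return(0)
    max(min(0.5 * (gm - gp) / den, 0.5), -0.5)
  }, numeric(1))
  x_um <- (colv - 1) * px_lateral
  z_um <- (zrow - 1 + dz) * px_axial
  if (smooth && length(z_um) > 2 * smooth_halfwidth + 3) {
    # despike: short excursions (a few columns wide) where the path
    # detoured around a locally faint boundary are replaced by the local
    # median; genuine rete ridges are an order of magnitude wider and
    # survive the window
    if (length(z_um) > 51) {
      med <- runmed(z_um, 25, endrule = "median")
      spike <- abs(z_um - med) > 3
      z_um[spike] <- med[spike]
    }
    # median prefilter removes single-pixel staircase spikes the moving
    # average would only spread out
    z_um <- runmed(z_um, 2 * smooth_halfwidth + 1, endrule = "median")
    z_um <- moving_average(z_um, smooth_halfwidth)
  }
  pts <- data.frame(x_um = x_um, z_um = z_um)
  m <- delta_linearity(pts)
  structure(
    c(list(points = pts, path_cost = sp$cost,
           params = list(epsilon = epsilon, max_gap = max_gap,
                         smooth = smooth,
                         smooth_halfwidth = smooth_halfwidth,
                         sigma = edges$sigma, low = edges$low,
                         high = edges$high)),
      m),
    class = "boundary_trace"
  )
}

# centered moving average with edge replication
moving_average <- function(z, halfwidth) {
  if (halfwidth < 1) return(z)
  k <- 2 * halfwidth + 1
  n <- length(z)
  zp <- c(rep(z[1], halfwidth), z, rep(z[n], halfwidth))
  as.numeric(stats::filter(zp, rep(1 / k, k), sides = 2))[
    (halfwidth + 1):(halfwidth + n)]
}

#' @export
print.boundary_trace <- function(x, ...) {
  cat(sprintf(
    "boundary_trace: %d points, l = %.2f um, L = %.2f um, (dL)norm = %.4f\n",
    nrow(x$points), x$l_um, x$L_um, x$delta_L_norm))
  invisible(x)
}

#' Full interface measurement chain on one cross-section
#'
#' Convenience wrapper running the whole extraction pipeline on a
#' [cross_section()]: Otsu (or manual) thresholding of the SHG channel,
#' topmost-candidate extraction with speckle rejection, Canny-style edge
#' detection, minimal-cost tracing seeded at the extreme columns, and the
#' linearity measures.
#'
#' @param section A [cross_section()].
#' @param threshold_method Passed to [threshold_shg()].
#' @param manual_level Manual threshold level, if used.
#' @param sigma,low,high Edge detection parameters ([detect_edges()]).
#' @param jump Speckle rejection jump (px) for [topmost_candidates()].
#' @param ... Further arguments passed to [trace_boundary()].
#' @return A `boundary_trace`.
#' @examples
#' ph <- render_phantom(phantom_params(fov_width = 80, fov_depth = 80,
#'                                     rng_seed = 7),
#'                      boundary_model(40))
#' tr <- measure_ecti(ph$section)
#' tr$delta_L_norm
#' @export
measure_ecti <- function(section, threshold_method = "otsu",
                         manual_level = NULL, sigma = 1.5, low = 0.2,
                         high = 0.5, jump = 15, ...) {
  stopifnot(inherits(section, "cross_section"))
  mask <- threshold_shg(section, method = threshold_method,
                        manual_level = manual_level)
  cand <- topmost_candidates(mask, jump = jump)
  edges <- detect_edges(section$channel_shg, sigma = sigma,
                        low = low, high = high)
  trace_boundary(edges, px_lateral = section$px_lateral,
                 px_axial = section$px_axial, candidates = cand, ...)
}
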