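#' Acquisition and rendering parameters for synthetic phantoms
#'
#' Bundles the acquisition geometry and intensity/noise model used by
#' [render_phantom()] and [render_enface()]. Defaults reproduce the imaging
#' protocol the package targets: a 320 x 320 um field of view sampled at
#' 0.625 um/pixel laterally (512 pixels) with 1 um axial steps, 8-bit
#' grayscale intensities, and a ~10 um keratinized band at the surface.
#'
#' @param fov_width Lateral field-of-view width (um).
#' @param fov_depth Axial extent of a cross-section (um).
#' @param px_lateral Lateral pixel size (um/px).
#' @param px_axial Axial pixel size, i.e. z-step (um/px).
#' @param keratin_thickness Thickness (um) of the bright keratinized surface
#'   band in the autofluorescence channel.
#' @param intensity_keratin,intensity_epithelium,intensity_lamina_af
#'   Autofluorescence levels (8-bit units, 0-255) of the keratin band,
#'   epithelium, and lamina propria.
#' @param intensity_lamina_shg SHG level (0-255) of the lamina propria;
#'   the epithelium carries no SHG signal.
#' @param intensity_cytoplasm,intensity_nucleus En-face autofluorescence
#'   levels (0-255) of bright cytoplasm and dark nuclei.
#' @param noise_gaussian_sd Additive Gaussian read-noise sd (intensity units).
#' @param noise_poisson_scale Signal-dependent (shot) noise scale: the noise
#'   variance contribution is `noise_poisson_scale * intensity`.
#' @param texture_strength Relative amplitude of the multiplicative fibrous
#'   texture applied to the lamina propria.
#' @param texture_scale Correlation length (px) of the texture field.
#' @param render_nuclei Render dark elliptical nuclei in cross-sectional
#'   epithelium (off by default: cross-sectional nuclear contrast is poor in
#'   normal epithelium).
#' @param bit_depth 8 or 16; controls TIFF encoding in [write_phantom()].
#' @param rng_seed Optional integer seed; a fixed seed makes rendering
#'   bit-identical across runs.
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(fov_width = 320, fov_depth = 200,
                           px_lateral = 0.625, px_axial = 1,
                           keratin_thickness = 10,
                           intensity_keratin = 200,
                           intensity_epithelium = 120,
                           intensity_lamina_af = 90,
                           intensity_lamina_shg = 140,
                           intensity_cytoplasm = 180,
                           intensity_nucleus = 60,
                           noise_gaussian_sd = 5,
                           noise_poisson_scale = 0.1,
                           texture_strength = 0.25,
                           texture_scale = 4,
                           render_nuclei = FALSE,
                           bit_depth = 8L,
                           rng_seed = NULL) {
  stopifnot(fov_width > 0, fov_depth > 0, px_lateral > 0, px_axial > 0)
  nx <- fov_width / px_lateral
  nz <- fov_depth / px_axial
  if (abs(nx - round(nx)) > 1e-8 || abs(nz - round(nz)) > 1e-8) {
    stop("fov_width/px_lateral and fov_depth/px_axial must be integers ",
         "(got ", nx, " x ", nz, " pixels)")
  }
  ints <- c(intensity_keratin, intensity_epithelium, intensity_lamina_af,
            intensity_lamina_shg, intensity_cytoplasm, intensity_nucleus)
  if (any(ints < 0 | ints > 255)) stop("intensities must lie in [0, 255]")
  if (keratin_thickness < 0 || keratin_thickness >= fov_depth) {
    stop("`keratin_thickness` must lie in [0, fov_depth)")
  }
  if (noise_gaussian_sd < 0 || noise_poisson_scale < 0) {
    stop("noise parameters must be >= 0")
  }
  if (!bit_depth %in% c(8L, 16L)) stop("`bit_depth` must be 8 or 16")
  structure(
    list(fov_width = fov_width, fov_depth = fov_depth,
         px_lateral = px_lateral, px_axial = px_axial,
         keratin_thickness = keratin_thickness,
         intensity_keratin = intensity_keratin,
         intensity_epithelium = intensity_epithelium,
         intensity_lamina_af = intensity_lamina_af,
         intensity_lamina_shg = intensity_lamina_shg,
         intensity_cytoplasm = intensity_cytoplasm,
         intensity_nucleus = intensity_nucleus,
         noise_gaussian_sd = noise_gaussian_sd,
         noise_poisson_scale = noise_poisson_scale,
         texture_strength = texture_strength,
         texture_scale = texture_scale,
         render_nuclei = render_nuclei,
         bit_depth = as.integer(bit_depth),
         rng_seed = rng_seed),
    class = "phantom_params"
  )
}

#' Two-channel cross-section container
#'
#' A cross-section holds the autofluorescence and SHG channels of one x-z
#' (or y-z) plane as matrices with rows indexed by depth z and columns by
#' lateral position x, together with the physical pixel sizes. Row i maps to
#' depth `(i-1) * px_axial` um and column j to `(j-1) * px_lateral` um.
#'
#' @param channel_af,channel_shg Numeric matrices of identical dimensions
#'   (intensities in 0-255 units).
#' @param px_lateral,px_axial Pixel sizes (um/px), both positive.
#' @return An object of class `cross_section`.
#' @export
cross_section <- function(channel_af, channel_shg, px_lateral, px_axial) {
  channel_af <- as.matrix(channel_af)
  channel_shg <- as.matrix(channel_shg)
  if (!identical(dim(channel_af), dim(channel_shg))) {
    stop("channels must have identical dimensions")
  }
  stopifnot(px_lateral > 0, px_axial > 0)
  structure(
    list(channel_af = channel_af, channel_shg = channel_shg,
         px_lateral = px_lateral, px_axial = px_axial),
    class = "cross_section"
  )
}

#' @export
print.cross_section <- function(x, ...) {
  d <- dim(x$channel_shg)
  cat(sprintf("cross_section: %d x %d px (%.1f um deep x %.1f um wide)\n",
              d[1], d[2], d[1] * x$px_axial, d[2] * x$px_lateral))
  invisible(x)
}

# smooth multiplicative texture field, mean 1, clipped at 0
texture_field <- function(nz, nx, strength, scale_px) {
  if (strength <= 0) return(matrix(1, nz, nx))
  field <- matrix(rnorm(nz * nx), nz, nx)
  field <- gaussian_smooth(field, sigma = scale_px)
  field <- field / max(sd(c(field)), 1e-12)
  pmax(1 + strength * field, 0)
}

apply_noise <- function(img, gaussian_sd, poisson_scale) {
  if (gaussian_sd > 0) {
    img <- img + rnorm(length(img), 0, gaussian_sd)
  }
  if (poisson_scale > 0) {
    img <- img + rnorm(length(img)) * sqrt(poisson_scale * pmax(img, 0))
  }
  img
}

#' Render a cross-sectional phantom with known boundary geometry
#'
#' Builds a two-channel synthetic cross-section from a [boundary_model()]:
#' the autofluorescence channel shows a bright keratin band at the surface,
#' a moderately bright epithelium, and textured lamina propria below the
#' interface; the SHG channel is exactly zero above the true boundary
#' (before noise) and carries a textured fibrous signal below it. Additive
#' Gaussian and signal-dependent noise are applied per `params`. A fixed
#' `rng_seed` yields bit-identical output.
#'
#' @param params A [phantom_params()].
#' @param model A [boundary_model()]; its depth profile must stay within the
#'   axial field of view and below the keratin band.
#' @return A list of class `ecti_phantom` with elements `section`
#'   (a [cross_section()]) and `truth` (ground truth: the model, per-column
#'   true boundary depth, surface depth and thickness profile in um, and the
#'   analytic `true_delta_linearity` evaluated over the pixel-center span).
#' @examples
#' ph <- render_phantom(phantom_params(fov_width = 80, fov_depth = 80,
#'                                     rng_seed = 1),
#'                      boundary_model(40))
#' range(ph$section$channel_shg)
#' @export
render_phantom <- function(params, model) {
  stopifnot(inherits(params, "phantom_params"),
            inherits(model, "boundary_model"))
  nx <- as.integer(round(params$fov_width / params$px_lateral))
  nz <- as.integer(round(params$fov_depth / params$px_axial))
  if (nx < 64L || nz < 64L) {
    stop("raster must be at least 64 x 64 pixels")
  }
  x <- (seq_len(nx) - 1) * params$px_lateral
  z <- (seq_len(nz) - 1) * params$px_axial
  jitter_seed <- if (is.null(params$rng_seed)) NULL else params$rng_seed + 1L
  depth_x <- boundary_profile(model, x, fov_width = params$fov_width,
                              seed = jitter_seed)
  if (any(depth_x >= params$fov_depth)) {
    stop("boundary deeper than the axial field of view")
  }
  if (any(depth_x <= params$keratin_thickness)) {
    stop("boundary must lie below the keratin band")
  }

  render <- function() {
    below <- outer(z, depth_x, ">=")            # TRUE at/below the interface
    keratin <- matrix(z < params$keratin_thickness, nz, nx)
    af <- matrix(params$intensity_epithelium, nz, nx)
    af[keratin] <- params$intensity_keratin
    tex_af <- texture_field(nz, nx, params$texture_strength,
                            params$texture_scale)
    af[below] <- (params$intensity_lamina_af * tex_af)[below]
    if (params$render_nuclei) {
      af <- paint_cross_section_nuclei(af, depth_x, params)
    }
    tex_shg <- texture_field(nz, nx, params$texture_strength,
                             params$texture_scale)
    shg <- matrix(0, nz, nx)
    shg[below] <- (params$intensity_lamina_shg * tex_shg)[below]
    af <- apply_noise(af, params$noise_gaussian_sd, params$noise_poisson_scale)
    shg <- apply_noise(shg, params$noise_gaussian_sd,
                       params$noise_poisson_scale)
    list(af = round(pmin(pmax(af, 0), 255)),
         shg = round(pmin(pmax(shg, 0), 255)))
  }
  ch <- if (is.null(params$rng_seed)) render() else {
    withr::with_seed(params$rng_seed, render())
  }

  tdl <- if (model$roughness_sd == 0) {
    true_delta_linearity(model, params$fov_width, xlim = range(x))
  } else {
    pts <- cbind(x, depth_x)
    arc <- arc_length(pts)
    chord <- sqrt(diff(range(x))^2 + (depth_x[nx] - depth_x[1])^2)
    (arc - chord) / chord
  }
  truth <- structure(
    list(boundary_model = model,
         true_depth_um = depth_x,
         true_surface_depth_um = rep(0, nx),
         true_thickness_profile_um = depth_x,
         true_delta_linearity = tdl,
         x_um = x),
    class = "ground_truth"
  )
  structure(
    list(section = cross_section(ch$af, ch$shg,
                                 params$px_lateral, params$px_axial),
         truth = truth,
         params = params),
    class = "ecti_phantom"
  )
}

# sparse dark ellipses in the epithelial band (cosmetic realism only)
paint_cross_section_nuclei <- function(af, depth_x, params) {
  nz <- nrow(af); nx <- ncol(af)
  n <- max(1L, floor(params$fov_width / 20))
  cx <- runif(n, 0, params$fov_width)
  cz <- runif(n, params$keratin_thickness + 5,
              pmax(depth_x[pmin(pmax(round(cx / params$px_lateral) + 1, 1),
                                nx)] - 5,
                   params$keratin_thickness + 6))
  ax <- runif(n, 2.5, 4)   # semi-axes, um
  az <- runif(n, 3.5, 5.5)
  xs <- (seq_len(nx) - 1) * params$px_lateral
  zs <- (seq_len(nz) - 1) * params$px_axial
  for (k in seq_len(n)) {
    dx2 <- ((xs - cx[k]) / ax[k])^2
    dz2 <- ((zs - cz[k]) / az[k])^2
    inside <- outer(dz2, dx2, "+") <= 1
    af[inside] <- params$intensity_nucleus
  }
  af
}

#' Render an en-face frame with hard-core nuclei
#'
#' Places non-overlapping dark nuclei (a hard-core point process: centers are
#' rejected if two nuclei would overlap) on a bright cytoplasm background at
#' the requested expected density, then applies texture and noise. The number
#' of nuclei is Poisson with mean `density * area / 100`; placement uses dart
#' throwing. An infeasible request -- expected disk area fraction above the
#' random sequential packing regime (0.45) or placement failure -- raises a
#' packing error.
#'
#' @param density Expected nuclei per 100 um^2.
#' @param nucleus_diameter Diameter range (um), e.g. `c(8, 10)` for normal
#'   and `c(16, 18)` for dysplastic epithelium; each nucleus draws its
#'   diameter uniformly from this range.
#' @param fov Field of view `c(width, height)` in um (a scalar is square).
#' @param params A [phantom_params()]; supplies pixel size, intensities,
#'   noise model and seed.
#' @return A list of class `enface_phantom` with `raster` (matrix, rows = y),
#'   `truth` (data frame of true centers `x_um`, `y_um` and `radius_um`,
#'   plus realized count and density), and `params`.
#' @export
render_enface <- function(density, nucleus_diameter = c(8, 10),
                          fov = c(100, 100), params = phantom_params()) {
  stopifnot(density >= 0, all(nucleus_diameter > 0),
            length(nucleus_diameter) == 2L)
  if (length(fov) == 1L) fov <- c(fov, fov)
  px <- params$px_lateral
  nxp <- as.integer(round(fov[1] / px))
  nyp <- as.integer(round(fov[2] / px))
  area <- fov[1] * fov[2]
  mean_r <- mean(nucleus_diameter) / 2
  packing_fraction <- density / 100 * pi * mean_r^2
  if (packing_fraction > 0.45) {
    stop("packing error: requested density ", density, "/100 um^2 with ",
         "diameters ", nucleus_diameter[1], "-", nucleus_diameter[2],
         " um implies disk area fraction ", round(packing_fraction, 2),
         ", beyond hard-core feasibility")
  }

  build <- function() {
    n <- rpois(1, density * area / 100)
    centers <- matrix(numeric(0), 0, 2)
    radii <- numeric(0)
    attempts <- 0L
    while (nrow(centers) < n) {
      attempts <- attempts + 1L
      if (attempts > 2000L * max(n, 1L)) {
        stop("packing error: could not place ", n, " non-overlapping nuclei")
      }
      r <- runif(1, nucleus_diameter[1], nucleus_diameter[2]) / 2
      p <- c(runif(1, 0, fov[1]), runif(1, 0, fov[2]))
      if (nrow(centers) > 0) {
        d <- sqrt((centers[, 1] - p[1])^2 + (centers[, 2] - p[2])^2)
        if (any(d < radii + r)) next
      }
      centers <- rbind(centers, p)
      radii <- c(radii, r)
    }
    raster <- matrix(params$intensity_cytoplasm, nyp, nxp)
    xs <- (seq_len(nxp) - 1) * px
    ys <- (seq_len(nyp) - 1) * px
    for (k in seq_len(nrow(centers))) {
      dy2 <- (ys - centers[k, 2])^2
      dx2 <- (xs - centers[k, 1])^2
      inside <- outer(dy2, dx2, "+") <= radii[k]^2
      raster[inside] <- params$intensity_nucleus
    }
    # epithelial cytoplasm shows fine-grained speckle, not the coarse
    # fibrous texture of the lamina propria
    tex <- texture_field(nyp, nxp, params$texture_strength / 3, 1.5)
    raster <- raster * tex
    raster <- apply_noise(raster, params$noise_gaussian_sd,
                          params$noise_poisson_scale)
    list(raster = round(pmin(pmax(raster, 0), 255)),
         centers = centers, radii = radii)
  }
  out <- if (is.null(params$rng_seed)) build() else {
    withr::with_seed(params$rng_seed, build())
  }
  truth <- list(
    centers = data.frame(x_um = out$centers[, 1], y_um = out$centers[, 2],
                         radius_um = out$radii),
    count = nrow(out$centers),
    density_per_100um2 = nrow(out$centers) / area * 100,
    fov_um = fov
  )
  structure(list(raster = out$raster, truth = truth, params = params),
            class = "enface_phantom")
}
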