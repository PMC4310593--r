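#' Analytic model of the epithelial-connective tissue interface
#'
#' Describes the depth of the ECTI below the tissue surface as a function of
#' lateral position x: a flat baseline, an optional sinusoidal undulation,
#' Gaussian bumps standing in for individual rete ridges, and optional
#' small-scale roughness. Depth increases downward from the surface at
#' z = 0 um, and both sine crests and bumps push the interface deeper --
#' the direction rete ridges protrude during dysplastic remodelling.
#'
#' @param baseline_depth Depth (um) of the flat interface; must be positive.
#' @param sine_amplitude Amplitude (um) of the sinusoidal undulation
#'   (0 disables it).
#' @param sine_period Lateral period (um) of the undulation; required
#'   positive when `sine_amplitude > 0`.
#' @param bumps `NULL` or a data frame with columns `center`, `amplitude`,
#'   `width` (all um); each row adds `amplitude * exp(-(x-center)^2/(2 width^2))`
#'   to the depth.
#' @param roughness_sd Standard deviation (um) of per-position Gaussian
#'   jitter; models small-scale irregularity. A model with
#'   `roughness_sd > 0` is stochastic and has no analytic linearity.
#'
#' @return An object of class `boundary_model`.
#' @seealso [boundary_profile()], [true_delta_linearity()], [render_phantom()]
#' @examples
#' flat <- boundary_model(baseline_depth = 100)
#' wavy <- boundary_model(100, sine_amplitude = 20, sine_period = 80)
#' ridged <- boundary_model(100,
#'   bumps = data.frame(center = 160, amplitude = 30, width = 15))
#' @export
boundary_model <- function(baseline_depth, sine_amplitude = 0,
                           sine_period = NA_real_, bumps = NULL,
                           roughness_sd = 0) {
  if (!is.numeric(baseline_depth) || length(baseline_depth) != 1L ||
      !is.finite(baseline_depth) || baseline_depth <= 0) {
    stop("`baseline_depth` must be a single positive number (um)")
  }
  if (sine_amplitude < 0) stop("`sine_amplitude` must be >= 0")
  if (sine_amplitude > 0 && (!is.finite(sine_period) || sine_period <= 0)) {
    stop("`sine_period` must be > 0 when `sine_amplitude` > 0")
  }
  if (!is.null(bumps)) {
    bumps <- as.data.frame(bumps)
    need <- c("center", "amplitude", "width")
    if (!all(need %in% names(bumps))) {
      stop("`bumps` needs columns center, amplitude, width")
    }
    if (any(bumps$width <= 0)) stop("bump widths must be > 0")
  }
  if (roughness_sd < 0) stop("`roughness_sd` must be >= 0")
  structure(
    list(baseline_depth = baseline_depth,
         sine_amplitude = sine_amplitude,
         sine_period = sine_period,
         bumps = bumps,
         roughness_sd = roughness_sd),
    class = "boundary_model"
  )
}

#' @export
print.boundary_model <- function(x, ...) {
  cat("ECTI boundary model\n")
  cat("  baseline depth:", x$baseline_depth, "um\n")
  if (x$sine_amplitude > 0) {
    cat("  sine: amplitude", x$sine_amplitude, "um, period",
        x$sine_period, "um\n")
  }
  if (!is.null(x$bumps)) cat("  rete-ridge bumps:", nrow(x$bumps), "\n")
  if (x$roughness_sd > 0) cat("  roughness sd:", x$roughness_sd, "um\n")
  invisible(x)
}

#' Evaluate the boundary depth profile
#'
#' Evaluates the modelled ECTI depth at the given lateral positions. The
#' deterministic part is `baseline + sine + sum of Gaussian bumps`; jitter is
#' added only when the model has `roughness_sd > 0` and a `seed` is supplied,
#' so the same seed always reproduces the same profile.
#'
#' @param model A [boundary_model()].
#' @param x Lateral positions (um).
#' @param fov_width Optional field-of-view width (um); positions outside
#'   `[0, fov_width]` raise an error.
#' @param seed Optional integer seed for the roughness jitter.
#' @return Numeric vector of depths (um), one per element of `x`.
#' @export
boundary_profile <- function(model, x, fov_width = NULL, seed = NULL) {
  stopifnot(inherits(model, "boundary_model"), is.numeric(x))
  if (!is.null(fov_width) && any(x < 0 | x > fov_width)) {
    stop("lateral positions outside the field of view [0, ", fov_width, "] um")
  }
  depth <- rep(model$baseline_depth, length(x))
  if (model$sine_amplitude > 0) {
    depth <- depth + model$sine_amplitude * sin(2 * pi * x / model$sine_period)
  }
  if (!is.null(model$bumps)) {
    for (k in seq_len(nrow(model$bumps))) {
      b <- model$bumps[k, ]
      depth <- depth + b$amplitude * exp(-(x - b$center)^2 / (2 * b$width^2))
    }
  }
  if (model$roughness_sd > 0 && !is.null(seed)) {
    depth <- depth + withr::with_seed(seed,
      rnorm(length(x), 0, model$roughness_sd))
  }
  if (any(!is.finite(depth))) stop("non-finite boundary depth")
  depth
}

# analytic d(depth)/dx of the deterministic part of the model
boundary_slope <- function(model, x) {
  slope <- rep(0, length(x))
  if (model$sine_amplitude > 0) {
    w <- 2 * pi / model$sine_period
    slope <- slope + model$sine_amplitude * w * cos(w * x)
  }
  if (!is.null(model$bumps)) {
    for (k in seq_len(nrow(model$bumps))) {
      b <- model$bumps[k, ]
      slope <- slope - b$amplitude * (x - b$center) / b$width^2 *
        exp(-(x - b$center)^2 / (2 * b$width^2))
    }
  }
  slope
}

#' True deviation from linearity of an analytic boundary
#'
#' Computes the ground-truth \eqn{(\Delta L)_{norm} = (l - L)/L} of a
#' boundary model by dense numerical quadrature: the arc length
#' \eqn{l = \int \sqrt{1 + f'(x)^2}\,dx} is evaluated with composite
#' Simpson's rule on the analytic derivative, and the chord \eqn{L} joins the
#' curve's two endpoints. This is the oracle against which measured traces
#' are validated; it supports only deterministic models
#' (`roughness_sd = 0`). `model` may alternatively be a plain function
#' `f(x)` returning depth, in which case the arc length is computed by
#' polyline summation over `n` points (used e.g. for closed-form test
#' curves such as a semicircle).
#'
#' @param model A [boundary_model()] with `roughness_sd = 0`, or a function.
#' @param fov_width Width (um) of the lateral extent.
#' @param xlim Integration limits (um); defaults to `c(0, fov_width)`.
#'   A rendered phantom samples pixel centers on `[0, fov_width - px]`, so
#'   recovery tests pass the pixel-center span here.
#' @param n Number of quadrature points (forced odd; default 200001 keeps
#'   the relative error well below 1e-4 for smooth models).
#' @return The dimensionless deviation from linearity (>= 0).
#' @examples
#' true_delta_linearity(boundary_model(100), 320) # flat -> 0
#' @export
true_delta_linearity <- function(model, fov_width, xlim = c(0, fov_width),
                                 n = 200001L) {
  stopifnot(length(xlim) == 2L, xlim[2] > xlim[1], n >= 3)
  if (n %% 2L == 0L) n <- n + 1L
  x <- seq(xlim[1], xlim[2], length.out = n)
  if (is.function(model)) {
    depth <- model(x)
    arc <- sum(sqrt(diff(x)^2 + diff(depth)^2))
    ends <- c(depth[1], depth[n])
  } else {
    stopifnot(inherits(model, "boundary_model"))
    if (model$roughness_sd > 0) {
      stop("stochastic model: analytic linearity is undefined for ",
           "roughness_sd > 0")
    }
    integrand <- sqrt(1 + boundary_slope(model, x)^2)
    h <- (xlim[2] - xlim[1]) / (n - 1L)
    w <- rep(c(4, 2), length.out = n - 2L)
    arc <- h / 3 * (integrand[1] + integrand[n] +
                      sum(w * integrand[2:(n - 1L)]))
    ends <- boundary_profile(model, xlim)
  }
  chord <- sqrt((xlim[2] - xlim[1])^2 + (ends[2] - ends[1])^2)
  max((arc - chord) / chord, 0)
}
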