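# Shared fixtures: small phantoms, analytic curves, and independent oracles.

# quick phantom parameters for an 80 x 80 um field (128 x 80 px)
small_params <- function(seed = 1L, ...) {
  phantom_params(fov_width = 80, fov_depth = 80, rng_seed = seed, ...)
}

# noiseless, texture-free rendering for exact geometric assertions
clean_params <- function(seed = 1L, ...) {
  phantom_params(fov_width = 80, fov_depth = 80, rng_seed = seed,
                 noise_gaussian_sd = 0, noise_poisson_scale = 0,
                 texture_strength = 0, ...)
}

# semicircular depth profile spanning [0, 2R]: chord 2R, arc pi*R
semicircle_fun <- function(R, baseline = 100) {
  function(x) baseline + sqrt(pmax(R^2 - (x - R)^2, 0))
}

# dense semicircular polyline (parametric, so endpoint slopes are exact)
semicircle_points <- function(R = 50, n = 5000) {
  th <- seq(0, pi, length.out = n)
  cbind(x = R - R * cos(th), z = R * sin(th))
}

# independent shortest-path oracle: Bellman-style relaxation to a fixed
# point over the 8-connected grid, per-pixel cost summed including start
relax_grid_cost <- function(cost, start, end) {
  nr <- nrow(cost); nc <- ncol(cost)
  d <- matrix(Inf, nr, nc)
  d[start[1], start[2]] <- cost[start[1], start[2]]
  offs <- expand.grid(di = -1:1, dj = -1:1)
  offs <- offs[!(offs$di == 0 & offs$dj == 0), ]
  repeat {
    changed <- FALSE
    for (j in seq_len(nc)) for (i in seq_len(nr)) {
      for (k in seq_len(nrow(offs))) {
        i2 <- i + offs$di[k]; j2 <- j + offs$dj[k]
        if (i2 < 1 || i2 > nr || j2 < 1 || j2 > nc) next
        cand <- d[i, j] + cost[i2, j2]
        if (cand < d[i2, j2] - 1e-12) { d[i2, j2] <- cand; changed <- TRUE }
      }
    }
    if (!changed) break
  }
  d[end[1], end[2]]
}

# minimal cost over x-monotone paths (vertical moves allowed) by dynamic
# programming: an upper bound certificate for the unrestricted minimum
monotone_path_cost <- function(cost, start, end) {
  nr <- nrow(cost); nc <- ncol(cost)
  best <- rep(Inf, nr); best[start[1]] <- cost[start[1], start[2]]
  relax_col <- function(v, col_cost) {
    # allow arbitrary vertical runs within a column
    for (i in 2:nr) v[i] <- min(v[i], v[i - 1] + col_cost[i])
    for (i in (nr - 1):1) v[i] <- min(v[i], v[i + 1] + col_cost[i])
    v
  }
  best <- relax_col(best, cost[, start[2]])
  for (j in (start[2] + 1):nc) {
    step <- rep(Inf, nr)
    for (i in seq_len(nr)) {
      prev <- best[max(1, i - 1):min(nr, i + 1)]
      step[i] <- min(prev) + cost[i, j]
    }
    step <- relax_col(step, cost[, j])
    best <- step
  }
  best[end[1]]
}

# all-pairs concordance AUC (ties count one half)
concordance_auc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# grid of analytic boundary models within the method's validity domain
# (max |slope| <= 1.8) spanning true (dL)norm ~ 0.014 to ~ 0.49
oracle_model_grid <- function() {
  ms <- list()
  for (A in c(6, 10, 14, 18)) for (P in c(70, 90, 160)) {
    if (A * 2 * pi / P <= 1.8) {
      ms[[length(ms) + 1]] <- boundary_model(100, sine_amplitude = A,
                                             sine_period = P)
    }
  }
  for (A in c(22, 28)) {
    ms[[length(ms) + 1]] <- boundary_model(
      100, sine_amplitude = A, sine_period = ceiling(A * 2 * pi / 1.6))
  }
  for (amp in c(16, 20, 24, 30)) {
    ms[[length(ms) + 1]] <- boundary_model(
      100, bumps = data.frame(center = c(80, 180, 260),
                              amplitude = c(amp, amp * 0.8, amp * 1.1),
                              width = c(13, 16, 11)))
  }
  for (A in c(8, 12, 16)) {
    ms[[length(ms) + 1]] <- boundary_model(
      95, sine_amplitude = A, sine_period = 100,
      bumps = data.frame(center = c(120, 240), amplitude = c(18, 14),
                         width = c(14, 12)))
  }
  ms
}
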