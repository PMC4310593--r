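#' Specification of one simulated cohort group
#'
#' Describes how per-site deviation-from-linearity values are drawn for one
#' histopathological group. Three families are supported:
#' `"truncated-gaussian"` (Gaussian truncated at 0, used for the tightly
#' distributed normal group), `"lognormal"` (log-scale parameters
#' moment-matched so the untruncated mean and sd equal the targets; captures
#' the right skew of dysplastic groups), and `"point-mass"` (degenerate, for
#' tests).
#'
#' @param group Group label: one of `"normal"`, `"mild"`, `"moderate"`,
#'   `"severe"`, `"dysplasia"` (pooled).
#' @param n_sites Number of imaged sites to draw (>= 1).
#' @param family Distribution family.
#' @param mean,sd Target mean and standard deviation of the drawn values.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(group, n_sites,
                        family = c("truncated-gaussian", "lognormal",
                                   "point-mass"),
                        mean, sd = 0) {
  family <- match.arg(family)
  groups <- c("normal", "mild", "moderate", "severe", "dysplasia")
  if (!group %in% groups) {
    stop("`group` must be one of: ", paste(groups, collapse = ", "))
  }
  stopifnot(n_sites >= 1, sd >= 0)
  if (family == "point-mass" && sd > 0) {
    stop("point-mass family cannot have sd > 0")
  }
  if (family == "lognormal" && mean <= 0) {
    stop("lognormal family needs mean > 0")
  }
  structure(list(group = group, n_sites = as.integer(n_sites),
                 family = family, mean = mean, sd = sd),
            class = "cohort_spec")
}

#' Moment-matched lognormal parameters
#'
#' Log-scale location and scale such that a lognormal variate has the given
#' arithmetic mean and standard deviation:
#' `sdlog^2 = log(1 + (sd/mean)^2)`, `meanlog = log(mean) - sdlog^2 / 2`.
#'
#' @param mean,sd Target arithmetic mean (> 0) and sd (>= 0).
#' @return Named vector `c(meanlog, sdlog)`.
#' @export
lognormal_params <- function(mean, sd) {
  stopifnot(mean > 0, sd >= 0)
  s2 <- log(1 + (sd / mean)^2)
  c(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

draw_group <- function(spec) {
  n <- spec$n_sites
  switch(spec$family,
    "point-mass" = rep(spec$mean, n),
    "lognormal" = {
      p <- lognormal_params(spec$mean, spec$sd)
      rlnorm(n, p["meanlog"], p["sdlog"])
    },
    "truncated-gaussian" = {
      # inverse-CDF sampling restricted to [0, Inf)
      p0 <- pnorm(0, spec$mean, spec$sd)
      if (spec$sd == 0) rep(max(spec$mean, 0), n)
      else qnorm(runif(n, p0, 1), spec$mean, spec$sd)
    }
  )
}

#' Draw a simulated per-site cohort
#'
#' Draws deviation-from-linearity values for each group specification and
#' stacks them into the cohort table used by the statistics stage. All
#' values are non-negative by construction. With a fixed `seed` the draw is
#' reproducible.
#'
#' @param specs A [cohort_spec()] or list of them.
#' @param seed Optional integer seed.
#' @param modality Modality tag stored with each row (`"imaging"` or
#'   `"histology"`).
#' @return A data frame with columns `site_id`, `group`, `modality`,
#'   `delta_linearity`.
#' @examples
#' specs <- default_cohort_specs("imaging")
#' head(sample_cohort(specs, seed = 1))
#' @export
sample_cohort <- function(specs, seed = NULL, modality = "imaging") {
  if (inherits(specs, "cohort_spec")) specs <- list(specs)
  stopifnot(all(vapply(specs, inherits, logical(1), "cohort_spec")))
  draw_all <- function() lapply(specs, draw_group)
  values <- if (is.null(seed)) draw_all() else {
    withr::with_seed(seed, draw_all())
  }
  out <- do.call(rbind, lapply(seq_along(specs), function(k) {
    s <- specs[[k]]
    data.frame(
      site_id = sprintf("%s-%s-%03d", modality, s$group,
                        seq_len(s$n_sites)),
      group = s$group,
      modality = modality,
      delta_linearity = values[[k]],
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Cohort specifications matching the reported group distributions
#'
#' Returns the generator settings the package uses to emulate the study
#' cohorts: 33 normal and 27 dysplastic sites, with the per-modality group
#' means and standard deviations of the reported measurements. The normal
#' group uses a truncated Gaussian; dysplastic groups use moment-matched
#' lognormals (right-skewed, non-negative). With `per_grade = TRUE` the 27
#' dysplastic sites are split evenly across mild/moderate/severe grades with
#' the per-grade parameters; otherwise a single pooled dysplasia group is
#' used.
#'
#' @param modality `"imaging"` (MPAM-SHGM measurements: normal 0.11 (0.04),
#'   pooled dysplasia 0.41 (0.24)) or `"histology"` (H&E: normal 0.09
#'   (0.03), pooled dysplasia 0.28 (0.16)).
#' @param per_grade Split dysplasia into grades instead of pooling.
#' @return A list of [cohort_spec()] objects.
#' @export
default_cohort_specs <- function(modality = c("imaging", "histology"),
                                 per_grade = FALSE) {
  modality <- match.arg(modality)
  tab <- if (modality == "imaging") {
    list(normal = c(0.11, 0.04), dysplasia = c(0.41, 0.24),
         mild = c(0.31, 0.17), moderate = c(0.45, 0.29),
         severe = c(0.41, 0.22))
  } else {
    list(normal = c(0.09, 0.03), dysplasia = c(0.28, 0.16),
         mild = c(0.14, 0.04), moderate = c(0.29, 0.10),
         severe = c(0.38, 0.19))
  }
  specs <- list(cohort_spec("normal", 33, "truncated-gaussian",
                            tab$normal[1], tab$normal[2]))
  if (per_grade) {
    for (g in c("mild", "moderate", "severe")) {
      specs <- c(specs, list(cohort_spec(g, 9, "lognormal",
                                         tab[[g]][1], tab[[g]][2])))
    }
  } else {
    specs <- c(specs, list(cohort_spec("dysplasia", 27, "lognormal",
                                       tab$dysplasia[1], tab$dysplasia[2])))
  }
  specs
}
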