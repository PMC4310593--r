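# coerce list-of-vectors / (values, groups) input into a named list
as_group_list <- function(groups, values = NULL) {
  if (!is.null(values)) groups <- split(values, groups)
  if (!is.list(groups)) stop("`groups` must be a list of numeric vectors")
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("g", seq_along(groups))
  }
  lapply(groups, as.numeric)
}

anova_ss <- function(groups) {
  all_v <- unlist(groups)
  grand <- mean(all_v)
  ssb <- sum(vapply(groups, function(v) length(v) * (mean(v) - grand)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1)))
  k <- length(groups); n <- length(all_v)
  list(ssb = ssb, ssw = ssw, df1 = k - 1L, df2 = n - k)
}

#' One-way fixed-effects analysis of variance
#'
#' Classical single-factor ANOVA comparing group means, as used to test
#' whether deviation-from-linearity (or thickness) differs among
#' histopathological grades. Degenerate inputs are handled explicitly: all
#' groups identical gives F = 0, p = 1; zero within-group variance with
#' unequal means gives F = Inf, p = 0.
#'
#' @param groups List of numeric vectors (one per group), each of length
#'   >= 2; alternatively a vector of values with `values` semantics via
#'   [split()] performed by the caller.
#' @return List with `F`, `p`, and the degrees of freedom `df1`, `df2`.
#' @examples
#' one_way_anova(list(c(1, 2, 3), c(2, 3, 4), c(9, 10, 11)))
#' @export
one_way_anova <- function(groups) {
  groups <- as_group_list(groups)
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (any(lengths(groups) < 2L)) stop("each group needs at least 2 values")
  ss <- anova_ss(groups)
  if (ss$ssw < .Machine$double.eps * max(1, ss$ssb)) {
    if (ss$ssb < .Machine$double.eps) {
      return(list(F = 0, p = 1, df1 = ss$df1, df2 = ss$df2))
    }
    return(list(F = Inf, p = 0, df1 = ss$df1, df2 = ss$df2))
  }
  vals <- unlist(groups)
  fac <- factor(rep(names(groups), lengths(groups)))
  ht <- oneway.test(vals ~ fac, var.equal = TRUE)
  list(F = unname(ht$statistic), p = unname(ht$p.value),
       df1 = unname(ht$parameter[1]), df2 = unname(ht$parameter[2]))
}

#' Tukey honest-significant-difference post hoc comparisons
#'
#' Pairwise group comparisons after ANOVA using the studentized range
#' distribution on the pooled within-group variance (Tukey's HSD), as used
#' to localize which grades differ. Degenerate zero-variance input is
#' mapped to p = 1 (identical means) or p = 0 (different means).
#'
#' @param groups List of numeric vectors, one per group.
#' @return Data frame with columns `group1`, `group2`, `diff` (mean
#'   difference), `p_adj`.
#' @export
tukey_hsd <- function(groups) {
  groups <- as_group_list(groups)
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (any(lengths(groups) < 2L)) stop("each group needs at least 2 values")
  nm <- names(groups)
  pairs <- utils::combn(seq_along(groups), 2)
  ss <- anova_ss(groups)
  if (ss$ssw < .Machine$double.eps * max(1, ss$ssb)) {
    out <- data.frame(
      group1 = nm[pairs[1, ]], group2 = nm[pairs[2, ]],
      diff = apply(pairs, 2, function(pr) {
        mean(groups[[pr[2]]]) - mean(groups[[pr[1]]])
      })
    )
    out$p_adj <- ifelse(abs(out$diff) < .Machine$double.eps, 1, 0)
    return(out)
  }
  vals <- unlist(groups)
  fac <- factor(rep(nm, lengths(groups)), levels = nm)
  tk <- TukeyHSD(aov(vals ~ fac))$fac
  comp <- strsplit(rownames(tk), "-", fixed = TRUE)
  data.frame(
    group1 = vapply(comp, `[`, character(1), 2),
    group2 = vapply(comp, `[`, character(1), 1),
    diff = unname(tk[, "diff"]),
    p_adj = unname(tk[, "p adj"])
  )
}

#' Box-plot style per-group summaries
#'
#' Median, quartiles (linear-interpolation convention), mean, sd, and
#' outliers beyond the 1.5 x IQR fences, for each group -- the numbers a
#' box-and-whisker display of a cohort encodes.
#'
#' @param values Numeric vector of per-site measurements.
#' @param groups Group label per value.
#' @return Data frame with one row per group (`group`, `n`, `mean`, `sd`,
#'   `median`, `q25`, `q75`) and the outliers in attribute `"outliers"`
#'   (named list per group).
#' @export
group_summary <- function(values, groups) {
  gl <- split(as.numeric(values), groups)
  rows <- lapply(names(gl), function(g) {
    v <- gl[[g]]
    q <- quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(group = g, n = length(v), mean = mean(v), sd = sd(v),
               median = q[2], q25 = q[1], q75 = q[3])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "outliers") <- lapply(gl, function(v) {
    q <- quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2] - q[1]
    v[v < q[1] - 1.5 * iqr | v > q[2] + 1.5 * iqr]
  })
  out
}

#' Empirical ROC curve and AUC
#'
#' Builds the empirical receiver operating characteristic for a score that
#' is higher in the positive (dysplastic) class: each distinct score is a
#' candidate cutoff, a site is called positive when its score is at or above
#' the cutoff, and sensitivity/specificity are tabulated per cutoff. The
#' AUC is computed by the trapezoidal rule, which for the empirical curve
#' equals the normalized Wilcoxon rank-sum statistic (ties counted one
#' half).
#'
#' @param scores Numeric scores (e.g. deviation from linearity).
#' @param labels Logical (or coercible) vector, `TRUE` for the positive
#'   class; both classes must be present.
#' @return Object of class `roc_result`: list with `points` (data frame
#'   `cutoff`, `sensitivity`, `specificity`, cutoffs descending so
#'   sensitivity is non-decreasing), `auc`, and class counts `n_pos`,
#'   `n_neg`.
#' @export
empirical_roc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present to build a ROC curve")
  }
  cutoffs <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  sens <- vapply(cutoffs, function(t) mean(scores[labels] >= t), numeric(1))
  spec <- vapply(cutoffs, function(t) mean(scores[!labels] < t), numeric(1))
  fpr <- 1 - spec
  auc <- sum(diff(fpr) * (head(sens, -1) + tail(sens, -1)) / 2)
  structure(
    list(points = data.frame(cutoff = cutoffs, sensitivity = sens,
                             specificity = spec),
         auc = auc, n_pos = n_pos, n_neg = n_neg),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("empirical ROC: %d positives, %d negatives, AUC = %.3f\n",
              x$n_pos, x$n_neg, x$auc))
  invisible(x)
}

#' Optimal operating point of a ROC curve
#'
#' Selects the cutoff optimizing the requested criterion -- by default
#' Youden's J = sensitivity + specificity - 1, with ties broken toward the
#' lower cutoff -- and reports the operating characteristics along with the
#' within-class rate table (TP + FN = 1 among positives, TN + FP = 1 among
#' negatives).
#'
#' @param roc A `roc_result` from [empirical_roc()].
#' @param criterion `"youden"` or `"closest"` (closest point to the
#'   (0, 1) corner of the ROC plane).
#' @return List with `cutoff`, `sensitivity_pct`, `specificity_pct`, and
#'   `rates` (named vector TP, FP, TN, FN as within-class proportions).
#' @export
operating_point <- function(roc, criterion = c("youden", "closest")) {
  stopifnot(inherits(roc, "roc_result"))
  criterion <- match.arg(criterion)
  p <- roc$points
  score <- switch(criterion,
    youden = p$sensitivity + p$specificity - 1,
    closest = -sqrt((1 - p$sensitivity)^2 + (1 - p$specificity)^2)
  )
  best <- which(score == max(score))
  i <- best[which.min(p$cutoff[best])]   # ties -> lower cutoff
  list(
    cutoff = p$cutoff[i],
    sensitivity_pct = 100 * p$sensitivity[i],
    specificity_pct = 100 * p$specificity[i],
    rates = c(TP = p$sensitivity[i], FP = 1 - p$specificity[i],
              TN = p$specificity[i], FN = 1 - p$sensitivity[i])
  )
}

#' Monte-Carlo discrimination study on simulated cohorts
#'
#' Repeatedly draws a normal and a pooled dysplastic cohort from the given
#' group distributions, and per replicate computes the empirical ROC, AUC,
#' the Youden-optimal operating point and the two-group ANOVA p-value. This
#' reproduces the classification analysis of the measured cohorts from
#' their reported distribution parameters alone.
#'
#' @param specs List of [cohort_spec()]s (one must be the `"normal"` group;
#'   all other groups are pooled as positives). Defaults to
#'   [default_cohort_specs()] for the chosen modality.
#' @param modality `"imaging"` or `"histology"` (selects the default
#'   parameter set).
#' @param n_reps Number of seeded replicates.
#' @param seed Integer seed for the whole study.
#' @return List of class `discrimination_sim`: `replicates` (data frame
#'   with per-replicate `auc`, `cutoff`, `sensitivity_pct`,
#'   `specificity_pct`, `anova_p`) and `summary` (means over replicates and
#'   the fraction of replicates with p < 0.01).
#' @examples
#' sim <- simulate_discrimination(n_reps = 20, seed = 1)
#' sim$summary
#' @export
simulate_discrimination <- function(specs = NULL,
                                    modality = c("imaging", "histology"),
                                    n_reps = 200L, seed = 1L) {
  modality <- match.arg(modality)
  if (is.null(specs)) specs <- default_cohort_specs(modality)
  seeds <- seed + seq_len(n_reps) - 1L
  rows <- lapply(seeds, function(s) {
    coh <- sample_cohort(specs, seed = s, modality = modality)
    pos <- coh$group != "normal"
    roc <- empirical_roc(coh$delta_linearity, pos)
    op <- operating_point(roc, "youden")
    aov2 <- one_way_anova(split(coh$delta_linearity, pos))
    data.frame(seed = s, auc = roc$auc, cutoff = op$cutoff,
               sensitivity_pct = op$sensitivity_pct,
               specificity_pct = op$specificity_pct,
               anova_p = aov2$p)
  })
  reps <- do.call(rbind, rows)
  structure(
    list(replicates = reps,
         summary = list(
           mean_auc = mean(reps$auc),
           mean_sensitivity_pct = mean(reps$sensitivity_pct),
           mean_specificity_pct = mean(reps$specificity_pct),
           median_anova_p = median(reps$anova_p),
           frac_p_below_0.01 = mean(reps$anova_p < 0.01),
           n_reps = n_reps)),
    class = "discrimination_sim"
  )
}
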