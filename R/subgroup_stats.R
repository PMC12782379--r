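#' Welch two-sample t-test
#'
#' Unequal-variance two-sample comparison with Welch-Satterthwaite degrees
#' of freedom and a two-tailed p-value, via [stats::t.test()]. The degenerate
#' case of two zero-variance groups with equal means is reported as `t = 0`,
#' `p = 1` rather than an error.
#'
#' @param a,b numeric vectors (each >= 2 finite values).
#' @return List with `t`, `df`, `p`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2 || !all(is.finite(c(a, b)))) {
    stop("each group needs at least 2 finite values", call. = FALSE)
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1))
    }
    return(list(t = sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2, p = 0))
  }
  ht <- t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Pearson correlation with two-tailed p-value
#'
#' Sample linear correlation; the p-value uses the t transform with `n - 2`
#' degrees of freedom, via [stats::cor.test()].
#'
#' @param x,y numeric vectors (n >= 3, both non-constant).
#' @return List with `r`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("need at least 3 paired values", call. = FALSE)
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("correlation undefined for a constant variable", call. = FALSE)
  }
  ht <- cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), p = ht$p.value, n = length(x))
}

#' Holm-Bonferroni step-down adjustment
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values (same order as input), monotone and capped at 1.
#' @export
holm_bonferroni <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(pvals, method = "holm")
}

#' Subgroup analysis of prediction accuracy
#'
#' For each binary participant factor (sex, limb shape, length class,
#' pediatric/adult age group) the two outcome metrics (signed volume
#' difference in % and mean L2 surface distance in mm) are compared with
#' Welch's t-test; age as a continuous covariate is tested against both
#' outcomes with Pearson's r. The resulting family (up to 10 p-values) is
#' Holm-Bonferroni corrected as a whole. A factor level with fewer than two
#' members makes that test non-estimable; it is excluded from the family.
#'
#' @param metrics data.frame with one row per participant: columns `id`,
#'   `v_diff_signed`, `mean_l2`.
#' @param meta data.frame with columns `id`, `sex`, `age`, `limb_length`,
#'   `length_class`, `shape_class`.
#' @param pediatric_cutoff age below which a participant is pediatric
#'   (default 18).
#' @return data.frame with one row per test: factor, test type, group sizes,
#'   group means/SDs (or r), statistic, df, p, holm_p, estimable.
#' @export
run_subgroup_analysis <- function(metrics, meta, pediatric_cutoff = 18) {
  df <- merge(metrics, meta, by = "id")
  if (nrow(df) < nrow(metrics)) stop("metadata missing for some participants",
                                     call. = FALSE)
  df$age_group <- ifelse(df$age < pediatric_cutoff, "pediatric", "adult")
  factors <- list(sex = c("F", "M"),
                  shape_class = c("conical", "cylindrical"),
                  length_class = c("short", "very_short"),
                  age_group = c("pediatric", "adult"))
  outcomes <- c(v_diff_signed = "v_diff_signed", mean_l2 = "mean_l2")
  rows <- list()
  for (fac in names(factors)) {
    lv <- factors[[fac]]
    for (oc in names(outcomes)) {
      a <- df[[oc]][df[[fac]] == lv[1]]
      b <- df[[oc]][df[[fac]] == lv[2]]
      est <- length(a) >= 2 && length(b) >= 2
      res <- if (est) welch_t(a, b) else list(t = NA_real_, df = NA_real_,
                                              p = NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        factor = fac, test = "welch_t", outcome = oc,
        group1 = lv[1], n1 = length(a),
        mean1 = if (length(a)) mean(a) else NA_real_,
        sd1 = if (length(a) > 1) sd(a) else NA_real_,
        group2 = lv[2], n2 = length(b),
        mean2 = if (length(b)) mean(b) else NA_real_,
        sd2 = if (length(b) > 1) sd(b) else NA_real_,
        statistic = res$t, df = res$df, p = res$p, estimable = est)
    }
  }
  for (oc in names(outcomes)) {
    est <- nrow(df) >= 3 && stats::var(df$age) > 0 && stats::var(df[[oc]]) > 0
    res <- if (est) pearson_r(df$age, df[[oc]]) else list(r = NA_real_,
                                                          p = NA_real_)
    rows[[length(rows) + 1L]] <- data.frame(
      factor = "age", test = "pearson_r", outcome = oc,
      group1 = "all", n1 = nrow(df), mean1 = NA_real_, sd1 = NA_real_,
      group2 = NA_character_, n2 = NA_integer_, mean2 = NA_real_,
      sd2 = NA_real_,
      statistic = res$r, df = if (est) res$n - 2 else NA_real_, p = res$p,
      estimable = est)
  }
  out <- do.call(rbind, rows)
  out$holm_p <- NA_real_
  est <- out$estimable
  out$holm_p[est] <- holm_bonferroni(out$p[est])
  out
}
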