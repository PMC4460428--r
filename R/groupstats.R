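#' One-way ANOVA across groups
#'
#' Standard fixed-effects one-way analysis of variance. Accepts either a
#' value vector plus a grouping factor, or a named list of numeric vectors.
#' Degenerate inputs are resolved explicitly: if the between-group sum of
#' squares is zero (all values equal) F is 0 with p = 1; if all within-group
#' variance is zero but groups differ, F is infinite with p = 0, flagged
#' with a warning.
#'
#' @param values Numeric vector, or a named list of numeric vectors (one
#'   per group, each of length >= 2).
#' @param groups Grouping factor (ignored when \code{values} is a list).
#' @return List with \code{F}, \code{p}, \code{df} (numerator,
#'   denominator).
#' @export
#' @examples
#' anova_oneway(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5)))$F  # 3
anova_oneway <- function(values, groups = NULL) {
  vg <- as_values_groups(values, groups)
  if (nlevels(vg$groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(table(vg$groups) < 2L))
    stop("every group needs at least 2 values", call. = FALSE)
  # degeneracy is detected on directly computed sums of squares; the qr-based
  # aov fit leaves ~1e-30 residuals where the exact answer is zero
  ssw <- sum((vg$values - stats::ave(vg$values, vg$groups))^2)
  ssb <- sum((stats::ave(vg$values, vg$groups) - mean(vg$values))^2)
  tab <- suppressWarnings(stats::anova(stats::aov(vg$values ~ vg$groups)))
  f <- tab[["F value"]][1]
  p <- tab[["Pr(>F)"]][1]
  if (ssb == 0) {
    f <- 0
    p <- 1
  } else if (ssw == 0) {
    warning("zero within-group variance: F is infinite")
    f <- Inf
    p <- 0
  }
  list(F = f, p = p, df = tab$Df)
}

as_values_groups <- function(values, groups) {
  if (is.list(values)) {
    groups <- factor(rep(names(values), lengths(values)),
                     levels = names(values))
    values <- unlist(values, use.names = FALSE)
  }
  stopifnot(length(values) == length(groups))
  keep <- is.finite(values) & !is.na(groups)
  list(values = values[keep], groups = droplevels(factor(groups[keep])))
}

#' Tukey-Kramer honest significant difference test
#'
#' All-pairs post-hoc comparison after a one-way ANOVA, using the
#' studentized-range distribution with the Kramer correction for unequal
#' group sizes (which makes the procedure conservative).
#'
#' @inheritParams anova_oneway
#' @param conf_level Family-wise confidence level.
#' @return data.frame with one row per unordered group pair: group_a,
#'   group_b, mean_diff, adjusted_p, significant_at_05.
#' @export
tukey_hsd <- function(values, groups = NULL, conf_level = 0.95) {
  vg <- as_values_groups(values, groups)
  if (nlevels(vg$groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(table(vg$groups) < 2L))
    stop("every group needs at least 2 values", call. = FALSE)
  fit <- stats::aov(values ~ groups, data = vg)
  tk <- stats::TukeyHSD(fit, conf.level = conf_level)$groups
  pairs <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
  out <- data.frame(group_a = pairs[, 1], group_b = pairs[, 2],
                    mean_diff = tk[, "diff"], adjusted_p = tk[, "p adj"],
                    significant_at_05 = tk[, "p adj"] < 0.05,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Pearson correlation of a network metric with a clinical score
#'
#' Runs the correlation per group and pooled over all subjects
#' (scope \code{"all"}), reporting p, R-squared and r for each scope as in
#' stage-wise clinical tables. Pairs with a missing value in either
#' variable are deleted pairwise; p-values are uncorrected by default
#' (set \code{adjust = "BH"} for Benjamini-Hochberg across scopes).
#'
#' @param metric Numeric vector of per-subject metric values.
#' @param score Numeric vector of per-subject clinical scores.
#' @param groups Optional grouping factor; when NULL only the pooled scope
#'   is computed.
#' @param metric_name,score_name Labels carried into the result.
#' @param adjust "none" (default) or "BH".
#' @return data.frame: metric_name, score_name, group_scope, n, r, R2, p,
#'   significant_at_05. Scopes with fewer than 3 complete pairs or a
#'   constant variable have NA statistics.
#' @export
correlate_metric_clinical <- function(metric, score, groups = NULL,
                                      metric_name = "metric",
                                      score_name = "score",
                                      adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(length(metric) == length(score))
  scopes <- list(all = seq_along(metric))
  if (!is.null(groups)) {
    stopifnot(length(groups) == length(metric))
    for (g in levels(factor(groups)))
      scopes[[g]] <- which(groups == g)
  }
  one <- function(idx, scope_name) {
    ok <- idx[stats::complete.cases(metric[idx], score[idx])]
    n_dropped <- length(idx) - length(ok)
    if (n_dropped > 0)
      an_log(n_dropped, " incomplete pairs dropped in scope ", scope_name)
    if (length(ok) < 3L || stats::sd(metric[ok]) == 0 ||
        stats::sd(score[ok]) == 0)
      return(data.frame(metric_name = metric_name, score_name = score_name,
                        group_scope = scope_name, n = length(ok),
                        r = NA_real_, R2 = NA_real_, p = NA_real_,
                        significant_at_05 = NA, stringsAsFactors = FALSE))
    ct <- stats::cor.test(metric[ok], score[ok], method = "pearson")
    r <- unname(ct$estimate)
    data.frame(metric_name = metric_name, score_name = score_name,
               group_scope = scope_name, n = length(ok), r = r, R2 = r^2,
               p = ct$p.value, significant_at_05 = ct$p.value < 0.05,
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, Map(one, scopes, names(scopes)))
  rownames(out) <- NULL
  if (adjust == "BH") {
    out$p <- stats::p.adjust(out$p, method = "BH")
    out$significant_at_05 <- out$p < 0.05
  }
  out
}
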