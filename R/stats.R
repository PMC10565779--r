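# Group statistics and reporting: Student's t, one-way ANOVA + Tukey HSD,
# mean +/- SEM summaries, significance stars.

#' Significance stars
#'
#' @param p P-value(s) in [0, 1].
#' @return \code{"ns"}, \code{"*"} (p < 0.05), \code{"**"} (p < 0.01) or
#'   \code{"***"} (p < 0.001).
#' @export
p_stars <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

.test_result <- function(name, statistic, df, p, alpha = 0.05) {
  structure(list(test = name, statistic = unname(statistic),
                 df = unname(df), p_value = unname(p), alpha = alpha,
                 significant = p < alpha, stars = p_stars(p)),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4f, df = %s, p = %.4g %s\n", x$test,
              x$statistic, paste(signif(x$df, 4), collapse = "/"),
              x$p_value, x$stars))
  invisible(x)
}

#' Unpaired two-tailed Student's t test
#'
#' Pooled-variance Student's t with df = n_a + n_b - 2, the per-comparison
#' test used throughout; Welch's correction is available behind a flag.
#' Degenerate inputs follow fixed conventions: zero pooled variance with
#' equal means gives p = 1; zero pooled variance with unequal means gives
#' p = 0 (flagged via an infinite statistic).
#'
#' @param a,b Numeric samples (each n >= 2).
#' @param alpha Significance level for the star/significant fields.
#' @param welch Use Welch's unequal-variance t instead.
#' @return A \code{"test_result"}: test, statistic, df, p_value, alpha,
#'   significant, stars.
#' @export
ttest_unpaired <- function(a, b, alpha = 0.05, welch = FALSE) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b))
      return(.test_result("student_t", 0, length(a) + length(b) - 2, 1, alpha))
    return(.test_result("student_t", sign(mean(a) - mean(b)) * Inf,
                        length(a) + length(b) - 2, 0, alpha))
  }
  ht <- stats::t.test(a, b, var.equal = !welch, alternative = "two.sided")
  .test_result(if (welch) "welch_t" else "student_t",
               ht$statistic, ht$parameter, ht$p.value, alpha)
}

#' One-way ANOVA with Tukey's post-hoc test
#'
#' Omnibus one-way ANOVA across three or more groups followed by Tukey HSD
#' pairwise comparisons with adjusted p-values.
#'
#' @param groups Named list of numeric samples (>= 3 groups, each n >= 2).
#' @param alpha Significance level.
#' @return List of class \code{"anova_tukey_result"}: \code{omnibus} (a
#'   \code{test_result} with the F statistic) and \code{pairwise} (a
#'   data.frame with comparison, diff, p_adj, stars).
#' @export
anova_tukey <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups))
  if (length(groups) < 3)
    stop("fewer than 3 groups: use ttest_unpaired")
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("every group needs n >= 2")
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  df <- data.frame(y = unlist(groups, use.names = FALSE),
                   g = factor(rep(names(groups),
                                  vapply(groups, length, integer(1)))))
  fit <- aov(y ~ g, data = df)
  tab <- summary(fit)[[1]]
  fstat <- tab[["F value"]][1]
  p <- tab[["Pr(>F)"]][1]
  if (is.na(fstat)) { fstat <- 0; p <- 1 } # all groups identical constants
  omnibus <- .test_result("anova_F", fstat,
                          c(tab[["Df"]][1], tab[["Df"]][2]), p, alpha)
  tk <- TukeyHSD(fit)$g
  pairwise <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                         lwr = tk[, "lwr"], upr = tk[, "upr"],
                         p_adj = tk[, "p adj"],
                         stars = p_stars(pmin(pmax(tk[, "p adj"], 0), 1)),
                         row.names = NULL)
  structure(list(omnibus = omnibus, pairwise = pairwise, alpha = alpha),
            class = "anova_tukey_result")
}

#' @export
print.anova_tukey_result <- function(x, ...) {
  print(x$omnibus)
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}

#' Group summaries as mean +/- SEM
#'
#' @param values Numeric vector of per-unit measurements.
#' @param group Group labels, same length.
#' @param units Unit string for the measure.
#' @return A \code{data.frame} of class \code{"group_summary"}: group, n,
#'   mean, sem, units, and a formatted \code{label} "mean +/- SEM, n = n"
#'   (SEM is NA for single observations).
#' @export
summarize_groups <- function(values, group, units = "") {
  stopifnot(length(values) == length(group))
  out <- do.call(rbind, lapply(split(values, group), function(v) {
    sem <- if (length(v) >= 2) stats::sd(v) / sqrt(length(v)) else NA_real_
    data.frame(n = length(v), mean = mean(v), sem = sem)
  }))
  out <- data.frame(group = rownames(out), out, units = units,
                    row.names = NULL)
  out$label <- sprintf("%.2f ± %s, n = %d", out$mean,
                       ifelse(is.na(out$sem), "NA", sprintf("%.2f", out$sem)),
                       out$n)
  class(out) <- c("group_summary", "data.frame")
  out
}
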