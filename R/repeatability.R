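check_measures <- function(data, subject_col = "subject_id",
                           value_col = "value") {
  if (!is.data.frame(data) || !all(c(subject_col, value_col) %in% names(data)))
    stop(sprintf("`data` must contain columns '%s' and '%s'",
                 subject_col, value_col))
  v <- data[[value_col]]
  bad <- which(!is.finite(v) | v <= 0)
  if (length(bad) > 0)
    stop(sprintf(
      "non-positive or non-finite value (row %d, subject %s): %s values must be strictly positive for the log transform",
      bad[1], data[[subject_col]][bad[1]], value_col))
  invisible(data)
}

#' Within-subject coefficient of variation (Bland-Altman log method)
#'
#' Natural logs of the repeated measurements are taken; within-subject
#' deviations from each subject's own mean are pooled across subjects
#' (df = sum over subjects of k_i - 1, a subject with one visit contributing
#' none), giving the pooled within-subject log-SD s_w.  The wCV is the
#' back-transform \code{exp(s_w) - 1}, reported in percent.  The 95%
#' confidence bounds come from the chi-square interval for the pooled
#' within-subject variance on its pooled df, each limit mapped through
#' \code{exp(sqrt(.)) - 1}.  One-way variance components on the log scale
#' (\code{\link{variance_components}}) are attached when at least two
#' subjects are present; the intra-subject component equals s_w^2.
#'
#' @param data Data frame of repeated measures.
#' @param subject_col,value_col Column names (values must be strictly
#'   positive).
#' @param conf_level Confidence level for the wCV bounds (default 0.95).
#' @return An object of class \code{repeatability_result}: \code{wcv}
#'   (percent), \code{wcv_bounds} (percent), \code{s_w}, \code{df},
#'   \code{inter_vc}, \code{intra_vc}, \code{ci_method}.
#' @export
wcv <- function(data, subject_col = "subject_id", value_col = "value",
                conf_level = 0.95) {
  check_measures(data, subject_col, value_col)
  logs <- log(data[[value_col]])
  subj <- factor(data[[subject_col]])
  k <- tabulate(subj)
  ss <- tapply(logs, subj, function(x) sum((x - mean(x))^2))
  df <- sum(k - 1)
  if (df < 1)
    stop("no within-subject replication: need >= 2 visits for >= 1 subject")
  s2 <- sum(ss) / df
  s_w <- sqrt(s2)
  alpha <- 1 - conf_level
  s2_bounds <- df * s2 / qchisq(c(1 - alpha / 2, alpha / 2), df)
  vc <- if (nlevels(subj) >= 2) {
    variance_components(data, subject_col, value_col)
  } else {
    list(inter_vc = NA_real_, intra_vc = s2)
  }
  structure(list(
    wcv = 100 * (exp(s_w) - 1),
    wcv_bounds = 100 * (exp(sqrt(s2_bounds)) - 1),
    s_w = s_w, df = df,
    inter_vc = vc$inter_vc, intra_vc = vc$intra_vc,
    ci_method = "chi-square on pooled within-subject log variance",
    conf_level = conf_level
  ), class = "repeatability_result")
}

#' @export
print.repeatability_result <- function(x, ...) {
  cat(sprintf("<repeatability_result> wCV = %.1f%% (%.0f%% CI %.1f-%.1f%%), df = %d\n",
              x$wcv, 100 * x$conf_level, x$wcv_bounds[1], x$wcv_bounds[2],
              x$df))
  cat(sprintf("  log-scale variance components: inter = %.4g, intra = %.4g\n",
              x$inter_vc, x$intra_vc))
  invisible(x)
}

#' One-way variance components on the log scale
#'
#' Method-of-moments (ANOVA) estimates for the one-way random-effects layout
#' of log-transformed repeated measures: the intra-subject component is the
#' within-group mean square; the inter-subject component is
#' \code{max(0, (MS_between - MS_within) / k0)} with \code{k0} the
#' (un)balanced-design group-size coefficient
#' \code{(N - sum(k_i^2) / N) / (a - 1)}.  Truncation at zero yields the
#' conventional printed "0.000" when between-subject spread is below the
#' within-subject noise floor.
#'
#' @inheritParams wcv
#' @return List with \code{inter_vc} and \code{intra_vc} (log-scale
#'   variances).
#' @export
variance_components <- function(data, subject_col = "subject_id",
                                value_col = "value") {
  check_measures(data, subject_col, value_col)
  logs <- log(data[[value_col]])
  subj <- factor(data[[subject_col]])
  a <- nlevels(subj)
  if (a < 2) stop("need measurements from at least 2 subjects")
  k <- tabulate(subj)
  n <- length(logs)
  if (n - a < 1)
    stop("no within-subject replication: need repeated visits")
  means <- tapply(logs, subj, mean)
  grand <- mean(logs)
  ssw <- sum(tapply(logs, subj, function(x) sum((x - mean(x))^2)))
  ssb <- sum(k * (means - grand)^2)
  msw <- ssw / (n - a)
  msb <- ssb / (a - 1)
  k0 <- (n - sum(k^2) / n) / (a - 1)
  list(inter_vc = max(0, (msb - msw) / k0), intra_vc = msw)
}

#' Paired log-scale comparisons between analysis methods
#'
#' For each requested contrast between two method combinations, pairs the
#' observations sharing (subject, visit, parameter), takes the paired mean
#' difference of natural logs, and tests it with a two-sided paired t test.
#' P-values are Bonferroni-adjusted over the supplied family of contrasts
#' (across all parameters), so with 13 contrasts the effective
#' per-comparison significance cutoff at overall alpha 0.05 is
#' 0.05 / 13 = 0.0038.
#'
#' @param data Data frame with columns \code{subject_id}, \code{visit_day},
#'   \code{parameter}, \code{method_combo}, \code{value} (> 0).
#' @param comparisons Data frame with columns \code{parameter}, \code{a},
#'   \code{b}: each row contrasts method combo \code{a} vs \code{b} for one
#'   parameter.
#' @param alpha Overall type I error rate (default 0.05).
#' @return Data frame with one row per contrast: \code{parameter},
#'   \code{comparison}, \code{estimate} (log-scale paired mean difference),
#'   \code{se}, \code{p}, \code{p_adj}, \code{significant}.  The
#'   per-comparison cutoff \code{alpha / nrow(comparisons)} is attached as
#'   attribute \code{"cutoff"}.
#' @export
compare_methods <- function(data, comparisons, alpha = 0.05) {
  check_measures(data, "subject_id", "value")
  need <- c("subject_id", "visit_day", "parameter", "method_combo")
  if (!all(need %in% names(data)))
    stop("`data` must contain columns ",
         paste(need, collapse = ", "), ", value")
  if (!is.data.frame(comparisons) ||
      !all(c("parameter", "a", "b") %in% names(comparisons)))
    stop("`comparisons` must have columns parameter, a, b")
  m <- nrow(comparisons)
  cutoff <- alpha / m

  rows <- lapply(seq_len(m), function(i) {
    cmp <- comparisons[i, ]
    sub <- data[data$parameter == cmp$parameter &
                  data$method_combo %in% c(cmp$a, cmp$b), ]
    da <- sub[sub$method_combo == cmp$a, ]
    db <- sub[sub$method_combo == cmp$b, ]
    key_a <- paste(da$subject_id, da$visit_day)
    key_b <- paste(db$subject_id, db$visit_day)
    if (length(key_a) == 0 || !setequal(key_a, key_b) ||
        anyDuplicated(key_a) || anyDuplicated(key_b))
      stop(sprintf(
        "contrast %s vs %s for %s: observations are not fully paired",
        cmp$a, cmp$b, cmp$parameter))
    diffs <- log(da$value) - log(db$value[match(key_a, key_b)])
    if (sd(diffs) < .Machine$double.eps^0.5 * max(abs(diffs), 1)) {
      est <- mean(diffs)
      p <- if (abs(est) < .Machine$double.eps^0.5) 1 else 0
      se <- 0
    } else {
      tt <- t.test(diffs)
      est <- unname(tt$estimate); p <- tt$p.value
      se <- unname(tt$stderr)
    }
    data.frame(parameter = cmp$parameter,
               comparison = paste(cmp$a, "vs", cmp$b),
               estimate = est, se = se, p = p,
               p_adj = min(1, p * m),
               significant = p < cutoff)
  })
  out <- do.call(rbind, rows)
  attr(out, "cutoff") <- cutoff
  out
}
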