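#' Subject x condition table of one metric
#'
#' @param values Numeric subjects x conditions matrix, or a long
#'   data.frame with columns `subject`, `condition`, `value`.
#' @param subject_ids,condition_names Optional dimnames for a matrix
#'   input.
#' @return A matrix of class `subject_condition_table` (subjects in rows).
#' @export
subject_condition_table <- function(values, subject_ids = NULL,
                                    condition_names = NULL) {
  if (is.data.frame(values)) {
    need <- c("subject", "condition", "value")
    if (!all(need %in% names(values)))
      stopf("long input needs columns %s", paste(need, collapse = ", "))
    wide <- tapply(values$value, list(values$subject, values$condition),
                   mean)
    values <- wide
  }
  if (!is.matrix(values)) stopf("`values` must be a matrix or long data.frame")
  if (nrow(values) < 2L) stopf("repeated-measures analysis needs >= 2 subjects")
  if (ncol(values) < 2L) stopf("need >= 2 conditions")
  if (!is.null(subject_ids)) rownames(values) <- subject_ids
  if (!is.null(condition_names)) colnames(values) <- condition_names
  if (is.null(rownames(values))) rownames(values) <- seq_len(nrow(values))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("C%d", seq_len(ncol(values)))
  class(values) <- c("subject_condition_table", class(values))
  values
}

as_sct <- function(x) {
  if (inherits(x, "subject_condition_table")) x
  else subject_condition_table(x)
}

#' Normality and homogeneity checks
#'
#' Per-condition Lilliefors-corrected Kolmogorov-Smirnov tests against a
#' normal with estimated mean and SD, and Levene's test (mean-centered) of
#' variance homogeneity across conditions. Advisory: the result carries
#' `ok` flags but analysis is not blocked.
#'
#' @param table A [subject_condition_table()] (or matrix/long
#'   data.frame).
#' @param alpha Flagging level (default 0.05).
#' @return List with data.frame `normality` (condition, statistic, p, ok)
#'   and one-row data.frame `homogeneity` (statistic, df1, df2, p, ok).
#' @export
check_assumptions <- function(table, alpha = 0.05) {
  tab <- as_sct(table)
  norm <- do.call(rbind, lapply(colnames(tab), function(cn) {
    x <- tab[, cn]
    kt <- nortest::lillie.test(x)
    data.frame(condition = cn, statistic = unname(kt$statistic),
               p = kt$p.value, ok = kt$p.value > alpha,
               stringsAsFactors = FALSE)
  }))
  long <- data.frame(value = as.vector(tab),
                     condition = factor(rep(colnames(tab),
                                            each = nrow(tab))))
  lev <- car::leveneTest(value ~ condition, data = long, center = mean)
  hom <- data.frame(statistic = lev[1, "F value"], df1 = lev[1, "Df"],
                    df2 = lev[2, "Df"], p = lev[1, "Pr(>F)"],
                    ok = lev[1, "Pr(>F)"] > alpha)
  if (any(!norm$ok))
    warnf("normality check failed in condition(s): %s (advisory)",
          paste(norm$condition[!norm$ok], collapse = ", "))
  if (!hom$ok) warnf("variance homogeneity check failed (advisory)")
  list(normality = norm, homogeneity = hom)
}

#' One-way repeated-measures ANOVA
#'
#' Classical within-subject one-way ANOVA: the condition effect is tested
#' against the condition-by-subject interaction,
#' `F = MS_condition / MS_(condition x subject)` with
#' `df = (c - 1, (c - 1)(s - 1))`.
#'
#' @param table A complete [subject_condition_table()].
#' @return List of class `rm_anova` with `F`, `df` (length 2), `p`,
#'   `ms_error`, `df_error`, `means` (condition means), `n` (subjects).
#' @export
rm_anova_oneway <- function(table) {
  tab <- as_sct(table)
  if (anyNA(tab)) stopf("RM-ANOVA requires a complete table (no missing cells)")
  s <- nrow(tab); c <- ncol(tab)
  long <- data.frame(value = as.vector(unclass(tab)),
                     subject = factor(rep(rownames(tab), times = c)),
                     condition = factor(rep(colnames(tab), each = s)))
  fit <- aov(value ~ condition + Error(subject), data = long)
  sm <- summary(fit)[["Error: Within"]][[1]]
  Fv <- sm["condition", "F value"]
  p <- sm["condition", "Pr(>F)"]
  ms_err <- sm["Residuals", "Mean Sq"]
  structure(list(F = unname(Fv), df = c(c - 1, (c - 1) * (s - 1)),
                 p = unname(p), ms_error = unname(ms_err),
                 df_error = (c - 1) * (s - 1),
                 means = colMeans(tab), n = s),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("RM-ANOVA: F(%d, %d) = %.4f, p = %.4g\n",
              x$df[1], x$df[2], x$F, x$p))
  invisible(x)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; monotone, each adjusted value
#' at least the raw value and capped at 1.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
fdr_bh <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Scheffe post hoc contrasts after a repeated-measures ANOVA
#'
#' For every condition pair the Scheffe statistic uses the ANOVA error
#' mean square: `F_S = (m_A - m_B)^2 / (2 MS_err / n) / (c - 1)` compared
#' against `F(c - 1, df_err)`. The direction string `"A > B"` is reported
#' for pairs significant at `alpha`.
#'
#' @param table The [subject_condition_table()] that was analysed.
#' @param anova A [rm_anova_oneway()] result for `table` (recomputed when
#'   missing).
#' @param alpha Significance level for the direction column
#'   (default 0.05).
#' @return data.frame with columns `pair`, `diff`, `F`, `p`, `direction`
#'   (empty when not significant).
#' @export
scheffe_posthoc <- function(table, anova = NULL, alpha = 0.05) {
  tab <- as_sct(table)
  anova <- anova %||% rm_anova_oneway(tab)
  cn <- colnames(tab)
  c <- ncol(tab); n <- nrow(tab)
  pairs <- utils::combn(cn, 2, simplify = FALSE)
  out <- do.call(rbind, lapply(pairs, function(pr) {
    d <- anova$means[pr[1]] - anova$means[pr[2]]
    Fs <- (d^2 / (2 * anova$ms_error / n)) / (c - 1)
    p <- pf(Fs, c - 1, anova$df_error, lower.tail = FALSE)
    dir <- if (p >= alpha) ""
           else if (d > 0) sprintf("%s > %s", pr[1], pr[2])
           else sprintf("%s > %s", pr[2], pr[1])
    data.frame(pair = paste(pr, collapse = " vs "), diff = unname(d),
               F = unname(Fs), p = unname(p), direction = dir,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Cohen's d with effect-size band
#'
#' `d = (mean(x) - mean(y)) / s_pooled`; the band classifies `|d|` as
#' small (< 0.2), moderate (0.2 to 0.8) or large (> 0.8).
#'
#' @param x,y Numeric samples (each length >= 2).
#' @return List with `d` and `band`.
#' @export
cohens_d <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) stopf("both samples need >= 2 values")
  n1 <- length(x); n2 <- length(y)
  sp <- sqrt(((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2))
  if (sp == 0) stopf("pooled SD is zero; d undefined")
  d <- (mean(x) - mean(y)) / sp
  list(d = d, band = effect_band(abs(d)))
}

effect_band <- function(a) {
  if (a < 0.2) "small" else if (a <= 0.8) "moderate" else "large"
}

#' Pearson correlation with strength band
#'
#' Correlates a complexity metric with a behavioural score and classifies
#' `|r|` as low (< 0.3), moderate (0.3 to 0.6) or strong (> 0.6). The
#' reporting convention of showing only `|r| > 0.45` is exposed as the
#' `reportable` flag and applied only at formatting time.
#'
#' @param metric_values,behavior_values Paired numeric vectors,
#'   length >= 3.
#' @return List with `r`, `p` (two-sided), `band`, `reportable`.
#' @export
correlate_behavior <- function(metric_values, behavior_values) {
  x <- as.numeric(metric_values); y <- as.numeric(behavior_values)
  if (length(x) != length(y)) stopf("inputs must be paired")
  if (length(x) < 3L) stopf("need >= 3 pairs")
  if (sd(x) == 0 || sd(y) == 0)
    stopf("zero variance in one of the vectors; correlation undefined")
  ct <- cor.test(x, y, method = "pearson")
  r <- unname(ct$estimate)
  band <- if (abs(r) < 0.3) "low" else if (abs(r) <= 0.6) "moderate"
          else "strong"
  list(r = r, p = ct$p.value, band = band, reportable = abs(r) > 0.45)
}

#' Minimum sample size for the within-factor repeated-measures F test
#'
#' Noncentral-F power computation in the G*Power "within factors"
#' convention: noncentrality `lambda = n m f^2 / (1 - rho)` and degrees of
#' freedom `((m - 1) eps, (n - 1)(m - 1) eps)`, where `m` is the number of
#' repeated measurements, `rho` the correlation among them and `eps` the
#' nonsphericity correction. Returns the smallest subject count reaching
#' the target power.
#'
#' @param effect_size_f Cohen's f (> 0).
#' @param alpha Type-I level (default 0.05).
#' @param target_power Desired power (default 0.8).
#' @param n_groups Number of between groups (default 1).
#' @param n_measurements Repeated measurements m (default 3).
#' @param corr_rep Correlation among repeated measures (default 0.5).
#' @param epsilon Nonsphericity correction in (0, 1] (default 1).
#' @param n_cap Search cap (default 1e6; exceeding it is an error).
#' @return Integer minimum total sample size, with achieved power in
#'   attribute `"power"`.
#' @examples
#' rm_anova_sample_size(0.25, 0.05, 0.8, 1, 3, 0.5, 1)  # 28
#' @export
rm_anova_sample_size <- function(effect_size_f, alpha = 0.05,
                                 target_power = 0.8, n_groups = 1,
                                 n_measurements = 3, corr_rep = 0.5,
                                 epsilon = 1, n_cap = 1e6) {
  if (effect_size_f <= 0) stopf("effect_size_f must be > 0")
  if (alpha <= 0 || alpha >= 1) stopf("alpha must be in (0, 1)")
  if (target_power <= 0 || target_power >= 1)
    stopf("target_power must be in (0, 1)")
  if (corr_rep < 0 || corr_rep >= 1) stopf("corr_rep must be in [0, 1)")
  if (epsilon <= 0 || epsilon > 1) stopf("epsilon must be in (0, 1]")
  m <- n_measurements; g <- n_groups
  power_at <- function(n) {
    lambda <- n * m * effect_size_f^2 / (1 - corr_rep)
    df1 <- (m - 1) * epsilon
    df2 <- (n - g) * (m - 1) * epsilon
    if (df2 <= 0) return(0)
    1 - pf(qf(1 - alpha, df1, df2), df1, df2, ncp = lambda)
  }
  n <- g + 1
  while (power_at(n) < target_power) {
    n <- n + 1
    if (n > n_cap)
      stopf("required sample size exceeds cap (%g); target power unreachable",
            n_cap)
  }
  structure(as.integer(n), power = power_at(n))
}

#' Repeated-measures ANOVA across metrics with FDR correction
#'
#' Runs [rm_anova_oneway()] per metric of a long table and corrects the
#' omnibus p-values across metrics with Benjamini-Hochberg. Scheffe
#' contrasts and Cohen's d per condition pair complete the report.
#'
#' @param metrics_long data.frame with columns `subject`, `condition`,
#'   `metric`, `value` (e.g. from [study_sequence_metrics()]).
#' @param alpha Significance level (default 0.05).
#' @return data.frame with one row per metric: `metric`, `F`, `df1`,
#'   `df2`, `p`, `p_fdr`, `significant`, and for each pair the Scheffe
#'   direction of significant contrasts (column `post_hoc`).
#' @export
rm_anova_by_metric <- function(metrics_long, alpha = 0.05) {
  need <- c("subject", "condition", "metric", "value")
  if (!all(need %in% names(metrics_long)))
    stopf("need columns %s", paste(need, collapse = ", "))
  ms <- unique(metrics_long$metric)
  rows <- lapply(ms, function(m) {
    sub <- metrics_long[metrics_long$metric == m, ]
    tab <- subject_condition_table(sub)
    an <- rm_anova_oneway(tab)
    ph <- scheffe_posthoc(tab, an, alpha = alpha)
    dir <- paste(ph$direction[nzchar(ph$direction)], collapse = "; ")
    data.frame(metric = m, F = an$F, df1 = an$df[1], df2 = an$df[2],
               p = an$p, post_hoc = dir, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- fdr_bh(out$p)
  out$significant <- out$p_fdr < alpha
  out[, c("metric", "F", "df1", "df2", "p", "p_fdr", "significant",
          "post_hoc")]
}
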