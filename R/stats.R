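#' Paired sample container
#'
#' Two measurements per animal (e.g. mean seizure count per bin during
#' normoxia and during hypoxia), animals being the experimental unit.
#'
#' @param animal Animal identifiers.
#' @param a,b Condition values, same ordering as `animal`.
#' @param conditions Length-2 character vector of condition names.
#' @param measure Measure label (units in the label, e.g.
#'   `"SWS count per 5-min bin"`).
#' @return Data frame of class `paired_sample`.
#' @export
paired_sample <- function(animal, a, b,
                          conditions = c("condition_a", "condition_b"),
                          measure = "value") {
  if (length(a) != length(b) || length(a) != length(animal)) {
    stop("`animal`, `a` and `b` must have equal length")
  }
  if (length(a) < 2) stop("a paired sample needs n >= 2 animals")
  df <- data.frame(animal = animal, a = as.numeric(a), b = as.numeric(b),
                   stringsAsFactors = FALSE)
  attr(df, "conditions") <- conditions
  attr(df, "measure") <- measure
  class(df) <- c("paired_sample", "data.frame")
  df
}

#' Normality gate for paired differences
#'
#' All data are tested for normality before the comparison: Shapiro-Wilk
#' on the paired differences; the parametric branch is taken when
#' `p >= alpha`. Constant differences (zero variance) are outside the
#' test's domain and default to the parametric branch (the degenerate case
#' is handled by [paired_compare()] directly).
#'
#' @param d Numeric vector of paired differences, n >= 3.
#' @param alpha Gate level.
#' @return List `p` (Shapiro-Wilk p, `NA` for constant input) and
#'   `parametric` (logical).
#' @export
normality_gate <- function(d, alpha = 0.05) {
  if (length(d) < 3) stop("normality testing needs n >= 3 differences")
  if (stats::sd(d) == 0) return(list(p = NA_real_, parametric = TRUE))
  p <- stats::shapiro.test(d)$p.value
  list(p = p, parametric = p >= alpha)
}

#' Normality-gated paired comparison
#'
#' Paired t-test when the differences pass the Shapiro-Wilk gate, Wilcoxon
#' signed-rank otherwise (exact p for n <= 25 without ties or zero
#' differences, normal approximation with continuity correction above).
#' All-zero differences give a degenerate result with p = 1. Condition
#' summaries are reported as mean +/- SEM.
#'
#' @param sample A [paired_sample()].
#' @param alpha Significance level.
#' @return List of class `stat_result`: `test_name`, `statistic`, `df`,
#'   `p_value`, `n`, `means`, `ses`, `conditions`, `normality_p`, `alpha`,
#'   `measure`.
#' @export
paired_compare <- function(sample, alpha = 0.05) {
  stopifnot(inherits(sample, "paired_sample"))
  a <- sample$a; b <- sample$b
  n <- length(a)
  d <- b - a
  se <- function(v) stats::sd(v) / sqrt(length(v))
  base <- list(n = n, means = c(mean(a), mean(b)), ses = c(se(a), se(b)),
               conditions = attr(sample, "conditions"),
               measure = attr(sample, "measure"), alpha = alpha)
  if (all(d == 0)) {
    res <- c(list(test_name = "degenerate (all differences zero)",
                  statistic = 0, df = n - 1, p_value = 1,
                  normality_p = NA_real_), base)
    class(res) <- "stat_result"
    return(res)
  }
  gate <- normality_gate(d, alpha)
  if (gate$parametric) {
    tt <- stats::t.test(b, a, paired = TRUE)
    res <- c(list(test_name = "paired t-test",
                  statistic = unname(tt$statistic),
                  df = unname(tt$parameter), p_value = tt$p.value,
                  normality_p = gate$p), base)
  } else {
    wt <- suppressWarnings(
      stats::wilcox.test(b, a, paired = TRUE, exact = n <= 25,
                         correct = TRUE))
    res <- c(list(test_name = "Wilcoxon signed-rank",
                  statistic = unname(wt$statistic), df = NA_real_,
                  p_value = wt$p.value, normality_p = gate$p), base)
  }
  class(res) <- "stat_result"
  res
}

#' @export
print.stat_result <- function(x, ...) {
  cat("<stat_result> ", x$measure, "\n", sep = "")
  for (i in 1:2) {
    cat(sprintf("  %s: %.4g +/- %.4g\n", x$conditions[i], x$means[i],
                x$ses[i]))
  }
  cat(sprintf("  %s: statistic = %.4g, df = %s, p = %.3g, n = %d\n",
              x$test_name, x$statistic,
              if (is.na(x$df)) "-" else format(round(x$df, 3)),
              x$p_value, x$n))
  invisible(x)
}

# Greenhouse-Geisser epsilon from the double-centered condition covariance.
gg_epsilon <- function(S) {
  k <- ncol(S)
  H <- diag(k) - matrix(1 / k, k, k)
  D <- H %*% S %*% H
  denom <- (k - 1) * sum(D^2)
  if (denom <= 0) return(1)
  sum(diag(D))^2 / denom
}

#' One-way repeated-measures ANOVA with sphericity correction
#'
#' Within-subject ANOVA on an animals x conditions matrix. The F ratio is
#' `(SS_condition / df1) / (SS_error / df2)` after removing the per-animal
#' effect; degrees of freedom are scaled by the Greenhouse-Geisser epsilon
#' estimated from the condition covariance matrix (Huynh-Feldt available).
#' With k = 2 conditions epsilon is exactly 1 and F equals the square of
#' the paired t statistic. Pairwise post-hoc comparisons run through
#' [paired_compare()] with Holm correction.
#'
#' @param data Numeric matrix (or data frame), rows = animals, columns =
#'   conditions; complete cases required (no imputation).
#' @param correction `"greenhouse-geisser"` (default), `"huynh-feldt"`, or
#'   `"none"`.
#' @param posthoc Run Holm-corrected pairwise comparisons.
#' @param alpha Significance level.
#' @return List of class `rm_anova_result`: `F`, `df1`, `df2` (corrected,
#'   possibly non-integer), `p_value`, `epsilon`, `correction`,
#'   `df1_uncorrected`, `df2_uncorrected`, `ss_condition`, `ss_error`,
#'   `n`, `k`, `means`, `ses`, `posthoc` (data frame or `NULL`).
#' @export
rm_anova_gg <- function(data, correction = c("greenhouse-geisser",
                                             "huynh-feldt", "none"),
                        posthoc = TRUE, alpha = 0.05) {
  correction <- match.arg(correction)
  m <- as.matrix(data)
  if (anyNA(m)) stop("missing cells are not supported (no imputation)")
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("need at least 2 animals and 2 conditions")
  grand <- mean(m)
  col_m <- colMeans(m)
  row_m <- rowMeans(m)
  ss_cond <- n * sum((col_m - grand)^2)
  resid <- m - outer(row_m, col_m, "+") + grand
  ss_err <- sum(resid^2)
  df1 <- k - 1
  df2 <- (k - 1) * (n - 1)
  eps <- switch(correction,
                "greenhouse-geisser" = gg_epsilon(stats::cov(m)),
                "huynh-feldt" = {
                  e <- gg_epsilon(stats::cov(m))
                  min(1, (n * (k - 1) * e - 2) /
                        ((k - 1) * (n - 1 - (k - 1) * e)))
                },
                "none" = 1)
  if (ss_cond <= .Machine$double.eps * n * k * max(1, grand^2)) {
    Fval <- 0; p <- 1
  } else {
    Fval <- (ss_cond / df1) / (ss_err / df2)
    p <- stats::pf(Fval, eps * df1, eps * df2, lower.tail = FALSE)
  }
  ph <- NULL
  if (posthoc && k >= 2) {
    pairs <- utils::combn(k, 2)
    cn <- colnames(m)
    if (is.null(cn)) cn <- paste0("cond_", seq_len(k))
    ph <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      i1 <- pairs[1, j]; i2 <- pairs[2, j]
      r <- paired_compare(paired_sample(seq_len(n), m[, i1], m[, i2],
                                        conditions = cn[c(i1, i2)]))
      data.frame(comparison = paste(cn[i1], "vs", cn[i2]),
                 test = r$test_name, statistic = r$statistic,
                 p_value = r$p_value, stringsAsFactors = FALSE)
    }))
    ph$p_holm <- stats::p.adjust(ph$p_value, method = "holm")
  }
  se <- function(v) stats::sd(v) / sqrt(length(v))
  structure(list(F = Fval, df1 = eps * df1, df2 = eps * df2, p_value = p,
                 epsilon = eps, correction = correction,
                 df1_uncorrected = df1, df2_uncorrected = df2,
                 ss_condition = ss_cond, ss_error = ss_err, n = n, k = k,
                 means = col_m, ses = apply(m, 2, se), posthoc = ph,
                 alpha = alpha),
            class = "rm_anova_result")
}

#' @export
print.rm_anova_result <- function(x, ...) {
  cat(sprintf(
    "<rm_anova_result> F(%.3f, %.3f) = %.4g, p = %.3g (%s, eps = %.3f)\n",
    x$df1, x$df2, x$F, x$p_value, x$correction, x$epsilon))
  if (!is.null(x$posthoc)) {
    cat("post-hoc (Holm):\n")
    print(x$posthoc)
  }
  invisible(x)
}

#' Results table from a list of comparisons
#'
#' One row per comparison in the layout of the study's summary tables:
#' per-condition mean +/- SEM, n, the test used, its statistic, df, and p.
#'
#' @param results List of `stat_result` objects from [paired_compare()].
#' @param path Optional CSV path to write.
#' @return Data frame with columns `comparison`, `condition_a`,
#'   `mean_se_a`, `condition_b`, `mean_se_b`, `n`, `test`, `statistic`,
#'   `df`, `p_value`.
#' @export
results_table <- function(results, path = NULL) {
  fmt <- function(m, s) sprintf("%.3g ± %.3g", m, s)
  rows <- lapply(results, function(r) {
    stopifnot(inherits(r, "stat_result"))
    data.frame(comparison = r$measure,
               condition_a = r$conditions[1],
               mean_se_a = fmt(r$means[1], r$ses[1]),
               condition_b = r$conditions[2],
               mean_se_b = fmt(r$means[2], r$ses[2]),
               n = r$n, test = r$test_name, statistic = r$statistic,
               df = r$df, p_value = r$p_value,
               stringsAsFactors = FALSE)
  })
  tab <- if (length(rows) == 0) {
    data.frame(comparison = character(), condition_a = character(),
               mean_se_a = character(), condition_b = character(),
               mean_se_b = character(), n = integer(), test = character(),
               statistic = numeric(), df = numeric(), p_value = numeric(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows)
  }
  if (!is.null(path)) utils::write.csv(tab, path, row.names = FALSE)
  tab
}
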