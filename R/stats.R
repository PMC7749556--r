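#' Per-tract ANCOVA group effect
#'
#' Fits outcome ~ group + covariates by least squares, with the three-level
#' group factor coded as two dummies against the HC reference, and tests
#' the group effect with the partial F statistic comparing the full model
#' against the covariates-only model (exact F reference distribution).
#' Covariate effects are reported as the full-model coefficient t tests.
#' The default covariate set is age, gender, illness duration and number
#' of depressive episodes; duration and episodes are zero-filled in
#' controls but vary in patients, so the design remains full rank. Rows
#' with missing values in the outcome or any covariate are dropped
#' (listwise within this model).
#'
#' @param table a `cohort_table` (or plain data.frame with the columns).
#' @param outcome name of the numeric outcome column (e.g. `"fa_body_cc_L"`).
#' @param covariates character vector of covariate column names.
#' @param group_col name of the group column.
#' @return An object of class `ancova_result`: outcome name, group `F`,
#'   `p`, numerator/denominator df, `n` used, a `covariates` data.frame
#'   (term, estimate, t, p), the fitted coefficients and their covariance
#'   (reused by [posthoc_pairwise()]), and a `significant` flag (set by
#'   [family_correct()], `NA` until then).
#' @export
ancova_group_effect <- function(table, outcome,
                                covariates = c("age", "gender", "duration", "episodes"),
                                group_col = "group") {
  prep <- ancova_design(table, outcome, covariates, group_col)
  fit <- ancova_fit(prep$X_full, prep$X_red, matrix(prep$y, ncol = 1))
  cov_idx <- match(covariates, colnames(prep$X_full))
  res <- structure(list(
    outcome = outcome,
    F = fit$F[1], p = fit$p[1], df1 = fit$df1, df2 = fit$df2,
    n = length(prep$y),
    covariates = data.frame(term = covariates,
                            estimate = fit$coef[cov_idx, 1],
                            t = fit$t[cov_idx, 1],
                            p = fit$coef_p[cov_idx, 1],
                            row.names = NULL),
    coef = fit$coef[, 1], vcov = fit$vcov[[1]], df_resid = fit$df2,
    significant = NA), class = "ancova_result")
  res
}

# Shared design construction: complete cases, level checks, rank check.
ancova_design <- function(table, outcome, covariates, group_col) {
  cols <- c(outcome, group_col, covariates)
  miss <- setdiff(cols, names(table))
  if (length(miss) > 0L) {
    stop_tendtract("bad_input", "missing column(s): %s", paste(miss, collapse = ", "))
  }
  dat <- table[stats::complete.cases(table[, cols, drop = FALSE]), cols, drop = FALSE]
  g <- factor(dat[[group_col]], levels = c("HC", "MDD", "BD"))
  counts <- table(g)
  if (any(counts < 2L)) {
    stop_tendtract("bad_input",
                   "each group needs >= 2 complete observations; got %s",
                   paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
  }
  X_red <- cbind(`(Intercept)` = 1,
                 as.matrix(dat[, covariates, drop = FALSE]))
  X_full <- cbind(X_red[, 1, drop = FALSE],
                  groupMDD = as.numeric(g == "MDD"),
                  groupBD = as.numeric(g == "BD"),
                  X_red[, -1, drop = FALSE])
  qrf <- qr(X_full)
  if (qrf$rank < ncol(X_full)) {
    dropped <- colnames(X_full)[qrf$pivot[(qrf$rank + 1L):ncol(X_full)]]
    stop_tendtract("collinear_design",
                   "design matrix is rank deficient; offending column(s): %s",
                   paste(dropped, collapse = ", "))
  }
  list(y = as.numeric(dat[[outcome]]), X_full = X_full, X_red = X_red, group = g)
}

# Core least-squares machinery shared by the single-outcome and batch
# paths: Y may hold many outcome columns over one common design.
ancova_fit <- function(X_full, X_red, Y) {
  n <- nrow(X_full)
  qf <- qr(X_full)
  qr_red <- qr(X_red)
  rss_f <- colSums(qr.resid(qf, Y)^2)
  rss_r <- colSums(qr.resid(qr_red, Y)^2)
  df1 <- ncol(X_full) - ncol(X_red)
  df2 <- n - ncol(X_full)
  Fstat <- pmax(0, (rss_r - rss_f) / df1 / (rss_f / df2))
  # zero-variance outcomes (all residuals at rounding level) carry no group
  # signal; define F = 0 rather than letting 0/0 noise through
  tss <- colSums(sweep(Y, 2, colMeans(Y))^2)
  Fstat[tss <= 1e-12 * n * (colMeans(Y)^2 + .Machine$double.xmin)] <- 0
  pval <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  coef <- qr.coef(qf, Y)
  xtx_inv <- chol2inv(chol(crossprod(X_full)))
  s2 <- rss_f / df2
  se <- sqrt(outer(diag(xtx_inv), s2))
  tstat <- coef / se
  coef_p <- 2 * stats::pt(abs(tstat), df2, lower.tail = FALSE)
  vcovs <- lapply(seq_along(s2), function(j) {
    v <- xtx_inv * s2[j]
    dimnames(v) <- list(colnames(X_full), colnames(X_full))
    v
  })
  rownames(coef) <- colnames(X_full)
  list(F = Fstat, p = pval, df1 = df1, df2 = df2, coef = coef, se = se,
       t = tstat, coef_p = coef_p, vcov = vcovs)
}

#' @export
print.ancova_result <- function(x, ...) {
  cat(sprintf("ANCOVA group effect on %s: F(%d, %d) = %.3f, p = %.4g (n = %d)\n",
              x$outcome, x$df1, x$df2, x$F, x$p, x$n))
  invisible(x)
}

#' ANCOVA over many tracts with a shared design
#'
#' Runs [ancova_group_effect()] for every FA column in one pass: tracts
#' with complete data share a single QR factorization of the common design
#' matrix (mathematically identical to the per-outcome fit, which remains
#' the reference path and is tested against this one); tracts with missing
#' cells fall back to the per-outcome fit with listwise deletion.
#'
#' @param table a `cohort_table`.
#' @param tracts tract names (without the `fa_` prefix); defaults to all
#'   `fa_` columns.
#' @param covariates covariate column names.
#' @return A data.frame with one row per tract: `tract`, `F`, `p`,
#'   covariate t/p columns, and `n`.
#' @export
ancova_all_tracts <- function(table,
                              tracts = sub("^fa_", "", grep("^fa_", names(table), value = TRUE)),
                              covariates = c("age", "gender", "duration", "episodes")) {
  fa_cols <- paste0("fa_", tracts)
  complete_design <- stats::complete.cases(table[, c("group", covariates), drop = FALSE])
  fa_ok <- vapply(fa_cols, function(cl) !anyNA(table[[cl]][complete_design]), logical(1))

  out <- vector("list", length(tracts))
  if (any(fa_ok)) {
    prep <- ancova_design(table[complete_design, , drop = FALSE],
                          fa_cols[which(fa_ok)[1]], covariates, "group")
    Y <- as.matrix(table[complete_design, fa_cols[fa_ok], drop = FALSE])
    fit <- ancova_fit(prep$X_full, prep$X_red, Y)
    cov_idx <- match(covariates, colnames(prep$X_full))
    k <- 0L
    for (j in which(fa_ok)) {
      k <- k + 1L
      row <- data.frame(tract = tracts[j], F = fit$F[k], p = fit$p[k],
                        n = nrow(Y), stringsAsFactors = FALSE)
      for (m in seq_along(covariates)) {
        row[[paste0("t_", covariates[m])]] <- fit$t[cov_idx[m], k]
        row[[paste0("p_", covariates[m])]] <- fit$coef_p[cov_idx[m], k]
      }
      out[[j]] <- row
    }
  }
  for (j in which(!fa_ok)) {
    r <- ancova_group_effect(table, fa_cols[j], covariates)
    row <- data.frame(tract = tracts[j], F = r$F, p = r$p, n = r$n,
                      stringsAsFactors = FALSE)
    for (m in seq_along(covariates)) {
      row[[paste0("t_", covariates[m])]] <- r$covariates$t[m]
      row[[paste0("p_", covariates[m])]] <- r$covariates$p[m]
    }
    out[[j]] <- row
  }
  do.call(rbind, out)
}

#' Family-wise Bonferroni control over the tract family
#'
#' Two modes: `"paper"` applies the literal per-test threshold (default
#' .001, the rounded Bonferroni level conventionally quoted as
#' approximately 0.05/54); `"exact"` uses alpha / n_tests exactly.
#'
#' @param results a list of `ancova_result` objects or a data.frame with a
#'   `p` column (as from [ancova_all_tracts()]).
#' @param n_tests family size (>= 1; default 54 tracts).
#' @param alpha family-wise level for exact mode.
#' @param mode `"paper"` or `"exact"`.
#' @param paper_threshold literal threshold used in paper mode.
#' @return The input with significance flags set; the per-test threshold
#'   is attached as attribute `"threshold"`.
#' @export
family_correct <- function(results, n_tests = 54L, alpha = 0.05,
                           mode = c("paper", "exact"), paper_threshold = 0.001) {
  mode <- match.arg(mode)
  if (n_tests < 1L) stop_tendtract("bad_input", "n_tests must be >= 1")
  threshold <- if (mode == "paper") paper_threshold else alpha / n_tests
  if (is.data.frame(results)) {
    results$significant <- results$p < threshold
  } else {
    results <- lapply(results, function(r) { r$significant <- r$p < threshold; r })
  }
  attr(results, "threshold") <- threshold
  results
}

#' Bonferroni post hoc pairwise group contrasts
#'
#' Pairwise comparisons of covariate-adjusted group means from the full
#' ANCOVA model: each contrast (MDD-HC, BD-HC, MDD-BD) is a linear
#' combination of the group dummy coefficients, tested with the
#' full-model residual t distribution; two-sided p values are multiplied
#' by 3 (the number of pairwise comparisons) and capped at 1.
#'
#' @inheritParams ancova_group_effect
#' @return An object of class `posthoc_result`: a data.frame `contrasts`
#'   with columns `contrast`, `estimate` (adjusted mean difference), `se`,
#'   `t`, `p` (unadjusted) and `p_adj`.
#' @export
posthoc_pairwise <- function(table, outcome,
                             covariates = c("age", "gender", "duration", "episodes"),
                             group_col = "group") {
  res <- ancova_group_effect(table, outcome, covariates, group_col)
  cmat <- rbind(`MDD-HC` = c(groupMDD = 1, groupBD = 0),
                `BD-HC`  = c(groupMDD = 0, groupBD = 1),
                `MDD-BD` = c(groupMDD = 1, groupBD = -1))
  idx <- match(c("groupMDD", "groupBD"), names(res$coef))
  est <- as.vector(cmat %*% res$coef[idx])
  se <- sqrt(diag(cmat %*% res$vcov[idx, idx] %*% t(cmat)))
  tstat <- est / se
  p <- 2 * stats::pt(abs(tstat), res$df_resid, lower.tail = FALSE)
  structure(list(outcome = outcome,
                 contrasts = data.frame(contrast = rownames(cmat),
                                        estimate = est, se = se, t = tstat,
                                        p = p, p_adj = pmin(1, 3 * p),
                                        row.names = NULL),
                 df = res$df_resid, n = res$n),
            class = "posthoc_result")
}

#' @export
print.posthoc_result <- function(x, ...) {
  cat(sprintf("Bonferroni post hoc contrasts on %s (df = %d):\n", x$outcome, x$df))
  print(x$contrasts, digits = 4)
  invisible(x)
}

#' Pearson correlation with t-based test
#'
#' Standard product-moment correlation; the two-sided p value comes from
#' the t transform with n - 2 degrees of freedom (via [stats::cor.test()]).
#'
#' @param x,y numeric vectors; incomplete pairs are dropped.
#' @param pair optional label for the variable pair.
#' @param grouping label for the subset analyzed (`"MDD"`, `"BD"`, `"HC"`
#'   or `"Total"`).
#' @return An object of class `corr_result`: `r`, `p`, `n`, `grouping`,
#'   `pair`.
#' @export
pearson_corr <- function(x, y, pair = NULL, grouping = "Total") {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) {
    stop_tendtract("bad_input", "need >= 3 complete pairs, got %d", length(x))
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_tendtract("undefined_correlation",
                   "correlation undefined: a variable has zero variance")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  structure(list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
                 grouping = grouping, pair = pair),
            class = "corr_result")
}

#' @export
print.corr_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f (p = %.4g, n = %d, %s%s)\n", x$r, x$p, x$n,
              x$grouping, if (is.null(x$pair)) "" else paste0(", ", x$pair)))
  invisible(x)
}

#' One-way ANOVA from group summary statistics
#'
#' F = MS_between / MS_within with MS_between computed from the group
#' means about the size-weighted grand mean and MS_within the pooled
#' within-group variance. Applied to per-group summaries of raw data this
#' equals the raw-data one-way ANOVA exactly; it lets printed cohort
#' tables (means +/- SDs) be re-tested without subject-level data.
#'
#' @param means,sds,ns equal-length numeric vectors of group means, SDs
#'   (> 0) and sizes (>= 2).
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
anova_from_summary <- function(means, sds, ns) {
  k <- length(means)
  if (length(sds) != k || length(ns) != k) {
    stop_tendtract("bad_input", "means, sds and ns must have equal length")
  }
  if (k < 2L) stop_tendtract("bad_input", "need at least two groups")
  if (any(ns < 2L)) stop_tendtract("bad_input", "every group needs n >= 2")
  if (any(sds <= 0)) stop_tendtract("bad_input", "SDs must be > 0")
  N <- sum(ns)
  grand <- sum(ns * means) / N
  ms_between <- sum(ns * (means - grand)^2) / (k - 1)
  ms_within <- sum((ns - 1) * sds^2) / (N - k)
  Fstat <- ms_between / ms_within
  list(F = Fstat, df1 = k - 1, df2 = N - k,
       p = stats::pf(Fstat, k - 1, N - k, lower.tail = FALSE))
}

#' Two-sample t test from summary statistics
#'
#' Pooled-variance t by default (with equal group sizes the pooled and
#' Welch statistics coincide); `welch = TRUE` uses the
#' Welch-Satterthwaite form.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 group summaries (SDs > 0, ns >= 2).
#' @param welch use the unequal-variance form.
#' @return List with `t`, `df`, `p` (two-sided).
#' @export
t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2, welch = FALSE) {
  if (sd1 <= 0 || sd2 <= 0) stop_tendtract("bad_input", "SDs must be > 0")
  if (n1 < 2L || n2 < 2L) stop_tendtract("bad_input", "ns must be >= 2")
  if (welch) {
    se2 <- sd1^2 / n1 + sd2^2 / n2
    tstat <- (mean1 - mean2) / sqrt(se2)
    df <- se2^2 / ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    tstat <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  list(t = tstat, df = df, p = 2 * stats::pt(abs(tstat), df, lower.tail = FALSE))
}

#' Pearson chi-square test of independence
#'
#' Pearson X^2 = sum (O - E)^2 / E on an r x c contingency table with
#' df = (r - 1)(c - 1) and no continuity correction, as used for
#' comparing a gender split across groups.
#'
#' @param counts numeric matrix of observed counts.
#' @return List with `statistic`, `df`, `p`, and the `expected` table.
#' @export
chi_square_independence <- function(counts) {
  counts <- as.matrix(counts)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop_tendtract("bad_input", "contingency table has a zero row or column total")
  }
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  if (any(ht$expected <= 0)) {
    stop_tendtract("bad_input", "all expected counts must be > 0")
  }
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, expected = ht$expected)
}

#' Demographic and clinical comparison table
#'
#' Reproduces the cohort-description analysis from a cohort table: one-way
#' ANOVA (from per-group summaries) for variables observed in all three
#' groups, a chi-square test for the gender split, and pooled two-sample
#' t tests (MDD vs BD) for the patient-only clinical variables.
#'
#' @param table a `cohort_table`.
#' @param anova_vars columns compared across all three groups.
#' @param t_vars patient-only columns compared MDD vs BD.
#' @return A data.frame with per-variable group summaries (`mean +/- sd`),
#'   the test statistic and its p value.
#' @export
demographics_tests <- function(table, anova_vars = c("age"),
                               t_vars = c("duration", "episodes")) {
  groups <- c("MDD", "BD", "HC")
  fmt <- function(v) sprintf("%.1f ± %.1f", mean(v), stats::sd(v))
  rows <- list()
  for (v in anova_vars) {
    by <- split(table[[v]], factor(table$group, groups))
    a <- anova_from_summary(vapply(by, mean, 1), vapply(by, stats::sd, 1),
                            vapply(by, length, 1))
    rows[[v]] <- data.frame(variable = v,
                            MDD = fmt(by$MDD), BD = fmt(by$BD), HC = fmt(by$HC),
                            statistic = sprintf("F = %.3f", a$F),
                            p = a$p, stringsAsFactors = FALSE)
  }
  counts <- rbind(MDD = table(factor(table$gender[table$group == "MDD"], 0:1)),
                  BD = table(factor(table$gender[table$group == "BD"], 0:1)),
                  HC = table(factor(table$gender[table$group == "HC"], 0:1)))
  cs <- chi_square_independence(counts)
  rows[["gender"]] <- data.frame(
    variable = "gender (female/male)",
    MDD = paste(counts["MDD", ], collapse = "/"),
    BD = paste(counts["BD", ], collapse = "/"),
    HC = paste(counts["HC", ], collapse = "/"),
    statistic = sprintf("chi2 = %.3f", cs$statistic), p = cs$p,
    stringsAsFactors = FALSE)
  for (v in t_vars) {
    m <- table[[v]][table$group == "MDD"]; b <- table[[v]][table$group == "BD"]
    tt <- t_from_summary(mean(m), stats::sd(m), length(m),
                         mean(b), stats::sd(b), length(b))
    rows[[v]] <- data.frame(variable = v, MDD = fmt(m), BD = fmt(b), HC = "",
                            statistic = sprintf("t = %.3f", tt$t), p = tt$p,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}
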