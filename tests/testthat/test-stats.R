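test_that("a constant outcome gives a zero group F statistic", {
  tab <- tiny_cohort()
  tab$fa_body_cc_L <- 0.45
  r <- ancova_group_effect(tab, "fa_body_cc_L")
  expect_equal(r$F, 0)
})

test_that("the ANCOVA group F matches an explicit RSS-ratio computation", {
  tab <- tiny_cohort()
  r <- ancova_group_effect(tab, "fa_body_cc_L")
  expect_equal(r$F, brute_force_ancova_F(tab, "fa_body_cc_L"), tolerance = 1e-10)
  expect_equal(r$df1, 2L)
  expect_equal(r$df2, nrow(tab) - 7L)

  # larger random datasets, cross-checked against lm()/anova()
  for (s in 1:3) {
    set.seed(100 + s)
    n <- 10 * 3
    dat <- data.frame(
      subject_id = as.character(seq_len(n)),
      group = rep(c("HC", "MDD", "BD"), each = 10),
      age = rnorm(n, 50, 10), gender = rbinom(n, 1, 0.5),
      duration = c(rep(0, 10), abs(rnorm(20, 10, 5))),
      episodes = c(rep(0, 10), round(abs(rnorm(20, 5, 3)))),
      fa_x = rnorm(n, 0.45, 0.05), stringsAsFactors = FALSE)
    r <- ancova_group_effect(dat, "fa_x")
    g <- factor(dat$group, c("HC", "MDD", "BD"))
    full <- lm(fa_x ~ g + age + gender + duration + episodes, dat)
    red <- lm(fa_x ~ age + gender + duration + episodes, dat)
    ora <- anova(red, full)
    expect_equal(r$F, ora$F[2], tolerance = 1e-10)
    expect_equal(r$p, ora$`Pr(>F)`[2], tolerance = 1e-10)
    # covariate t values match the full-model summary
    sm <- summary(full)$coefficients
    expect_equal(r$covariates$t,
                 unname(sm[c("age", "gender", "duration", "episodes"), "t value"]),
                 tolerance = 1e-9)
  }
})

test_that("zero-filled control covariates leave the design full rank", {
  tab <- tiny_cohort()
  expect_silent(r <- ancova_group_effect(tab, "fa_body_cc_L"))
  expect_true(is.finite(r$F))
  # a covariate constant across everyone is flagged by name
  tab$episodes <- 1
  expect_error(ancova_group_effect(tab, "fa_body_cc_L"),
               regexp = "episodes", class = "tendtract_collinear_design")
})

test_that("the batch tract scan equals per-tract fits, including missing cells", {
  tab <- make_cohort(cohort_spec(n_per_group = 15, seed = 12))
  tab$fa_fornix_L[c(3, 40)] <- NA
  anc <- ancova_all_tracts(tab)
  for (tr in c("body_cc_L", "fornix_L", "tapetum_R")) {
    single <- ancova_group_effect(tab, paste0("fa_", tr))
    row <- anc[anc$tract == tr, ]
    expect_equal(row$F, single$F, tolerance = 1e-12)
    expect_equal(row$p, single$p, tolerance = 1e-12)
    expect_equal(row$n, single$n)
    expect_equal(row$t_age, single$covariates$t[1], tolerance = 1e-12)
  }
})

test_that("family correction applies the literal and exact Bonferroni thresholds", {
  res <- data.frame(tract = c("a", "b", "c"),
                    p = c(0.0005, 0.002, 0.0008))
  paper <- family_correct(res, n_tests = 54)
  expect_equal(attr(paper, "threshold"), 0.001)
  expect_equal(paper$significant, c(TRUE, FALSE, TRUE))
  exact <- family_correct(res, n_tests = 54, alpha = 0.05, mode = "exact")
  expect_equal(attr(exact, "threshold"), 0.05 / 54)
  expect_equal(exact$significant, c(TRUE, FALSE, TRUE))
  one <- family_correct(res, n_tests = 1, alpha = 0.05, mode = "exact")
  expect_equal(attr(one, "threshold"), 0.05)
})

test_that("post hoc contrasts are Bonferroni-scaled model contrasts", {
  tab <- tiny_cohort()
  ph <- posthoc_pairwise(tab, "fa_body_cc_L")
  expect_equal(ph$contrasts$p_adj, pmin(1, 3 * ph$contrasts$p))
  # estimates equal differences of lm group coefficients
  g <- factor(tab$group, c("HC", "MDD", "BD"))
  fit <- lm(fa_body_cc_L ~ g + age + gender + duration + episodes, tab)
  cf <- coef(fit)
  expect_equal(ph$contrasts$estimate,
               unname(c(cf["gMDD"], cf["gBD"], cf["gMDD"] - cf["gBD"])),
               tolerance = 1e-10)
  # t and p agree with the contrast variance from vcov(lm)
  V <- vcov(fit)[c("gMDD", "gBD"), c("gMDD", "gBD")]
  cm <- rbind(c(1, 0), c(0, 1), c(1, -1))
  se <- sqrt(diag(cm %*% V %*% t(cm)))
  expect_equal(ph$contrasts$se, unname(se), tolerance = 1e-10)
})

test_that("Pearson correlation handles exact, degenerate and affine cases", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_corr(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_corr(x, -x)$r, -1)
  set.seed(14)
  a <- rnorm(40); b <- rnorm(40) + 0.5 * a
  r0 <- pearson_corr(a, b)
  ct <- cor.test(a, b)
  expect_equal(r0$r, unname(ct$estimate))
  expect_equal(r0$p, ct$p.value)
  # affine invariance with positive slope
  expect_equal(pearson_corr(10 + 3 * a, 2 * b - 7)$r, r0$r, tolerance = 1e-12)
  expect_error(pearson_corr(rep(1, 5), x), class = "tendtract_undefined_correlation")
  expect_error(pearson_corr(x[1:2], x[1:2]), class = "tendtract_bad_input")
})

test_that("summary-statistic ANOVA matches raw-data ANOVA and the t^2 identity", {
  set.seed(15)
  vals <- list(rnorm(12, 10, 2), rnorm(9, 11, 2.5), rnorm(15, 9.5, 1.8))
  a <- anova_from_summary(vapply(vals, mean, 1), vapply(vals, sd, 1),
                          vapply(vals, length, 1))
  dat <- data.frame(y = unlist(vals),
                    g = rep(letters[1:3], times = vapply(vals, length, 1)))
  raw_F <- anova(lm(y ~ g, dat))$`F value`[1]
  expect_equal(a$F, raw_F, tolerance = 1e-10)

  expect_equal(anova_from_summary(c(5, 5, 5), c(1, 2, 1.5), c(8, 8, 8))$F, 0)

  t2 <- t_from_summary(mean(vals[[1]]), sd(vals[[1]]), 12,
                       mean(vals[[2]]), sd(vals[[2]]), 9)
  a2 <- anova_from_summary(vapply(vals[1:2], mean, 1), vapply(vals[1:2], sd, 1),
                           c(12, 9))
  expect_equal(a2$F, t2$t^2, tolerance = 1e-10)
  expect_error(anova_from_summary(5, 1, 10), class = "tendtract_bad_input")
})

test_that("summary t tests match t.test and collapse pooled/Welch at equal n", {
  set.seed(16)
  x <- rnorm(20, 5, 2); y <- rnorm(20, 6.5, 2.4)
  tt <- t_from_summary(mean(x), sd(x), 20, mean(y), sd(y), 20)
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(tt$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(tt$p, ref$p.value, tolerance = 1e-10)
  tw <- t_from_summary(mean(x), sd(x), 20, mean(y), sd(y), 20, welch = TRUE)
  expect_equal(tw$t, tt$t, tolerance = 1e-12)
  refw <- t.test(x, y)
  expect_equal(tw$df, unname(refw$parameter), tolerance = 1e-9)
  expect_equal(t_from_summary(5, 1, 10, 5, 2, 12)$t, 0)
})

test_that("the chi-square test reproduces hand-computed statistics", {
  expect_equal(chi_square_independence(rbind(c(10, 0), c(0, 10)))$statistic, 20)
  # independence: table proportional to the outer product of its margins
  outer_tab <- outer(c(10, 20, 30), c(2, 3)) / 6
  expect_equal(chi_square_independence(outer_tab)$statistic, 0, tolerance = 1e-12)
  expect_error(chi_square_independence(rbind(c(0, 0), c(3, 4))),
               class = "tendtract_bad_input")
})

test_that("the demographics table reports the three test families", {
  tab <- make_cohort(cohort_spec(n_per_group = 20, seed = 17))
  dem <- demographics_tests(tab)
  expect_equal(dem$variable,
               c("age", "gender (female/male)", "duration", "episodes"))
  expect_true(all(dem$p >= 0 & dem$p <= 1))
  expect_match(dem$statistic[1], "^F = ")
  expect_match(dem$statistic[2], "^chi2 = ")
  expect_match(dem$statistic[3], "^t = ")
})
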