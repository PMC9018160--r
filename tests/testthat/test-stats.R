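test_that("BH adjustment reproduces the step-up procedure", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(bh_adjust(c(0.001, 0.3, 0.8)), c(0.003, 0.45, 0.8))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  # random sets agree with an independent hand implementation
  set.seed(10)
  for (i in 1:20) {
    p <- runif(sample(2:40, 1))^2
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("BH is monotone, capped at one, and family-separated", {
  set.seed(3)
  p <- runif(30)
  q <- bh_adjust(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))      # order preserved
  expect_true(all(q >= p) && all(q <= 1))
  fam <- rep(c("a", "b"), 15)
  qf <- bh_adjust(p, family = fam)
  expect_equal(qf[fam == "a"], bh_adjust(p[fam == "a"]))
  expect_equal(qf[fam == "b"], bh_adjust(p[fam == "b"]))
})

test_that("BH controls empirical FDR on a null/alternative mixture", {
  set.seed(77)
  reps <- 400
  fdp <- replicate(reps, {
    z <- c(rnorm(40), rnorm(10, 3.5))
    p <- 2 * pnorm(-abs(z))
    disc <- which(bh_adjust(p) < 0.05)
    if (length(disc)) mean(disc <= 40) else 0
  })
  expect_lt(mean(fdp), 0.05 + 2 * sd(fdp) / sqrt(reps) + 0.01)
})

test_that("ANCOVA group F matches an explicit sum-of-squares oracle", {
  # 6-subject fixture, one covariate
  metric <- c(1.2, 0.8, 1.9, 2.6, 3.1, 2.2)
  group <- c("control", "control", "control", "case", "case", "case")
  edu <- c(12, 16, 14, 10, 15, 13)
  gc <- ancova_group_comparison(metric, group,
                                data.frame(education = edu))
  X_full <- cbind(1, ifelse(group == "control", 1, 0), edu)
  X_red <- cbind(1, edu)
  rss <- function(X) sum(lm.fit(X, metric)$residuals^2)
  F_oracle <- (rss(X_red) - rss(X_full)) / (rss(X_full) / (6 - 3))
  expect_equal(gc$F, F_oracle, tolerance = 1e-10)
  expect_equal(gc$df, c(1, 3))
  expect_equal(gc$p, pf(F_oracle, 1, 3, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("ANCOVA without covariates equals one-way ANOVA", {
  set.seed(12)
  y <- rnorm(40) + rep(c(0, 0.8), each = 20)
  g <- rep(c("case", "control"), each = 20)
  gc <- ancova_group_comparison(y, g)
  aov_F <- anova(lm(y ~ g))["g", "F value"]
  expect_equal(gc$F, aov_F, tolerance = 1e-10)
})

test_that("ANCOVA rejects singular designs naming the collinear term", {
  set.seed(12)
  y <- rnorm(30)
  g <- rep(c("case", "control"), 15)
  covs <- data.frame(education = rnorm(30))
  covs$twice <- 2 * covs$education
  expect_error(ancova_group_comparison(y, g, covs), "twice|collinear")
  expect_error(ancova_group_comparison(y, rep("case", 30)), "2 levels")
})

test_that("paired test matches the textbook formula and guards degeneracy", {
  set.seed(9)
  a <- rnorm(147); b <- rnorm(147)
  res <- paired_modality_test(a, b)
  d <- a - b
  t_oracle <- mean(d) / (sd(d) / sqrt(147))
  expect_equal(res$t, t_oracle, tolerance = 1e-10)
  expect_equal(res$df, 146)
  expect_equal(res$p, 2 * pt(-abs(t_oracle), 146), tolerance = 1e-10)

  same <- rnorm(10)
  res0 <- paired_modality_test(same, same)
  expect_equal(res0$t, 0)
  expect_equal(res0$p, 1)
  res_inf <- paired_modality_test(same + 2, same)
  expect_true(is.infinite(res_inf$t))
  expect_equal(res_inf$p, 0)
  expect_match(res_inf$note, "zero-variance")
})

test_that("Fisher r-to-z comparison matches a permutation oracle", {
  expect_equal(fisher_r_to_z_test(0.4, 50, 0.4, 80)$z, 0)
  expect_equal(fisher_r_to_z_test(0.4, 50, 0.4, 80)$p, 1)
  expect_error(fisher_r_to_z_test(0.5, 3, 0.1, 50), "n > 3")

  set.seed(15)
  n <- 100
  make_pair <- function(r) {
    x <- rnorm(n); y <- r * x + sqrt(1 - r^2) * rnorm(n)
    cbind(x, y)
  }
  g1 <- make_pair(0.5); g2 <- make_pair(0.0)
  r1 <- cor(g1)[1, 2]; r2 <- cor(g2)[1, 2]
  p_fisher <- fisher_r_to_z_test(r1, n, r2, n)$p
  pooled <- rbind(g1, g2)
  obs <- abs(atanh(r1) - atanh(r2))
  perm <- replicate(2000, {
    idx <- sample(2 * n, n)
    abs(atanh(cor(pooled[idx, ])[1, 2]) -
          atanh(cor(pooled[-idx, ])[1, 2]))
  })
  p_perm <- (1 + sum(perm >= obs)) / 2001
  expect_lt(abs(p_fisher - p_perm), 0.02 + 2 * sqrt(p_perm / 2000))
})

test_that("group correlation comparison wires Fisher z through groups", {
  set.seed(18)
  n1 <- 60; n2 <- 50
  x <- rnorm(n1 + n2)
  y <- c(0.6 * x[1:n1], 0 * x[n1 + 1:n2]) + rnorm(n1 + n2, 0, 0.8)
  g <- rep(c("case", "control"), c(n1, n2))
  res <- modality_correlation_comparison(x, y, g)
  expect_equal(nrow(res$per_group), 2)
  z_oracle <- fisher_r_to_z_test(res$per_group$rho[1], n1,
                                 res$per_group$rho[2], n2)
  expect_equal(res$difference$z, z_oracle$z)
  expect_error(modality_correlation_comparison(x[1:6], y[1:6],
                                               c(rep("a", 3), rep("b", 3))),
               "n > 3|n = 3")
})

test_that("sex-difference analysis detects a planted GM-only male effect", {
  set.seed(23)
  n <- 150
  sex <- rbinom(n, 1, 0.5)
  npad <- data.frame(GM = rnorm(n) + 1.0 * sex,
                     WM = rnorm(n),
                     multimodal = rnorm(n) + 0.6 * sex)
  res <- sex_difference_analysis(npad, sex, rep("case", n))
  expect_equal(res$p_corrected, bh_adjust(res$p_raw))
  expect_lt(res$p_corrected[res$modality == "GM"], 0.05)
  expect_gt(res$p_corrected[res$modality == "WM"], 0.05)
  expect_gt(res$mean_sex1[res$modality == "GM"],
            res$mean_sex0[res$modality == "GM"])
  # null world: corrected p stays large
  null <- sex_difference_analysis(data.frame(GM = rnorm(n)), sex)
  expect_gt(null$p_corrected, 0.05)
  # single-sex group skipped with note
  skip_res <- sex_difference_analysis(npad, rep(1, n), rep("case", n))
  expect_match(skip_res$note[1], "single-sex")
})

test_that("outlier exclusion applies the single-pass three-SD rule", {
  set.seed(31)
  coh <- data.frame(subject_id = sprintf("s%02d", 1:40),
                    dose = rnorm(40, 300, 50),
                    panss_neg = rnorm(40, 16, 5))
  res <- exclude_outliers(coh, c("dose", "panss_neg"))
  expect_equal(res$n_excluded, 0)
  coh$dose[5] <- 300 + 10 * 50        # ~10 SD out
  res <- exclude_outliers(coh, c("dose", "panss_neg"))
  expect_equal(res$excluded$subject_id, "s05")
  expect_equal(res$excluded$field, "dose")
  expect_equal(nrow(res$cohort), 39)
  # single pass: thresholds from the pre-exclusion sample
  m <- mean(coh$dose); s <- sd(coh$dose)
  expect_identical(sort(res$excluded$subject_id),
                   sort(coh$subject_id[abs(coh$dose - m) > 3 * s]))
  expect_error(exclude_outliers(coh, "missing_field"), "missing_field")
  coh2 <- data.frame(subject_id = c("a", "b"), v = c(0, 1e9))
  expect_error(exclude_outliers(coh2, "v", threshold_sd = 0.1),
               "all subjects")
})

test_that("exclusion fraction under normality matches its expectation", {
  set.seed(52)
  frac <- replicate(40, {
    coh <- data.frame(subject_id = as.character(1:2000),
                      a = rnorm(2000), b = rnorm(2000), c = rnorm(2000))
    exclude_outliers(coh, c("a", "b", "c"))$n_excluded / 2000
  })
  # union of three ~0.27% per-field events, minus sampling wiggle
  expect_gt(mean(frac), 0.002)
  expect_lt(mean(frac), 0.015)
})

test_that("phenotype regressions match the normal-equations oracle", {
  set.seed(41)
  n <- 12
  ph <- data.frame(onset_age = rnorm(n, 23, 5), duration = rnorm(n, 7, 3),
                   dose = rnorm(n, 300, 100), panss_pos = rnorm(n, 13, 4),
                   panss_neg = rnorm(n, 16, 5), panss_gen = rnorm(n, 28, 7),
                   fsiq = rnorm(n, 94, 10), education = rnorm(n, 14, 2))
  npad <- data.frame(WM = rnorm(n))
  tab <- phenotype_regressions(npad, ph)
  X <- cbind(1, ph$duration, ph$onset_age, ph$dose)
  beta <- as.numeric(solve(crossprod(X), crossprod(X, npad$WM)))
  res <- npad$WM - X %*% beta
  sigma2 <- sum(res^2) / (n - 4)
  se <- sqrt(diag(solve(crossprod(X))) * sigma2)
  clin <- tab[tab$model_class == "clinical_factors" & tab$outcome == "WM", ]
  expect_equal(clin$estimate[clin$predictor == "duration"], beta[2],
               tolerance = 1e-10)
  expect_equal(clin$se[clin$predictor == "onset_age"], se[3],
               tolerance = 1e-10)
  # education is controlled in the FSIQ model but not BH-corrected
  fs <- tab[tab$model_class == "fsiq" & tab$outcome == "WM", ]
  expect_true(is.na(fs$p_corrected[fs$predictor == "education"]))
  expect_false(is.na(fs$p_corrected[fs$predictor == "fsiq"]))
  # correction happens within model class across outcomes
  npad2 <- data.frame(GM = rnorm(n), WM = rnorm(n))
  tab2 <- phenotype_regressions(npad2, ph)
  sym <- tab2[tab2$model_class == "symptom_severity", ]
  expect_equal(sym$p_corrected, bh_adjust(sym$p_raw))
  expect_error(phenotype_regressions(npad, ph[, -1]), "onset_age")
})

test_that("null phenotypes give estimates centered on zero", {
  set.seed(61)
  n <- 140
  ph <- data.frame(onset_age = rnorm(n, 23, 5), duration = rnorm(n, 7, 3),
                   dose = rnorm(n, 300, 100), panss_pos = rnorm(n, 13, 4),
                   panss_neg = rnorm(n, 16, 5), panss_gen = rnorm(n, 28, 7),
                   fsiq = rnorm(n, 94, 10), education = rnorm(n, 14, 2))
  tab <- phenotype_regressions(data.frame(WM = rnorm(n)), ph)
  expect_true(all(abs(tab$estimate) < 4 * tab$se))
})
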