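make_norm_fit <- function(n = 300, noise = 3, sex_effect = 0, seed = 21,
                          kernel_opts = list()) {
  set.seed(seed)
  age <- runif(n, 15, 90)
  sex <- rbinom(n, 1, 0.5)
  predicted <- age + sex_effect * sex + rnorm(n, 0, noise)
  list(model = fit_normative_gpr(predicted, age, sex,
                                 kernel_opts = kernel_opts, seed = seed),
       age = age, sex = sex, predicted = predicted)
}

test_that("identity signal recovers the diagonal with a small peer SD", {
  f <- make_norm_fit(noise = 0.2)
  grid <- seq(25, 80, by = 5)
  pm <- peer_moments(f$model, grid, rep(0, length(grid)))
  expect_lt(max(abs(pm$peer_mean - grid)), 1)
  expect_true(all(pm$peer_sd > 0))
  expect_lt(max(pm$peer_sd), 1)
})

test_that("peer SD approximates the generative noise on the interior", {
  f <- make_norm_fit(n = 500, noise = 3)
  grid <- seq(30, 75, by = 5)
  pm <- peer_moments(f$model, grid, rep(1, length(grid)))
  expect_true(all(abs(pm$peer_sd - 3) / 3 < 0.2))
})

test_that("peer moments match a windowed local average of predicted age", {
  f <- make_norm_fit(n = 500, noise = 3, seed = 8)
  for (a in c(35, 55, 70)) {
    idx <- which(abs(f$age - a) <= 2 & f$sex == 0)
    local_mean <- mean(f$predicted[idx])
    se <- sd(f$predicted[idx]) / sqrt(length(idx))
    pm <- peer_moments(f$model, a, 0)
    expect_lt(abs(pm$peer_mean - local_mean), 2 * se + 0.5)
  }
})

test_that("a planted sex offset in predicted age moves the peer means", {
  f <- make_norm_fit(n = 500, noise = 2, sex_effect = 3)
  grid <- seq(30, 70, by = 10)
  pm1 <- peer_moments(f$model, grid, rep(1, length(grid)))
  pm0 <- peer_moments(f$model, grid, rep(0, length(grid)))
  expect_true(all(pm1$peer_mean - pm0$peer_mean > 1))
})

test_that("normative fitting is deterministic and validates its inputs", {
  f1 <- make_norm_fit(seed = 33)
  f2 <- make_norm_fit(seed = 33)
  grid <- seq(20, 85, by = 7)
  expect_identical(peer_moments(f1$model, grid, rep(0, length(grid))),
                   peer_moments(f2$model, grid, rep(0, length(grid))))
  set.seed(1)
  age <- runif(100, 20, 80)
  expect_error(fit_normative_gpr(age + rnorm(100), age, rep(1, 100)),
               "both sexes")
  expect_error(fit_normative_gpr(rep(50, 100), age,
                                 rbinom(100, 1, 0.5)), "constant")
  expect_error(fit_normative_gpr(age[1:30], age[1:30],
                                 rbinom(30, 1, 0.5)), "least 50")
  expect_error(peer_moments(list(), 50, 0), "not a fitted")
})

test_that("extrapolation beyond the training range +/- 5 years is flagged", {
  f <- make_norm_fit()
  rng <- f$model$training_summary$age_range
  pm <- peer_moments(f$model, c(rng[1] - 6, mean(rng), rng[2] + 6), c(0, 0, 0))
  expect_identical(pm$extrapolation, c(TRUE, FALSE, TRUE))
  np <- score_npad(f$model, c(50, 50, 50),
                   c(rng[1] - 6, mean(rng), rng[2] + 6), c(0, 0, 0))
  expect_identical(attr(np, "extrapolation"), c(TRUE, FALSE, TRUE))
})

test_that("nPAD is the peer z-score, exactly", {
  f <- make_norm_fit(n = 200, seed = 14)
  pm <- peer_moments(f$model, f$age, f$sex)
  np <- score_npad(f$model, f$predicted, f$age, f$sex)
  expect_equal(as.numeric(np),
               (f$predicted - pm$peer_mean) / pm$peer_sd,
               tolerance = 1e-12)
  # predicted exactly at the peer mean scores zero
  np0 <- score_npad(f$model, pm$peer_mean[1:5], f$age[1:5], f$sex[1:5])
  expect_equal(as.numeric(np0), rep(0, 5), tolerance = 1e-12)
})

test_that("PAD and cPAD follow their defining formulas", {
  expect_equal(score_pad(55, 50), 5)
  expect_equal(score_pad(50, 50), 0)
  p <- runif(20, 20, 90); a <- runif(20, 20, 90)
  expect_equal(score_pad(p, a), p - a)

  set.seed(2)
  age <- runif(200, 15, 90)
  pad_lin <- -0.25 * age + 8          # exactly linear in age
  fit <- fit_bias_correction(pad_lin, age)
  expect_equal(fit$alpha, -0.25, tolerance = 1e-10)
  expect_equal(score_cpad(fit, pad_lin, age), rep(0, 200),
               tolerance = 1e-10)
  # residual orthogonality on the fitting set
  pad_noisy <- -0.25 * age + 8 + rnorm(200, 0, 3)
  fit2 <- fit_bias_correction(pad_noisy, age)
  expect_lt(abs(cor(score_cpad(fit2, pad_noisy, age), age)), 1e-10)
  expect_error(fit_bias_correction(pad_noisy[1:10], age[1:10]), "least 30")
  expect_error(fit_bias_correction(pad_noisy, rep(40, 200)), "constant")
})

test_that("bias-correction slope is recovered within 3 standard errors", {
  set.seed(6)
  age <- runif(482, 14, 92)
  pad <- -0.3 * age + 10 + rnorm(482, 0, 4)
  fit <- fit_bias_correction(pad, age)
  se <- summary(lm(pad ~ age))$coefficients["age", "Std. Error"]
  expect_lt(abs(fit$alpha - (-0.3)), 3 * se)
})

test_that("raising one subject's predicted age raises only their scores", {
  f <- make_norm_fit(n = 120, seed = 17)
  fitc <- fit_bias_correction(score_pad(f$predicted, f$age), f$age)
  base_pad <- score_pad(f$predicted, f$age)
  base_cpad <- score_cpad(fitc, base_pad, f$age)
  base_npad <- as.numeric(score_npad(f$model, f$predicted, f$age, f$sex))
  bumped <- f$predicted
  bumped[7] <- bumped[7] + 2
  new_pad <- score_pad(bumped, f$age)
  new_cpad <- score_cpad(fitc, new_pad, f$age)
  new_npad <- as.numeric(score_npad(f$model, bumped, f$age, f$sex))
  expect_gt(new_pad[7], base_pad[7])
  expect_gt(new_cpad[7], base_cpad[7])
  expect_gt(new_npad[7], base_npad[7])
  expect_equal(new_pad[-7], base_pad[-7])
  expect_equal(new_cpad[-7], base_cpad[-7])
  expect_equal(new_npad[-7], base_npad[-7], tolerance = 1e-12)
})

test_that("age-bias report matches a raw-sums Pearson oracle", {
  set.seed(30)
  scores <- data.frame(pad = rnorm(10), cpad = rnorm(10), npad = rnorm(10))
  age <- runif(10, 20, 80)
  rep <- age_bias_report(scores, age, "fixture")
  for (i in seq_len(nrow(rep))) {
    col <- c(PAD = "pad", cPAD = "cpad", nPAD = "npad")[[rep$metric[i]]]
    expect_equal(rep$rho[i], pearson_oracle(scores[[col]], age),
                 tolerance = 1e-10)
  }
  # degenerate metric: flagged, not crashed
  scores$npad <- 0
  rep2 <- age_bias_report(scores, age, "fixture")
  expect_true(is.nan(rep2$rho[rep2$metric == "nPAD"]))
  expect_match(rep2$note[rep2$metric == "nPAD"], "constant")
})

test_that("permutation p-values agree with the t approximation", {
  set.seed(44)
  scores <- data.frame(pad = rnorm(60))
  age <- scores$pad * 0.5 + rnorm(60)
  r1 <- age_bias_report(scores, age, "x")
  r2 <- age_bias_report(scores, age, "x", permutation = TRUE,
                        n_perm = 4000)
  expect_lt(abs(r1$p - r2$p), 0.02 + 3 * sqrt(r1$p / 4000))
})

test_that("peer means agree with an independent GP implementation", {
  skip_if_not_installed("kernlab")
  set.seed(55)
  n <- 300
  age <- runif(n, 15, 90)
  sex <- rbinom(n, 1, 0.5)
  predicted <- 0.9 * age + 4 + rnorm(n, 0, 3)
  ours <- fit_normative_gpr(predicted, age, sex, seed = 1)
  ref <- kernlab::gausspr(x = matrix(age), y = predicted,
                          kernel = "rbfdot", var = 9 / var(predicted),
                          scaled = TRUE)
  grid <- matrix(seq(30, 75, by = 5))
  theirs <- as.numeric(kernlab::predict(ref, grid))
  mine <- (peer_moments(ours, grid[, 1], rep(0, nrow(grid)))$peer_mean +
             peer_moments(ours, grid[, 1], rep(1, nrow(grid)))$peer_mean) / 2
  expect_lt(max(abs(mine - theirs)), 1.5)
})
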