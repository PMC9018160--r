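# Shared fixtures, built in code. Heavy objects are memoised so several
# test files can reuse one fitted world.

.npad_cache <- new.env(parent = emptyenv())

# A small world for unit tests: few features, modest n, fast GP fits.
small_config <- function(...) {
  args <- list(n_reference = 120L, n_test = 40L,
               n_case = 50L, n_control = 50L,
               n_features_per_block = c(volume = 8L, thickness = 10L,
                                        gfa = 6L, md = 6L),
               n_interaction_features = 2L,
               seed = 11L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(synthetic_config, args)
}

# A noise-free linear world where features are exact functions of age/sex.
noisefree_config <- function(...) {
  synthetic_config(noise_sd = 0, latent_aging_sd = 0,
                   curvature_range = c(0, 0),
                   aging_signal_strength = 1,
                   n_interaction_features = 0L,
                   n_reference = 200L, seed = 7L, ...)
}

# Full-scale study world shared by the acceptance tests: reference cohort at
# the study's training size, ridge predictors per modality, out-of-fold CV
# predictions, GP normative models and linear bias corrections.
study_world <- function() {
  if (!is.null(.npad_cache$world)) return(.npad_cache$world)
  cfg <- synthetic_config(seed = 1L)
  ref <- generate_reference_cohort(cfg)
  w <- list(cfg = cfg, ref = ref, models = list(), normative = list(),
            correction = list(), cv = list())
  for (mod in c("GM", "WM", "multimodal")) {
    w$models[[mod]] <- train_predictor(ref$features, ref$cohort, mod,
                                       backend = "ridge", seed = 1L)
    w$cv[[mod]] <- crossvalidate_10fold(ref$features, ref$cohort, mod,
                                        backend = "ridge", seed = 1L)
    pred <- w$cv[[mod]]$predictions
    w$normative[[mod]] <- fit_normative_gpr(pred, ref$cohort$age,
                                            ref$cohort$sex, seed = 1L)
    w$correction[[mod]] <- fit_bias_correction(
      score_pad(pred, ref$cohort$age), ref$cohort$age)
  }
  .npad_cache$world <- w
  w
}

# Stack a case/control pair into one pooled cohort + feature matrix.
pool_case_control <- function(cc) {
  feats <- feature_matrix(
    rbind(unclass(cc$case$features), unclass(cc$control$features)),
    colnames(cc$case$features),
    attr(cc$case$features, "modality"),
    c(rownames(cc$case$features), rownames(cc$control$features)))
  cohort <- rbind(cc$case$cohort[names(cc$control$cohort)],
                  cc$control$cohort)
  list(features = feats, cohort = cohort)
}

# nPAD for a cohort under a fitted world, per modality.
world_npad <- function(w, features, cohort,
                       modalities = c("GM", "WM", "multimodal")) {
  out <- lapply(modalities, function(mod) {
    pred <- predict_age(w$models[[mod]], features, cohort$sex)
    as.numeric(score_npad(w$normative[[mod]], pred, cohort$age, cohort$sex))
  })
  names(out) <- modalities
  out
}

# Hand Pearson correlation from raw sums (independent of stats::cor).
pearson_oracle <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# Hand Benjamini-Hochberg step-up.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# Compact pipeline configuration for end-to-end smoke/determinism tests.
pipeline_config <- function(seed = 31L) {
  synthetic_config(n_reference = 150L, n_test = 40L, n_case = 60L,
                   n_control = 60L,
                   n_features_per_block = c(volume = 10L, thickness = 12L,
                                            gfa = 8L, md = 8L),
                   n_interaction_features = 2L, seed = seed)
}

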