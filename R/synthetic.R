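#' Configuration for the synthetic cohort generator
#'
#' Defines the generative world for a simulated brain-aging study: a healthy
#' reference cohort used to train brain-age models, an independent held-out
#' normal cohort, and a case-control pair in which cases carry a latent
#' advanced-aging shift. Feature trajectories follow
#' \deqn{x_{ij} = \mu_j + \beta_j a_i + \kappa_j a_i^2 + \gamma_j s_i +
#'   \varepsilon_{ij}}
#' with age \eqn{a_i} in years, sex \eqn{s_i \in \{0,1\}} and independent
#' Gaussian noise. Volumes, cortical thickness and GFA decline with age
#' (\eqn{\beta_j \le 0}); mean diffusivity increases (\eqn{\beta_j \ge 0}).
#' Every subject carries a latent brain-aging deviation applied in
#' age-equivalent years: healthy subjects (reference, test, control) draw
#' it from \eqn{N(0, \eta^2)} -- the normal heterogeneity a normative
#' model is built to describe -- while cases draw a shifted, wider
#' deviation \eqn{\Delta_i \sim N(\delta, \tau^2)}. A configurable
#' subset of features additionally steepens its slope in cases only, so
#' group-by-feature interaction mapping has a recoverable target.
#'
#' @param n_reference,n_test,n_case,n_control cohort sizes. Defaults mirror a
#'   typical single-site study (482 training normals, 70 held-out normals,
#'   147 cases, 130 controls).
#' @param age_range reference/test age span in years.
#' @param case_age_range age span for cases and controls.
#' @param sex_ratio probability that a subject is coded sex = 1 (male).
#' @param n_features_per_block named feature counts for the four blocks
#'   (volume, thickness, gfa, md).
#' @param aging_signal_strength fraction of features per block with a
#'   non-zero aging slope.
#' @param noise_sd residual noise level in age-equivalent years: feature j's
#'   residual SD is \code{noise_sd} times the typical absolute aging slope of
#'   its block. The four blocks live on scales spanning four orders of
#'   magnitude, so noise is parameterised relative to each block's slope
#'   scale rather than as one absolute SD. A scalar applies to all blocks;
#'   a named vector sets per-block levels. The defaults make the
#'   grey-matter blocks noisier per feature than the diffusion blocks, so
#'   the WM brain-age model is the more accurate one, as observed in
#'   held-out evaluations of real multimodal models.
#' @param latent_aging_sd SD \eqn{\eta} of the latent aging deviation of
#'   healthy subjects (years).
#' @param case_offset_years mean of the latent advanced-aging shift
#'   \eqn{\Delta_i} of cases (years).
#' @param case_offset_sd total SD of \eqn{\Delta_i} in cases (years);
#'   slightly wider than the healthy deviation by default.
#' @param n_interaction_features number of features given a case-specific
#'   extra slope.
#' @param interaction_blocks blocks from which interaction features are
#'   drawn (round-robin if several).
#' @param interaction_slope_delta case-only gain of the planted features on
#'   the latent advanced-aging shift, in multiples of the block's typical
#'   absolute aging slope, signed along the block's aging direction (so a
#'   planted thickness feature thins faster per year of advanced aging).
#'   The default is calibrated so a planted feature yields a
#'   single-feature interaction effect of Cohen's f2 near 0.08 at the
#'   default cohort sizes.
#' @param curvature_range range of the quadratic-term ratio
#'   \eqn{\kappa_j/\beta_j} for signal features (mild accelerating
#'   decline by default).
#' @param phenotype_coupling named correlations linking the standardized
#'   latent shift to case phenotypes; recognised names are
#'   \code{panss_neg}, \code{fsiq}, \code{onset_age}.
#' @param seed integer seed; generation is byte-reproducible given the seed.
#'
#' @return an object of class \code{npad_config}.
#' @export
synthetic_config <- function(n_reference = 482L,
                             n_test = 70L,
                             n_case = 147L,
                             n_control = 130L,
                             age_range = c(14, 92),
                             case_age_range = c(16, 62),
                             sex_ratio = 0.47,
                             n_features_per_block = c(volume = 56L,
                                                      thickness = 68L,
                                                      gfa = 45L,
                                                      md = 45L),
                             aging_signal_strength = 0.8,
                             noise_sd = c(volume = 45, thickness = 45,
                                          gfa = 30, md = 30),
                             latent_aging_sd = 5,
                             case_offset_years = 4.5,
                             case_offset_sd = 6.5,
                             n_interaction_features = 10L,
                             interaction_blocks = "thickness",
                             interaction_slope_delta = 9,
                             curvature_range = c(-0.002, 0.004),
                             phenotype_coupling = c(panss_neg = 0.5,
                                                    fsiq = -0.5,
                                                    onset_age = -0.3),
                             seed = 1L) {
  cfg <- list(n_reference = as.integer(n_reference),
              n_test = as.integer(n_test),
              n_case = as.integer(n_case),
              n_control = as.integer(n_control),
              age_range = as.numeric(age_range),
              case_age_range = as.numeric(case_age_range),
              sex_ratio = sex_ratio,
              n_features_per_block = n_features_per_block,
              aging_signal_strength = aging_signal_strength,
              noise_sd = noise_sd,
              latent_aging_sd = latent_aging_sd,
              case_offset_years = case_offset_years,
              case_offset_sd = case_offset_sd,
              n_interaction_features = as.integer(n_interaction_features),
              interaction_blocks = interaction_blocks,
              interaction_slope_delta = interaction_slope_delta,
              curvature_range = as.numeric(curvature_range),
              phenotype_coupling = phenotype_coupling,
              seed = as.integer(seed))
  validate_config(cfg)
  class(cfg) <- "npad_config"
  cfg
}

validate_config <- function(cfg) {
  for (f in c("n_reference", "n_test", "n_case", "n_control")) {
    if (length(cfg[[f]]) != 1L || is.na(cfg[[f]]) || cfg[[f]] <= 0L)
      stop_validation("config field '%s' must be a positive count", f)
  }
  for (f in c("age_range", "case_age_range")) {
    if (length(cfg[[f]]) != 2L || cfg[[f]][1] >= cfg[[f]][2])
      stop_validation("config field '%s' must satisfy min < max", f)
  }
  if (cfg$sex_ratio < 0 || cfg$sex_ratio > 1)
    stop_validation("config field 'sex_ratio' must lie in [0, 1]")
  if (cfg$aging_signal_strength < 0 || cfg$aging_signal_strength > 1)
    stop_validation("config field 'aging_signal_strength' must lie in [0, 1]")
  blocks <- c("volume", "thickness", "gfa", "md")
  if (!all(blocks %in% names(cfg$n_features_per_block)))
    stop_validation("config field 'n_features_per_block' must name blocks %s",
                    paste(blocks, collapse = ", "))
  if (any(cfg$n_features_per_block <= 0))
    stop_validation("config field 'n_features_per_block' must be positive")
  if (any(cfg$noise_sd < 0))
    stop_validation("config field 'noise_sd' must be non-negative")
  if (length(cfg$noise_sd) > 1L && !all(blocks %in% names(cfg$noise_sd)))
    stop_validation("vector 'noise_sd' must name all blocks %s",
                    paste(blocks, collapse = ", "))
  if (cfg$case_offset_sd < 0)
    stop_validation("config field 'case_offset_sd' must be non-negative")
  if (cfg$latent_aging_sd < 0)
    stop_validation("config field 'latent_aging_sd' must be non-negative")
  if (!all(cfg$interaction_blocks %in% blocks))
    stop_validation("config field 'interaction_blocks' must be among %s",
                    paste(blocks, collapse = ", "))
  n_avail <- sum(cfg$n_features_per_block[cfg$interaction_blocks])
  if (cfg$n_interaction_features > n_avail)
    stop_validation(paste0("config field 'n_interaction_features' (%d) ",
                           "exceeds available features (%d) in blocks %s"),
                    cfg$n_interaction_features, n_avail,
                    paste(cfg$interaction_blocks, collapse = ", "))
  invisible(cfg)
}

# Per-block scale constants: typical feature level and typical absolute
# aging slope (units per year), with the canonical aging direction.
block_scales <- function() {
  data.frame(block = c("volume", "thickness", "gfa", "md"),
             prefix = c("vol", "ct", "gfa", "md"),
             mu_lo = c(3, 2.0, 0.30, 6e-4),
             mu_hi = c(60, 4.0, 0.70, 9e-4),
             slope = c(0.046, 0.00385, 6.4e-4, 1.54e-6),
             sign = c(-1, -1, -1, +1),
             stringsAsFactors = FALSE)
}

# Draw the generative world: per-feature intercepts, slopes, curvatures,
# sex offsets and noise SDs. Consumes RNG state.
draw_world <- function(cfg) {
  sc <- block_scales()
  names_all <- character(0)
  block_tag <- character(0)
  mu <- beta <- kappa <- gamma <- sigma <- numeric(0)
  for (b in seq_len(nrow(sc))) {
    nb <- cfg$n_features_per_block[[sc$block[b]]]
    nm <- sprintf("%s_%s_%03d", sc$prefix[b],
                  if (sc$block[b] %in% c("gfa", "md")) "tract" else "roi",
                  seq_len(nb))
    mu_b <- runif(nb, sc$mu_lo[b], sc$mu_hi[b])
    n_sig <- round(cfg$aging_signal_strength * nb)
    sig_idx <- sample.int(nb, n_sig)
    beta_b <- rep(0, nb)
    beta_b[sig_idx] <- sc$sign[b] * sc$slope[b] * runif(n_sig, 0.5, 1.5)
    kappa_b <- beta_b * runif(nb, cfg$curvature_range[1],
                              cfg$curvature_range[2])
    gamma_b <- rnorm(nb, 0, 5 * sc$slope[b])
    nsd <- if (length(cfg$noise_sd) > 1L) cfg$noise_sd[[sc$block[b]]] else
      cfg$noise_sd
    sigma_b <- rep(nsd * sc$slope[b], nb)
    names_all <- c(names_all, nm)
    block_tag <- c(block_tag, rep(sc$block[b], nb))
    mu <- c(mu, mu_b); beta <- c(beta, beta_b); kappa <- c(kappa, kappa_b)
    gamma <- c(gamma, gamma_b); sigma <- c(sigma, sigma_b)
  }
  # plant interaction features: case-only slope along the block's aging
  # direction, drawn from the features WITHOUT a normal-aging slope in the
  # configured blocks -- regions recruited only by the disease process, so
  # the case-specific slope is the sole aging signal they carry
  is_int <- rep(FALSE, length(names_all))
  pool <- which(block_tag %in% cfg$interaction_blocks & beta == 0)
  if (cfg$n_interaction_features > 0L) {
    if (length(pool) < cfg$n_interaction_features)
      stop_validation(paste0("need %d interaction features but only %d ",
                             "non-aging features exist in blocks %s; ",
                             "lower aging_signal_strength"),
                      cfg$n_interaction_features, length(pool),
                      paste(cfg$interaction_blocks, collapse = ", "))
    picked <- sample(pool, cfg$n_interaction_features)
    is_int[picked] <- TRUE
  }
  delta_slope <- rep(0, length(names_all))
  sgn <- setNames(sc$sign, sc$block)
  slp <- setNames(sc$slope, sc$block)
  delta_slope[is_int] <- cfg$interaction_slope_delta *
    slp[block_tag[is_int]] * sgn[block_tag[is_int]]
  list(feature_names = names_all, block = block_tag, mu = mu, beta = beta,
       kappa = kappa, gamma = gamma, sigma = sigma,
       is_interaction_feature = is_int, delta_slope = delta_slope)
}

# Feature values for given effective ages (age + latent shift) and sexes.
# In cases the planted interaction features additionally track the latent
# advanced-aging shift with gain delta_slope (units per year of advanced
# aging): the case-only signal rides the biological deviation, which is
# what makes the feature's relationship with nPAD group-specific.
draw_features <- function(world, age_eff, sex, case_shift = NULL) {
  n <- length(age_eff)
  p <- length(world$mu)
  mean_mat <- outer(rep(1, n), world$mu) +
    outer(age_eff, world$beta) +
    outer(age_eff^2, world$kappa) +
    outer(sex, world$gamma)
  if (!is.null(case_shift))
    mean_mat <- mean_mat + outer(case_shift, world$delta_slope)
  noise <- matrix(rnorm(n * p), n, p) %*% diag(world$sigma, p)
  mean_mat + noise
}

# Right-skewed lifespan age distribution for the reference/test cohorts
# (shifted gamma truncated to the configured range).
draw_reference_ages <- function(n, range) {
  span <- range[2] - range[1]
  x <- range[1] + rgamma(n, shape = 2, scale = span / 6.8)
  bad <- which(x > range[2])
  guard <- 0L
  while (length(bad) > 0L && guard < 1000L) {
    x[bad] <- range[1] + rgamma(length(bad), shape = 2, scale = span / 6.8)
    bad <- bad[x[bad] > range[2]]
    guard <- guard + 1L
  }
  pmin(x, range[2])
}

make_cohort_table <- function(ids, age, sex, education, group) {
  data.frame(subject_id = ids, age = age, sex = sex,
             education = education, group = group,
             stringsAsFactors = FALSE)
}

#' Generate the healthy reference cohort
#'
#' Draws the generative world (feature intercepts, aging slopes, curvature,
#' sex offsets, noise) and a reference cohort from it. The returned
#' \code{truth} element carries the full world so downstream recovery
#' metrics can be computed without re-deriving the generative model, and is
#' required to generate matched test/case/control cohorts.
#'
#' @param config an \code{\link{synthetic_config}} object.
#' @return list with \code{cohort} (data.frame: subject_id, age, sex,
#'   education, group), \code{features} (an \code{\link{feature_matrix}}),
#'   and \code{truth} (list with the generative world).
#' @export
generate_reference_cohort <- function(config) {
  validate_config(config)
  set.seed(config$seed)
  world <- draw_world(config)
  n <- config$n_reference
  age <- draw_reference_ages(n, config$age_range)
  sex <- rbinom(n, 1, config$sex_ratio)
  edu <- round(rnorm_trunc(n, 14.5, 2.5, 6, 20), 1)
  ids <- sprintf("ref_%04d", seq_len(n))
  eta <- rnorm(n, 0, config$latent_aging_sd)
  feats <- draw_features(world, age + eta, sex)
  cohort <- make_cohort_table(ids, age, sex, edu, "reference")
  features <- feature_matrix(feats, world$feature_names, world$block, ids)
  list(cohort = cohort, features = features,
       truth = list(world = world, config = config))
}

#' Generate an independent held-out normal cohort
#'
#' Same generative model as the reference cohort (shared world parameters),
#' new subjects.
#'
#' @param config an \code{\link{synthetic_config}} object.
#' @param truth the \code{truth} element returned by
#'   \code{\link{generate_reference_cohort}}.
#' @param n number of subjects (default \code{config$n_test}).
#' @param seed seed for this draw (default \code{config$seed + 1}).
#' @return list with \code{cohort} and \code{features}.
#' @export
generate_test_cohort <- function(config, truth, n = config$n_test,
                                 seed = config$seed + 1L) {
  validate_config(config)
  world <- truth$world
  set.seed(seed)
  age <- draw_reference_ages(n, config$age_range)
  sex <- rbinom(n, 1, config$sex_ratio)
  edu <- round(rnorm_trunc(n, 14.5, 2.5, 6, 20), 1)
  ids <- sprintf("tst_%04d", seq_len(n))
  eta <- rnorm(n, 0, config$latent_aging_sd)
  feats <- draw_features(world, age + eta, sex)
  list(cohort = make_cohort_table(ids, age, sex, edu, "test"),
       features = feature_matrix(feats, world$feature_names, world$block, ids))
}

#' Generate matched case and control cohorts
#'
#' Controls are drawn from the reference generative model. Each case i
#' receives a latent advanced-aging shift \eqn{\Delta_i \sim
#' N(\delta, \tau^2)} applied in age-equivalent years to every feature
#' trajectory; planted interaction features additionally steepen their
#' aging slope in cases only. Case phenotypes (PANSS scores, FSIQ, onset
#' age, illness duration, antipsychotic dose) are drawn around published
#' clinical means, with the configured couplings between the standardized
#' latent shift and negative symptoms, FSIQ and onset age.
#'
#' @inheritParams generate_test_cohort
#' @param seed seed for this draw (default \code{config$seed + 2}).
#' @return list with elements \code{case} and \code{control}, each a list of
#'   \code{cohort} and \code{features}; the case cohort carries phenotype
#'   columns and \code{truth$delta_age_years}.
#' @export
generate_case_control_cohorts <- function(config, truth,
                                          seed = config$seed + 2L) {
  validate_config(config)
  world <- truth$world
  set.seed(seed)

  ## controls
  n_nc <- config$n_control
  age_nc <- rnorm_trunc(n_nc, 31, 8.4, config$case_age_range[1],
                        config$case_age_range[2])
  sex_nc <- rbinom(n_nc, 1, config$sex_ratio)
  edu_nc <- round(rnorm_trunc(n_nc, 15.9, 1.2, 6, 20), 1)
  ids_nc <- sprintf("ctl_%04d", seq_len(n_nc))
  eta_nc <- rnorm(n_nc, 0, config$latent_aging_sd)
  feats_nc <- draw_features(world, age_nc + eta_nc, sex_nc)
  control <- list(
    cohort = make_cohort_table(ids_nc, age_nc, sex_nc, edu_nc, "control"),
    features = feature_matrix(feats_nc, world$feature_names, world$block,
                              ids_nc))

  ## cases
  n_sz <- config$n_case
  age_sz <- rnorm_trunc(n_sz, 31, 8.4, config$case_age_range[1],
                        config$case_age_range[2])
  sex_sz <- rbinom(n_sz, 1, config$sex_ratio)
  edu_sz <- round(rnorm_trunc(n_sz, 14.3, 2.5, 6, 20), 1)
  delta <- rnorm(n_sz, config$case_offset_years, config$case_offset_sd)
  ids_sz <- sprintf("cas_%04d", seq_len(n_sz))
  feats_sz <- draw_features(world, age_sz + delta, sex_sz,
                            case_shift = delta)
  cohort_sz <- make_cohort_table(ids_sz, age_sz, sex_sz, edu_sz, "case")
  cohort_sz <- cbind(cohort_sz,
                     draw_case_phenotypes(config, delta, age_sz))
  case <- list(
    cohort = cohort_sz,
    features = feature_matrix(feats_sz, world$feature_names, world$block,
                              ids_sz),
    truth = list(delta_age_years = delta,
                 is_interaction_feature = world$is_interaction_feature))
  list(case = case, control = control)
}

# Phenotypes with configurable coupling to the standardized latent shift.
draw_case_phenotypes <- function(config, delta, age) {
  n <- length(delta)
  z_delta <- if (sd(delta) > 0) as.numeric(scale(delta)) else rep(0, n)
  couple <- function(r) {
    r <- r %||% 0
    r * z_delta + sqrt(max(0, 1 - r^2)) * rnorm(n)
  }
  cp <- config$phenotype_coupling
  panss_neg <- round(pmin(pmax(15.8 + 7.2 * couple(cp[["panss_neg"]]), 7), 49))
  panss_pos <- round(pmin(pmax(13.1 + 5.1 * rnorm(n), 7), 49))
  panss_gen <- round(pmin(pmax(28.2 + 8.4 * rnorm(n), 16), 112))
  fsiq <- round(pmin(pmax(93.8 + 12.9 * couple(cp["fsiq"]), 40), 160))
  onset <- pmin(pmax(23.4 + 6.9 * couple(cp["onset_age"]), 13), age - 0.5)
  duration <- pmin(pmax(7.5 + 7.0 * rnorm(n), 0.2), age - onset)
  dose <- pmax(312.8 + 269.8 * rnorm(n), 0)
  data.frame(onset_age = round(onset, 1), duration = round(duration, 1),
             dose = round(dose, 1), panss_pos = panss_pos,
             panss_neg = panss_neg, panss_gen = panss_gen, fsiq = fsiq)
}
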