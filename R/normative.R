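#' Fit a Gaussian-process normative model of predicted age
#'
#' Models brain-predicted age as a function of chronological age and sex in
#' a healthy reference cohort, giving at any (age, sex) the peer mean and
#' peer SD of predicted age. The predictive SD is the total SD (latent
#' variance plus observation noise): a normative range describes where
#' individual predicted ages fall, not where the mean sits.
#'
#' @param predicted_age per-subject brain-predicted age (years).
#' @param age chronological age (years).
#' @param sex 0/1 vector; both levels must be present.
#' @param kernel_opts list: \code{ell_init}, \code{ell_lower} (default 1
#'   year), \code{ell_upper} (default 50 years), \code{n_restarts}
#'   (default 5).
#' @param seed seed for the optimiser restarts.
#' @return object of class \code{normative_model}.
#' @export
fit_normative_gpr <- function(predicted_age, age, sex, kernel_opts = list(),
                              seed = 1L) {
  check_aligned(predicted_age, age, sex, n = 50)
  check_numeric(predicted_age, "predicted_age")
  check_numeric(age, "age")
  if (!all(sex %in% c(0, 1))) stop_validation("sex must be coded 0/1")
  if (length(unique(sex)) < 2L)
    stop_validation("both sexes must be present in the normative cohort")
  if (sd(predicted_age) == 0)
    stop_validation("predicted age is constant; normative model undefined")
  fit <- gp_fit(age, sex, predicted_age, kernel_opts, seed = seed)
  structure(list(kernel_spec = fit$par,
                 training_summary = list(n = length(age),
                                         age_range = range(age),
                                         sex_levels = sort(unique(sex))),
                 fit = fit),
            class = "normative_model")
}

#' @export
print.normative_model <- function(x, ...) {
  k <- x$kernel_spec
  cat(sprintf(paste0("GP normative model (n = %d, ages %.1f-%.1f): ",
                     "sf = %.2f, l = %.1f y, sex sd = %.2f, noise = %.2f y\n"),
              x$training_summary$n, x$training_summary$age_range[1],
              x$training_summary$age_range[2], k$sf, k$ell, k$ss, k$sn))
  invisible(x)
}

#' Peer mean and SD of predicted age at given (age, sex)
#'
#' Queries more than 5 years outside the training age range are answered
#' but flagged for extrapolation.
#'
#' @param model a \code{\link{fit_normative_gpr}} fit.
#' @param age,sex query vectors (recycled to common length).
#' @return data.frame with \code{age}, \code{sex}, \code{peer_mean},
#'   \code{peer_sd} (both years) and logical \code{extrapolation}.
#' @export
peer_moments <- function(model, age, sex) {
  if (!inherits(model, "normative_model") || is.null(model$fit))
    stop_validation("model is not a fitted normative model")
  n <- max(length(age), length(sex))
  age <- rep_len(age, n); sex <- rep_len(sex, n)
  check_numeric(age, "age")
  if (!all(sex %in% c(0, 1))) stop_validation("sex must be coded 0/1")
  pr <- gp_predict(model$fit, age, sex)
  if (any(pr$sd <= 0))
    stop_computation("non-positive peer SD; normative fit is degenerate")
  rng <- model$training_summary$age_range
  data.frame(age = age, sex = sex, peer_mean = pr$mean, peer_sd = pr$sd,
             extrapolation = age < rng[1] - 5 | age > rng[2] + 5)
}

#' Normalized predicted age difference (nPAD)
#'
#' \deqn{nPAD = (PredictedAge - \bar{x}_{peers}) / \hat{S}_{peers}}
#' the z-score of an individual's predicted age relative to same-age,
#' same-sex peers in the normative cohort.
#'
#' @inheritParams peer_moments
#' @param predicted_age per-subject predicted age (years).
#' @return numeric vector of nPAD z-scores, with attribute
#'   \code{extrapolation} (logical per subject).
#' @export
score_npad <- function(model, predicted_age, age, sex) {
  check_aligned(predicted_age, age, sex)
  pm <- peer_moments(model, age, sex)
  npad <- (predicted_age - pm$peer_mean) / pm$peer_sd
  attr(npad, "extrapolation") <- pm$extrapolation
  npad
}

#' Predicted age difference (PAD)
#'
#' @param predicted_age,age aligned vectors (years).
#' @return predicted_age - age, in years.
#' @export
score_pad <- function(predicted_age, age) {
  check_aligned(predicted_age, age)
  predicted_age - age
}

#' Linear age-bias correction of PAD (cPAD benchmark)
#'
#' Fits PAD = alpha * age + beta by OLS in the reference cohort;
#' \code{score_cpad} then removes this trend: cPAD = PAD - (alpha * age +
#' beta). This is the conventional regression-based bias correction that
#' nPAD is benchmarked against.
#'
#' @param pad reference-cohort PAD values (years).
#' @param age reference-cohort ages (years), non-constant, n >= 30.
#' @return object of class \code{bias_correction} with \code{alpha},
#'   \code{beta}, \code{fit_n}.
#' @export
fit_bias_correction <- function(pad, age) {
  check_aligned(pad, age, n = 30)
  if (sd(age) == 0) stop_validation("age is constant; cannot fit correction")
  fit <- lm(pad ~ age)
  structure(list(alpha = unname(coef(fit)[2]), beta = unname(coef(fit)[1]),
                 fit_n = length(pad)),
            class = "bias_correction")
}

#' @rdname fit_bias_correction
#' @param fit a \code{bias_correction} object.
#' @export
score_cpad <- function(fit, pad, age) {
  if (!inherits(fit, "bias_correction"))
    stop_validation("fit must come from fit_bias_correction()")
  check_aligned(pad, age)
  pad - (fit$alpha * age + fit$beta)
}

#' Score a cohort: PAD, cPAD and nPAD per subject
#'
#' Convenience wrapper producing the tidy per-subject score table.
#'
#' @param model a \code{brain_age_model}.
#' @param normative a \code{normative_model} fitted on the reference
#'   cohort's predicted ages.
#' @param correction a \code{bias_correction} fitted on the reference
#'   cohort (or NULL to omit cPAD).
#' @param features an \code{\link{feature_matrix}} for the cohort.
#' @param cohort data.frame with \code{subject_id}, \code{age}, \code{sex}.
#' @param predicted optional precomputed predicted ages (e.g. out-of-fold
#'   cross-validation predictions for the training cohort itself);
#'   bypasses \code{\link{predict_age}}.
#' @return data.frame: subject_id, modality, predicted_age, pad, cpad,
#'   npad, extrapolation_flag.
#' @export
score_cohort <- function(model, normative, correction, features, cohort,
                         predicted = NULL) {
  pred <- predicted %||% predict_age(model, features, cohort$sex)
  if (length(pred) != nrow(cohort))
    stop_validation("predicted ages (%d) do not align with cohort (%d)",
                    length(pred), nrow(cohort))
  pad <- score_pad(pred, cohort$age)
  npad <- score_npad(normative, pred, cohort$age, cohort$sex)
  cpad <- if (is.null(correction)) NA_real_ else
    score_cpad(correction, pad, cohort$age)
  data.frame(subject_id = cohort$subject_id,
             modality = model$modality,
             predicted_age = as.numeric(pred),
             pad = as.numeric(pad),
             cpad = as.numeric(cpad),
             npad = as.numeric(npad),
             extrapolation_flag = attr(npad, "extrapolation"),
             stringsAsFactors = FALSE)
}

#' Age-bias diagnostics for PAD metrics
#'
#' Pearson correlation of each metric with chronological age, with
#' two-sided p-values (t approximation; optional permutation test for
#' small n). Mirrors the standard bias table: uncorrected PAD shows a
#' negative correlation with age, cPAD and nPAD should not.
#'
#' @param scores data.frame from \code{\link{score_cohort}} (any subset of
#'   pad/cpad/npad columns).
#' @param age chronological ages aligned with \code{scores}.
#' @param cohort_label label for the report rows.
#' @param permutation use a permutation p-value (recommended for n < 30).
#' @param n_perm permutation count.
#' @return data.frame: metric, cohort, rho, p, note.
#' @export
age_bias_report <- function(scores, age, cohort_label = "cohort",
                            permutation = FALSE, n_perm = 2000L) {
  if (nrow(scores) < 3L) stop_validation("need at least 3 subjects")
  metrics <- intersect(c("pad", "cpad", "npad"), names(scores))
  labels <- c(pad = "PAD", cpad = "cPAD", npad = "nPAD")
  rows <- lapply(metrics, function(m) {
    x <- scores[[m]]
    if (all(is.na(x)))
      return(data.frame(metric = labels[[m]], cohort = cohort_label,
                        rho = NA_real_, p = NA_real_, note = "not computed"))
    if (sd(x) == 0)
      return(data.frame(metric = labels[[m]], cohort = cohort_label,
                        rho = NaN, p = NA_real_,
                        note = "constant metric; correlation undefined"))
    if (permutation) {
      r_obs <- cor(x, age)
      r_null <- vapply(seq_len(n_perm),
                       function(i) cor(sample(x), age), numeric(1))
      p <- (1 + sum(abs(r_null) >= abs(r_obs))) / (n_perm + 1)
      data.frame(metric = labels[[m]], cohort = cohort_label, rho = r_obs,
                 p = p, note = sprintf("permutation (%d)", n_perm))
    } else {
      ct <- cor.test(x, age)
      data.frame(metric = labels[[m]], cohort = cohort_label,
                 rho = unname(ct$estimate), p = ct$p.value, note = "")
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
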