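#' Cohen's f-squared for an added regression term
#'
#' \deqn{f^2 = (R^2_{full} - R^2_{reduced}) / (1 - R^2_{full})}
#'
#' @param r2_full,r2_reduced coefficients of determination with
#'   \code{0 <= r2_reduced <= r2_full < 1}.
#' @return the effect size (dimensionless, >= 0).
#' @export
cohens_f2 <- function(r2_full, r2_reduced) {
  check_numeric(r2_full, "r2_full"); check_numeric(r2_reduced, "r2_reduced")
  if (any(r2_full >= 1)) stop_validation("r2_full must be < 1")
  if (any(r2_reduced < 0) || any(r2_full < 0))
    stop_validation("R-squared values must be non-negative")
  if (any(r2_reduced > r2_full + 1e-12))
    stop_validation("r2_reduced exceeds r2_full")
  pmax((r2_full - r2_reduced) / (1 - r2_full), 0)
}

#' Group-by-feature interaction regression on nPAD
#'
#' OLS of \code{npad ~ feature + group + feature:group + age + sex +
#' education}, with the group dummy coded control = 0, case = 1 so the
#' interaction coefficient reads as the case-specific increment of the
#' feature-nPAD slope. The interaction is tested by its t-test; the effect
#' size is Cohen's f2 from the full model versus the model without the
#' interaction term.
#'
#' @param feature per-subject feature values (natural units).
#' @param npad per-subject nPAD scores.
#' @param group two-level vector; "control"/"case" labels (or a factor
#'   whose first level is the control).
#' @param age,sex,education covariates.
#' @return list: \code{coefficient} (nPAD per feature unit),
#'   \code{std_coefficient} (per feature SD), \code{se}, \code{t},
#'   \code{p}, \code{r2_full}, \code{r2_reduced}, \code{f2}, \code{n}.
#' @export
fit_feature_interaction <- function(feature, npad, group, age, sex,
                                    education) {
  n <- check_aligned(feature, npad, group, age, sex, education)
  check_numeric(feature, "feature"); check_numeric(npad, "npad")
  if (sd(feature) == 0)
    stop_validation("zero-variance feature")
  g <- group_dummy(group)
  if (length(unique(g)) < 2L)
    stop_validation("both groups must be present")
  X_red <- cbind(1, feature, g, age, sex, education)
  X_full <- cbind(X_red, feature * g)
  colnames(X_full) <- c("(Intercept)", "feature", "group", "age", "sex",
                        "education", "feature:group")
  qr_full <- qr(X_full)
  if (qr_full$rank < ncol(X_full)) {
    bad <- colnames(X_full)[qr_full$pivot[(qr_full$rank + 1):ncol(X_full)]]
    stop_validation("collinear terms in interaction model: %s",
                    paste(bad, collapse = ", "))
  }
  fit_full <- lm.fit(X_full, npad)
  fit_red <- lm.fit(X_red, npad)
  tss <- sum((npad - mean(npad))^2)
  rss_full <- sum(fit_full$residuals^2)
  rss_red <- sum(fit_red$residuals^2)
  r2_full <- 1 - rss_full / tss
  r2_red <- 1 - rss_red / tss
  df <- n - ncol(X_full)
  sigma2 <- rss_full / df
  XtX_inv <- chol2inv(chol(crossprod(X_full)))
  k <- ncol(X_full)
  se <- sqrt(sigma2 * XtX_inv[k, k])
  b <- fit_full$coefficients[k]
  tval <- b / se
  list(coefficient = unname(b),
       std_coefficient = unname(b) * sd(feature),
       se = se, t = unname(tval), p = unname(2 * pt(-abs(tval), df)),
       r2_full = r2_full, r2_reduced = r2_red,
       f2 = cohens_f2(r2_full, r2_red), n = n)
}

group_dummy <- function(group) {
  if (is.numeric(group)) {
    if (!all(group %in% c(0, 1)))
      stop_validation("numeric group must be coded 0 (control) / 1 (case)")
    return(as.numeric(group))
  }
  g <- factor(group)
  if (nlevels(g) != 2L) stop_validation("group must have exactly 2 levels")
  if ("control" %in% levels(g)) g <- stats::relevel(g, "control")
  as.numeric(g) - 1
}

#' Scan every feature for group-specific association with nPAD
#'
#' Runs \code{\link{fit_feature_interaction}} for each feature, pairing GM
#' features (volume and thickness; the scan never pre-filters by feature
#' type) with the GM nPAD outcome and WM features (GFA, MD) with the WM
#' outcome. Benjamini-Hochberg correction is applied across all features
#' within each modality scan (or pooled, by flag); records are ranked by
#' Cohen's f2, descending, ties broken by feature name.
#'
#' @param features an \code{\link{feature_matrix}} for the pooled
#'   case + control sample.
#' @param npad named list or data.frame with elements \code{GM} and
#'   \code{WM} (and optionally \code{multimodal}) of per-subject nPAD.
#' @param cohort data.frame with group, age, sex, education, rows aligned
#'   with \code{features}.
#' @param include_multimodal also scan all features against the
#'   multimodal nPAD outcome (off by default).
#' @param bh_family \code{"modality"} (default) or \code{"pooled"}.
#' @param alpha corrected-p threshold defining the significant set.
#' @return data.frame of class \code{interaction_scan}: feature, modality
#'   (block tag), model (GM/WM), coefficient, std_coefficient, f2, p_raw,
#'   p_corrected, significant, rank; sorted by f2 descending. Skipped
#'   features (zero variance) are recorded in attribute \code{skipped}.
#' @export
scan_all_features <- function(features, npad, cohort,
                              include_multimodal = FALSE,
                              bh_family = c("modality", "pooled"),
                              alpha = 0.05) {
  bh_family <- match.arg(bh_family)
  npad <- as.list(npad)
  for (nm in c("GM", "WM"))
    if (is.null(npad[[nm]]))
      stop_validation("npad must provide element '%s'", nm)
  need <- c("group", "age", "sex", "education")
  if (!all(need %in% names(cohort)))
    stop_validation("cohort must contain %s", paste(need, collapse = ", "))
  tags <- attr(features, "modality")
  plan <- list(GM = which(tags %in% c("volume", "thickness")),
               WM = which(tags %in% c("gfa", "md")))
  if (include_multimodal) {
    if (is.null(npad$multimodal))
      stop_validation("include_multimodal = TRUE needs npad$multimodal")
    plan$multimodal <- seq_along(tags)
  }
  rows <- list()
  skipped <- character(0)
  for (mdl in names(plan)) {
    y <- npad[[mdl]]
    for (j in plan[[mdl]]) {
      res <- tryCatch(
        fit_feature_interaction(unclass(features)[, j], y, cohort$group,
                                cohort$age, cohort$sex, cohort$education),
        npad_validation_error = function(e) e)
      if (inherits(res, "error")) {
        skipped <- c(skipped,
                     sprintf("%s [%s]: %s", colnames(features)[j], mdl,
                             conditionMessage(res)))
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        feature = colnames(features)[j], modality = tags[[j]], model = mdl,
        coefficient = res$coefficient,
        std_coefficient = res$std_coefficient,
        f2 = res$f2, p_raw = res$p, p_corrected = NA_real_)
    }
  }
  tab <- do.call(rbind, rows)
  fam <- if (bh_family == "modality") tab$model else rep("all", nrow(tab))
  tab$p_corrected <- bh_adjust(tab$p_raw, family = fam)
  tab$significant <- tab$p_corrected < alpha
  tab <- tab[order(-tab$f2, tab$feature), , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  attr(tab, "skipped") <- skipped
  class(tab) <- c("interaction_scan", "data.frame")
  tab
}
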