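#' Benjamini-Hochberg adjusted p-values, per correction family
#'
#' Step-up FDR adjustment applied separately within each family of tests.
#'
#' @param p p-values in (0, 1].
#' @param family optional vector of family labels; adjustment is applied
#'   within each family (default: one family).
#' @return adjusted p-values in the original order.
#' @export
bh_adjust <- function(p, family = NULL) {
  check_numeric(p, "p")
  if (any(p <= 0 | p > 1))
    stop_validation("p-values must lie in (0, 1]")
  if (is.null(family)) family <- rep(1L, length(p))
  if (length(family) != length(p))
    stop_validation("family labels must align with p-values")
  out <- numeric(length(p))
  for (f in unique(family)) {
    i <- which(family == f)
    out[i] <- p.adjust(p[i], method = "BH")
  }
  out
}

#' Covariate-adjusted group comparison (ANCOVA)
#'
#' Linear model \code{metric ~ group + covariates} with a Type-II F-test of
#' the group term. The nPAD comparison conventionally adjusts education;
#' the cPAD benchmark adjusts sex and education.
#'
#' @param metric per-subject values.
#' @param group two-level factor or character vector.
#' @param covariates data.frame of covariates (may have zero columns).
#' @param metric_name label used in the output.
#' @return object of class \code{group_comparison}: list with group means
#'   and SDs, \code{F}, \code{df} (numerator, denominator), \code{p}.
#' @export
ancova_group_comparison <- function(metric, group, covariates = NULL,
                                    metric_name = "metric") {
  group <- factor(group)
  if (nlevels(group) != 2L)
    stop_validation("group must have exactly 2 levels, got %d",
                    nlevels(group))
  check_numeric(metric, "metric")
  dat <- data.frame(.metric = metric, .group = group)
  if (!is.null(covariates) && ncol(as.data.frame(covariates)) > 0) {
    covariates <- as.data.frame(covariates)
    if (anyNA(covariates)) stop_validation("covariates contain missing values")
    dat <- cbind(dat, covariates)
    fml <- stats::reformulate(c(".group", names(covariates)),
                              response = ".metric")
  } else {
    fml <- .metric ~ .group
  }
  fit <- lm(fml, data = dat)
  if (fit$rank < length(coef(fit))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop_validation("singular design; collinear terms: %s",
                    paste(bad, collapse = ", "))
  }
  an <- car::Anova(fit, type = 2)
  row <- an[".group", ]
  stats_by <- function(fn) tapply(metric, group, fn)
  structure(list(metric = metric_name,
                 groups = levels(group),
                 group_means = as.numeric(stats_by(mean)),
                 group_sds = as.numeric(stats_by(sd)),
                 group_ns = as.numeric(table(group)),
                 F = row[["F value"]],
                 df = c(row[["Df"]], an["Residuals", "Df"]),
                 p = row[["Pr(>F)"]],
                 covariates = if (is.null(covariates)) character(0)
                              else names(covariates)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: %s %.3f (%.3f) vs %s %.3f (%.3f); F(%d,%d) = %.2f, p = %.4g\n",
              x$metric, x$groups[1], x$group_means[1], x$group_sds[1],
              x$groups[2], x$group_means[2], x$group_sds[2],
              x$df[1], x$df[2], x$F, x$p))
  invisible(x)
}

#' Paired t-test between two nPAD modalities
#'
#' @param npad_a,npad_b aligned per-subject scores, n >= 3.
#' @return list with \code{t}, \code{df}, \code{p}, \code{mean_diff},
#'   \code{note} (degenerate-case annotation).
#' @export
paired_modality_test <- function(npad_a, npad_b) {
  n <- check_aligned(npad_a, npad_b, n = 3)
  d <- npad_a - npad_b
  if (sd(d) <= 1e-10 * max(abs(d), 1)) {
    if (all(d == 0))
      return(list(t = 0, df = n - 1L, p = 1, mean_diff = 0,
                  note = "identical vectors"))
    return(list(t = sign(mean(d)) * Inf, df = n - 1L, p = 0,
                mean_diff = mean(d),
                note = "zero-variance differences; t unbounded"))
  }
  tt <- t.test(npad_a, npad_b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = unname(tt$estimate), note = "")
}

#' Compare two independent Pearson correlations (Fisher r-to-z)
#'
#' z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3)), two-sided p.
#'
#' @param r1,r2 sample correlations.
#' @param n1,n2 sample sizes (> 3).
#' @return list with \code{z} and \code{p}.
#' @export
fisher_r_to_z_test <- function(r1, n1, r2, n2) {
  if (n1 <= 3 || n2 <= 3) stop_validation("both samples must have n > 3")
  if (abs(r1) >= 1 || abs(r2) >= 1)
    stop_validation("correlations must lie strictly in (-1, 1)")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Between-group comparison of cross-modality nPAD correlation
#'
#' Pearson correlation of two nPAD modalities within each group, plus a
#' Fisher r-to-z test of whether the two group correlations differ.
#'
#' @param npad_a,npad_b aligned per-subject scores.
#' @param group two-level grouping vector aligned with the scores.
#' @return list with \code{per_group} (data.frame group/n/rho/p) and
#'   \code{difference} (list z, p).
#' @export
modality_correlation_comparison <- function(npad_a, npad_b, group) {
  check_aligned(npad_a, npad_b, group)
  group <- factor(group)
  if (nlevels(group) != 2L) stop_validation("group must have 2 levels")
  per <- lapply(levels(group), function(g) {
    i <- which(group == g)
    if (length(i) <= 3L)
      stop_validation("group '%s' has n = %d; need n > 3", g, length(i))
    ct <- cor.test(npad_a[i], npad_b[i])
    data.frame(group = g, n = length(i), rho = unname(ct$estimate),
               p = ct$p.value)
  })
  per <- do.call(rbind, per)
  diff <- fisher_r_to_z_test(per$rho[1], per$n[1], per$rho[2], per$n[2])
  list(per_group = per, difference = diff)
}

#' Sex differences in nPAD within groups
#'
#' Welch two-sample t-test of nPAD between sexes, per modality and group,
#' with Benjamini-Hochberg correction across the modalities within each
#' group. Single-sex groups are skipped with a note.
#'
#' @param npad data.frame of per-subject nPAD columns (one per modality).
#' @param sex 0/1 vector.
#' @param group grouping vector (one family of corrected tests per group).
#' @return data.frame: group, modality, mean/sd per sex, t, p_raw,
#'   p_corrected, note.
#' @export
sex_difference_analysis <- function(npad, sex, group = NULL) {
  npad <- as.data.frame(npad)
  if (is.null(group)) group <- rep("all", nrow(npad))
  check_aligned(npad[[1]], sex, group)
  out <- list()
  for (g in unique(group)) {
    i <- which(group == g)
    if (length(unique(sex[i])) < 2L) {
      out[[g]] <- data.frame(group = g, modality = names(npad),
                             mean_sex1 = NA, sd_sex1 = NA,
                             mean_sex0 = NA, sd_sex0 = NA,
                             t = NA, p_raw = NA, p_corrected = NA,
                             note = "single-sex group; skipped")
      next
    }
    rows <- lapply(names(npad), function(m) {
      x1 <- npad[[m]][i][sex[i] == 1]; x0 <- npad[[m]][i][sex[i] == 0]
      tt <- t.test(x1, x0)
      data.frame(group = g, modality = m,
                 mean_sex1 = mean(x1), sd_sex1 = sd(x1),
                 mean_sex0 = mean(x0), sd_sex0 = sd(x0),
                 t = unname(tt$statistic), p_raw = tt$p.value,
                 p_corrected = NA_real_, note = "")
    })
    tab <- do.call(rbind, rows)
    tab$p_corrected <- bh_adjust(tab$p_raw)
    out[[g]] <- tab
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Exclude outlying subjects on clinical fields (3-SD rule)
#'
#' Single-pass rule: a subject is excluded iff any listed field deviates
#' from that field's sample mean by more than \code{threshold_sd} sample
#' SDs, with means and SDs computed on the pre-exclusion sample.
#'
#' @param cohort data.frame with a \code{subject_id} column.
#' @param fields names of numeric columns to screen.
#' @param threshold_sd exclusion threshold in SDs (default 3).
#' @return list with \code{cohort} (filtered), \code{excluded} (log
#'   data.frame: subject_id, field, value, z), and \code{n_excluded}.
#' @export
exclude_outliers <- function(cohort, fields, threshold_sd = 3) {
  missing_f <- setdiff(fields, names(cohort))
  if (length(missing_f))
    stop_validation("fields not in cohort: %s",
                    paste(missing_f, collapse = ", "))
  log_rows <- list()
  drop <- rep(FALSE, nrow(cohort))
  for (f in fields) {
    x <- cohort[[f]]
    if (!is.numeric(x)) stop_validation("field '%s' is not numeric", f)
    m <- mean(x, na.rm = TRUE); s <- sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0) next
    z <- (x - m) / s
    bad <- which(!is.na(z) & abs(z) > threshold_sd)
    if (length(bad)) {
      drop[bad] <- TRUE
      log_rows[[f]] <- data.frame(subject_id = cohort$subject_id[bad],
                                  field = f, value = x[bad], z = z[bad])
    }
  }
  if (all(drop)) stop_computation("outlier exclusion removed all subjects")
  excluded <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(subject_id = character(0), field = character(0),
               value = numeric(0), z = numeric(0))
  rownames(excluded) <- NULL
  list(cohort = cohort[!drop, , drop = FALSE], excluded = excluded,
       n_excluded = sum(drop))
}

#' Phenotype regressions on nPAD
#'
#' Three regression model classes per nPAD outcome: clinical factors
#' (duration + onset age + antipsychotic dose), symptom severity (PANSS
#' positive + negative + general), and FSIQ with education controlled.
#' Benjamini-Hochberg correction is applied within each model class across
#' its phenotype predictors and outcomes (covariates are reported but not
#' part of the correction family); the family policy can be switched to a
#' single pooled family.
#'
#' @param npad data.frame of nPAD outcome columns (e.g. GM, WM,
#'   multimodal), rows aligned with \code{phenotypes}.
#' @param phenotypes data.frame with onset_age, duration, dose, panss_pos,
#'   panss_neg, panss_gen, fsiq, education.
#' @param bh_family \code{"class"} (default: one family per model class)
#'   or \code{"pooled"}.
#' @return data.frame: model_class, outcome, predictor, estimate, se,
#'   p_raw, p_corrected, n.
#' @export
phenotype_regressions <- function(npad, phenotypes,
                                  bh_family = c("class", "pooled")) {
  bh_family <- match.arg(bh_family)
  npad <- as.data.frame(npad)
  if (nrow(npad) != nrow(phenotypes))
    stop_validation("npad and phenotypes must have aligned rows")
  classes <- list(
    clinical_factors = c("duration", "onset_age", "dose"),
    symptom_severity = c("panss_pos", "panss_neg", "panss_gen"),
    fsiq = c("fsiq", "education"))
  tested <- list(clinical_factors = classes$clinical_factors,
                 symptom_severity = classes$symptom_severity,
                 fsiq = "fsiq")   # education is a covariate, not tested
  need <- unique(unlist(classes))
  missing_f <- setdiff(need, names(phenotypes))
  if (length(missing_f))
    stop_validation("phenotypes missing columns: %s",
                    paste(missing_f, collapse = ", "))
  rows <- list()
  for (cl in names(classes)) {
    preds <- classes[[cl]]
    for (out_name in names(npad)) {
      dat <- cbind(data.frame(.y = npad[[out_name]]),
                   phenotypes[preds])
      dat <- dat[stats::complete.cases(dat), , drop = FALSE]
      fit <- lm(stats::reformulate(preds, ".y"), data = dat)
      if (fit$rank < length(coef(fit))) {
        bad <- names(coef(fit))[is.na(coef(fit))]
        stop_validation("rank-deficient phenotype model (%s ~ %s): %s",
                        out_name, cl, paste(bad, collapse = ", "))
      }
      sm <- summary(fit)$coefficients
      for (pr in preds) {
        rows[[length(rows) + 1L]] <- data.frame(
          model_class = cl, outcome = out_name, predictor = pr,
          estimate = sm[pr, "Estimate"], se = sm[pr, "Std. Error"],
          p_raw = sm[pr, "Pr(>|t|)"], p_corrected = NA_real_,
          n = nrow(dat), in_family = pr %in% tested[[cl]])
      }
    }
  }
  tab <- do.call(rbind, rows)
  fam <- if (bh_family == "class") tab$model_class else "all"
  idx <- which(tab$in_family)
  tab$p_corrected[idx] <- bh_adjust(tab$p_raw[idx],
                                    family = if (length(fam) > 1)
                                      fam[idx] else rep(fam, length(idx)))
  tab$in_family <- NULL
  rownames(tab) <- NULL
  tab
}
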