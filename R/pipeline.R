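#' Read and write cohort and feature tables
#'
#' Tables are comma-separated UTF-8 with a header row, '.' decimal, sex
#' coded 0/1 (1 = male), ages in decimal years, missing values as empty
#' cells. Feature tables carry \code{subject_id} in the first column;
#' modality is inferred from the feature-name prefix (\code{vol_},
#' \code{ct_}, \code{gfa_}, \code{md_}) unless given explicitly.
#'
#' @param cohort,features objects to write.
#' @param path file path.
#' @name npad_io
NULL

#' @rdname npad_io
#' @export
write_cohort_csv <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname npad_io
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop_validation("no such file: %s", path)
  dat <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "age", "sex", "group")
  missing_c <- setdiff(need, names(dat))
  if (length(missing_c))
    stop_validation("cohort table %s lacks columns: %s", path,
                    paste(missing_c, collapse = ", "))
  dat
}

#' @rdname npad_io
#' @export
write_features_csv <- function(features, path) {
  df <- data.frame(subject_id = rownames(features),
                   unclass(features), check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname npad_io
#' @param modality optional explicit per-feature modality tags.
#' @export
read_feature_table <- function(path, modality = NULL) {
  if (!file.exists(path)) stop_validation("no such file: %s", path)
  dat <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(dat)[1] != "subject_id")
    stop_validation("feature table %s must start with 'subject_id'", path)
  ids <- dat[[1]]
  vals <- as.matrix(dat[, -1, drop = FALSE])
  if (is.null(modality)) {
    prefix <- sub("_.*$", "", colnames(vals))
    map <- c(vol = "volume", ct = "thickness", gfa = "gfa", md = "md")
    if (!all(prefix %in% names(map)))
      stop_validation("cannot infer modality for features: %s",
                      paste(head(colnames(vals)[!prefix %in% names(map)], 5),
                            collapse = ", "))
    modality <- unname(map[prefix])
  }
  feature_matrix(vals, colnames(vals), modality, ids)
}

#' Run the full brain-age analysis pipeline on a synthetic study
#'
#' Generates reference, held-out, case and control cohorts, trains
#' modality-specific brain-age predictors, fits the Gaussian-process
#' normative models, scores PAD/cPAD/nPAD for every cohort, and runs the
#' downstream statistics: bias diagnostics, covariate-adjusted group
#' comparisons, paired and correlation comparisons between modalities, sex
#' differences, outlier-screened phenotype regressions, and the per-feature
#' interaction scan. All tables are written as CSV beneath \code{out_dir}
#' together with a manifest; a rerun with the same config and seed
#' reproduces the outputs byte-identically.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @param out_dir output directory (created; refuses to overwrite an
#'   existing run unless \code{force}).
#' @param backend predictor backend (see \code{\link{train_predictor}}).
#' @param hyperparams backend hyperparameters.
#' @param cv run 10-fold cross-validation per modality (the slowest stage
#'   for the cascade backend).
#' @param modalities which models to build.
#' @param force overwrite an existing run.
#' @return (invisibly) a list with every intermediate and result object.
#' @export
run_pipeline <- function(config = synthetic_config(), out_dir,
                         backend = c("cascade", "ridge", "mean"),
                         hyperparams = list(), cv = TRUE,
                         modalities = c("GM", "WM", "multimodal"),
                         force = FALSE) {
  backend <- match.arg(backend)
  manifest_path <- file.path(out_dir, "manifest.json")
  if (file.exists(manifest_path) && !force)
    stop_validation("output directory %s holds a previous run; use force = TRUE",
                    out_dir)
  for (d in c("", "cohorts", "models", "results"))
    dir.create(file.path(out_dir, d), recursive = TRUE, showWarnings = FALSE)

  ## stage: simulate ------------------------------------------------------
  ref <- generate_reference_cohort(config)
  tst <- generate_test_cohort(config, ref$truth)
  cc <- generate_case_control_cohorts(config, ref$truth)
  cohorts <- list(reference = ref, test = tst,
                  case = cc$case, control = cc$control)
  for (nm in names(cohorts)) {
    write_cohort_csv(cohorts[[nm]]$cohort,
                     file.path(out_dir, "cohorts", paste0(nm, ".csv")))
    write_features_csv(cohorts[[nm]]$features,
                       file.path(out_dir, "cohorts",
                                 paste0("features_", nm, ".csv")))
  }
  truth <- list(delta_age_years = cc$case$truth$delta_age_years,
                is_interaction_feature =
                  setNames(as.list(ref$truth$world$is_interaction_feature),
                           ref$truth$world$feature_names))
  jsonlite::write_json(truth, file.path(out_dir, "cohorts", "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  yaml::write_yaml(unclass(config), file.path(out_dir, "cohorts",
                                              "config.yaml"))

  ## stage: train + normative + score ------------------------------------
  models <- list(); normatives <- list(); corrections <- list()
  cv_reports <- list(); score_tabs <- list()
  for (mod in modalities) {
    m <- train_predictor(ref$features, ref$cohort, modality = mod,
                         backend = backend, hyperparams = hyperparams,
                         seed = config$seed)
    models[[mod]] <- m
    if (cv)
      cv_reports[[mod]] <- crossvalidate_10fold(
        ref$features, ref$cohort, modality = mod, backend = backend,
        hyperparams = hyperparams, seed = config$seed)
    # normative and bias-correction fits use out-of-fold predictions when
    # available: in-sample predictions of an overfit regressor understate
    # both the peer SD and the age bias that held-out subjects will see
    pred_ref <- if (cv) cv_reports[[mod]]$predictions else
      predict_age(m, ref$features, ref$cohort$sex)
    normatives[[mod]] <- fit_normative_gpr(pred_ref, ref$cohort$age,
                                           ref$cohort$sex,
                                           seed = config$seed)
    corrections[[mod]] <- fit_bias_correction(
      score_pad(pred_ref, ref$cohort$age), ref$cohort$age)
    for (nm in names(cohorts)) {
      tab <- score_cohort(m, normatives[[mod]], corrections[[mod]],
                          cohorts[[nm]]$features, cohorts[[nm]]$cohort,
                          predicted = if (nm == "reference") pred_ref)
      tab$cohort <- nm
      score_tabs[[paste(mod, nm)]] <- tab
    }
    jsonlite::write_json(
      list(modality = mod,
           kernel = normatives[[mod]]$kernel_spec,
           training_summary = normatives[[mod]]$training_summary,
           bias_correction = unclass(corrections[[mod]])),
      file.path(out_dir, "models", paste0("normative_", mod, ".json")),
      auto_unbox = TRUE, digits = NA)
  }
  pad_scores <- do.call(rbind, score_tabs)
  rownames(pad_scores) <- NULL
  write.csv(pad_scores, file.path(out_dir, "results", "pad_scores.csv"),
            row.names = FALSE)
  if (cv) {
    cv_tab <- do.call(rbind, lapply(names(cv_reports), function(mod) {
      r <- cv_reports[[mod]]
      data.frame(modality = mod, k = r$k, pooled_rho = r$pooled_rho,
                 pooled_mae = r$pooled_mae)
    }))
    write.csv(cv_tab, file.path(out_dir, "models", "cv_report.csv"),
              row.names = FALSE)
  }

  ## stage: bias diagnostics ---------------------------------------------
  bias <- do.call(rbind, lapply(modalities, function(mod) {
    do.call(rbind, lapply(c("reference", "test"), function(nm) {
      sc <- pad_scores[pad_scores$modality == mod &
                         pad_scores$cohort == nm, ]
      rep <- age_bias_report(sc, cohorts[[nm]]$cohort$age, nm)
      rep$modality <- mod
      rep
    }))
  }))
  write.csv(bias, file.path(out_dir, "results", "bias_report.csv"),
            row.names = FALSE)

  ## stage: group comparisons --------------------------------------------
  cc_cohort <- rbind(cc$case$cohort[names(cc$control$cohort)],
                     cc$control$cohort)
  grab <- function(mod, nm, col)
    pad_scores[pad_scores$modality == mod & pad_scores$cohort == nm, col]
  comp_rows <- list()
  for (metric in c("npad", "cpad")) {
    for (mod in modalities) {
      y <- c(grab(mod, "case", metric), grab(mod, "control", metric))
      covs <- if (metric == "npad")
        data.frame(education = cc_cohort$education)
      else
        data.frame(sex = cc_cohort$sex, education = cc_cohort$education)
      gc <- ancova_group_comparison(y, cc_cohort$group, covs,
                                    metric_name = sprintf("%s-%s",
                                      ifelse(metric == "npad", "nPAD",
                                             "cPAD"), mod))
      comp_rows[[length(comp_rows) + 1L]] <- data.frame(
        metric = gc$metric, family = metric,
        mean_case = gc$group_means[gc$groups == "case"],
        sd_case = gc$group_sds[gc$groups == "case"],
        mean_control = gc$group_means[gc$groups == "control"],
        sd_control = gc$group_sds[gc$groups == "control"],
        F = gc$F, df1 = gc$df[1], df2 = gc$df[2], p_raw = gc$p,
        p_corrected = NA_real_)
    }
  }
  comp <- do.call(rbind, comp_rows)
  comp$p_corrected <- bh_adjust(comp$p_raw, family = comp$family)
  write.csv(comp, file.path(out_dir, "results", "group_comparisons.csv"),
            row.names = FALSE)

  ## stage: modality comparisons and sex differences ---------------------
  paired <- do.call(rbind, lapply(c("case", "control"), function(nm) {
    pt <- paired_modality_test(grab("GM", nm, "npad"),
                               grab("WM", nm, "npad"))
    data.frame(cohort = nm, comparison = "nPAD-GM vs nPAD-WM",
               t = pt$t, df = pt$df, p = pt$p, mean_diff = pt$mean_diff)
  }))
  write.csv(paired, file.path(out_dir, "results", "paired_tests.csv"),
            row.names = FALSE)

  npad_gm_cc <- c(grab("GM", "case", "npad"), grab("GM", "control", "npad"))
  npad_wm_cc <- c(grab("WM", "case", "npad"), grab("WM", "control", "npad"))
  corr_cmp <- modality_correlation_comparison(npad_gm_cc, npad_wm_cc,
                                              cc_cohort$group)
  corr_tab <- corr_cmp$per_group
  corr_tab$diff_z <- corr_cmp$difference$z
  corr_tab$diff_p <- corr_cmp$difference$p
  write.csv(corr_tab,
            file.path(out_dir, "results", "correlation_comparison.csv"),
            row.names = FALSE)

  npad_cc <- data.frame(GM = npad_gm_cc, WM = npad_wm_cc)
  if ("multimodal" %in% modalities)
    npad_cc$multimodal <- c(grab("multimodal", "case", "npad"),
                            grab("multimodal", "control", "npad"))
  sexdiff <- sex_difference_analysis(npad_cc, cc_cohort$sex,
                                     cc_cohort$group)
  write.csv(sexdiff, file.path(out_dir, "results", "sex_differences.csv"),
            row.names = FALSE)

  ## stage: phenotype regressions ----------------------------------------
  pheno_fields <- c("onset_age", "duration", "dose",
                    "panss_pos", "panss_neg", "panss_gen")
  excl <- exclude_outliers(cc$case$cohort, pheno_fields)
  keep_ids <- excl$cohort$subject_id
  case_npad <- lapply(modalities, function(mod) {
    sc <- pad_scores[pad_scores$modality == mod &
                       pad_scores$cohort == "case", ]
    sc$npad[match(keep_ids, sc$subject_id)]
  })
  names(case_npad) <- modalities
  case_npad <- as.data.frame(case_npad)
  pheno <- phenotype_regressions(case_npad, excl$cohort)
  write.csv(excl$excluded, file.path(out_dir, "results", "exclusions.csv"),
            row.names = FALSE)
  write.csv(pheno,
            file.path(out_dir, "results", "phenotype_regressions.csv"),
            row.names = FALSE)

  ## stage: interaction scan ---------------------------------------------
  feats_cc <- feature_matrix(
    rbind(unclass(cc$case$features), unclass(cc$control$features)),
    colnames(cc$case$features),
    attr(cc$case$features, "modality"),
    c(rownames(cc$case$features), rownames(cc$control$features)))
  scan <- scan_all_features(feats_cc,
                            list(GM = npad_gm_cc, WM = npad_wm_cc),
                            cc_cohort)
  write.csv(as.data.frame(scan),
            file.path(out_dir, "results", "interactions.csv"),
            row.names = FALSE)

  ## manifest -------------------------------------------------------------
  cohort_files <- list.files(file.path(out_dir, "cohorts"),
                             full.names = TRUE)
  manifest <- list(
    seed = config$seed, backend = backend, cv = cv,
    modalities = modalities,
    config = unclass(config),
    package_version = as.character(utils::packageVersion("npad")),
    input_md5 = as.list(setNames(as.character(tools::md5sum(sort(cohort_files))),
                                 basename(sort(cohort_files)))))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)

  invisible(list(config = config, cohorts = cohorts, models = models,
                 normatives = normatives, corrections = corrections,
                 cv_reports = cv_reports, pad_scores = pad_scores,
                 bias_report = bias, group_comparisons = comp,
                 paired_tests = paired, correlation_comparison = corr_tab,
                 sex_differences = sexdiff, exclusions = excl,
                 phenotype_regressions = pheno, interaction_scan = scan))
}
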