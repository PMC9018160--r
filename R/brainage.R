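#' Train a brain-age predictor
#'
#' Fits a regressor mapping standardized regional features plus sex to
#' chronological age on a reference cohort. The default backend is a
#' 12-block cascade feedforward network (dense skip connectivity, tanh
#' blocks, linear head, Adam with early stopping); a closed-form ridge
#' backend and a constant mean-age backend are provided because every
#' downstream score (PAD, cPAD, nPAD) is predictor-agnostic.
#'
#' @param features an \code{\link{feature_matrix}} for the training cohort.
#' @param demographics data.frame with \code{age} (years) and \code{sex}
#'   (0/1), rows aligned with \code{features}.
#' @param modality \code{"GM"} (volume + thickness), \code{"WM"}
#'   (GFA + MD) or \code{"multimodal"}.
#' @param backend \code{"cascade"}, \code{"ridge"} or \code{"mean"}.
#' @param hyperparams backend options. Cascade: \code{blocks}, \code{width},
#'   \code{lr}, \code{epochs}, \code{patience}, \code{val_frac}. Ridge:
#'   \code{lambda} (penalty on standardized predictors, default 1).
#' @param seed integer seed; training is reproducible end-to-end.
#' @return an object of class \code{brain_age_model}.
#' @export
train_predictor <- function(features, demographics,
                            modality = c("GM", "WM", "multimodal"),
                            backend = c("cascade", "ridge", "mean"),
                            hyperparams = list(), seed = 1L) {
  modality <- match.arg(modality)
  backend <- match.arg(backend)
  if (!all(c("age", "sex") %in% names(demographics)))
    stop_validation("demographics must contain 'age' and 'sex'")
  feats <- select_modality(features, modality)
  n <- nrow(feats)
  if (n != nrow(demographics))
    stop_validation("features (%d rows) and demographics (%d rows) differ",
                    n, nrow(demographics))
  if (n < 50L)
    stop_computation("need at least 50 training subjects, got %d", n)
  check_numeric(demographics$age, "age")
  if (!all(demographics$sex %in% c(0, 1)))
    stop_validation("sex must be coded 0/1")

  X <- cbind(unclass(feats), sex = demographics$sex)
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  dead <- names(scl)[scl <= 0 | !is.finite(scl)]
  if (length(dead))
    stop_validation("zero-variance predictors rejected: %s",
                    paste(head(dead, 10), collapse = ", "))
  Xs <- scale(X, center = ctr, scale = scl)
  y <- demographics$age

  set.seed(seed)
  fit <- switch(backend,
    cascade = cascade_train(Xs, y, hyperparams),
    ridge = ridge_train(Xs, y, hyperparams$lambda %||% 1),
    mean = list(mean_age = mean(y)))

  structure(list(modality = modality,
                 feature_names = colnames(feats),
                 center = ctr, scale = scl,
                 backend = backend, fit = fit,
                 training_metadata = list(n = n, seed = seed,
                                          hyperparams = hyperparams)),
            class = "brain_age_model")
}

# Ridge with unpenalized intercept on standardized predictors.
ridge_train <- function(Xs, y, lambda) {
  p <- ncol(Xs)
  yc <- y - mean(y)
  XtX <- crossprod(Xs) + diag(lambda, p)
  coefs <- solve(XtX, crossprod(Xs, yc))
  list(coefs = drop(coefs), intercept = mean(y), lambda = lambda)
}

#' Predict brain age
#'
#' Applies the stored standardization and backend. Feature columns are
#' matched by name (order-free); any mismatch is a schema error listing
#' the differences.
#'
#' @param model a \code{\link{train_predictor}} fit.
#' @param features an \code{\link{feature_matrix}} (may contain extra
#'   modalities; the model's feature set is selected by name).
#' @param sex per-subject 0/1 vector.
#' @return named numeric vector of predicted ages (years).
#' @export
predict_age <- function(model, features, sex) {
  tags <- attr(features, "modality")
  want <- setdiff(model$feature_names, "sex")
  have <- colnames(features)
  if (all(want %in% have)) {
    Xf <- unclass(features)[, want, drop = FALSE]
  } else {
    Xf <- align_features(features, want)   # errors with the name diff
  }
  if (length(sex) != nrow(Xf))
    stop_validation("sex vector length (%d) != subjects (%d)",
                    length(sex), nrow(Xf))
  if (!all(sex %in% c(0, 1))) stop_validation("sex must be coded 0/1")
  X <- cbind(Xf, sex = sex)
  Xs <- scale(X[, names(model$center), drop = FALSE],
              center = model$center, scale = model$scale)
  pred <- switch(model$backend,
    cascade = cascade_predict(model$fit, Xs),
    ridge = drop(Xs %*% model$fit$coefs) + model$fit$intercept,
    mean = rep(model$fit$mean_age, nrow(Xs)))
  if (any(!is.finite(pred)))
    stop_computation("non-finite predicted ages produced")
  setNames(pred, rownames(Xf))
}

#' Pearson correlation and mean absolute error of predicted age
#'
#' @param predicted,actual aligned numeric vectors (years), length >= 3.
#' @return list with \code{rho} and \code{mae}. A constant prediction
#'   vector yields \code{rho = NaN} with a warning; \code{mae} stays valid.
#' @export
performance_metrics <- function(predicted, actual) {
  check_aligned(predicted, actual, n = 3)
  check_numeric(predicted, "predicted"); check_numeric(actual, "actual")
  if (sd(actual) == 0)
    stop_validation("actual ages are constant; correlation undefined")
  mae <- mean(abs(predicted - actual))
  if (sd(predicted) == 0) {
    warning("constant predictions: correlation undefined (NaN)")
    rho <- NaN
  } else {
    rho <- cor(predicted, actual)
  }
  list(rho = rho, mae = mae)
}

#' k-fold cross-validated performance of a brain-age model
#'
#' Subjects are shuffled with the given seed and split into k contiguous
#' folds; each fold is predicted by a model trained on the remainder.
#' Reports per-fold and pooled (out-of-fold) Pearson rho and MAE.
#'
#' @inheritParams train_predictor
#' @param k fold count (default 10).
#' @return an object of class \code{cv_report}: list with \code{k},
#'   \code{per_fold} (data.frame fold/n/rho/mae), \code{pooled_rho},
#'   \code{pooled_mae}, \code{predictions} (out-of-fold, in input order),
#'   and \code{seed}.
#' @export
crossvalidate_10fold <- function(features, demographics,
                                 modality = c("GM", "WM", "multimodal"),
                                 backend = c("cascade", "ridge", "mean"),
                                 hyperparams = list(), seed = 1L, k = 10L) {
  modality <- match.arg(modality)
  backend <- match.arg(backend)
  n <- nrow(features)
  if (k > n) stop_validation("k = %d exceeds n = %d", k, n)
  set.seed(seed)
  # seeded shuffle then contiguous split
  ord <- sample.int(n)
  sizes <- diff(floor(seq(0, n, length.out = k + 1)))
  fold_of <- integer(n)
  fold_of[ord] <- rep(seq_len(k), times = sizes)

  pred <- rep(NA_real_, n)
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    hold <- which(fold_of == f)
    train <- which(fold_of != f)
    m <- train_predictor(
      feature_matrix(unclass(features)[train, , drop = FALSE],
                     colnames(features),
                     attr(features, "modality"),
                     rownames(features)[train]),
      demographics[train, , drop = FALSE],
      modality = modality, backend = backend,
      hyperparams = hyperparams, seed = seed + f)
    ph <- predict_age(m,
      feature_matrix(unclass(features)[hold, , drop = FALSE],
                     colnames(features),
                     attr(features, "modality"),
                     rownames(features)[hold]),
      demographics$sex[hold])
    pred[hold] <- ph
    pm <- performance_metrics(ph, demographics$age[hold])
    per_fold[[f]] <- data.frame(fold = f, n = length(hold),
                                rho = pm$rho, mae = pm$mae)
  }
  pooled <- performance_metrics(pred, demographics$age)
  structure(list(k = k, per_fold = do.call(rbind, per_fold),
                 pooled_rho = pooled$rho, pooled_mae = pooled$mae,
                 predictions = setNames(pred, rownames(features)),
                 seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold CV: pooled rho = %.3f, pooled MAE = %.2f years\n",
              x$k, x$pooled_rho, x$pooled_mae))
  invisible(x)
}

#' Serialize a brain-age predictor to JSON
#'
#' Writes metadata and (for the linear backends) the fitted weights;
#' cascade weights are written as flat numeric arrays. The file can be
#' restored with \code{\link{read_predictor}}.
#'
#' @param model a \code{brain_age_model}.
#' @param path output file.
#' @export
write_predictor <- function(model, path) {
  obj <- unclass(model)
  if (model$backend == "cascade") {
    par <- model$fit$par
    obj$fit$par <- NULL
    obj$fit$theta <- cascade_pack(par)
    obj$fit$shape <- list(p = length(model$center),
                          blocks = length(par$W),
                          width = nrow(par$W[[1]]))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_predictor
#' @export
read_predictor <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  nm <- c(unlist(obj$feature_names), "sex")
  obj$feature_names <- unlist(obj$feature_names)
  obj$center <- setNames(unlist(obj$center), nm)
  obj$scale <- setNames(unlist(obj$scale), nm)
  if (obj$backend == "ridge") obj$fit$coefs <- unlist(obj$fit$coefs)
  if (obj$backend == "cascade") {
    sh <- obj$fit$shape
    skel <- cascade_init(sh$p, sh$blocks, sh$width)
    obj$fit$par <- cascade_unpack(unlist(obj$fit$theta), skel)
    obj$fit$theta <- NULL; obj$fit$shape <- NULL
  }
  class(obj) <- "brain_age_model"
  obj
}
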