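#' Construct a feature matrix
#'
#' A subjects-by-features numeric matrix with unique feature names and a
#' per-feature modality tag (volume, thickness, gfa or md). Row order must
#' match the accompanying cohort table.
#'
#' @param values numeric matrix, subjects in rows.
#' @param feature_names character vector of unique column names.
#' @param modality per-feature tag in volume/thickness/gfa/md.
#' @param subject_ids row identifiers.
#' @return an object of class \code{npad_features} (a matrix with a
#'   \code{modality} attribute).
#' @export
feature_matrix <- function(values, feature_names = colnames(values),
                           modality, subject_ids = rownames(values)) {
  values <- as.matrix(values)
  if (is.null(feature_names) || anyDuplicated(feature_names))
    stop_validation("feature names must be present and unique")
  if (length(feature_names) != ncol(values))
    stop_validation("feature_names length (%d) != number of columns (%d)",
                    length(feature_names), ncol(values))
  if (length(modality) != ncol(values))
    stop_validation("modality tags must be given per feature")
  if (!all(modality %in% c("volume", "thickness", "gfa", "md")))
    stop_validation("modality tags must be volume/thickness/gfa/md")
  if (is.null(subject_ids) || anyDuplicated(subject_ids))
    stop_validation("subject ids must be present and unique")
  if (anyNA(values) || any(!is.finite(values))) {
    bad <- subject_ids[apply(values, 1, function(r) any(!is.finite(r)))]
    stop_validation("missing/non-finite feature values for subjects: %s",
                    paste(head(bad, 10), collapse = ", "))
  }
  dimnames(values) <- list(subject_ids, feature_names)
  structure(values, modality = setNames(modality, feature_names),
            class = c("npad_features", "matrix", "array"))
}

#' Subset a feature matrix by modality grouping
#'
#' \code{"GM"} selects volume + thickness features, \code{"WM"} selects
#' GFA + MD, \code{"multimodal"} selects everything.
#'
#' @param features an \code{\link{feature_matrix}}.
#' @param modality \code{"GM"}, \code{"WM"} or \code{"multimodal"}.
#' @return an \code{npad_features} with the selected columns.
#' @export
select_modality <- function(features, modality = c("GM", "WM", "multimodal")) {
  modality <- match.arg(modality)
  tags <- attr(features, "modality")
  keep <- switch(modality,
                 GM = tags %in% c("volume", "thickness"),
                 WM = tags %in% c("gfa", "md"),
                 multimodal = rep(TRUE, length(tags)))
  feature_matrix(unclass(features)[, keep, drop = FALSE],
                 colnames(features)[keep], tags[keep], rownames(features))
}

# Align a feature matrix to a model's expected feature names; order-free
# but otherwise strict.
align_features <- function(features, expected_names) {
  have <- colnames(features)
  missing <- setdiff(expected_names, have)
  extra <- setdiff(have, expected_names)
  if (length(missing) || length(extra))
    stop_validation("feature name mismatch; missing: [%s]; unexpected: [%s]",
                    paste(head(missing, 5), collapse = ", "),
                    paste(head(extra, 5), collapse = ", "))
  unclass(features)[, expected_names, drop = FALSE]
}
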