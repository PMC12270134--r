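#' Labeled expression dataset
#'
#' Container for a samples-by-features expression matrix with binary class
#' labels. Labels are held internally in the canonical -1/+1 coding (so the
#' product `y_j * y_k` used by the fidelity loss and the SVC dual is exact);
#' on-disk tables use 0/1 and the mapping is recorded in the object.
#'
#' @param features numeric matrix, samples in rows, features in columns.
#' @param labels vector coercible to -1/+1: accepts -1/+1, 0/1 (0 maps to -1),
#'   or a two-level factor (first level maps to -1).
#' @param sample_ids,feature_ids optional character identifiers; defaults are
#'   generated.
#' @return An object of class `labeled_dataset` with elements `features`
#'   (matrix), `labels` (integer -1/+1), `sample_ids`, `feature_ids`,
#'   `label_map` (named integer recording the original-to-internal coding).
#' @examples
#' ds <- labeled_dataset(matrix(rnorm(12), 6, 2), c(0, 0, 0, 1, 1, 0))
#' table(ds$labels)
#' @export
labeled_dataset <- function(features, labels, sample_ids = NULL, feature_ids = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (anyNA(features) || any(!is.finite(features)))
    stop("features contain missing or non-finite entries", call. = FALSE)
  if (nrow(features) != length(labels))
    stop(sprintf("row count of features (%d) must equal length of labels (%d)",
                 nrow(features), length(labels)), call. = FALSE)
  canon <- canonicalize_labels(labels)
  sample_ids <- as.character(sample_ids %||% sprintf("s%03d", seq_len(nrow(features))))
  feature_ids <- as.character(feature_ids %||%
                                (colnames(features) %||% sprintf("f%02d", seq_len(ncol(features)))))
  if (length(sample_ids) != nrow(features)) stop("sample_ids length mismatch", call. = FALSE)
  if (length(feature_ids) != ncol(features)) stop("feature_ids length mismatch", call. = FALSE)
  dimnames(features) <- NULL
  structure(list(features = features, labels = canon$labels,
                 sample_ids = sample_ids, feature_ids = feature_ids,
                 label_map = canon$map),
            class = "labeled_dataset")
}

canonicalize_labels <- function(labels) {
  if (is.factor(labels)) {
    lv <- levels(droplevels(labels))
    if (length(lv) > 2L) stop("labels must have exactly two levels", call. = FALSE)
    labels <- as.character(labels)
    map <- stats::setNames(c(-1L, 1L)[seq_along(lv)], lv)
    return(list(labels = unname(map[labels]), map = map))
  }
  u <- sort(unique(labels))
  if (length(u) > 2L) stop("labels must take at most two distinct values", call. = FALSE)
  if (all(u %in% c(-1, 1))) {
    map <- stats::setNames(as.integer(u), as.character(u))
  } else if (all(u %in% c(0, 1))) {
    map <- stats::setNames(ifelse(u == 0, -1L, 1L), as.character(u))
  } else {
    map <- stats::setNames(c(-1L, 1L)[seq_along(u)], as.character(u))
  }
  list(labels = unname(map[as.character(labels)]), map = map)
}

#' @export
print.labeled_dataset <- function(x, ...) {
  tab <- table(factor(x$labels, levels = c(-1L, 1L)))
  cat(sprintf("<labeled_dataset> %d samples x %d features\n",
              nrow(x$features), ncol(x$features)))
  cat(sprintf("  classes: %d (-1) / %d (+1)\n", tab[["-1"]], tab[["1"]]))
  invisible(x)
}

#' @export
dim.labeled_dataset <- function(x) dim(x$features)

#' Subset a labeled dataset by row indices
#' @param ds a [labeled_dataset()].
#' @param idx integer (or logical) row indices.
#' @return the subsetted [labeled_dataset()].
#' @export
subset_dataset <- function(ds, idx) {
  labeled_dataset(ds$features[idx, , drop = FALSE], ds$labels[idx],
                  sample_ids = ds$sample_ids[idx], feature_ids = ds$feature_ids)
}

#' Per-class sample counts
#' @param ds a [labeled_dataset()].
#' @return named integer vector `c(neg = ..., pos = ...)` over the internal
#'   -1/+1 classes.
#' @export
class_counts <- function(ds) {
  c(neg = sum(ds$labels == -1L), pos = sum(ds$labels == 1L))
}
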