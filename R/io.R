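#' Read and write expression tables
#'
#' Delimited text with samples as rows and features as columns; the reserved
#' columns `sample_id` and `label` carry identifiers and the 0/1 class coding
#' used on disk (0 = majority/internal -1, 1 = minority/internal +1). The
#' delimiter is inferred from the extension: `.csv` is comma, anything else
#' (`.tsv`, `.txt`) is tab. A write/read round trip reproduces features to
#' full precision and labels exactly.
#'
#' @param path file path.
#' @param ds a [labeled_dataset()].
#' @return `read_expression_table` returns a [labeled_dataset()];
#'   `write_expression_table` invisibly returns `path`.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' ds <- generate_two_class(5, 3, d = 2, seed = 1)
#' write_expression_table(ds, f)
#' identical(read_expression_table(f)$labels, ds$labels)
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  sep <- table_delim(path)
  lines <- readLines(path)
  if (length(lines) < 2L) stop("expression table needs a header and at least one sample row",
                               call. = FALSE)
  header <- strsplit(lines[[1L]], sep, fixed = TRUE)[[1L]]
  if (!"label" %in% header) stop("missing required 'label' column", call. = FALSE)
  if (!"sample_id" %in% header) stop("missing required 'sample_id' column", call. = FALSE)
  ncol_expected <- length(header)
  cells <- strsplit(lines[-1L], sep, fixed = TRUE)
  widths <- lengths(cells)
  if (any(widths != ncol_expected)) {
    bad <- which(widths != ncol_expected)[1L]
    stop(sprintf("ragged row %d: %d fields, expected %d", bad, widths[bad], ncol_expected),
         call. = FALSE)
  }
  mat <- do.call(rbind, cells)
  colnames(mat) <- header
  feat_cols <- setdiff(header, c("sample_id", "label"))
  feats <- matrix(NA_real_, nrow(mat), length(feat_cols),
                  dimnames = list(NULL, feat_cols))
  for (j in seq_along(feat_cols)) {
    v <- suppressWarnings(as.numeric(mat[, feat_cols[j]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1L]
      stop(sprintf("non-numeric feature cell at row %d, column '%s': '%s'",
                   bad, feat_cols[j], mat[bad, feat_cols[j]]), call. = FALSE)
    }
    feats[, j] <- v
  }
  lab_raw <- suppressWarnings(as.numeric(mat[, "label"]))
  if (anyNA(lab_raw) || !all(lab_raw %in% c(0, 1, -1))) {
    bad <- which(is.na(lab_raw) | !(lab_raw %in% c(0, 1, -1)))[1L]
    stop(sprintf("invalid label at row %d: '%s' (expected 0/1)", bad, mat[bad, "label"]),
         call. = FALSE)
  }
  labeled_dataset(feats, lab_raw, sample_ids = mat[, "sample_id"], feature_ids = feat_cols)
}

#' @rdname read_expression_table
#' @export
write_expression_table <- function(ds, path) {
  stopifnot(inherits(ds, "labeled_dataset"))
  sep <- table_delim(path)
  header <- c("sample_id", ds$feature_ids, "label")
  lab01 <- ifelse(ds$labels == 1L, 1L, 0L)
  rows <- vapply(seq_len(nrow(ds$features)), function(i) {
    paste(c(ds$sample_ids[i],
            format(ds$features[i, ], digits = 17, scientific = TRUE, trim = TRUE),
            lab01[i]), collapse = sep)
  }, character(1))
  writeLines(c(paste(header, collapse = sep), rows), path)
  invisible(path)
}

table_delim <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}
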