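#' Subject-level dataset of features, confounds and a target
#'
#' Bundles an `n x dG` feature matrix `G` (e.g. voxelwise grey-matter values),
#' an `n x dC` confound matrix `C` (continuous, or two-level discrete encoded
#' as a single 0/1 column) and a length-`n` target vector `y` (e.g. a clinical
#' score or age), with aligned subject identifiers. All downstream modelling
#' and evaluation functions consume this container.
#'
#' @param G Numeric matrix (or data frame) of features, one row per subject.
#' @param y Numeric target vector, length `nrow(G)`.
#' @param C Optional numeric matrix/data frame of confounds; two-level
#'   discrete confounds must be encoded as one column with exactly two
#'   distinct values. `NULL` means no confounds (`dC = 0`).
#' @param subject_ids Optional character vector of identifiers; defaults to
#'   `"s1" ... "sn"`.
#' @param feature_names,confound_names Optional column labels; taken from the
#'   matrices when present.
#'
#' @return An object of class `confound_dataset`: a list with elements
#'   `subject_ids`, `G`, `C`, `y`, `feature_names`, `confound_names`.
#' @examples
#' ds <- confound_dataset(G = matrix(rnorm(20), 5, 4), y = rnorm(5),
#'                        C = matrix(c(0, 1, 0, 1, 1), 5, 1))
#' ds
#' @export
confound_dataset <- function(G, y, C = NULL, subject_ids = NULL,
                             feature_names = NULL, confound_names = NULL) {
  G <- as.matrix(G)
  storage.mode(G) <- "double"
  rownames(G) <- NULL
  n <- nrow(G)
  y <- as.numeric(y)
  if (is.null(C)) C <- matrix(numeric(0), n, 0)
  C <- as.matrix(C)
  storage.mode(C) <- "double"
  rownames(C) <- NULL
  if (length(y) != n || nrow(C) != n)
    abort(sprintf("row counts differ: G has %d, C has %d, y has %d",
                  n, nrow(C), length(y)), class = "deconfound_validation_error")
  if (is.null(subject_ids)) subject_ids <- paste0("s", seq_len(n))
  subject_ids <- as.character(subject_ids)
  if (length(subject_ids) != n)
    abort("subject_ids length does not match number of rows",
          class = "deconfound_validation_error")
  if (anyNA(G) || anyNA(C) || anyNA(y) ||
      !all(is.finite(G)) || (ncol(C) > 0 && !all(is.finite(C))) || !all(is.finite(y)))
    abort("missing or non-finite values are not supported; remove or impute upstream",
          class = "deconfound_validation_error")
  feature_names <- feature_names %||% colnames(G) %||% paste0("g", seq_len(ncol(G)))
  confound_names <- confound_names %||% colnames(C) %||%
    (if (ncol(C) > 0) paste0("c", seq_len(ncol(C))) else character(0))
  colnames(G) <- feature_names
  if (ncol(C) > 0) colnames(C) <- confound_names
  structure(list(subject_ids = subject_ids, G = G, C = C, y = y,
                 feature_names = feature_names, confound_names = confound_names),
            class = "confound_dataset")
}

#' @export
print.confound_dataset <- function(x, ...) {
  cat(sprintf("<confound_dataset> n = %d subjects, dG = %d features, dC = %d confounds\n",
              nrow(x$G), ncol(x$G), ncol(x$C)))
  cat(sprintf("  y: mean %.3f, sd %.3f, range [%.3f, %.3f]\n",
              mean(x$y), sd(x$y), min(x$y), max(x$y)))
  for (j in seq_len(ncol(x$C))) {
    u <- unique(x$C[, j])
    lab <- if (length(u) == 2) sprintf("two-level {%g, %g}", min(u), max(u)) else "continuous"
    cat(sprintf("  confound %s: %s\n", x$confound_names[j], lab))
  }
  invisible(x)
}

#' @export
dim.confound_dataset <- function(x) c(nrow(x$G), ncol(x$G))

#' Subset a dataset by subject
#'
#' @param x A [confound_dataset()].
#' @param i Integer or logical subject index.
#' @param ... Unused.
#' @return A `confound_dataset` restricted to the selected subjects.
#' @export
`[.confound_dataset` <- function(x, i, ...) {
  confound_dataset(G = x$G[i, , drop = FALSE], y = x$y[i],
                   C = x$C[i, , drop = FALSE], subject_ids = x$subject_ids[i],
                   feature_names = x$feature_names, confound_names = x$confound_names)
}

#' @export
as_tibble.confound_dataset <- function(x, ...) {
  dplyr::bind_cols(
    tibble(subject_id = x$subject_ids, y = x$y),
    as_tibble(x$C, .name_repair = "minimal"),
    as_tibble(x$G, .name_repair = "minimal")
  )
}

#' Build a dataset from a single tidy data frame
#'
#' Interprets one column as the target, an optional set as confounds, and all
#' remaining numeric columns as features.
#'
#' @param data A data frame, one row per subject.
#' @param target Name of the target column.
#' @param confounds Character vector of confound column names (may be empty).
#' @param id_col Name of the subject-identifier column, if present.
#' @return A [confound_dataset()].
#' @export
as_confound_dataset <- function(data, target, confounds = character(0),
                                id_col = "subject_id") {
  data <- as.data.frame(data)
  stopifnot(target %in% names(data), all(confounds %in% names(data)))
  ids <- if (id_col %in% names(data)) as.character(data[[id_col]]) else NULL
  drop <- c(target, confounds, intersect(id_col, names(data)))
  feats <- data[, setdiff(names(data), drop), drop = FALSE]
  C <- if (length(confounds)) as.matrix(data[, confounds, drop = FALSE]) else NULL
  confound_dataset(G = as.matrix(feats), y = data[[target]], C = C,
                   subject_ids = ids, confound_names = confounds)
}

#' Read a dataset from delimited feature and metadata tables
#'
#' The feature table holds one row per subject with a header of feature names;
#' the metadata table holds the subject identifier, target and confound
#' columns. Rows are aligned on the identifier column, following the feature
#' table's order; any mismatch in subject sets is an error.
#'
#' @param features_path Path to the features table (tab- or comma-delimited).
#' @param meta_path Path to the metadata table.
#' @param target Name of the target column in the metadata.
#' @param confounds Character vector of confound column names in the metadata.
#' @param id_col Subject-identifier column name, present in both tables.
#' @return A [confound_dataset()].
#' @export
read_dataset <- function(features_path, meta_path, target,
                         confounds = character(0), id_col = "subject_id") {
  feats <- as.data.frame(readr::read_delim(features_path, show_col_types = FALSE,
                                           progress = FALSE))
  meta <- as.data.frame(readr::read_delim(meta_path, show_col_types = FALSE,
                                          progress = FALSE))
  if (!id_col %in% names(feats) || !id_col %in% names(meta))
    abort(sprintf("identifier column '%s' must be present in both tables", id_col),
          class = "deconfound_alignment_error")
  fid <- as.character(feats[[id_col]])
  mid <- as.character(meta[[id_col]])
  if (!setequal(fid, mid) || anyDuplicated(fid) || anyDuplicated(mid))
    abort(sprintf("subject sets differ between features and metadata (%d vs %d unique ids)",
                  length(unique(fid)), length(unique(mid))),
          class = "deconfound_alignment_error")
  meta <- meta[match(fid, mid), , drop = FALSE]
  G <- as.matrix(feats[, setdiff(names(feats), id_col), drop = FALSE])
  C <- if (length(confounds)) as.matrix(meta[, confounds, drop = FALSE]) else NULL
  confound_dataset(G = G, y = meta[[target]], C = C, subject_ids = fid,
                   confound_names = confounds)
}

#' Write a dataset as delimited feature and metadata tables
#'
#' @param ds A [confound_dataset()].
#' @param dir Output directory (created if absent).
#' @param target Column name used for the target in the metadata table.
#' @return Invisibly, the two file paths written.
#' @export
write_dataset <- function(ds, dir, target = "y") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- file.path(dir, "features.tsv")
  mp <- file.path(dir, "meta.tsv")
  fdf <- data.frame(subject_id = ds$subject_ids, ds$G, check.names = FALSE)
  mdf <- data.frame(subject_id = ds$subject_ids, check.names = FALSE)
  mdf[[target]] <- ds$y
  for (j in seq_len(ncol(ds$C))) mdf[[ds$confound_names[j]]] <- ds$C[, j]
  readr::write_tsv(fdf, fp, progress = FALSE)
  readr::write_tsv(mdf, mp, progress = FALSE)
  invisible(c(features = fp, meta = mp))
}

#' Flatten masked 3-D volumes into a feature matrix
#'
#' Converts per-subject 3-D arrays into rows of a feature matrix by selecting
#' voxels inside a binary mask, in the mask's column-major scan order (the
#' natural array order, so voxel `(i, j, k)` precedes `(i + 1, j, k)`).
#'
#' @param volumes A list of 3-D numeric arrays (one per subject) or a 4-D
#'   array with subjects along the fourth dimension.
#' @param mask A 3-D array of the same spatial shape; voxels with value
#'   `> 0` (or `TRUE`) are retained.
#' @return An `n x sum(mask)` matrix; columns named `vox<linear index>`.
#' @export
flatten_volumes <- function(volumes, mask) {
  if (is.array(volumes) && length(dim(volumes)) == 4)
    volumes <- lapply(seq_len(dim(volumes)[4]), function(i) volumes[, , , i])
  mask <- as.array(mask)
  keep <- which(as.logical(mask != 0))
  G <- t(vapply(volumes, function(v) {
    v <- as.array(v)
    if (!identical(dim(v), dim(mask)))
      abort("volume and mask dimensions differ", class = "deconfound_shape_error")
    as.numeric(v)[keep]
  }, numeric(length(keep))))
  colnames(G) <- paste0("vox", keep)
  G
}

#' Augment a confound matrix with an intercept column
#'
#' Prepends a column of ones to `C`, producing the design matrix used by the
#' feature-adjustment regressions. Re-augmenting an already augmented matrix
#' is rejected unless `allow_augmented = TRUE` (in which case it is a no-op).
#'
#' @param C Numeric confound matrix (`n x dC`, `dC >= 0`).
#' @param allow_augmented If `TRUE`, return `C` unchanged when its first
#'   column is already all ones.
#' @return An `n x (dC + 1)` matrix whose first column is all ones.
#' @export
augment_confounds <- function(C, allow_augmented = FALSE) {
  C <- as.matrix(C)
  if (ncol(C) >= 1 && nrow(C) > 0 && all(C[, 1] == 1)) {
    if (allow_augmented) return(C)
    abort("first column is already an intercept; refusing to augment twice",
          class = "deconfound_validation_error")
  }
  out <- cbind(intercept = rep(1, nrow(C)), C)
  out
}

#' Standardize features using training-set statistics
#'
#' Centres and scales each column to zero mean and unit variance using the
#' mean and sample standard deviation (denominator `n - 1`) of the training
#' rows only, then applies the same transform to an optional second matrix.
#' Constant training columns map to all-zero columns in both outputs so that
#' feature indexing stays stable.
#'
#' @param train Numeric training matrix (rows = subjects).
#' @param other Optional matrix with the same number of columns (e.g. test
#'   features), transformed with the training statistics.
#' @param stats Optional precomputed statistics (as returned in `$stats`);
#'   when supplied, `train` is transformed with them instead.
#' @return A list with `train`, `other` (or `NULL`) and `stats` (a list with
#'   `center` and `scale` vectors; `scale` holds the raw sd, zeros marking
#'   constant columns).
#' @export
standardize_features <- function(train, other = NULL, stats = NULL) {
  train <- as.matrix(train)
  if (is.null(stats)) {
    center <- colMeans(train)
    scale <- apply(train, 2, sd)
    stats <- list(center = center, scale = scale)
  }
  apply_stats <- function(M) {
    if (is.null(M)) return(NULL)
    M <- as.matrix(M)
    if (ncol(M) != length(stats$center))
      abort(sprintf("feature count mismatch: %d vs %d", ncol(M), length(stats$center)),
            class = "deconfound_shape_error")
    s <- ifelse(stats$scale > 0, stats$scale, 1)
    out <- sweep(sweep(M, 2, stats$center, "-"), 2, s, "/")
    out[, stats$scale == 0] <- 0
    out
  }
  list(train = apply_stats(train), other = apply_stats(other), stats = stats)
}

#' Write a prediction table
#'
#' @param predictions Tibble/data frame with columns `subject_id`, `y_true`,
#'   `y_pred` (as produced by the evaluation functions).
#' @param path Output path for the tab-delimited table.
#' @return Invisibly, `path`.
#' @export
write_predictions <- function(predictions, path) {
  readr::write_tsv(as.data.frame(predictions), path, progress = FALSE)
  invisible(path)
}
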