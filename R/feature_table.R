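#' Feature table container
#'
#' A `feature_table` holds a rectangular samples x features grid together
#' with per-feature metadata: the modality the feature came from
#' (`"clinical"` or `"radiomics"`) and its kind (`"categorical"` or
#' `"continuous"`). Categorical cells are stored as character level codes;
#' continuous cells as doubles. Missing cells are `NA`.
#'
#' @param values data.frame of feature columns (samples in rows). Row names
#'   are used as sample ids; if absent, `"s1".."sn"` are assigned.
#' @param meta data.frame with columns `name`, `modality`, `kind` and
#'   optionally `parent` (set by one-hot encoding); one row per feature
#'   column, in column order.
#' @return An object of class `feature_table` with elements `values`,
#'   `meta` and `sample_ids`.
#' @export
feature_table <- function(values, meta) {
  values <- as.data.frame(values, stringsAsFactors = FALSE)
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (is.null(meta$parent)) meta$parent <- NA_character_
  if (!all(c("name", "modality", "kind") %in% names(meta))) {
    stop("meta must have columns name, modality, kind")
  }
  if (nrow(meta) != ncol(values)) {
    stop("meta rows (", nrow(meta), ") must match feature columns (",
         ncol(values), ")")
  }
  if (anyDuplicated(meta$name)) {
    stop("feature names must be unique; duplicated: ",
         paste(unique(meta$name[duplicated(meta$name)]), collapse = ", "))
  }
  if (!all(meta$modality %in% c("clinical", "radiomics"))) {
    stop("modality must be 'clinical' or 'radiomics'")
  }
  if (!all(meta$kind %in% c("categorical", "continuous"))) {
    stop("kind must be 'categorical' or 'continuous'")
  }
  names(values) <- meta$name
  ids <- rownames(values)
  if (is.null(ids) || identical(ids, as.character(seq_len(nrow(values))))) {
    ids <- paste0("s", seq_len(nrow(values)))
  }
  if (anyDuplicated(ids)) stop("sample ids must be unique")
  rownames(values) <- ids
  structure(
    list(values = values, meta = meta, sample_ids = ids),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf(
    "<feature_table> %d samples x %d features (%d clinical, %d radiomics; %d categorical)\n",
    nrow(x$values), ncol(x$values),
    sum(x$meta$modality == "clinical"), sum(x$meta$modality == "radiomics"),
    sum(x$meta$kind == "categorical")
  ))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

is_feature_table <- function(x) inherits(x, "feature_table")

#' Subset a feature table by rows and/or feature names
#'
#' @param ft a [feature_table()]
#' @param rows row indices (default: all)
#' @param features feature names (default: all), kept in the given order
#' @return The subsetted [feature_table()] with aligned metadata.
#' @export
ft_subset <- function(ft, rows = NULL, features = NULL) {
  stopifnot(is_feature_table(ft))
  v <- ft$values
  m <- ft$meta
  if (!is.null(features)) {
    idx <- match(features, m$name)
    if (anyNA(idx)) {
      stop("unknown features: ", paste(features[is.na(idx)], collapse = ", "))
    }
    v <- v[, idx, drop = FALSE]
    m <- m[idx, , drop = FALSE]
  }
  if (!is.null(rows)) v <- v[rows, , drop = FALSE]
  feature_table(v, m)
}

#' Numeric matrix view of an all-continuous feature table
#'
#' @param ft a [feature_table()] whose features are all continuous
#'   (run [one_hot_encode()] first otherwise)
#' @return Numeric matrix (samples x features) suitable as model input.
#' @export
ft_matrix <- function(ft) {
  stopifnot(is_feature_table(ft))
  if (any(ft$meta$kind == "categorical")) {
    stop("table still has categorical features; one_hot_encode() first")
  }
  as.matrix(as.data.frame(lapply(ft$values, as.numeric),
                          row.names = rownames(ft$values),
                          check.names = FALSE))
}

#' Write / read the package's on-disk dataset dialect
#'
#' A dataset is a CSV (features plus a `nihss_group` label column with
#' values A/B/C) and a JSON sidecar carrying per-feature metadata and,
#' when available, the simulation ground truth.
#'
#' @param table a `feature_table`
#' @param labels factor of class labels A/B/C, one per sample
#' @param path CSV output path; the sidecar is written at `<path>.meta.json`
#' @param ground_truth optional list, stored verbatim in the sidecar
#' @return `path`, invisibly.
#' @export
write_dataset <- function(table, labels, path, ground_truth = NULL) {
  stopifnot(is_feature_table(table), length(labels) == nrow(table$values))
  out <- table$values
  out$nihss_group <- as.character(labels)
  df <- cbind(sample_id = table$sample_ids, out)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  side <- list(
    feature_meta = table$meta,
    ground_truth = ground_truth
  )
  jsonlite::write_json(side, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_dataset
#' @return `read_dataset()` returns a list with `table`, `labels` and
#'   `ground_truth`.
#' @export
read_dataset <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        na.strings = "")
  side <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  meta <- as.data.frame(side$feature_meta, stringsAsFactors = FALSE)
  labels <- factor(df$nihss_group, levels = c("A", "B", "C"))
  ids <- df$sample_id
  vals <- df[, meta$name, drop = FALSE]
  for (j in seq_len(ncol(vals))) {
    if (meta$kind[j] == "continuous") vals[[j]] <- as.numeric(vals[[j]])
    else vals[[j]] <- as.character(vals[[j]])
  }
  rownames(vals) <- ids
  list(
    table = feature_table(vals, meta),
    labels = labels,
    ground_truth = side$ground_truth
  )
}
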