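#' Monte Carlo multiple imputation
#'
#' Fills missing cells of a feature table. Continuous cells are imputed
#' with a multiple Monte Carlo estimate of the feature's expectation: the
#' average over `M` repetitions of the mean of `N` draws taken with
#' replacement from the feature's observed values (an empirical-bootstrap
#' mean of means). Categorical cells are imputed with the modal observed
#' category (ties broken by level order). Observed cells are never
#' altered.
#'
#' When `pool` is supplied (a feature table of training rows), observed
#' values are drawn from the pool instead of from `table` itself, so test
#' rows can be imputed without touching their own distribution.
#'
#' @param table a [feature_table()]
#' @param M imputation repetitions (default 5)
#' @param N draws per repetition (default 20)
#' @param seed integer seed
#' @param pool optional [feature_table()] providing the observed-value
#'   pools (defaults to `table`)
#' @return A [feature_table()] without missing cells.
#' @export
impute_monte_carlo <- function(table, M = 5L, N = 20L, seed = 1L,
                               pool = NULL) {
  stopifnot(is_feature_table(table), M >= 1, N >= 1)
  pool <- pool %||% table
  stopifnot(identical(pool$meta$name, table$meta$name))
  vals <- table$values
  with_seed(derive_seed(seed, "impute"), {
    for (j in seq_len(ncol(vals))) {
      x <- vals[[j]]
      miss <- is.na(x)
      if (!any(miss)) next
      obs <- pool$values[[j]]
      obs <- obs[!is.na(obs)]
      if (length(obs) == 0L) {
        stop("feature '", table$meta$name[j], "' has no observed values")
      }
      if (table$meta$kind[j] == "continuous") {
        for (i in which(miss)) {
          reps <- vapply(seq_len(M), function(m) {
            mean(sample(obs, N, replace = TRUE))
          }, numeric(1))
          x[i] <- mean(reps)
        }
      } else {
        tab <- table(factor(obs, levels = unique(obs)))
        x[miss] <- names(tab)[which.max(tab)]
      }
      vals[[j]] <- x
    }
    feature_table(vals, table$meta)
  })
}

#' Variance filtering of continuous features
#'
#' Retains continuous features whose population variance (divide-by-n)
#' exceeds `threshold`, computed on raw, pre-standardization values.
#' Categorical features are retained unconditionally. Column order is
#' preserved.
#'
#' @param table a [feature_table()]
#' @param threshold nonnegative variance threshold (default 0.3)
#' @param rows optional row subset (e.g. training rows) on which variances
#'   are computed
#' @return Filtered [feature_table()]; the retained/dropped names are
#'   attached as attributes `kept` and `dropped`.
#' @export
variance_filter <- function(table, threshold = 0.3, rows = NULL) {
  stopifnot(is_feature_table(table))
  if (!is.numeric(threshold) || threshold < 0) {
    stop("threshold must be a nonnegative number")
  }
  vals <- if (is.null(rows)) table$values else table$values[rows, , drop = FALSE]
  keep <- vapply(seq_len(ncol(vals)), function(j) {
    if (table$meta$kind[j] == "categorical") return(TRUE)
    v <- pop_var(as.numeric(vals[[j]]))
    !is.na(v) && v > threshold
  }, logical(1))
  out <- ft_subset(table, features = table$meta$name[keep])
  attr(out, "kept") <- table$meta$name[keep]
  attr(out, "dropped") <- table$meta$name[!keep]
  out
}

#' One-hot encoding of categorical features
#'
#' Expands each categorical feature with n levels into n indicator
#' columns (`feature=level`), a full partition of unity with no reference
#' level dropped. Continuous features pass through unchanged, in place.
#' Level sets default to those observed in `table`; pass the `levels`
#' attribute of an encoded training table to reuse training-time levels,
#' in which case an unseen level raises an error.
#'
#' @param table a [feature_table()]
#' @param levels optional named list mapping categorical feature names to
#'   level vectors (training-time level sets)
#' @return A [feature_table()] of continuous/indicator columns; the level
#'   map is attached as attribute `levels` and indicator metadata records
#'   the parent feature.
#' @export
one_hot_encode <- function(table, levels = NULL) {
  stopifnot(is_feature_table(table))
  cat_idx <- which(table$meta$kind == "categorical")
  if (length(cat_idx) == 0L) {
    attr(table, "levels") <- list()
    return(table)
  }
  lvmap <- levels %||% lapply(cat_idx, function(j) {
    sort(unique(as.character(table$values[[j]])))
  })
  if (is.null(levels)) names(lvmap) <- table$meta$name[cat_idx]

  out_cols <- list()
  out_meta <- list()
  for (j in seq_len(ncol(table$values))) {
    nm <- table$meta$name[j]
    if (table$meta$kind[j] == "continuous") {
      out_cols[[length(out_cols) + 1L]] <- as.numeric(table$values[[j]])
      out_meta[[length(out_meta) + 1L]] <-
        data.frame(name = nm, modality = table$meta$modality[j],
                   kind = "continuous", parent = NA_character_,
                   stringsAsFactors = FALSE)
    } else {
      lv <- lvmap[[nm]]
      if (is.null(lv)) stop("no level set known for feature '", nm, "'")
      x <- as.character(table$values[[j]])
      bad <- setdiff(unique(x[!is.na(x)]), lv)
      if (length(bad)) {
        stop("unseen level '", bad[1], "' in feature '", nm, "'")
      }
      for (l in lv) {
        out_cols[[length(out_cols) + 1L]] <- as.numeric(x == l)
        out_meta[[length(out_meta) + 1L]] <-
          data.frame(name = paste0(nm, "=", l),
                     modality = table$meta$modality[j],
                     kind = "continuous", parent = nm,
                     stringsAsFactors = FALSE)
      }
    }
  }
  meta <- do.call(rbind, out_meta)
  df <- as.data.frame(out_cols, col.names = meta$name, check.names = FALSE)
  names(df) <- meta$name
  rownames(df) <- table$sample_ids
  out <- feature_table(df, meta)
  attr(out, "levels") <- lvmap
  out
}

#' Z-score standardization fitted on training rows
#'
#' `fit_standardizer()` computes per-feature mean and population SD on the
#' given training rows; `apply_standardizer()` maps each continuous,
#' non-indicator feature x to (x - mu) / sigma using those training
#' moments, so test rows never contribute to the fit. Indicator columns
#' produced by [one_hot_encode()] are left on their 0/1 scale.
#'
#' @param table a fully numeric [feature_table()]
#' @param rows training row indices (default: all rows)
#' @return `fit_standardizer()` returns a `standardizer` object (features,
#'   mu, sigma); `apply_standardizer()` returns the transformed table.
#' @export
fit_standardizer <- function(table, rows = NULL) {
  stopifnot(is_feature_table(table))
  if (any(table$meta$kind == "categorical")) {
    stop("one_hot_encode() categorical features before standardizing")
  }
  rows <- rows %||% seq_len(nrow(table$values))
  std_feats <- table$meta$name[is.na(table$meta$parent)]
  mu <- numeric(length(std_feats))
  sigma <- numeric(length(std_feats))
  for (k in seq_along(std_feats)) {
    x <- as.numeric(table$values[rows, std_feats[k]])
    if (anyNA(x)) stop("impute before standardizing: ", std_feats[k])
    mu[k] <- mean(x)
    sigma[k] <- pop_sd(x)
    if (sigma[k] <= 0) {
      stop("feature '", std_feats[k],
           "' has zero variance on training rows; run variance_filter() first")
    }
  }
  structure(list(features = std_feats, mu = mu, sigma = sigma),
            class = "standardizer")
}

#' @rdname fit_standardizer
#' @param params a `standardizer` from `fit_standardizer()`
#' @export
apply_standardizer <- function(params, table) {
  stopifnot(inherits(params, "standardizer"), is_feature_table(table))
  vals <- table$values
  idx <- match(params$features, table$meta$name)
  if (anyNA(idx)) {
    stop("table lacks features: ",
         paste(params$features[is.na(idx)], collapse = ", "))
  }
  for (k in seq_along(idx)) {
    vals[[idx[k]]] <- (as.numeric(vals[[idx[k]]]) - params$mu[k]) / params$sigma[k]
  }
  out <- feature_table(vals, table$meta)
  attr(out, "levels") <- attr(table, "levels")
  out
}

#' Serialize / restore a standardizer
#' @param params a `standardizer`
#' @param path JSON file path
#' @return `read_standardizer()` returns the restored `standardizer`.
#' @export
write_standardizer <- function(params, path) {
  stopifnot(inherits(params, "standardizer"))
  jsonlite::write_json(unclass(params), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_standardizer
#' @export
read_standardizer <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(features = obj$features, mu = obj$mu, sigma = obj$sigma),
            class = "standardizer")
}

#' Label-percentage stratified train/test split
#'
#' Splits sample indices so that each class contributes
#' round-half-up(`train_frac` * class size) training samples — the
#' largest-remainder allocation between the train and test shares within
#' each class. Sampling within classes is seed-deterministic.
#'
#' @param labels factor of class labels
#' @param train_frac training fraction, strictly inside (0, 1)
#' @param seed integer seed
#' @return list with integer vectors `train` and `test` (disjoint,
#'   exhaustive, sorted).
#' @export
stratified_split <- function(labels, train_frac = 0.7, seed = 1L) {
  labels <- as.factor(labels)
  if (!is.numeric(train_frac) || train_frac <= 0 || train_frac >= 1) {
    stop("train_frac must lie strictly in (0, 1)")
  }
  counts <- table(labels)
  if (any(counts < 2)) {
    stop("class ", names(counts)[which(counts < 2)[1]],
         " has fewer than 2 members")
  }
  train <- integer(0)
  with_seed(derive_seed(seed, "split"), {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      n_tr <- floor(train_frac * length(idx) + 0.5)  # round half up
      n_tr <- max(1L, min(length(idx) - 1L, n_tr))
      train <- c(train, sample(idx, n_tr))
    }
  })
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}
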