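# Resampling methods for imbalanced three-class training data. All
# operate on a numeric matrix X (rows = samples, typically the
# standardized one-hot representation) and a factor y, and return a
# `resample_result`: list(X, y, counts_before, counts_after, provenance)
# where provenance marks each surviving row "original" or "synthetic" and
# records the rows ENN removed.

.resample_result <- function(X, y, counts_before, provenance, removed = character(0)) {
  y <- droplevels_keep(y)
  structure(
    list(X = X, y = y,
         counts_before = counts_before,
         counts_after = table(y),
         provenance = provenance,
         removed = removed),
    class = "resample_result"
  )
}

droplevels_keep <- function(y) factor(y, levels = levels(y))

#' @export
print.resample_result <- function(x, ...) {
  cat("<resample_result> counts before:",
      paste(sprintf("%s=%d", names(x$counts_before), x$counts_before),
            collapse = " "),
      "-> after:",
      paste(sprintf("%s=%d", names(x$counts_after), x$counts_after),
            collapse = " "), "\n")
  invisible(x)
}

.check_Xy <- function(X, y) {
  X <- as.matrix(X)
  y <- as.factor(y)
  stopifnot(nrow(X) == length(y), is.numeric(X))
  counts <- table(y)
  if (any(counts == 0)) {
    stop("empty class: ", names(counts)[counts == 0][1])
  }
  list(X = X, y = y, counts = counts)
}

#' Random oversampling to the majority count
#'
#' Duplicates minority-class rows (with replacement, seeded) until every
#' class matches the majority class count. Original rows are untouched.
#'
#' @param X numeric matrix of training rows
#' @param y class factor
#' @param seed integer seed
#' @return A `resample_result`.
#' @export
random_oversample <- function(X, y, seed = 1L) {
  d <- .check_Xy(X, y)
  n_max <- max(d$counts)
  extra_idx <- integer(0)
  with_seed(derive_seed(seed, "ros"), {
    for (cl in names(d$counts)) {
      need <- n_max - d$counts[[cl]]
      if (need > 0) {
        idx <- which(d$y == cl)
        extra_idx <- c(extra_idx, sample(idx, need, replace = TRUE))
      }
    }
  })
  X2 <- rbind(d$X, d$X[extra_idx, , drop = FALSE])
  y2 <- factor(c(as.character(d$y), as.character(d$y[extra_idx])),
               levels = levels(d$y))
  prov <- c(rep("original", nrow(d$X)), rep("synthetic", length(extra_idx)))
  .resample_result(X2, y2, d$counts, prov)
}

#' Random undersampling to the minority count
#'
#' Removes majority-class rows (without replacement, seeded) until every
#' class matches the minority class count.
#'
#' @inheritParams random_oversample
#' @return A `resample_result`.
#' @export
random_undersample <- function(X, y, seed = 1L) {
  d <- .check_Xy(X, y)
  n_min <- min(d$counts)
  keep <- integer(0)
  with_seed(derive_seed(seed, "rus"), {
    for (cl in names(d$counts)) {
      idx <- which(d$y == cl)
      keep <- c(keep, if (length(idx) > n_min) sample(idx, n_min) else idx)
    }
  })
  keep <- sort(keep)
  .resample_result(d$X[keep, , drop = FALSE], d$y[keep], d$counts,
                   rep("original", length(keep)))
}

# k nearest neighbours of row i within candidate rows `pool` (Euclidean,
# self excluded, distance ties broken by row index).
.knn_idx <- function(X, i, pool, k) {
  pool <- pool[pool != i]
  dx <- sqrt(colSums((t(X[pool, , drop = FALSE]) - X[i, ])^2))
  pool[order(dx, pool)][seq_len(min(k, length(pool)))]
}

#' SMOTE oversampling
#'
#' Synthesizes minority-class points by convex interpolation: a random
#' same-class base point p, one of its k same-class nearest neighbours q
#' (Euclidean), and u ~ Uniform(0,1) give p + u (q - p). Class counts are
#' equalized to the majority count. For classes with fewer than k + 1
#' members, k is lowered to size - 1 (recorded in attribute
#' `k_effective`).
#'
#' @inheritParams random_oversample
#' @param k neighbour count (default 5)
#' @return A `resample_result`.
#' @export
smote <- function(X, y, k = 5L, seed = 1L) {
  d <- .check_Xy(X, y)
  if (any(d$counts == 1)) {
    stop("class of size 1 cannot be interpolated: ",
         names(d$counts)[d$counts == 1][1])
  }
  n_max <- max(d$counts)
  new_rows <- list()
  new_y <- character(0)
  k_eff <- stats::setNames(rep(NA_integer_, length(d$counts)), names(d$counts))
  with_seed(derive_seed(seed, "smote"), {
    for (cl in names(d$counts)) {
      need <- n_max - d$counts[[cl]]
      if (need == 0) next
      idx <- which(d$y == cl)
      kc <- min(k, length(idx) - 1L)
      k_eff[cl] <- kc
      for (s in seq_len(need)) {
        i <- idx[sample.int(length(idx), 1L)]
        nb <- .knn_idx(d$X, i, idx, kc)
        q <- nb[sample.int(length(nb), 1L)]
        u <- stats::runif(1)
        new_rows[[length(new_rows) + 1L]] <-
          d$X[i, ] + u * (d$X[q, ] - d$X[i, ])
        new_y <- c(new_y, cl)
      }
    }
  })
  X2 <- rbind(d$X, do.call(rbind, new_rows))
  rownames(X2) <- NULL
  y2 <- factor(c(as.character(d$y), new_y), levels = levels(d$y))
  prov <- c(rep("original", nrow(d$X)), rep("synthetic", length(new_y)))
  out <- .resample_result(X2, y2, d$counts, prov)
  attr(out, "k_effective") <- k_eff
  out
}

#' Edited nearest neighbours (ENN) cleaning
#'
#' Removes every sample whose class disagrees with the majority vote of
#' its k nearest neighbours (self excluded), with votes computed once on
#' the full input set. Vote ties and distance ties are broken by class
#' level order and row index respectively, so the edit is deterministic.
#'
#' @inheritParams random_oversample
#' @param k neighbour count (default 3)
#' @return A `resample_result`; removed row indices (w.r.t. the input)
#'   are in `$removed`.
#' @export
enn <- function(X, y, k = 3L) {
  d <- .check_Xy(X, y)
  n <- nrow(d$X)
  if (n <= k) stop("need more than k samples for ENN")
  all_idx <- seq_len(n)
  bad <- logical(n)
  for (i in all_idx) {
    nb <- .knn_idx(d$X, i, all_idx, k)
    votes <- table(factor(d$y[nb], levels = levels(d$y)))
    win <- names(votes)[which.max(votes)]  # tie -> first class level
    bad[i] <- !identical(win, as.character(d$y[i]))
  }
  keep <- which(!bad)
  .resample_result(d$X[keep, , drop = FALSE], d$y[keep], d$counts,
                   rep("original", length(keep)), removed = which(bad))
}

#' Hybrid SMOTE + ENN balancing
#'
#' Runs [smote()] to equalize class counts, then a single [enn()] pass on
#' the post-SMOTE set to prune points that fall inside other-class
#' neighbourhoods. Provenance is composed: surviving rows keep their
#' original/synthetic tag.
#'
#' @inheritParams random_oversample
#' @param k_smote SMOTE neighbour count (default 5)
#' @param k_enn ENN neighbour count (default 3)
#' @return A `resample_result`.
#' @export
smoteenn <- function(X, y, k_smote = 5L, k_enn = 3L, seed = 1L) {
  sm <- smote(X, y, k = k_smote, seed = seed)
  cleaned <- enn(sm$X, sm$y, k = k_enn)
  keep <- setdiff(seq_len(nrow(sm$X)), cleaned$removed)
  out <- .resample_result(sm$X[keep, , drop = FALSE], sm$y[keep],
                          table(as.factor(y)),
                          sm$provenance[keep], removed = cleaned$removed)
  attr(out, "counts_after_smote") <- sm$counts_after
  out
}
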