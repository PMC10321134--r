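# Stacked generalization over the three deep base learners, plus
# hard/soft voting baselines. Meta-features are out-of-fold class
# probabilities; the meta-learner is a seed-fixed random forest.

# A base "family" is normally a learner_spec, but any object of class
# `custom_learner` (a list with fit(X, y, seed) and predict(model, X)
# closures) plugs into the same slots — used for oracle checks and for
# mixing in non-neural baselines.
.fit_family <- function(spec, X, y, seed) {
  if (inherits(spec, "learner_spec")) fit_learner(spec, X, y, seed = seed)
  else if (inherits(spec, "custom_learner")) spec$fit(X, y, seed)
  else stop("base family must be a learner_spec or custom_learner")
}

.predict_family <- function(spec, model, X) {
  if (inherits(spec, "learner_spec")) predict_proba(model, X)
  else spec$predict(model, X)
}

#' Wrap fit/predict closures as a stacking base family
#'
#' @param fit function(X, y, seed) returning an arbitrary model object
#' @param predict function(model, X) returning a row-stochastic
#'   probability matrix with class columns
#' @return A `custom_learner` usable in [stacking_fit()] family lists.
#' @export
custom_learner <- function(fit, predict) {
  structure(list(fit = fit, predict = predict), class = "custom_learner")
}

# Stratified fold assignment: within each class, samples are dealt to
# folds in seeded random order, so per-fold class proportions differ by
# at most one sample.
stratified_folds <- function(y, T_folds, seed) {
  y <- as.factor(y)
  fold <- integer(length(y))
  with_seed(derive_seed(seed, "folds"), {
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep(seq_len(T_folds), length.out = length(idx))
    }
  })
  fold
}

#' Fit a stacking ensemble with out-of-fold meta-features
#'
#' For each base-learner family, every training sample receives class
#' probabilities from a model trained with that sample's fold held out;
#' the concatenated probability blocks (3 classes x number of families)
#' form the meta-feature matrix on which a random-forest meta-learner is
#' fit. Each family is then refit on the full training set for test-time
#' inference.
#'
#' @param specs named list of [learner_spec()] objects (typically
#'   `dnn`, `lstm_rnn`, `dbn`)
#' @param X numeric training matrix
#' @param y 3-class factor
#' @param T_folds number of stratified folds (default 5; must not exceed
#'   the smallest class count)
#' @param seed integer seed
#' @param ntree meta-forest size (default 100)
#' @return A `stack_model` with per-family refit learners, the
#'   meta-forest, the fold map and the meta-feature matrix.
#' @export
stacking_fit <- function(specs, X, y, T_folds = 5L, seed = 1L, ntree = 100L) {
  stopifnot(is.list(specs), length(specs) >= 1)
  X <- as.matrix(X)
  y <- as.factor(y)
  if (T_folds < 2) stop("T_folds must be at least 2 (no held-out fold otherwise)")
  counts <- table(y)
  if (any(counts < T_folds)) {
    stop("class ", names(counts)[counts < T_folds][1],
         " has fewer members (", min(counts), ") than T_folds = ", T_folds)
  }
  if (is.null(names(specs))) {
    names(specs) <- vapply(seq_along(specs), function(i) {
      if (inherits(specs[[i]], "learner_spec")) specs[[i]]$family
      else paste0("custom", i)
    }, character(1))
  }
  fold <- stratified_folds(y, T_folds, seed)
  K <- nlevels(y)
  meta <- matrix(NA_real_, nrow(X), K * length(specs))
  colnames(meta) <- as.vector(outer(levels(y), names(specs),
                                    function(c, f) paste0(f, ".", c)))
  for (fi in seq_along(specs)) {
    cols <- (fi - 1L) * K + seq_len(K)
    for (t in seq_len(T_folds)) {
      hold <- fold == t
      m <- .fit_family(specs[[fi]], X[!hold, , drop = FALSE], y[!hold],
                       seed = derive_seed(seed, paste0("fold", fi, "_", t)))
      meta[hold, cols] <- .predict_family(specs[[fi]], m,
                                          X[hold, , drop = FALSE])
    }
  }
  base <- lapply(seq_along(specs), function(fi) {
    .fit_family(specs[[fi]], X, y,
                seed = derive_seed(seed, paste0("refit", fi)))
  })
  names(base) <- names(specs)
  forest <- with_seed(derive_seed(seed, "meta_rf"), {
    randomForest::randomForest(x = meta, y = y, ntree = ntree)
  })
  structure(
    list(specs = specs, base = base, forest = forest, fold = fold,
         meta_features = meta, classes = levels(y), T_folds = T_folds,
         seed = seed),
    class = "stack_model"
  )
}

#' @export
print.stack_model <- function(x, ...) {
  cat(sprintf("<stack_model> %d base families (%s), %d folds, meta width %d\n",
              length(x$base), paste(names(x$base), collapse = ", "),
              x$T_folds, ncol(x$meta_features)))
  invisible(x)
}

#' Predict from a stacking ensemble
#'
#' Base families (refit on the full training set) score the new rows;
#' their concatenated class probabilities feed the meta-forest.
#'
#' @param model a `stack_model`
#' @param X numeric matrix
#' @return list with `labels` (factor) and `probs` (row-stochastic
#'   matrix).
#' @export
stacking_predict <- function(model, X) {
  stopifnot(inherits(model, "stack_model"))
  X <- as.matrix(X)
  meta <- do.call(cbind, lapply(seq_along(model$base), function(fi) {
    .predict_family(model$specs[[fi]], model$base[[fi]], X)
  }))
  colnames(meta) <- colnames(model$meta_features)
  probs <- stats::predict(model$forest, meta, type = "prob")
  labels <- factor(model$classes[max.col(probs, ties.method = "first")],
                   levels = model$classes)
  list(labels = labels, probs = probs)
}

#' Hard (majority) voting over per-family label predictions
#'
#' @param votes list of factors (one per family, equal length); all must
#'   share the same level set
#' @return Factor of modal labels, ties broken by class level order.
#' @export
hard_vote <- function(votes) {
  stopifnot(is.list(votes), length(votes) >= 1)
  lev <- levels(as.factor(votes[[1]]))
  M <- vapply(votes, as.character, character(length(votes[[1]])))
  if (is.null(dim(M))) M <- matrix(M, nrow = 1)
  out <- apply(M, 1, function(r) {
    tab <- table(factor(r, levels = lev))
    names(tab)[which.max(tab)]   # which.max -> first maximum -> class order
  })
  factor(out, levels = lev)
}

#' Soft voting over per-family class probabilities
#'
#' @param probs list of row-stochastic matrices with identical shapes and
#'   column order
#' @return Factor of argmax labels of the arithmetic-mean probabilities,
#'   ties broken by class column order.
#' @export
soft_vote <- function(probs) {
  stopifnot(is.list(probs), length(probs) >= 1)
  avg <- Reduce(`+`, lapply(probs, as.matrix)) / length(probs)
  lev <- colnames(probs[[1]])
  factor(lev[max.col(avg, ties.method = "first")], levels = lev)
}
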