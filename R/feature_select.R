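#' Gradient-boosting feature importance ranking
#'
#' Scores every feature with one of two embedded gradient-boosting
#' conventions:
#' \describe{
#'   \item{`leafwise_gain`}{a leaf-wise (best-leaf-first) boosted tree
#'     ensemble, scored by total split gain;}
#'   \item{`secondorder_weight`}{a depth-wise second-order boosted tree
#'     ensemble, scored by split count ("weight" — how often a feature is
#'     selected).}
#' }
#' Both run a multiclass softprob objective on a single thread so results
#' are deterministic given the seed. Features never used in a split score
#' 0 and rank after all used features (ties broken by column order).
#'
#' @param table a fully numeric [feature_table()]
#' @param labels 3-class factor
#' @param method `"leafwise_gain"` or `"secondorder_weight"`
#' @param nrounds boosting rounds (default 60)
#' @param seed integer seed
#' @return An `importance_ranking`: list with `method`, `scores` (named,
#'   nonnegative) and `ranking` (feature names, best first).
#' @export
rank_importance <- function(table, labels,
                            method = c("leafwise_gain", "secondorder_weight"),
                            nrounds = 60L, seed = 1L) {
  method <- match.arg(method)
  stopifnot(is_feature_table(table))
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2) {
    stop("labels must contain at least two classes")
  }
  X <- ft_matrix(table)
  if (anyNA(X)) stop("impute missing values before ranking importance")
  y <- as.integer(droplevels(labels)) - 1L
  nclass <- length(unique(y))

  params <- list(
    objective = "multi:softprob",
    num_class = nclass,
    eta = 0.1,
    nthread = 1,
    subsample = 1,
    colsample_bytree = 1
  )
  if (method == "leafwise_gain") {
    params$tree_method <- "hist"
    params$grow_policy <- "lossguide"
    params$max_depth <- 0
    params$max_leaves <- 31
  } else {
    params$max_depth <- 6
  }
  dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
  booster <- with_seed(derive_seed(seed, method), {
    xgboost::xgb.train(params = params, data = dtrain, nrounds = nrounds,
                       verbose = 0)
  })
  imp <- xgboost::xgb.importance(model = booster)
  scores <- stats::setNames(rep(0, ncol(X)), colnames(X))
  if (nrow(imp)) {
    col <- if (method == "leafwise_gain") imp$Gain else imp$Frequency
    scores[imp$Feature] <- col
  }
  ranking <- names(scores)[order(-scores, seq_along(scores))]
  structure(list(method = method, scores = scores, ranking = ranking),
            class = "importance_ranking")
}

#' @export
print.importance_ranking <- function(x, ...) {
  cat(sprintf("<importance_ranking> %s over %d features; top: %s\n",
              x$method, length(x$scores),
              paste(utils::head(x$ranking, 5), collapse = ", ")))
  invisible(x)
}

#' Union-of-top-k feature selection from two rankings
#'
#' Combines two importance rankings over the same feature set into
#' `(top-k_pool(A) intersect top-k_pool(B)) union top-k_head(A) union
#' top-k_head(B)`: features strongly supported by both scorers, plus the
#' very best of each. Output order is by ascending mean rank across the
#' two scorers.
#'
#' @param rankA,rankB `importance_ranking` objects over identical feature
#'   sets
#' @param k_pool depth of the agreement pool (default 50)
#' @param k_head depth of the per-method head (default 10)
#' @return A `selection_result`: list with `selected` (ordered names),
#'   `provenance` (named character: `in_both_top50`, `top10_methodA`,
#'   `top10_methodB`) and `dropped_pairs` (empty here; filled by
#'   [prune_correlated()]).
#' @export
select_union_topk <- function(rankA, rankB, k_pool = 50L, k_head = 10L) {
  stopifnot(inherits(rankA, "importance_ranking"),
            inherits(rankB, "importance_ranking"))
  if (!setequal(rankA$ranking, rankB$ranking)) {
    stop("rankings cover different feature sets")
  }
  if (k_head > k_pool) stop("k_head must not exceed k_pool")
  k_pool <- min(k_pool, length(rankA$ranking))
  k_head <- min(k_head, k_pool)
  topA <- rankA$ranking[seq_len(k_pool)]
  topB <- rankB$ranking[seq_len(k_pool)]
  headA <- rankA$ranking[seq_len(k_head)]
  headB <- rankB$ranking[seq_len(k_head)]
  both <- intersect(topA, topB)
  sel <- union(both, union(headA, headB))

  prov <- vapply(sel, function(f) {
    if (f %in% both) "in_both_top50"
    else if (f %in% headA) "top10_methodA"
    else "top10_methodB"
  }, character(1))

  rkA <- match(sel, rankA$ranking)
  rkB <- match(sel, rankB$ranking)
  ord <- order((rkA + rkB) / 2, sel)
  structure(
    list(selected = sel[ord], provenance = prov[ord],
         dropped_pairs = data.frame(kept = character(0),
                                    dropped = character(0),
                                    r = numeric(0))),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d features selected", length(x$selected)))
  if (nrow(x$dropped_pairs)) {
    cat(sprintf("; %d dropped by correlation", nrow(x$dropped_pairs)))
  }
  cat("\n")
  invisible(x)
}

#' Greedy Pearson correlation pruning
#'
#' Scans candidate features in descending importance and drops any
#' candidate whose absolute Pearson correlation with an already-kept
#' feature exceeds `threshold`, so no kept pair is more correlated than
#' the threshold. The default keeps the higher-importance member of a
#' correlated pair deterministically; `keep = "random"` instead keeps a
#' seeded random member (candidates are scanned in seeded random order).
#'
#' @param table a fully numeric [feature_table()] (Pearson r is
#'   scale-invariant, so raw or standardized values give identical prunes)
#' @param candidates candidate feature names, subset of the table
#' @param threshold absolute-correlation threshold (default 0.9)
#' @param ranking an `importance_ranking`, or a character vector of
#'   feature names in descending importance, used to order candidates
#' @param keep `"importance"` (default) or `"random"`
#' @param seed seed for `keep = "random"`
#' @return A `selection_result` with the kept features (descending
#'   importance) and the dropped pairs with their r values.
#' @export
prune_correlated <- function(table, candidates, threshold = 0.9,
                             ranking = NULL, keep = c("importance", "random"),
                             seed = 1L) {
  keep <- match.arg(keep)
  stopifnot(is_feature_table(table))
  if (!all(candidates %in% table$meta$name)) {
    stop("candidates not in table: ",
         paste(setdiff(candidates, table$meta$name), collapse = ", "))
  }
  X <- ft_matrix(ft_subset(table, features = candidates))
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant column(s) ", paste(candidates[sds == 0], collapse = ", "),
         "; run variance_filter() first")
  }
  ord <- if (keep == "importance") {
    if (is.null(ranking)) stop("ranking required for keep = 'importance'")
    rk <- if (is.character(ranking)) ranking else ranking$ranking
    candidates[order(match(candidates, rk))]
  } else {
    with_seed(derive_seed(seed, "prune"), sample(candidates))
  }
  cm <- stats::cor(X)
  kept <- character(0)
  dropped <- list()
  for (f in ord) {
    if (length(kept)) {
      r <- cm[f, kept]
      hit <- which(abs(r) > threshold)
      if (length(hit)) {
        dropped[[length(dropped) + 1L]] <-
          data.frame(kept = kept[hit[1]], dropped = f, r = unname(r[hit[1]]),
                     stringsAsFactors = FALSE)
        next
      }
    }
    kept <- c(kept, f)
  }
  structure(
    list(selected = kept,
         provenance = stats::setNames(rep("kept", length(kept)), kept),
         dropped_pairs = if (length(dropped)) do.call(rbind, dropped)
                         else data.frame(kept = character(0),
                                         dropped = character(0),
                                         r = numeric(0))),
    class = "selection_result"
  )
}

#' Fuse clinical and radiomics feature tables
#'
#' Column-wise concatenation of two tables over the same samples, aligned
#' by sample id (row order of the first input wins). Modality metadata is
#' preserved so downstream stages can still distinguish the blocks.
#'
#' @param clinical,radiomics [feature_table()] objects with identical
#'   sample id sets and disjoint feature names
#' @return The fused [feature_table()].
#' @export
fuse_features <- function(clinical, radiomics) {
  stopifnot(is_feature_table(clinical), is_feature_table(radiomics))
  if (!setequal(clinical$sample_ids, radiomics$sample_ids)) {
    off <- c(setdiff(clinical$sample_ids, radiomics$sample_ids),
             setdiff(radiomics$sample_ids, clinical$sample_ids))
    stop("sample id mismatch: ", paste(off, collapse = ", "))
  }
  dup <- intersect(clinical$meta$name, radiomics$meta$name)
  if (length(dup)) {
    stop("duplicate feature names across inputs: ",
         paste(dup, collapse = ", "))
  }
  rad_aligned <- radiomics$values[match(clinical$sample_ids,
                                        radiomics$sample_ids), , drop = FALSE]
  df <- cbind(clinical$values, rad_aligned)
  rownames(df) <- clinical$sample_ids
  feature_table(df, rbind(clinical$meta, radiomics$meta))
}

#' Serialize a selection result to JSON
#' @param sel a `selection_result`
#' @param path output path
#' @export
write_selection <- function(sel, path) {
  stopifnot(inherits(sel, "selection_result"))
  jsonlite::write_json(
    list(selected = sel$selected,
         provenance = as.list(sel$provenance),
         dropped_pairs = sel$dropped_pairs),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
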