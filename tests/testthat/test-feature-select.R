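fake_ranking <- function(names_ordered, method = "leafwise_gain") {
  scores <- stats::setNames(rev(seq_along(names_ordered)), names_ordered)
  structure(list(method = method, scores = scores, ranking = names_ordered),
            class = "importance_ranking")
}

test_that("both boosters rank a single separating feature first", {
  set.seed(11)
  n <- 400
  X <- matrix(rnorm(n * 100), n, 100)
  y <- factor(rep(c("A", "B", "C"), length.out = n))
  X[, 1] <- X[, 1] + (as.integer(y) - 2) * 2   # effect 2 SD
  tab <- ft_from_matrix(X)

  # univariate AUC oracle: feature 1 is the only one separating any pair
  auc_ab <- vapply(1:100, function(j) {
    mw_auc(X[y == "A", j], X[y == "B", j])
  }, numeric(1))
  expect_gt(abs(auc_ab[1] - 0.5), 0.3)
  expect_true(all(abs(auc_ab[-1] - 0.5) < 0.2))

  for (m in c("leafwise_gain", "secondorder_weight")) {
    rk <- rank_importance(tab, y, m, seed = 2)
    expect_equal(rk$ranking[1], "f1")
    expect_true(all(rk$scores >= 0))
    expect_setequal(rk$ranking, tab$meta$name)
    # determinism
    rk2 <- rank_importance(tab, y, m, seed = 2)
    expect_identical(rk$scores, rk2$scores)
  }
  expect_error(rank_importance(tab, factor(rep("A", n))), "two classes")
})

test_that("noise features never dominate and duplicates share the top", {
  set.seed(12)
  n <- 200
  X <- matrix(rnorm(n * 30), n, 30)
  y <- factor(rep(c("A", "B", "C"), length.out = n))
  tab <- ft_from_matrix(X)
  rk <- rank_importance(tab, y, "leafwise_gain", seed = 1)
  # all-noise: observed scores comparable to label-permutation scores
  perm_max <- vapply(1:5, function(s) {
    set.seed(100 + s)
    max(rank_importance(tab, sample(y), "leafwise_gain", seed = s)$scores)
  }, numeric(1))
  expect_lt(max(rk$scores), max(perm_max) * 3)

  # duplicated informative feature: the pair outranks all noise jointly
  Xd <- X
  Xd[, 1] <- Xd[, 1] + (as.integer(y) - 2) * 2
  Xd[, 2] <- Xd[, 1]
  tabd <- ft_from_matrix(Xd)
  for (m in c("leafwise_gain", "secondorder_weight")) {
    rkd <- rank_importance(tabd, y, m, seed = 1)
    expect_gt(rkd$scores["f1"] + rkd$scores["f2"], max(rkd$scores[-(1:2)]))
  }
})

test_that("union-of-top-k follows its set algebra", {
  feats <- sprintf("g%02d", 1:60)
  # identical rankings: intersection dominates -> exactly top k_pool
  rA <- fake_ranking(feats)
  sel <- select_union_topk(rA, rA, k_pool = 50, k_head = 10)
  expect_setequal(sel$selected, feats[1:50])
  expect_true(all(sel$provenance == "in_both_top50"))

  # disjoint top-50 lists (padded so rankings share the feature set):
  # result is the two top-10 heads, 20 features
  all_feats <- c(sprintf("a%02d", 1:50), sprintf("b%02d", 1:50))
  rA <- fake_ranking(all_feats)
  rB <- fake_ranking(c(rev(tail(all_feats, 50)), rev(head(all_feats, 50))))
  sel <- select_union_topk(rA, rB, k_pool = 50, k_head = 10)
  expect_setequal(sel$selected,
                  c(sprintf("a%02d", 1:10), sprintf("b%02d", 50:41)))
  expect_length(sel$selected, 20)

  # hand-enumerated toy: A ranks g01..g60, B shifts the top 15 to the
  # back; expected = intersection of top-50s plus both heads
  shifted <- c(feats[16:60], feats[1:15])
  rB <- fake_ranking(shifted)
  sel <- select_union_topk(fake_ranking(feats), rB, k_pool = 50, k_head = 10)
  inter <- intersect(feats[1:50], shifted[1:50])
  expected <- union(inter, union(feats[1:10], shifted[1:10]))
  expect_setequal(sel$selected, expected)

  # symmetry up to provenance
  s1 <- select_union_topk(fake_ranking(feats), rB)
  s2 <- select_union_topk(rB, fake_ranking(feats))
  expect_setequal(s1$selected, s2$selected)

  expect_error(select_union_topk(rA, rA, k_pool = 10, k_head = 20),
               "k_head")
})

test_that("correlation pruning keeps the invariant and prefers importance", {
  set.seed(13)
  n <- 120
  base <- rnorm(n)
  X <- cbind(f1 = base, f2 = base,                        # exact duplicate
             f3 = 0.95 * base + sqrt(1 - 0.95^2) * rnorm(n),
             f4 = rnorm(n), f5 = rnorm(n))
  tab <- ft_from_matrix(X, prefix = "")
  colnames(X) <- paste0("f", 1:5)
  tab <- ft_from_matrix(X, prefix = "f")
  tab$meta$name <- colnames(tab$values) <- paste0("f", 1:5)
  cand <- paste0("f", 1:5)
  rk <- fake_ranking(cand)

  res <- prune_correlated(tab, cand, threshold = 0.9, ranking = rk)
  # exact duplicate: exactly one kept, the higher-importance one (f1)
  expect_true("f1" %in% res$selected)
  expect_false("f2" %in% res$selected)
  # invariant: no kept pair exceeds the threshold
  cm <- abs(stats::cor(ft_matrix(ft_subset(tab, features = res$selected))))
  expect_true(all(cm[upper.tri(cm)] <= 0.9))

  # brute-force greedy oracle on the known correlation structure
  cmat <- abs(stats::cor(X))
  kept <- character(0)
  for (f in cand) {
    if (!length(kept) || all(cmat[f, kept] <= 0.9)) kept <- c(kept, f)
  }
  expect_identical(res$selected, kept)

  # all pairwise below threshold: identity
  res2 <- prune_correlated(tab, c("f1", "f4", "f5"), threshold = 0.9,
                           ranking = rk)
  expect_setequal(res2$selected, c("f1", "f4", "f5"))

  # dropped pairs carry the offending correlation
  expect_true(all(abs(res$dropped_pairs$r) > 0.9))

  constant <- ft_from_matrix(cbind(k1 = rep(1, 10), k2 = rnorm(10)),
                             prefix = "k")
  expect_error(prune_correlated(constant, c("k1", "k2"), ranking = fake_ranking(c("k1", "k2"))),
               "variance_filter")
})

test_that("fusion aligns by sample id and preserves modality", {
  set.seed(14)
  c_tab <- ft_from_matrix(matrix(rnorm(30), 10, 3), modality = "clinical",
                          prefix = "c")
  r_tab <- ft_from_matrix(matrix(rnorm(20), 10, 2), modality = "radiomics",
                          prefix = "r")
  fused <- fuse_features(c_tab, r_tab)
  expect_equal(dim(fused), c(10L, 5L))
  expect_equal(sum(fused$meta$modality == "clinical"), 3)

  # shuffled sample order in one input: output equals unshuffled fusion
  perm <- sample(10)
  r_shuf <- feature_table(r_tab$values[perm, ], r_tab$meta)
  r_shuf$sample_ids <- r_tab$sample_ids[perm]
  rownames(r_shuf$values) <- r_shuf$sample_ids
  fused2 <- fuse_features(c_tab, r_shuf)
  expect_equal(fused2$values, fused$values)

  # doubling a table against itself under new names doubles columns
  r2 <- r_tab; r2$meta$name <- paste0(r2$meta$name, "_copy")
  names(r2$values) <- r2$meta$name
  both <- fuse_features(r_tab, r2)
  expect_equal(ncol(both$values), 4)

  bad <- ft_from_matrix(matrix(rnorm(18), 9, 2), prefix = "r")
  expect_error(fuse_features(c_tab, bad), "mismatch")
})
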