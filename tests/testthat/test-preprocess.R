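mk_table <- function(df, kinds, modality = "clinical") {
  feature_table(df, data.frame(name = names(df),
                               modality = modality, kind = kinds,
                               stringsAsFactors = FALSE))
}

test_that("imputation fills every gap and never alters observed cells", {
  df <- data.frame(a = c(1, 2, NA, 4), b = c(3, 3, 3, NA),
                   c = c("x", "x", "y", NA), stringsAsFactors = FALSE)
  tab <- mk_table(df, c("continuous", "continuous", "categorical"))
  out <- impute_monte_carlo(tab, seed = 1)
  expect_false(anyNA(out$values))
  expect_equal(out$values$a[c(1, 2, 4)], c(1, 2, 4))
  # degenerate distribution: all observed values 3.0 -> exactly 3.0
  expect_equal(out$values$b[4], 3.0)
  # categorical: modal category
  expect_equal(out$values$c[4], "x")
  # identity on a complete table
  full <- mk_table(data.frame(a = 1:4 + 0), "continuous")
  expect_identical(impute_monte_carlo(full, seed = 1)$values, full$values)
  # fully missing feature errors by name
  allna <- mk_table(data.frame(bad = c(NA_real_, NA_real_)), "continuous")
  expect_error(impute_monte_carlo(allna), "bad")
})

test_that("bootstrap mean-of-means lands near the observed mean", {
  # observed {0,10}: each N=50 draw mean has SE sqrt(25/50); averaging
  # M=50 repetitions gives SE 0.1, so 3 SE = 0.3
  errs <- vapply(1:20, function(s) {
    df <- data.frame(a = c(rep(c(0, 10), 25), NA))
    tab <- mk_table(df, "continuous")
    out <- impute_monte_carlo(tab, M = 50, N = 50, seed = s)
    out$values$a[51] - 5
  }, numeric(1))
  expect_true(all(abs(errs) < 0.3))
})

test_that("variance filter uses population variance and spares categoricals", {
  df <- data.frame(const = rep(1, 4), flip = c(0, 1, 0, 1),
                   wide = c(0, 5, -5, 3), cat = c("a", "b", "a", "b"),
                   stringsAsFactors = FALSE)
  tab <- mk_table(df, c("continuous", "continuous", "continuous", "categorical"))
  # population variance of {0,1,0,1} is 0.25 <= 0.3 -> removed
  out <- variance_filter(tab, threshold = 0.3)
  expect_equal(out$meta$name, c("wide", "cat"))
  # threshold 0 removes exactly the constant feature
  out0 <- variance_filter(tab, threshold = 0)
  expect_equal(out0$meta$name, c("flip", "wide", "cat"))
  expect_error(variance_filter(tab, threshold = -1), "nonnegative")
})

test_that("one-hot encoding forms a partition of unity and flags unseen levels", {
  df <- data.frame(yn = c("yes", "no", "yes"),
                   ocsp = c("TACI", "PACI", "LACI"),
                   age = c(60, 70, 80), stringsAsFactors = FALSE)
  tab <- mk_table(df, c("categorical", "categorical", "continuous"))
  enc <- one_hot_encode(tab)
  expect_equal(enc$values[["yn=yes"]], c(1, 0, 1))
  expect_equal(enc$values[["yn=no"]], c(0, 1, 0))
  ocsp_cols <- grep("^ocsp=", enc$meta$name, value = TRUE)
  expect_equal(length(ocsp_cols), 3)
  expect_equal(rowSums(enc$values[, ocsp_cols]), rep(1, 3),
               ignore_attr = TRUE)
  expect_equal(enc$meta$parent[enc$meta$name == "yn=yes"], "yn")
  # continuous-only table passes through unchanged
  cont <- mk_table(data.frame(a = 1:3 + 0), "continuous")
  expect_equal(one_hot_encode(cont)$values, cont$values)
  # unseen level at transform time errors with feature and level
  lv <- attr(enc, "levels")
  df2 <- df; df2$ocsp[1] <- "POCI"
  tab2 <- mk_table(df2, c("categorical", "categorical", "continuous"))
  expect_error(one_hot_encode(tab2, levels = lv), "POCI")
})

test_that("standardization uses training moments only", {
  tab <- mk_table(data.frame(a = c(1, 2, 3)), "continuous")
  std <- fit_standardizer(tab)
  z <- apply_standardizer(std, tab)
  expect_equal(z$values$a, c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  # applying training params to an identical column reproduces outputs
  expect_equal(apply_standardizer(std, tab)$values$a, z$values$a)

  set.seed(2)
  big <- mk_table(as.data.frame(matrix(rnorm(500, 5, 3), 100, 5)),
                  rep("continuous", 5))
  stdb <- fit_standardizer(big)
  zb <- ft_matrix(apply_standardizer(stdb, big))
  expect_lt(max(abs(colMeans(zb))), 1e-10)
  expect_lt(max(abs(apply(zb, 2, function(x) sqrt(mean((x - mean(x))^2))) - 1)),
            1e-10)

  # training moments, not test moments: shifted test rows keep their shift
  test_tab <- mk_table(data.frame(a = c(11, 12, 13)), "continuous")
  zt <- apply_standardizer(std, test_tab)
  expect_equal(zt$values$a, z$values$a + 10 / std$sigma)

  const <- mk_table(data.frame(a = rep(2, 3)), "continuous")
  expect_error(fit_standardizer(const), "variance_filter")
})

test_that("stratified split reproduces per-class largest-remainder counts", {
  cfg <- synth_config(seed = 1, n_radiomics = 10,
                      n_informative_radiomics = 1, n_redundant_blocks = 0)
  ds <- generate_dataset(cfg)
  sp <- stratified_split(ds$labels, 0.7, seed = 5)
  expect_equal(as.integer(table(ds$labels[sp$train])), c(74L, 202L, 32L))
  expect_equal(as.integer(table(ds$labels[sp$test])), c(32L, 87L, 14L))
  expect_setequal(c(sp$train, sp$test), seq_along(ds$labels))
  expect_length(intersect(sp$train, sp$test), 0)
  # determinism
  sp2 <- stratified_split(ds$labels, 0.7, seed = 5)
  expect_identical(sp, sp2)
  # degenerate fractions rejected
  expect_error(stratified_split(ds$labels, 1.0), "strictly")
  expect_error(stratified_split(ds$labels, 0), "strictly")
  expect_error(stratified_split(factor(c("A", "B", "B", "C", "C")), 0.7),
               "fewer than 2")
})

test_that("pipeline stages are idempotent on clean standardized data", {
  set.seed(9)
  X <- matrix(rnorm(200), 50, 4)
  X <- scale(X, center = colMeans(X),
             scale = apply(X, 2, function(x) sqrt(mean((x - mean(x))^2))))
  tab <- mk_table(as.data.frame(X), rep("continuous", 4))
  out <- impute_monte_carlo(tab, seed = 1)
  out <- one_hot_encode(out)
  out <- apply_standardizer(fit_standardizer(out), out)
  expect_lt(max(abs(ft_matrix(out) - X)), 1e-10)
})
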