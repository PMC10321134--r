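test_that("class counts follow largest-remainder rounding for assorted n", {
  for (n in c(441L, 100L, 37L, 10L)) {
    cfg <- synth_config(n_samples = n, n_radiomics = 20,
                        n_informative_radiomics = 2, n_redundant_blocks = 1,
                        block_size = 3, seed = 7)
    ds <- generate_dataset(cfg)
    q <- n * c(106, 289, 46) / 441
    base <- floor(q)
    rem <- n - sum(base)
    if (rem > 0) {
      ord <- order(-(q - base), 1:3)
      base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
    }
    expect_equal(as.integer(table(ds$labels)), as.integer(base))
  }
  # the default cohort reproduces the 106/289/46 split exactly
  ds <- generate_dataset(synth_config(seed = 1))
  expect_equal(as.integer(table(ds$labels)), c(106L, 289L, 46L))
})

test_that("degenerate class weights raise an error naming the class", {
  expect_error(
    generate_dataset(synth_config(n_samples = 50,
                                  class_props = c(100, 100, 0.1),
                                  n_radiomics = 20,
                                  n_informative_radiomics = 2,
                                  n_redundant_blocks = 0)),
    "class C"
  )
})

test_that("missing markers appear only when requested, only on clinical continuous", {
  cfg0 <- synth_config(missing_rate = 0, n_radiomics = 30,
                       n_informative_radiomics = 3, n_redundant_blocks = 1,
                       seed = 3)
  ds0 <- generate_dataset(cfg0)
  expect_false(anyNA(ds0$table$values))

  cfg1 <- synth_config(missing_rate = 0.2, n_radiomics = 30,
                       n_informative_radiomics = 3, n_redundant_blocks = 1,
                       seed = 3)
  ds1 <- generate_dataset(cfg1)
  na_by_col <- vapply(ds1$table$values, function(x) sum(is.na(x)), integer(1))
  meta <- ds1$table$meta
  expect_true(any(na_by_col > 0))
  expect_true(all(na_by_col[meta$modality == "radiomics"] == 0))
  expect_true(all(na_by_col[meta$kind == "categorical"] == 0))
})

test_that("redundant blocks reach the target within-block correlation", {
  # leader-member pairs sit at rho, member-member at rho^2; for rho=0.95
  # and block size 5 the mean pairwise r is ~0.92
  rs <- vapply(1:10, function(s) {
    cfg <- synth_config(n_samples = 300, n_radiomics = 40,
                        n_informative_radiomics = 4, n_redundant_blocks = 1,
                        block_size = 5, block_corr = 0.95, missing_rate = 0,
                        seed = s)
    ds <- generate_dataset(cfg)
    b <- ds$ground_truth$blocks[[1]]
    cm <- stats::cor(as.matrix(ds$table$values[, b]))
    mean(cm[upper.tri(cm)])
  }, numeric(1))
  expect_gt(mean(rs), 0.9)
  expect_lt(mean(rs), 0.99)
})

test_that("identical seeds give byte-identical CSV exports", {
  cfg <- synth_config(n_samples = 60, n_radiomics = 15,
                      n_informative_radiomics = 2, n_redundant_blocks = 1,
                      block_size = 3, seed = 42)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  ds1 <- generate_dataset(cfg)
  ds2 <- generate_dataset(cfg)
  write_dataset(ds1$table, ds1$labels, f1, ds1$ground_truth)
  write_dataset(ds2$table, ds2$labels, f2, ds2$ground_truth)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  rt <- read_dataset(f1)
  expect_equal(rt$labels, ds1$labels, ignore_attr = TRUE)
  expect_equal(dim(rt$table), dim(ds1$table))
})

test_that("ground truth ids exist in the generated table", {
  cfg <- synth_config(n_radiomics = 40, n_informative_radiomics = 5,
                      n_redundant_blocks = 2, block_size = 3, seed = 9)
  ds <- generate_dataset(cfg)
  inf <- unlist(ds$ground_truth$informative)
  expect_true(all(inf %in% ds$table$meta$name))
  expect_true(all(unlist(ds$ground_truth$blocks) %in% ds$table$meta$name))
})

test_that("split-signal design: neither modality suffices alone, the union does", {
  gains <- vapply(1:5, function(s) {
    cfg <- synth_config(n_samples = 300, n_radiomics = 30,
                        n_informative_clinical = 4,
                        n_informative_radiomics = 4, n_redundant_blocks = 0,
                        missing_rate = 0, effect_size = 2, seed = s)
    ds <- generate_split_signal_dataset(cfg)
    enc <- one_hot_encode(ds$table)
    X <- ft_matrix(enc)
    clin_cols <- enc$meta$modality == "clinical"
    acc <- function(cols) {
      rf <- with(list(), {
        set.seed(s)
        randomForest::randomForest(x = X[, cols, drop = FALSE], y = ds$labels)
      })
      mean(predict(rf) == ds$labels)  # OOB predictions
    }
    acc(rep(TRUE, ncol(X))) - max(acc(clin_cols), acc(!clin_cols))
  }, numeric(1))
  expect_true(all(gains > 0))
})

test_that("zero effect size carries no learnable signal", {
  cfg <- synth_config(n_samples = 240, n_radiomics = 20,
                      n_informative_radiomics = 3, n_redundant_blocks = 0,
                      missing_rate = 0, effect_size = 0, seed = 5)
  ds <- generate_dataset(cfg)
  enc <- one_hot_encode(ds$table)
  X <- ft_matrix(enc)
  set.seed(5)
  rf <- randomForest::randomForest(x = X, y = ds$labels)
  acc <- mean(predict(rf) == ds$labels)  # OOB accuracy
  p_max <- max(table(ds$labels)) / length(ds$labels)
  ci_hw <- 2.6 * sqrt(p_max * (1 - p_max) / length(ds$labels))
  expect_lt(acc, p_max + ci_hw)

  # feature-label associations behave like pure noise: about 5% of
  # continuous features reach p < 0.05 under a Kruskal-Wallis test
  pvals <- vapply(which(ds$table$meta$kind == "continuous"), function(j) {
    stats::kruskal.test(as.numeric(ds$table$values[[j]]), ds$labels)$p.value
  }, numeric(1))
  expect_lt(mean(pvals < 0.05), 0.2)
})
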