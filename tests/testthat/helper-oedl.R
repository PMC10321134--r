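# Shared fixtures, built in code at test time.

# Small linearly separable 3-class cloud (class A shifted in dim 1,
# class C in dim 2). Separability is re-checked where a test relies on it.
toy_separable <- function(n_per_class = 50, shift = 3, seed = 1) {
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed); expr
  }
  withr_seed({
    n <- 3 * n_per_class
    X <- cbind(rnorm(n), rnorm(n))
    y <- factor(rep(c("A", "B", "C"), each = n_per_class))
    X[y == "A", 1] <- X[y == "A", 1] + shift
    X[y == "C", 2] <- X[y == "C", 2] + shift
    list(X = X, y = y)
  })
}

# Training profile used in learner tests: enough optimization to converge
# on toy problems while keeping each fit under a second.
fast_spec <- function(family, neurons = c(10, 10), epochs = 60) {
  learner_spec(family, neurons = neurons, lr = 1e-2, epochs = epochs,
               pretrain_epochs = 3)
}

# Build a feature_table of continuous features from a numeric matrix.
ft_from_matrix <- function(X, modality = "radiomics", prefix = "f") {
  colnames(X) <- paste0(prefix, seq_len(ncol(X)))
  feature_table(
    as.data.frame(X),
    data.frame(name = colnames(X), modality = modality, kind = "continuous",
               stringsAsFactors = FALSE)
  )
}

# Independent Mann-Whitney AUC oracle (0.5 credit per tie), used to check
# the trapezoid ROC implementation.
mw_auc <- function(scores_pos, scores_neg) {
  s <- 0
  for (p in scores_pos) {
    s <- s + sum(p > scores_neg) + 0.5 * sum(p == scores_neg)
  }
  s / (length(scores_pos) * length(scores_neg))
}
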