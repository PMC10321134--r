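#' Run configuration for the end-to-end pipeline
#'
#' Bundles every knob of the workflow: data source (a [synth_config()]
#' plus scenario, or a CSV path in the package's dataset dialect),
#' feature set, balancing method, model, split fraction, training
#' profile and architecture-search budget.
#'
#' @param synth a [synth_config()] (ignored when `data_path` is given)
#' @param scenario `"standard"` or `"split_signal"` synthetic design
#' @param data_path optional CSV path readable by [read_dataset()]
#' @param feature_set `"joint"`, `"clinical"` or `"radiomics"`
#' @param balance `"smoteenn"`, `"none"`, `"random_over"`,
#'   `"random_under"` or `"smote"`
#' @param model one of `"oedl"`, `"edl"`, `"dnn"`, `"lstm_rnn"`,
#'   `"dbn"`, `"hard_vote"`, `"soft_vote"`, `"reference:dt"`,
#'   `"reference:svm"`, `"reference:rf"`
#' @param train_frac training fraction (default 0.7)
#' @param seed master seed for every stage
#' @param profile `"reduced"` (desk-scale: 60 epochs at lr 1e-3) or
#'   `"full"` (1000 epochs at lr 1e-4), or a list with `epochs`, `lr`,
#'   `pretrain_epochs`, `search_epochs`
#' @param variance_threshold radiomics variance-filter threshold
#'   (default 0.3)
#' @param k_pool,k_head union-selection depths (defaults 50 and 10)
#' @param cor_threshold Pearson pruning threshold (default 0.9)
#' @param impute_M,impute_N Monte Carlo imputation repetitions and draws
#' @param T_folds stacking folds (default 5)
#' @param bboa list of search knobs: `pop`, `T`, `L_max`
#' @param balance_before_split balance the whole dataset before
#'   splitting instead of the training rows only (fidelity mode; leaks
#'   synthetic points into the test set, default FALSE)
#' @param select_on_all run feature selection on all rows instead of
#'   training rows only (fidelity mode, default FALSE, warns loudly)
#' @return A `run_config`.
#' @export
run_config <- function(synth = synth_config(),
                       scenario = c("standard", "split_signal"),
                       data_path = NULL,
                       feature_set = c("joint", "clinical", "radiomics"),
                       balance = c("smoteenn", "none", "random_over",
                                   "random_under", "smote"),
                       model = "edl",
                       train_frac = 0.7,
                       seed = 1L,
                       profile = "reduced",
                       variance_threshold = 0.3,
                       k_pool = 50L, k_head = 10L,
                       cor_threshold = 0.9,
                       impute_M = 5L, impute_N = 20L,
                       T_folds = 5L,
                       bboa = list(pop = 5L, T = 4L, L_max = 2L),
                       balance_before_split = FALSE,
                       select_on_all = FALSE) {
  scenario <- match.arg(scenario)
  feature_set <- match.arg(feature_set)
  balance <- match.arg(balance)
  models <- c("oedl", "edl", "dnn", "lstm_rnn", "dbn", "hard_vote",
              "soft_vote", "reference:dt", "reference:svm", "reference:rf")
  if (!model %in% models) {
    stop("model must be one of: ", paste(models, collapse = ", "))
  }
  if (!is.null(data_path) && !file.exists(data_path)) {
    stop("data_path does not exist: ", data_path)
  }
  if (is.character(profile)) {
    profile <- switch(match.arg(profile, c("reduced", "full")),
      reduced = list(epochs = 60L, lr = 1e-3, pretrain_epochs = 5L,
                     search_epochs = 20L),
      full = list(epochs = 1000L, lr = 1e-4, pretrain_epochs = 15L,
                  search_epochs = 100L)
    )
  }
  structure(
    list(synth = synth, scenario = scenario, data_path = data_path,
         feature_set = feature_set, balance = balance, model = model,
         train_frac = train_frac, seed = as.integer(seed),
         profile = profile,
         variance_threshold = variance_threshold,
         k_pool = as.integer(k_pool), k_head = as.integer(k_head),
         cor_threshold = cor_threshold,
         impute_M = as.integer(impute_M), impute_N = as.integer(impute_N),
         T_folds = as.integer(T_folds), bboa = bboa,
         balance_before_split = balance_before_split,
         select_on_all = select_on_all),
    class = "run_config"
  )
}

.spec_from_profile <- function(family, config, neurons = c(10L, 10L)) {
  learner_spec(family = family, neurons = neurons,
               lr = config$profile$lr, batch_size = 20L,
               momentum_beta = 0.9, epochs = config$profile$epochs,
               pretrain_epochs = config$profile$pretrain_epochs)
}

# Preprocess + select + fuse. Returns the model-ready numeric matrix for
# all samples plus bookkeeping. Fitted parameters (imputation pools,
# variance filter, standardizer, rankings, level sets) only ever see
# training rows unless select_on_all is set.
prepare_features <- function(table, labels, split, config) {
  train <- split$train
  sel_rows <- if (config$select_on_all) seq_along(labels) else train
  if (config$select_on_all) {
    warning("select_on_all = TRUE: feature selection sees test rows; ",
            "results are not leakage-safe", call. = FALSE)
  }

  train_pool <- ft_subset(table, rows = train)
  table <- impute_monte_carlo(table, M = config$impute_M, N = config$impute_N,
                              seed = derive_seed(config$seed, "impute"),
                              pool = train_pool)

  clin <- ft_subset(table, features = table$meta$name[table$meta$modality == "clinical"])
  rad <- ft_subset(table, features = table$meta$name[table$meta$modality == "radiomics"])

  # radiomics funnel: variance filter -> standardize -> dual-booster
  # union selection -> correlation pruning
  rad_sel_names <- character(0)
  rankA <- rankB <- NULL
  if (config$feature_set %in% c("radiomics", "joint")) {
    rad <- variance_filter(rad, config$variance_threshold, rows = train)
    std <- fit_standardizer(rad, rows = train)
    rad <- apply_standardizer(std, rad)
    rad_fit <- ft_subset(rad, rows = sel_rows)
    y_fit <- labels[sel_rows]
    rankA <- rank_importance(rad_fit, y_fit, "leafwise_gain",
                             seed = derive_seed(config$seed, "rankA"))
    rankB <- rank_importance(rad_fit, y_fit, "secondorder_weight",
                             seed = derive_seed(config$seed, "rankB"))
    un <- select_union_topk(rankA, rankB, config$k_pool, config$k_head)
    pruned <- prune_correlated(rad_fit, un$selected, config$cor_threshold,
                               ranking = un$selected)
    rad_sel_names <- pruned$selected
    rad <- ft_subset(rad, features = rad_sel_names)
  }

  # clinical funnel: correlation check only, then one-hot + z-score
  clin_sel_names <- character(0)
  if (config$feature_set %in% c("clinical", "joint")) {
    clin_fit <- ft_subset(clin, rows = sel_rows)
    cont <- clin$meta$name[clin$meta$kind == "continuous"]
    if (length(cont) > 1) {
      pruned <- prune_correlated(ft_subset(clin_fit, features = cont),
                                 cont, config$cor_threshold, ranking = cont)
      keep_cont <- pruned$selected
    } else keep_cont <- cont
    clin_sel_names <- clin$meta$name[clin$meta$kind == "categorical" |
                                       clin$meta$name %in% keep_cont]
    clin <- ft_subset(clin, features = clin_sel_names)
    enc_train <- one_hot_encode(ft_subset(clin, rows = train))
    clin <- one_hot_encode(clin, levels = attr(enc_train, "levels"))
    std <- fit_standardizer(clin, rows = train)
    clin <- apply_standardizer(std, clin)
  }

  fused <- switch(config$feature_set,
    clinical = clin,
    radiomics = rad,
    joint = fuse_features(clin, rad)
  )
  list(X = ft_matrix(fused),
       selected = list(clinical = clin_sel_names, radiomics = rad_sel_names),
       rankings = list(A = rankA, B = rankB))
}

.balance_train <- function(X, y, method, seed) {
  switch(method,
    none = list(X = X, y = y),
    random_over = random_oversample(X, y, seed = seed),
    random_under = random_undersample(X, y, seed = seed),
    smote = smote(X, y, seed = seed),
    smoteenn = smoteenn(X, y, seed = seed)
  )
}

# Fit the configured model on (balanced) training data and return test
# probabilities plus model artifacts.
.fit_and_score <- function(config, Xb, yb, Xte) {
  seed <- config$seed
  families <- c("dnn", "lstm_rnn", "dbn")
  if (config$model %in% families) {
    spec <- .spec_from_profile(config$model, config)
    m <- fit_learner(spec, Xb, yb, seed = derive_seed(seed, "single"))
    list(probs = predict_proba(m, Xte), specs = list(spec), model = m)
  } else if (config$model %in% c("hard_vote", "soft_vote")) {
    ms <- lapply(families, function(f) {
      fit_learner(.spec_from_profile(f, config), Xb, yb,
                  seed = derive_seed(seed, paste0("vote_", f)))
    })
    pr <- lapply(ms, predict_proba, X = Xte)
    probs <- Reduce(`+`, pr) / length(pr)
    labels <- if (config$model == "hard_vote") {
      hard_vote(lapply(pr, function(p) {
        factor(colnames(p)[max.col(p, ties.method = "first")],
               levels = levels(yb))
      }))
    } else soft_vote(pr)
    list(probs = probs, labels = labels,
         specs = lapply(ms, function(m) m$spec), model = ms)
  } else if (config$model == "edl") {
    specs <- stats::setNames(lapply(families, .spec_from_profile,
                                    config = config), families)
    sm <- stacking_fit(specs, Xb, yb, T_folds = config$T_folds,
                       seed = derive_seed(seed, "edl"))
    pred <- stacking_predict(sm, Xte)
    list(probs = pred$probs, labels = pred$labels, specs = specs, model = sm)
  } else if (config$model == "oedl") {
    inner <- stratified_split(yb, 0.8, seed = derive_seed(seed, "inner"))
    base <- .spec_from_profile("dnn", config)
    found <- search_architecture(
      families, Xb[inner$train, , drop = FALSE], yb[inner$train],
      Xb[inner$test, , drop = FALSE], yb[inner$test],
      L_max = config$bboa$L_max %||% 2L,
      epochs = config$profile$search_epochs,
      pop = config$bboa$pop %||% 5L, T = config$bboa$T %||% 4L,
      seed = derive_seed(seed, "bboa"), base_spec = base
    )
    specs <- lapply(found, function(f) f$spec)
    sm <- stacking_fit(specs, Xb, yb, T_folds = config$T_folds,
                       seed = derive_seed(seed, "oedl"))
    pred <- stacking_predict(sm, Xte)
    list(probs = pred$probs, labels = pred$labels, specs = specs,
         model = sm, search = found)
  } else { # reference:*
    name <- sub("^reference:", "", config$model)
    m <- fit_reference(name, Xb, yb, seed = derive_seed(seed, "ref"))
    list(probs = predict_reference(m, Xte), specs = NULL, model = m)
  }
}

#' Execute one pipeline run
#'
#' Generates or loads the dataset, performs the stratified split,
#' preprocessing, per-modality feature selection, fusion, training-only
#' balancing, model fitting and evaluation on the untouched test rows,
#' and returns a manifest sufficient to reproduce the run bit for bit.
#'
#' @param config a [run_config()]
#' @return A `run_manifest`: config echo, package version, per-stage
#'   timings, selected features, learner specs and the test-set
#'   `metric_report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  timings <- c()
  tic <- function() Sys.time()
  lap <- function(t0, stage) {
    timings[stage] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  }

  t0 <- tic()
  ds <- if (!is.null(config$data_path)) {
    read_dataset(config$data_path)
  } else if (config$scenario == "split_signal") {
    generate_split_signal_dataset(config$synth)
  } else {
    generate_dataset(config$synth)
  }
  lap(t0, "data")

  t0 <- tic()
  split <- stratified_split(ds$labels, config$train_frac,
                            seed = derive_seed(config$seed, "outer_split"))
  prep <- prepare_features(ds$table, ds$labels, split, config)
  lap(t0, "preprocess_select")

  t0 <- tic()
  Xtr <- prep$X[split$train, , drop = FALSE]
  ytr <- droplevels_keep(ds$labels[split$train])
  Xte <- prep$X[split$test, , drop = FALSE]
  yte <- droplevels_keep(ds$labels[split$test])
  if (config$balance_before_split) {
    bal <- .balance_train(prep$X, ds$labels, config$balance,
                          seed = derive_seed(config$seed, "balance"))
    # fidelity mode: rebuild split on the balanced pool
    split_b <- stratified_split(bal$y, config$train_frac,
                                seed = derive_seed(config$seed, "outer_split"))
    Xtr <- bal$X[split_b$train, , drop = FALSE]
    ytr <- droplevels_keep(bal$y[split_b$train])
    Xte <- bal$X[split_b$test, , drop = FALSE]
    yte <- droplevels_keep(bal$y[split_b$test])
  } else {
    bal <- .balance_train(Xtr, ytr, config$balance,
                          seed = derive_seed(config$seed, "balance"))
    Xtr <- bal$X
    ytr <- bal$y
  }
  lap(t0, "balance")

  t0 <- tic()
  fit <- .fit_and_score(config, Xtr, ytr, Xte)
  lap(t0, "fit")

  t0 <- tic()
  report <- evaluate_predictions(yte, fit$probs)
  if (!is.null(fit$labels)) {
    # voting models decide labels by vote, not by meta-probability argmax
    rep2 <- macro_metrics(confusion(yte, fit$labels))
    rep2$macro_AUC <- report$macro_AUC
    rep2$per_class_auc <- report$per_class_auc
    report <- rep2
  }
  lap(t0, "evaluate")

  structure(
    list(config = config,
         version = as.character(utils::packageVersion("oedl")),
         n_train = length(split$train), n_test = length(split$test),
         counts_train = table(ytr), counts_test = table(yte),
         selected = prep$selected,
         specs = fit$specs,
         search = fit$search,
         timings = timings,
         report = report),
    class = "run_manifest"
  )
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> model=%s features=%s balance=%s seed=%d\n",
              x$config$model, x$config$feature_set, x$config$balance,
              x$config$seed))
  print(x$report)
  invisible(x)
}

#' Re-execute a run from its manifest
#'
#' Replays the embedded configuration; because every stage derives its
#' randomness from the config seed, the metrics reproduce bit for bit.
#'
#' @param manifest a `run_manifest`
#' @return A fresh `run_manifest`.
#' @export
run_from_manifest <- function(manifest) {
  stopifnot(inherits(manifest, "run_manifest"))
  run_pipeline(manifest$config)
}

#' Run a grid of configurations with shared splits
#'
#' Executes each configuration (all built from the same seed so split,
#' preprocessing and balancing draws coincide wherever configs agree)
#' and collects a long-format comparison table.
#'
#' @param configs list of [run_config()] objects
#' @return data.frame with one row per run: factor levels and the five
#'   headline metrics; manifests attached as attribute `manifests`.
#' @export
run_grid <- function(configs) {
  stopifnot(is.list(configs), length(configs) >= 1)
  manifests <- lapply(configs, run_pipeline)
  rows <- lapply(manifests, function(m) {
    data.frame(model = m$config$model, feature_set = m$config$feature_set,
               balance = m$config$balance, seed = m$config$seed,
               ACC = m$report$ACC, macro_P = m$report$macro_P,
               macro_R = m$report$macro_R, macro_F1 = m$report$macro_F1,
               macro_AUC = m$report$macro_AUC %||% NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "manifests") <- manifests
  out
}

#' Shallow reference learners for comparison rows
#'
#' Seed-fixed decision tree (`dt`), RBF support vector machine (`svm`)
#' and random forest (`rf`) fits used only to populate baseline rows of
#' comparison tables.
#'
#' @param name `"dt"`, `"svm"` or `"rf"`
#' @param X numeric training matrix
#' @param y class factor
#' @param seed integer seed
#' @return A `reference_model`.
#' @export
fit_reference <- function(name = c("dt", "svm", "rf"), X, y, seed = 1L) {
  name <- match.arg(name)
  X <- as.matrix(X)
  y <- as.factor(y)
  df <- data.frame(X, check.names = FALSE)
  fit <- with_seed(derive_seed(seed, paste0("ref_", name)), {
    switch(name,
      dt = rpart::rpart(y ~ ., data = cbind(df, y = y), method = "class"),
      svm = e1071::svm(x = X, y = y, probability = TRUE, kernel = "radial"),
      rf = randomForest::randomForest(x = X, y = y, ntree = 100)
    )
  })
  structure(list(name = name, fit = fit, classes = levels(y)),
            class = "reference_model")
}

#' @rdname fit_reference
#' @param model a `reference_model`
#' @return `predict_reference()` returns a row-stochastic probability
#'   matrix.
#' @export
predict_reference <- function(model, X) {
  stopifnot(inherits(model, "reference_model"))
  X <- as.matrix(X)
  probs <- switch(model$name,
    dt = stats::predict(model$fit, data.frame(X, check.names = FALSE),
                        type = "prob"),
    svm = attr(stats::predict(model$fit, X, probability = TRUE),
               "probabilities")[, model$classes, drop = FALSE],
    rf = stats::predict(model$fit, X, type = "prob")
  )
  probs <- as.matrix(probs)
  probs / rowSums(probs)
}

#' Write a run manifest to JSON
#' @param manifest a `run_manifest`
#' @param path output path
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "run_manifest"))
  cfg <- manifest$config
  cfg$synth <- unclass(cfg$synth)
  out <- list(
    config = unclass(cfg),
    version = manifest$version,
    n_train = manifest$n_train, n_test = manifest$n_test,
    selected = manifest$selected,
    timings = as.list(manifest$timings),
    report = list(ACC = manifest$report$ACC,
                  macro_P = manifest$report$macro_P,
                  macro_R = manifest$report$macro_R,
                  macro_F1 = manifest$report$macro_F1,
                  macro_AUC = manifest$report$macro_AUC)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
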