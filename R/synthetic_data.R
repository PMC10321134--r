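#' Configuration for the synthetic cohort generator
#'
#' Describes a three-class tabular dataset with the structure the modelling
#' pipeline assumes: a small block of mixed-type clinical features and a
#' wide block of continuous radiomics-style features containing informative
#' features, correlated redundant blocks and pure noise. Defaults mirror a
#' single-centre stroke-prognosis cohort: 441 patients in class proportions
#' 106:289:46 (discharge NIHSS bands A <1, B 1-4, C >= 5), 17 clinical
#' features, and a few hundred radiomics features.
#'
#' @param n_samples number of samples (default 441)
#' @param class_props three nonnegative class weights, normalized internally
#'   (default `c(106, 289, 46)`)
#' @param n_clinical number of clinical features (default 17; roughly
#'   one-third continuous, the rest categorical with 2-4 levels)
#' @param n_radiomics number of continuous radiomics-style features
#'   (default 200)
#' @param n_informative_clinical,n_informative_radiomics number of features
#'   per modality carrying class signal (defaults 5 and 10)
#' @param n_redundant_blocks number of correlated radiomics blocks; each
#'   block consists of one informative "leader" plus `block_size - 1` noisy
#'   copies (default 6)
#' @param block_size features per redundant block including the leader
#'   (default 5)
#' @param block_corr target Pearson correlation between a block member and
#'   its leader, in `[0, 1)` (default 0.9)
#' @param missing_rate MCAR missingness rate applied to clinical continuous
#'   cells only (default 0.05)
#' @param effect_size class-mean separation of informative continuous
#'   features, in within-class SD units. The default 0.6 places single
#'   deep learners in the mid-80s accuracy range on the default cohort,
#'   the regime where ensembling and balancing visibly matter
#' @param seed integer seed; identical configurations generate identical
#'   datasets
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_samples = 441L,
                         class_props = c(106, 289, 46),
                         n_clinical = 17L,
                         n_radiomics = 200L,
                         n_informative_clinical = 5L,
                         n_informative_radiomics = 10L,
                         n_redundant_blocks = 6L,
                         block_size = 5L,
                         block_corr = 0.9,
                         missing_rate = 0.05,
                         effect_size = 0.6,
                         seed = 1L) {
  cfg <- list(
    n_samples = as.integer(n_samples),
    class_props = as.numeric(class_props),
    n_clinical = as.integer(n_clinical),
    n_radiomics = as.integer(n_radiomics),
    n_informative_clinical = as.integer(n_informative_clinical),
    n_informative_radiomics = as.integer(n_informative_radiomics),
    n_redundant_blocks = as.integer(n_redundant_blocks),
    block_size = as.integer(block_size),
    block_corr = as.numeric(block_corr),
    missing_rate = as.numeric(missing_rate),
    effect_size = as.numeric(effect_size),
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_samples >= 3,
    length(cfg$class_props) == 3, all(cfg$class_props >= 0),
    sum(cfg$class_props) > 0,
    cfg$n_clinical >= 1, cfg$n_radiomics >= 1,
    cfg$n_informative_clinical >= 0,
    cfg$n_informative_clinical <= cfg$n_clinical,
    cfg$n_informative_radiomics >= 0,
    cfg$n_informative_radiomics <= cfg$n_radiomics,
    cfg$n_redundant_blocks >= 0, cfg$block_size >= 2,
    cfg$block_corr >= 0, cfg$block_corr < 1,
    cfg$missing_rate >= 0, cfg$missing_rate < 1,
    cfg$effect_size >= 0
  )
  extra <- cfg$n_redundant_blocks * (cfg$block_size - 1L)
  if (cfg$n_informative_radiomics + extra > cfg$n_radiomics) {
    stop("n_radiomics too small for the requested informative features ",
         "and redundant blocks")
  }
  class(cfg) <- "synth_config"
  cfg
}

# Class-mean contrast patterns (in SD units, scaled by effect_size) cycled
# over informative continuous features. Each pattern separates at least one
# class pair by `effect_size`.
.contrast_cycle <- list(
  c(-1, 0, 1), c(1, -1, 0), c(0, 1, -1), c(1, 0, -1), c(-1, 1, 0), c(0, -1, 1)
)

# Deterministic kind/level layout for clinical features: roughly one-third
# continuous (lab-value-like), the rest categorical; the first two
# categorical features get 4 levels (lesion-position / OCSP-like), every
# fifth thereafter 3, the rest binary (history-variable-like).
.clinical_layout <- function(n_clinical) {
  n_cont <- max(1L, round(n_clinical * 6 / 17))
  kinds <- c(rep("continuous", n_cont),
             rep("categorical", n_clinical - n_cont))
  n_cat <- n_clinical - n_cont
  levels <- integer(0)
  if (n_cat > 0) {
    levels <- rep(2L, n_cat)
    if (n_cat >= 1) levels[1] <- 4L
    if (n_cat >= 2) levels[2] <- 4L
    if (n_cat >= 5) levels[seq(5, n_cat, by = 5)] <- 3L
  }
  list(kinds = kinds, n_cont = n_cont, cat_levels = levels)
}

.class_counts <- function(cfg) {
  counts <- largest_remainder(cfg$n_samples, cfg$class_props)
  if (any(counts == 0)) {
    stop("degenerate class weights: expected count 0 for class ",
         paste(c("A", "B", "C")[counts == 0], collapse = ", "))
  }
  counts
}

# Shared generator core. `clin_patterns` / `rad_patterns` give the class
# contrast assigned to each informative feature of the modality (recycled).
.generate_core <- function(cfg, clin_patterns, rad_patterns,
                           cat_signal_classes = c(1L, 2L, 3L)) {
  counts <- .class_counts(cfg)
  with_seed(cfg$seed, {
    y <- factor(rep(c("A", "B", "C"), counts), levels = c("A", "B", "C"))
    perm <- sample.int(cfg$n_samples)
    y <- y[perm]
    cls <- as.integer(y)
    n <- cfg$n_samples

    layout <- .clinical_layout(cfg$n_clinical)
    vals <- vector("list", cfg$n_clinical + cfg$n_radiomics)
    meta_name <- character(length(vals))
    meta_mod <- character(length(vals))
    meta_kind <- character(length(vals))
    informative_clin <- character(0)

    # --- clinical block ---------------------------------------------------
    # informative slots are spread across kinds: continuous first, then
    # categorical, in feature order.
    inf_clin_idx <- seq_len(cfg$n_informative_clinical)
    cat_seen <- 0L
    for (j in seq_len(cfg$n_clinical)) {
      nm <- sprintf("clin_%02d", j)
      meta_name[j] <- nm
      meta_mod[j] <- "clinical"
      meta_kind[j] <- layout$kinds[j]
      informative <- j %in% inf_clin_idx
      if (layout$kinds[j] == "continuous") {
        mu <- rep(0, 3)
        if (informative) {
          pat <- clin_patterns[[(j - 1L) %% length(clin_patterns) + 1L]]
          mu <- pat * cfg$effect_size
          informative_clin <- c(informative_clin, nm)
        }
        vals[[j]] <- stats::rnorm(n, mean = mu[cls], sd = 1)
      } else {
        cat_seen <- cat_seen + 1L
        L <- layout$cat_levels[cat_seen]
        lv <- paste0("l", seq_len(L))
        probs <- matrix(1 / L, nrow = 3, ncol = L)
        if (informative) {
          # tilt each signal-carrying class toward its own modal level
          w <- cfg$effect_size / (cfg$effect_size + 2)
          for (c in cat_signal_classes) {
            target <- (c - 1L) %% L + 1L
            probs[c, ] <- (1 - w) / L
            probs[c, target] <- probs[c, target] + w
          }
          informative_clin <- c(informative_clin, nm)
        }
        draw <- character(n)
        for (c in 1:3) {
          idx <- which(cls == c)
          if (length(idx)) {
            draw[idx] <- sample(lv, length(idx), replace = TRUE,
                                prob = probs[c, ])
          }
        }
        vals[[j]] <- draw
      }
    }

    # --- radiomics block --------------------------------------------------
    n_inf <- cfg$n_informative_radiomics
    n_blocks <- cfg$n_redundant_blocks
    bsz <- cfg$block_size
    informative_rad <- character(0)
    blocks <- list()
    p_cls <- counts / n
    rad_col <- function(k) cfg$n_clinical + k
    rad_name <- function(k) sprintf("rad_%03d", k)

    inf_store <- list()  # raw informative columns, reused as block leaders
    inf_sd <- numeric(n_inf)
    for (k in seq_len(n_inf)) {
      pat <- rad_patterns[[(k - 1L) %% length(rad_patterns) + 1L]]
      mu <- pat * cfg$effect_size
      x <- stats::rnorm(n, mean = mu[cls], sd = 1)
      m_marg <- sum(p_cls * mu)
      vb <- sum(p_cls * mu^2) - m_marg^2
      inf_sd[k] <- sqrt(1 + vb)       # theoretical marginal SD
      inf_store[[k]] <- x
      j <- rad_col(k)
      vals[[j]] <- x
      meta_name[j] <- rad_name(k)
      meta_mod[j] <- "radiomics"
      meta_kind[j] <- "continuous"
      informative_rad <- c(informative_rad, rad_name(k))
    }

    k_next <- n_inf
    rho <- cfg$block_corr
    for (b in seq_len(n_blocks)) {
      if (n_inf > 0) {
        lead_k <- (b - 1L) %% n_inf + 1L
        leader <- inf_store[[lead_k]]
        lead_sd <- inf_sd[lead_k]
        lead_nm <- rad_name(lead_k)
      } else {
        # no informative features: make a dedicated noise leader
        k_next <- k_next + 1L
        leader <- stats::rnorm(n)
        lead_sd <- 1
        j <- rad_col(k_next)
        vals[[j]] <- leader
        meta_name[j] <- rad_name(k_next)
        meta_mod[j] <- "radiomics"
        meta_kind[j] <- "continuous"
        lead_nm <- rad_name(k_next)
      }
      members <- lead_nm
      for (m in seq_len(bsz - 1L)) {
        k_next <- k_next + 1L
        x <- rho * leader + sqrt(1 - rho^2) * lead_sd * stats::rnorm(n)
        j <- rad_col(k_next)
        vals[[j]] <- x
        meta_name[j] <- rad_name(k_next)
        meta_mod[j] <- "radiomics"
        meta_kind[j] <- "continuous"
        members <- c(members, rad_name(k_next))
      }
      blocks[[paste0("block_", b)]] <- members
    }

    for (k in seq(k_next + 1L, length.out = cfg$n_radiomics - k_next)) {
      j <- rad_col(k)
      vals[[j]] <- stats::rnorm(n)
      meta_name[j] <- rad_name(k)
      meta_mod[j] <- "radiomics"
      meta_kind[j] <- "continuous"
    }

    # --- missingness (MCAR, clinical continuous only) ---------------------
    if (cfg$missing_rate > 0) {
      for (j in seq_len(cfg$n_clinical)) {
        if (meta_kind[j] == "continuous") {
          miss <- stats::runif(n) < cfg$missing_rate
          vals[[j]][miss] <- NA_real_
        }
      }
    }

    df <- as.data.frame(vals, col.names = meta_name, check.names = FALSE)
    names(df) <- meta_name
    rownames(df) <- sprintf("s%04d", seq_len(n))
    tab <- feature_table(
      df,
      data.frame(name = meta_name, modality = meta_mod, kind = meta_kind,
                 stringsAsFactors = FALSE)
    )
    gt <- list(
      informative = list(clinical = informative_clin,
                         radiomics = informative_rad),
      blocks = blocks,
      classes = as.character(y)
    )
    list(table = tab, labels = y, ground_truth = gt)
  })
}

#' Generate a synthetic clinical + radiomics cohort
#'
#' Continuous features are class-conditional Gaussians with unit
#' within-class SD; informative features receive class-mean contrasts of
#' magnitude `effect_size`. Categorical clinical features are
#' class-conditional multinomials, tilted toward a class-specific modal
#' level when informative. Redundant radiomics blocks are noisy copies of
#' an informative leader at correlation `block_corr`. Class counts follow
#' largest-remainder rounding of `class_props`, so the default
#' configuration yields exactly 106/289/46 samples.
#'
#' @param cfg a [synth_config()]
#' @return list with `table` (a [feature_table()]), `labels`
#'   (factor A/B/C) and `ground_truth` (informative feature ids per
#'   modality, block membership, class assignment).
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  .generate_core(cfg, .contrast_cycle, .contrast_cycle)
}

#' Generate a cohort whose class signal is split across modalities
#'
#' Clinical informative features separate class A from classes B and C
#' only; radiomics informative features separate class C from A and B
#' only. Neither modality alone can resolve all three classes, but their
#' union can — the design used to probe the value of feature fusion.
#'
#' @inheritParams generate_dataset
#' @return As [generate_dataset()].
#' @export
generate_split_signal_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (cfg$n_informative_clinical < 1 || cfg$n_informative_radiomics < 1) {
    stop("split-signal design needs informative features in both modalities")
  }
  .generate_core(
    cfg,
    clin_patterns = list(c(1, 0, 0), c(-1, 0, 0)),  # A vs {B,C} only
    rad_patterns = list(c(0, 0, 1), c(0, 0, -1)),   # C vs {A,B} only
    cat_signal_classes = 1L                          # categorical tilt: A only
  )
}
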