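#' Architecture descriptor for a deep base learner
#'
#' The unit the architecture optimizer searches over: a learner family
#' plus hidden-layer count and per-layer neuron counts (each in 1..100),
#' together with the fixed training hyperparameters (learning rate 1e-4,
#' batch size 20, first-moment decay 0.9, 1000 epochs by default; tests
#' and architecture search use reduced epoch profiles).
#'
#' @param family `"dnn"`, `"lstm_rnn"` or `"dbn"`
#' @param neurons integer vector of neurons per hidden layer (default
#'   `c(10, 10)`: two layers of 10)
#' @param lr learning rate
#' @param batch_size minibatch size
#' @param momentum_beta Adam first-moment decay
#' @param epochs training epochs
#' @param input_mode LSTM input shaping: `"single_step"` (default; the
#'   feature vector enters as one time step) or `"feature_steps"`
#'   (features fed one per time step)
#' @param pretrain_epochs DBN-only: contrastive-divergence epochs per RBM
#'   layer (default 15)
#' @return A `learner_spec`.
#' @export
learner_spec <- function(family = c("dnn", "lstm_rnn", "dbn"),
                         neurons = c(10L, 10L),
                         lr = 1e-4, batch_size = 20L, momentum_beta = 0.9,
                         epochs = 1000L,
                         input_mode = c("single_step", "feature_steps"),
                         pretrain_epochs = 15L) {
  family <- match.arg(family)
  input_mode <- match.arg(input_mode)
  neurons <- as.integer(neurons)
  if (length(neurons) < 1 || any(neurons < 1) || any(neurons > 100)) {
    stop("neurons must be a vector of counts in [1, 100]")
  }
  stopifnot(lr > 0, batch_size >= 1, momentum_beta >= 0, momentum_beta < 1,
            epochs >= 1)
  structure(
    list(family = family, n_hidden_layers = length(neurons),
         neurons = neurons, lr = lr, batch_size = as.integer(batch_size),
         momentum_beta = momentum_beta, epochs = as.integer(epochs),
         input_mode = input_mode, pretrain_epochs = as.integer(pretrain_epochs)),
    class = "learner_spec"
  )
}

#' @export
print.learner_spec <- function(x, ...) {
  cat(sprintf("<learner_spec> %s, layers [%s], lr=%g, batch=%d, epochs=%d\n",
              x$family, paste(x$neurons, collapse = ","), x$lr,
              x$batch_size, x$epochs))
  invisible(x)
}

# ---------------------------------------------------------------------------
# LSTM cell and stack

# One LSTM layer's parameters: W (4H x D input weights), U (4H x H
# recurrent weights), b (4H). Gate row blocks in order i, f, o, g.
lstm_layer_init <- function(D, H, seed = 1L) {
  with_seed(seed, {
    sc <- sqrt(1 / D)
    list(W = matrix(stats::rnorm(4 * H * D, sd = sc), 4 * H, D),
         U = matrix(stats::rnorm(4 * H * H, sd = sqrt(1 / H)), 4 * H, H),
         b = numeric(4 * H))
  })
}

.gate_rows <- function(H) {
  list(i = 1:H, f = (H + 1):(2 * H), o = (2 * H + 1):(3 * H),
       g = (3 * H + 1):(4 * H))
}

#' Single LSTM cell forward step
#'
#' Standard recurrences: gates i, f, o are sigmoids of affine maps of the
#' current input and previous hidden state, the candidate g is a tanh,
#' the cell state updates as C = f * C_prev + i * g, and the hidden state
#' is h = o * tanh(C).
#'
#' @param cell list with `W` (4H x D), `U` (4H x H), `b` (4H); gate blocks
#'   stacked in order input, forget, output, candidate
#' @param x_t input matrix (n x D)
#' @param h_prev,C_prev previous hidden / cell state (n x H)
#' @return list with `h`, `C` and the gate activations `i`, `f`, `o`,
#'   `g` (all n x H, gates strictly inside (0,1)).
#' @export
lstm_forward <- function(cell, x_t, h_prev, C_prev) {
  x_t <- as.matrix(x_t); h_prev <- as.matrix(h_prev); C_prev <- as.matrix(C_prev)
  H <- ncol(h_prev)
  if (nrow(cell$W) != 4 * H || ncol(cell$W) != ncol(x_t) ||
      ncol(cell$U) != H) {
    stop("shape mismatch between cell parameters and inputs")
  }
  Z <- x_t %*% t(cell$W) + h_prev %*% t(cell$U) +
    matrix(cell$b, nrow(x_t), 4 * H, byrow = TRUE)
  g_ <- .gate_rows(H)
  i <- 1 / (1 + exp(-Z[, g_$i, drop = FALSE]))
  f <- 1 / (1 + exp(-Z[, g_$f, drop = FALSE]))
  o <- 1 / (1 + exp(-Z[, g_$o, drop = FALSE]))
  g <- tanh(Z[, g_$g, drop = FALSE])
  C <- f * C_prev + i * g
  h <- o * tanh(C)
  list(h = h, C = C, i = i, f = f, o = o, g = g)
}

# Forward pass of the full stacked-LSTM classifier over a sequence.
# `seqs` is a list of (n x D_t) input matrices, one per time step.
.lstm_stack_forward <- function(params, arch, seqs) {
  n <- nrow(seqs[[1]])
  caches <- vector("list", length(arch$H))
  inputs <- seqs
  for (l in seq_along(arch$H)) {
    H <- arch$H[l]
    cell <- list(W = params[[paste0("W", l)]], U = params[[paste0("U", l)]],
                 b = params[[paste0("b", l)]])
    h <- matrix(0, n, H); C <- matrix(0, n, H)
    steps <- vector("list", length(inputs))
    outs <- vector("list", length(inputs))
    for (t in seq_along(inputs)) {
      st <- lstm_forward(cell, inputs[[t]], h, C)
      steps[[t]] <- c(st, list(x = inputs[[t]], h_prev = h, C_prev = C))
      h <- st$h; C <- st$C
      outs[[t]] <- h
    }
    caches[[l]] <- steps
    inputs <- outs
  }
  hT <- inputs[[length(inputs)]]
  logits <- hT %*% t(params$Wout) +
    matrix(params$bout, n, length(params$bout), byrow = TRUE)
  list(probs = softmax_rows(logits), hT = hT, caches = caches)
}

.lstm_shape <- function(X, input_mode) {
  if (input_mode == "single_step") {
    list(X)
  } else {
    lapply(seq_len(ncol(X)), function(j) X[, j, drop = FALSE])
  }
}

# ---------------------------------------------------------------------------
# Restricted Boltzmann machine (energy-level ops + CD-1)

#' RBM parameter initializer
#' @param n_vis,n_hid visible / hidden unit counts
#' @param seed integer seed
#' @return list with `W` (n_hid x n_vis), `b` (visible bias), `c` (hidden
#'   bias).
#' @export
rbm_init <- function(n_vis, n_hid, seed = 1L) {
  with_seed(seed, {
    list(W = matrix(stats::rnorm(n_hid * n_vis, sd = 0.1), n_hid, n_vis),
         b = numeric(n_vis), c = numeric(n_hid))
  })
}

#' RBM joint energy
#'
#' E(v, h) = -b'v - c'h - h'Wv for a visible configuration v and hidden
#' configuration h. The joint probability is exp(-E)/Z with Z summing
#' exp(-E) over all configurations.
#'
#' @param params RBM parameters from [rbm_init()]
#' @param v visible vector
#' @param h hidden vector
#' @return Scalar energy.
#' @export
rbm_energy <- function(params, v, h) {
  v <- as.numeric(v); h <- as.numeric(h)
  if (length(v) != ncol(params$W) || length(h) != nrow(params$W)) {
    stop("shape mismatch between parameters and configuration")
  }
  -sum(params$b * v) - sum(params$c * h) - as.numeric(t(h) %*% params$W %*% v)
}

#' RBM free energy of a visible vector
#'
#' F(v) = -b'v - sum_j log(1 + exp(c_j + W_j v)), i.e. the hidden units
#' analytically summed out (binary hidden units).
#'
#' @inheritParams rbm_energy
#' @return Scalar free energy.
#' @export
rbm_free_energy <- function(params, v) {
  v <- as.numeric(v)
  if (length(v) != ncol(params$W)) stop("shape mismatch")
  act <- params$c + as.numeric(params$W %*% v)
  -sum(params$b * v) - sum(log1p(exp(act)))
}

#' One CD-1 contrastive-divergence update
#'
#' Performs a single Gibbs step from the data: hidden probabilities from
#' v, a sampled hidden state, a reconstruction (mean-field for Gaussian
#' visibles, sigmoid probabilities for Bernoulli), re-inferred hidden
#' probabilities, and a gradient step on the difference of positive and
#' negative statistics.
#'
#' @param params RBM parameters
#' @param v batch of visible rows (n x n_vis)
#' @param lr learning rate
#' @param seed integer seed for the hidden sampling
#' @param visible `"gaussian"` (unit-variance real visibles) or
#'   `"bernoulli"`
#' @return Updated parameter list; attribute `recon_error` holds the mean
#'   squared reconstruction error of the batch.
#' @export
rbm_cd_step <- function(params, v, lr = 0.01, seed = 1L,
                        visible = c("gaussian", "bernoulli")) {
  visible <- match.arg(visible)
  v <- as.matrix(v)
  if (ncol(v) != ncol(params$W)) stop("shape mismatch")
  n <- nrow(v)
  with_seed(seed, {
    h_prob <- 1 / (1 + exp(-(v %*% t(params$W) +
                               matrix(params$c, n, nrow(params$W), byrow = TRUE))))
    h_samp <- (matrix(stats::runif(length(h_prob)), n) < h_prob) * 1
    v_act <- h_samp %*% params$W +
      matrix(params$b, n, ncol(params$W), byrow = TRUE)
    v_rec <- if (visible == "gaussian") v_act else 1 / (1 + exp(-v_act))
    h_rec <- 1 / (1 + exp(-(v_rec %*% t(params$W) +
                              matrix(params$c, n, nrow(params$W), byrow = TRUE))))
    params$W <- params$W + lr * (t(h_prob) %*% v - t(h_rec) %*% v_rec) / n
    params$b <- params$b + lr * colMeans(v - v_rec)
    params$c <- params$c + lr * colMeans(h_prob - h_rec)
    attr(params, "recon_error") <- mean((v - v_rec)^2)
    params
  })
}

# Greedy layer-wise RBM pretraining; returns per-layer params and the
# propagated hidden representations.
.dbn_pretrain <- function(X, neurons, epochs, batch_size, seed) {
  rep_in <- X
  layers <- vector("list", length(neurons))
  for (l in seq_along(neurons)) {
    p <- rbm_init(ncol(rep_in), neurons[l], seed = derive_seed(seed, paste0("rbm_init", l)))
    vis <- if (l == 1) "gaussian" else "bernoulli"
    step_id <- 0L
    with_seed(derive_seed(seed, paste0("rbm_order", l)), {
      for (ep in seq_len(epochs)) {
        ord <- sample.int(nrow(rep_in))
        for (start in seq(1, nrow(rep_in), by = batch_size)) {
          idx <- ord[start:min(start + batch_size - 1, nrow(rep_in))]
          step_id <- step_id + 1L
          p <- rbm_cd_step(p, rep_in[idx, , drop = FALSE], lr = 0.05,
                           seed = derive_seed(seed, paste0("cd", l, "_", step_id)),
                           visible = vis)
        }
      }
    })
    layers[[l]] <- p
    rep_in <- 1 / (1 + exp(-(rep_in %*% t(p$W) +
                               matrix(p$c, nrow(rep_in), neurons[l], byrow = TRUE))))
  }
  layers
}

# ---------------------------------------------------------------------------
# Unified fit / predict contract

#' Fit a deep base learner
#'
#' Trains the learner family named in `spec` on a numeric feature matrix
#' and 3-class labels, minimizing softmax cross-entropy with Adam
#' (first-moment decay `spec$momentum_beta`) under seeded minibatch
#' shuffling, so training is fully deterministic for a fixed seed.
#'
#' Families: `dnn` is a fully connected ReLU stack; `lstm_rnn` is a stack
#' of LSTM cells (tabular rows enter as a single time step by default)
#' with a fully connected softmax head; `dbn` pretrains a sigmoid stack
#' greedily with CD-1 restricted Boltzmann machines (Gaussian visible
#' units on the standardized inputs, Bernoulli above) and then fine-tunes
#' the whole network by backpropagation.
#'
#' @param spec a [learner_spec()]
#' @param X numeric matrix (samples x features), no missing values
#' @param y 3-class factor
#' @param seed integer seed
#' @return A `trained_learner` with elements `spec`, `classes`, `net`,
#'   `params` and `loss_history` (one mean cross-entropy per epoch).
#' @export
fit_learner <- function(spec, X, y, seed = 1L) {
  stopifnot(inherits(spec, "learner_spec"))
  X <- as.matrix(X)
  if (anyNA(X)) stop("X must not contain missing values")
  y <- as.factor(y)
  classes <- levels(y)
  K <- length(classes)
  Y <- one_hot_labels(y, classes)
  D <- ncol(X)

  if (spec$family == "dnn") {
    net <- mlp_init(c(D, spec$neurons, K), act = "relu",
                    seed = derive_seed(seed, "dnn_init"))
    tr <- train_loop(net$params, X, Y, mlp_fb(net), spec$epochs,
                     spec$batch_size, spec$lr, spec$momentum_beta,
                     derive_seed(seed, "dnn_train"))
    model <- list(kind = "mlp", net = net, params = tr$params)
  } else if (spec$family == "lstm_rnn") {
    arch <- list(H = spec$neurons, input_mode = spec$input_mode)
    D_in <- if (spec$input_mode == "single_step") D else 1L
    params <- list()
    din <- D_in
    for (l in seq_along(arch$H)) {
      lp <- lstm_layer_init(din, arch$H[l],
                            seed = derive_seed(seed, paste0("lstm_init", l)))
      params[[paste0("W", l)]] <- lp$W
      params[[paste0("U", l)]] <- lp$U
      params[[paste0("b", l)]] <- lp$b
      din <- arch$H[l]
    }
    with_seed(derive_seed(seed, "lstm_head"), {
      params$Wout <- matrix(stats::rnorm(K * din, sd = sqrt(1 / din)), K, din)
      params$bout <- numeric(K)
    })
    # BPTT closure needs access to the per-layer caches of the forward
    # pass; wire it through an environment shared by fb calls.
    cache_env <- new.env(parent = emptyenv())
    fb <- local({
      arch_l <- arch
      function(params, Xb, Yb) {
        seqs <- .lstm_shape(Xb, arch_l$input_mode)
        fwd <- .lstm_stack_forward(params, arch_l, seqs)
        assign("caches", fwd$caches, envir = cache_env)
        .lstm_backward(params, arch_l, seqs, fwd, Yb)
      }
    })
    tr <- train_loop(params, X, Y, fb, spec$epochs, spec$batch_size,
                     spec$lr, spec$momentum_beta,
                     derive_seed(seed, "lstm_train"))
    model <- list(kind = "lstm", arch = arch, params = tr$params)
  } else { # dbn
    rbms <- .dbn_pretrain(X, spec$neurons,
                          epochs = spec$pretrain_epochs,
                          batch_size = spec$batch_size,
                          seed = derive_seed(seed, "dbn_pre"))
    net <- mlp_init(c(D, spec$neurons, K), act = "sigmoid",
                    seed = derive_seed(seed, "dbn_head"))
    for (l in seq_along(rbms)) {
      net$params[[paste0("W", l)]] <- rbms[[l]]$W
      net$params[[paste0("b", l)]] <- rbms[[l]]$c
    }
    tr <- train_loop(net$params, X, Y, mlp_fb(net), spec$epochs,
                     spec$batch_size, spec$lr, spec$momentum_beta,
                     derive_seed(seed, "dbn_train"))
    model <- list(kind = "mlp", net = net, params = tr$params, rbms = rbms)
  }

  structure(
    list(spec = spec, classes = classes, model = model,
         loss_history = tr$history, n_features = D),
    class = "trained_learner"
  )
}

# Full BPTT backward for the stacked LSTM (used inside fit_learner's fb).
.lstm_backward <- function(params, arch, seqs, fwd, Yb) {
  loss <- cross_entropy(fwd$probs, Yb)
  n <- nrow(Yb)
  Tlen <- length(seqs)
  dlogits <- (fwd$probs - Yb) / n
  grads <- list(Wout = -(t(dlogits) %*% fwd$hT), bout = -colSums(dlogits))
  dh_out <- vector("list", Tlen)
  dh_out[[Tlen]] <- dlogits %*% params$Wout
  for (l in rev(seq_along(arch$H))) {
    H <- arch$H[l]
    W <- params[[paste0("W", l)]]
    U <- params[[paste0("U", l)]]
    dW <- W * 0; dU <- U * 0; db <- numeric(4 * H)
    steps <- fwd$caches[[l]]
    dh_next <- matrix(0, n, H)
    dC_next <- matrix(0, n, H)
    dx_out <- vector("list", Tlen)
    for (t in rev(seq_len(Tlen))) {
      st <- steps[[t]]
      dh <- dh_next
      if (!is.null(dh_out[[t]])) dh <- dh + dh_out[[t]]
      tanhC <- tanh(st$C)
      do <- dh * tanhC
      dC <- dh * st$o * (1 - tanhC^2) + dC_next
      di <- dC * st$g
      dg <- dC * st$i
      df <- dC * st$C_prev
      dZ <- cbind(di * st$i * (1 - st$i),
                  df * st$f * (1 - st$f),
                  do * st$o * (1 - st$o),
                  dg * (1 - st$g^2))
      dW <- dW + t(dZ) %*% st$x
      dU <- dU + t(dZ) %*% st$h_prev
      db <- db + colSums(dZ)
      dx_out[[t]] <- dZ %*% W
      dh_next <- dZ %*% U
      dC_next <- dC * st$f
    }
    grads[[paste0("W", l)]] <- -dW
    grads[[paste0("U", l)]] <- -dU
    grads[[paste0("b", l)]] <- -db
    dh_out <- dx_out
  }
  list(loss = loss, grads = grads)
}

#' Class-probability predictions from a trained learner
#'
#' @param model a `trained_learner` from [fit_learner()]
#' @param X numeric matrix with the training feature width
#' @return Matrix (n x 3) of row-stochastic class probabilities, columns
#'   named by class.
#' @export
predict_proba <- function(model, X) {
  stopifnot(inherits(model, "trained_learner"))
  X <- as.matrix(X)
  if (ncol(X) != model$n_features) {
    stop("X has ", ncol(X), " features; model expects ", model$n_features)
  }
  probs <- if (model$model$kind == "mlp") {
    mlp_forward(model$model$net, model$model$params, X)$probs
  } else {
    seqs <- .lstm_shape(X, model$model$arch$input_mode)
    .lstm_stack_forward(model$model$params, model$model$arch, seqs)$probs
  }
  colnames(probs) <- model$classes
  probs
}

#' @export
print.trained_learner <- function(x, ...) {
  cat(sprintf("<trained_learner> %s [%s], final loss %.4f\n",
              x$spec$family, paste(x$spec$neurons, collapse = ","),
              utils::tail(x$loss_history, 1)))
  invisible(x)
}
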