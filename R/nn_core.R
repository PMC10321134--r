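# Minimal dense neural-network machinery shared by the deep base
# learners: numerically stable softmax / cross-entropy, Adam updates over
# arbitrary parameter lists, and a seeded minibatch training loop driven
# by a model-specific forward/backward closure.

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

one_hot_labels <- function(y, classes) {
  Y <- matrix(0, length(y), length(classes))
  Y[cbind(seq_along(y), match(as.character(y), classes))] <- 1
  Y
}

cross_entropy <- function(P, Y) {
  -mean(rowSums(Y * log(pmax(P, 1e-12))))
}

.act <- function(Z, kind) {
  switch(kind,
    relu = pmax(Z, 0),
    sigmoid = 1 / (1 + exp(-Z)),
    tanh = tanh(Z),
    linear = Z,
    stop("unknown activation: ", kind)
  )
}

.act_grad <- function(A, Z, kind) {
  switch(kind,
    relu = (Z > 0) * 1,
    sigmoid = A * (1 - A),
    tanh = 1 - A^2,
    linear = array(1, dim(Z)),
    stop("unknown activation: ", kind)
  )
}

# --- Adam -------------------------------------------------------------------

# `params` is a flat named list of numeric arrays; state tracks first and
# second moments per entry. beta1 is the configurable momentum term.
adam_new <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  for (k in names(params)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    mhat <- state$m[[k]] / (1 - beta1^t)
    vhat <- state$v[[k]] / (1 - beta2^t)
    params[[k]] <- params[[k]] + lr * mhat / (sqrt(vhat) + eps)  # ascent on -loss handled by caller sign
  }
  list(params = params, state = state)
}

# --- seeded minibatch loop --------------------------------------------------

# fb(params, Xb, Yb) must return list(loss = scalar, grads = named list
# matching params, already negated so that adam_step ascends -loss), i.e.
# grads = -dLoss/dparam.
train_loop <- function(params, X, Y, fb, epochs, batch_size, lr,
                       beta1, seed) {
  n <- nrow(X)
  state <- adam_new(params)
  history <- numeric(epochs)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      losses <- c()
      for (start in seq(1, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1, n)]
        out <- fb(params, X[idx, , drop = FALSE], Y[idx, , drop = FALSE])
        if (!is.finite(out$loss)) {
          stop("non-finite training loss at epoch ", ep)
        }
        losses <- c(losses, out$loss)
        upd <- adam_step(params, out$grads, state, lr, beta1 = beta1)
        params <- upd$params
        state <- upd$state
      }
      history[ep] <- mean(losses)
    }
  })
  list(params = params, history = history)
}

# --- multilayer perceptron --------------------------------------------------

# sizes = c(n_in, hidden..., n_classes); hidden activations uniform `act`.
mlp_init <- function(sizes, act = "relu", seed = 1L) {
  L <- length(sizes) - 1L
  params <- list()
  with_seed(seed, {
    for (l in seq_len(L)) {
      fan_in <- sizes[l]
      sc <- if (act == "relu") sqrt(2 / fan_in) else sqrt(1 / fan_in)
      params[[paste0("W", l)]] <- matrix(stats::rnorm(sizes[l + 1] * fan_in,
                                                      sd = sc),
                                         sizes[l + 1], fan_in)
      params[[paste0("b", l)]] <- numeric(sizes[l + 1])
    }
  })
  list(params = params, n_layers = L, act = act, sizes = sizes)
}

mlp_forward <- function(net, params, X) {
  L <- net$n_layers
  A <- list(t(X))  # columns = samples
  Zs <- list()
  for (l in seq_len(L)) {
    Z <- params[[paste0("W", l)]] %*% A[[l]] + params[[paste0("b", l)]]
    Zs[[l]] <- Z
    A[[l + 1]] <- if (l < L) .act(Z, net$act) else Z
  }
  probs <- softmax_rows(t(A[[L + 1]]))
  list(probs = probs, A = A, Z = Zs)
}

mlp_fb <- function(net) {
  force(net)
  function(params, Xb, Yb) {
    fwd <- mlp_forward(net, params, Xb)
    loss <- cross_entropy(fwd$probs, Yb)
    L <- net$n_layers
    n <- nrow(Xb)
    delta <- t(fwd$probs - Yb) / n   # K x n, dLoss/dZ_L
    grads <- list()
    for (l in rev(seq_len(L))) {
      grads[[paste0("W", l)]] <- -(delta %*% t(fwd$A[[l]]))
      grads[[paste0("b", l)]] <- -rowSums(delta)
      if (l > 1) {
        dA <- t(params[[paste0("W", l)]]) %*% delta
        delta <- dA * .act_grad(fwd$A[[l]], fwd$Z[[l - 1]], net$act)
      }
    }
    list(loss = loss, grads = grads)
  }
}
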