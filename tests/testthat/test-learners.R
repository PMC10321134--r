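test_that("learner specs enforce architecture bounds", {
  expect_error(learner_spec("dnn", neurons = c(0, 10)), "\\[1, 100\\]")
  expect_error(learner_spec("dnn", neurons = c(10, 101)), "\\[1, 100\\]")
  expect_error(learner_spec("dnn", neurons = integer(0)), "\\[1, 100\\]")
  s <- learner_spec("dbn", neurons = c(20, 5))
  expect_equal(s$n_hidden_layers, 2)
})

test_that("every family fits a separable toy and is seed-deterministic", {
  toy <- toy_separable(n_per_class = 50, shift = 4.5, seed = 31)
  # separability sanity: a linear reference classifier succeeds
  ref <- suppressWarnings(
    nnet_like <- e1071::svm(x = toy$X, y = toy$y, kernel = "linear")
  )
  expect_gt(mean(predict(ref, toy$X) == toy$y), 0.95)

  for (fam in c("dnn", "lstm_rnn", "dbn")) {
    spec <- fast_spec(fam, epochs = 120)
    m <- fit_learner(spec, toy$X, toy$y, seed = 5)
    p <- predict_proba(m, toy$X)
    acc <- mean(colnames(p)[max.col(p, ties.method = "first")] == toy$y)
    expect_gte(acc, 0.95)
    expect_true(all(is.finite(m$loss_history)))
    expect_length(m$loss_history, 120)
    # identical seed, identical loss trajectory
    m2 <- fit_learner(spec, toy$X, toy$y, seed = 5)
    expect_identical(m$loss_history, m2$loss_history)
  }
})

test_that("shuffled labels train to chance on held-out rows", {
  toy <- toy_separable(n_per_class = 40, seed = 32)
  set.seed(32)
  y_shuf <- sample(toy$y)
  tr <- 1:90; te <- 91:120
  for (fam in c("dnn", "dbn")) {
    m <- fit_learner(fast_spec(fam, epochs = 60), toy$X[tr, ], y_shuf[tr],
                     seed = 3)
    p <- predict_proba(m, toy$X[te, ])
    acc <- mean(colnames(p)[max.col(p, ties.method = "first")] == y_shuf[te])
    p_maj <- max(table(y_shuf[tr])) / length(tr)
    # within a generous binomial envelope of the majority rate
    expect_lt(acc, p_maj + 3 * sqrt(p_maj * (1 - p_maj) / length(te)))
  }
})

test_that("predicted probabilities are a softmax head over learned features", {
  toy <- toy_separable(n_per_class = 20, seed = 33)
  m <- fit_learner(fast_spec("dnn", neurons = 5, epochs = 10), toy$X, toy$y,
                   seed = 7)
  p <- predict_proba(m, toy$X)
  expect_lt(max(abs(rowSums(p) - 1)), 1e-6)
  expect_true(all(p >= 0))
  # duplicate inputs give identical rows
  p2 <- predict_proba(m, toy$X[c(1, 1), ])
  expect_identical(p2[1, ], p2[2, ])

  # hand-set final layer: probabilities equal a closed-form softmax
  hand <- m
  L <- hand$model$net$n_layers
  hand$model$params[[paste0("W", L)]][] <- 0
  hand$model$params[[paste0("b", L)]] <- c(1, 2, 3)
  ph <- predict_proba(hand, toy$X[1:4, ])
  expected <- exp(c(1, 2, 3)) / sum(exp(c(1, 2, 3)))
  for (i in 1:4) expect_equal(unname(ph[i, ]), expected, tolerance = 1e-12)
})

test_that("non-finite loss reports the epoch", {
  toy <- toy_separable(n_per_class = 10, seed = 34)
  spec <- learner_spec("dnn", neurons = 10, lr = 1e-2, epochs = 5)
  X_bad <- toy$X
  X_bad[1, 1] <- Inf   # drives the first softmax to NaN
  expect_error(fit_learner(spec, X_bad, toy$y, seed = 1), "epoch")
})

test_that("LSTM gating algebra holds and matches a reference recurrence", {
  set.seed(35)
  H <- 4; D <- 3; n <- 5
  cell <- list(W = matrix(rnorm(4 * H * D, sd = 0.3), 4 * H, D),
               U = matrix(rnorm(4 * H * H, sd = 0.3), 4 * H, H),
               b = rnorm(4 * H))
  x <- matrix(rnorm(n * D), n, D)
  h0 <- matrix(rnorm(n * H), n, H)
  C0 <- matrix(rnorm(n * H), n, H)

  out <- lstm_forward(cell, x, h0, C0)
  expect_true(all(out$i > 0 & out$i < 1))
  expect_true(all(out$f > 0 & out$f < 1))
  expect_true(all(out$o > 0 & out$o < 1))

  # forget and input gates forced shut -> cell state zero
  shut <- cell
  shut$b[(H + 1):(2 * H)] <- -1e9   # f -> 0
  shut$b[1:H] <- -1e9               # i -> 0
  shut$W[1:(2 * H), ] <- 0; shut$U[1:(2 * H), ] <- 0
  expect_equal(lstm_forward(shut, x, h0, C0)$C, C0 * 0)

  # forget gate open, input gate shut -> cell state carried through
  carry <- shut
  carry$b[(H + 1):(2 * H)] <- 1e9   # f -> 1
  expect_equal(lstm_forward(carry, x, h0, C0)$C, C0)

  # independent elementwise reference recurrence
  sig <- function(z) 1 / (1 + exp(-z))
  for (r in 1:n) {
    z <- as.numeric(cell$W %*% x[r, ] + cell$U %*% h0[r, ] + cell$b)
    i <- sig(z[1:H]); f <- sig(z[(H + 1):(2 * H)])
    o <- sig(z[(2 * H + 1):(3 * H)]); g <- tanh(z[(3 * H + 1):(4 * H)])
    C <- f * C0[r, ] + i * g
    h <- o * tanh(C)
    expect_equal(unname(out$C[r, ]), C, tolerance = 1e-10)
    expect_equal(unname(out$h[r, ]), h, tolerance = 1e-10)
  }
  expect_error(lstm_forward(cell, x[, 1:2], h0, C0), "shape")
})

test_that("RBM energies, exhaustive partition and CD learning behave", {
  # zero parameters: E(v, h) = 0 for every configuration
  p0 <- list(W = matrix(0, 2, 2), b = c(0, 0), c = c(0, 0))
  grid <- expand.grid(v1 = 0:1, v2 = 0:1, h1 = 0:1, h2 = 0:1)
  E0 <- apply(grid, 1, function(s) rbm_energy(p0, s[1:2], s[3:4]))
  expect_true(all(E0 == 0))

  # random 2x2 RBM: exp(-E)/Z sums to 1 over all 16 states
  set.seed(36)
  p <- list(W = matrix(rnorm(4), 2, 2), b = rnorm(2), c = rnorm(2))
  E <- apply(grid, 1, function(s) rbm_energy(p, s[1:2], s[3:4]))
  Z <- sum(exp(-E))
  expect_equal(sum(exp(-E) / Z), 1, tolerance = 1e-10)

  # free energy consistent with marginalizing h explicitly
  v <- c(1, 0)
  fe_enum <- -log(sum(exp(-apply(expand.grid(h1 = 0:1, h2 = 0:1), 1,
                                 function(h) rbm_energy(p, v, h)))))
  expect_equal(rbm_free_energy(p, v), fe_enum, tolerance = 1e-10)

  # CD-1 drives reconstruction error down on a 4-bit pattern set
  pats <- rbind(c(1, 0, 1, 0), c(0, 1, 0, 1), c(1, 1, 0, 0), c(0, 0, 1, 1))
  rb <- rbm_init(4, 6, seed = 1)
  errs <- numeric(200)
  for (s in 1:200) {
    rb <- rbm_cd_step(rb, pats, lr = 0.1, seed = s, visible = "bernoulli")
    errs[s] <- attr(rb, "recon_error")
  }
  expect_lt(mean(errs[181:200]), mean(errs[1:20]))
  expect_error(rbm_cd_step(rb, pats[, 1:3]), "shape")
})
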