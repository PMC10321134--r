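#' Big bang optimization algorithm (BBOA)
#'
#' A swarm metaheuristic in the particle-swarm family with three
#' additions: sinusoidal-chaotic-map dispersal of the initial population,
#' a linearly annealed ("adaptive") inertia weight, and strictly greedy
#' retention of personal and global bests. Designed for integer-valued
#' search boxes such as hidden-layer architecture grids, it maximizes an
#' arbitrary fitness function.
#'
#' @name bboa
NULL

#' Sinusoidal chaotic map sequence
#'
#' Iterates m[i] = a * m[i-1]^2 * sin(pi * m[i-1]) from `m0`, recording
#' each value before any scaling. With a near 2.3 and m0 in (0, 1) the
#' trajectory is chaotic in (0, 1), which disperses initial swarm
#' positions more evenly than iid draws.
#'
#' @param m0 initial value
#' @param a map constant (default 2.3)
#' @param length number of iterates to return
#' @return Numeric vector of `length` iterates (empty for `length = 0`).
#' @export
chaotic_sequence <- function(m0, a = 2.3, length = 1L) {
  length <- as.integer(length)
  if (length <= 0L) return(numeric(0))
  out <- numeric(length)
  m <- m0
  for (i in seq_len(length)) {
    m <- a * m^2 * sin(pi * m)
    out[i] <- m
  }
  out
}

#' BBOA configuration
#'
#' @param dims number of search dimensions
#' @param lower,upper per-dimension bounds (scalars are recycled); equal
#'   bounds pin a dimension to a single value
#' @param pop population size (galaxies; default 20)
#' @param T total iterations (default 100)
#' @param ef1,ef2 acceleration coefficients toward the personal and
#'   global bests (default 2.0 each)
#' @param w_s,w_e initial and final inertia weights (defaults 0.9, 0.4)
#' @param a chaotic-map constant (default 2.3)
#' @param vmax_frac velocity clamp as a fraction of each dimension's
#'   range (default 0.2)
#' @param integer_dims logical vector (recycled) marking dimensions that
#'   are rounded to integers (default TRUE: architecture search)
#' @param seed integer seed
#' @return A `bboa_config`.
#' @export
bboa_config <- function(dims, lower = 0, upper = 100, pop = 20L, T = 100L,
                        ef1 = 2, ef2 = 2, w_s = 0.9, w_e = 0.4, a = 2.3,
                        vmax_frac = 0.2, integer_dims = TRUE, seed = 1L) {
  lower <- rep_len(as.numeric(lower), dims)
  upper <- rep_len(as.numeric(upper), dims)
  integer_dims <- rep_len(as.logical(integer_dims), dims)
  if (any(lower > upper)) stop("lower bounds must not exceed upper bounds")
  stopifnot(pop >= 2, T >= 1, w_e > 0, w_e <= w_s)
  structure(
    list(dims = as.integer(dims), lower = lower, upper = upper,
         pop = as.integer(pop), T = as.integer(T), ef1 = ef1, ef2 = ef2,
         w_s = w_s, w_e = w_e, a = a, vmax_frac = vmax_frac,
         integer_dims = integer_dims, seed = as.integer(seed)),
    class = "bboa_config"
  )
}

#' Adaptive inertia weight
#'
#' w_w(t) = w_s - (w_s - w_e) * t / T: equals `w_s` at t = 0 and `w_e`
#' at t = T.
#'
#' @param t current iteration (0-based)
#' @param cfg a [bboa_config()]
#' @return Scalar inertia weight.
#' @export
bboa_inertia <- function(t, cfg) {
  cfg$w_s - (cfg$w_s - cfg$w_e) * t / cfg$T
}

.bboa_clamp <- function(x, cfg) {
  x <- pmin(pmax(x, cfg$lower), cfg$upper)
  x[cfg$integer_dims] <- round(x[cfg$integer_dims])
  x
}

.bboa_eval <- function(fitness_fn, positions) {
  vapply(seq_len(nrow(positions)), function(i) {
    f <- fitness_fn(positions[i, ])
    if (!is.numeric(f) || length(f) != 1L || !is.finite(f)) {
      stop("fitness function returned a non-finite value for galaxy ", i)
    }
    f
  }, numeric(1))
}

#' Initialize the BBOA swarm
#'
#' Chaotic states are seeded from random integers in \[0, 100\] (scaled
#' to (0, 1)), iterated through the sinusoidal map, and mapped affinely
#' into the search box; integer dimensions are rounded. Velocities start
#' at zero; personal and global bests are set from the initial fitness
#' evaluations.
#'
#' @param cfg a [bboa_config()]
#' @param fitness_fn function(position) -> finite scalar (maximized)
#' @return A `bboa_state`: positions, velocities, personal/global bests,
#'   iteration counter `t = 0` and best-fitness history.
#' @export
bboa_init <- function(cfg, fitness_fn) {
  stopifnot(inherits(cfg, "bboa_config"))
  pos <- matrix(0, cfg$pop, cfg$dims)
  with_seed(derive_seed(cfg$seed, "bboa_init"), {
    for (j in seq_len(cfg$pop)) {
      m0 <- sample.int(101L, 1L) - 1L          # integer in [0, 100]
      m <- chaotic_sequence(m0 / 100, a = cfg$a, length = cfg$dims)
      u <- abs(m) %% 1                          # fold into [0, 1)
      pos[j, ] <- cfg$lower + u * (cfg$upper - cfg$lower)
    }
  })
  pos <- t(pmin(pmax(t(pos), cfg$lower), cfg$upper))
  pos[, cfg$integer_dims] <- round(pos[, cfg$integer_dims])
  fit <- .bboa_eval(fitness_fn, pos)
  gb <- which.max(fit)
  structure(
    list(cfg = cfg, positions = pos, velocities = pos * 0,
         fitness = fit, pbest_pos = pos, pbest_fit = fit,
         gbest_pos = pos[gb, ], gbest_fit = fit[gb],
         t = 0L, history = fit[gb]),
    class = "bboa_state"
  )
}

#' One BBOA iteration
#'
#' Computes the annealed inertia weight for the current iteration,
#' updates each galaxy's velocity with fresh per-dimension uniform draws
#' on the attraction terms toward its personal best and the global best,
#' clamps velocities and positions (rounding integer dimensions),
#' re-evaluates fitness, and greedily updates personal and global bests
#' (replacement on strict improvement only), so the best-so-far history
#' is monotone non-decreasing.
#'
#' @param state a `bboa_state`
#' @param fitness_fn function(position) -> finite scalar
#' @return The advanced `bboa_state`.
#' @export
bboa_step <- function(state, fitness_fn) {
  stopifnot(inherits(state, "bboa_state"))
  cfg <- state$cfg
  if (state$t >= cfg$T) stop("swarm already ran for T iterations")
  ww <- bboa_inertia(state$t, cfg)
  vmax <- cfg$vmax_frac * (cfg$upper - cfg$lower)
  with_seed(derive_seed(cfg$seed, paste0("bboa_step", state$t)), {
    for (j in seq_len(cfg$pop)) {
      r1 <- stats::runif(cfg$dims)
      r2 <- stats::runif(cfg$dims)
      v <- ww * state$velocities[j, ] +
        cfg$ef1 * r1 * (state$pbest_pos[j, ] - state$positions[j, ]) +
        cfg$ef2 * r2 * (state$gbest_pos - state$positions[j, ])
      v <- pmin(pmax(v, -vmax), vmax)
      state$velocities[j, ] <- v
      state$positions[j, ] <- .bboa_clamp(state$positions[j, ] + v, cfg)
    }
  })
  state$fitness <- .bboa_eval(fitness_fn, state$positions)
  for (j in seq_len(cfg$pop)) {
    if (state$fitness[j] > state$pbest_fit[j]) {
      state$pbest_fit[j] <- state$fitness[j]
      state$pbest_pos[j, ] <- state$positions[j, ]
    }
  }
  best <- which.max(state$pbest_fit)
  if (state$pbest_fit[best] > state$gbest_fit) {
    state$gbest_fit <- state$pbest_fit[best]
    state$gbest_pos <- state$pbest_pos[best, ]
  }
  state$t <- state$t + 1L
  state$history <- c(state$history, state$gbest_fit)
  state
}

#' Run a full BBOA optimization
#'
#' @inheritParams bboa_init
#' @return list with `best_position`, `best_fitness` and `history`
#'   (best-so-far fitness, length T + 1 including initialization).
#' @export
bboa_optimize <- function(cfg, fitness_fn) {
  state <- bboa_init(cfg, fitness_fn)
  for (t in seq_len(cfg$T)) state <- bboa_step(state, fitness_fn)
  list(best_position = state$gbest_pos, best_fitness = state$gbest_fit,
       history = state$history, state = state)
}

# Decode a BBOA position into a learner architecture: position =
# [n_layers, neurons_1 .. neurons_Lmax]; unused layer slots are ignored.
decode_architecture <- function(position, L_max) {
  n_layers <- max(1L, min(L_max, as.integer(round(position[1]))))
  neurons <- pmin(100L, pmax(1L, as.integer(round(position[1 + seq_len(n_layers)]))))
  list(n_layers = n_layers, neurons = neurons)
}

#' Architecture search for the deep base learners
#'
#' Runs an independent BBOA per learner family over the space
#' `n_layers in [1, L_max]` x `neurons per layer in [1, 100]`. The
#' fitness of a position is the validation macro-F1 of the family
#' trained at a reduced epoch budget on the training split; positions
#' decoding to the same architecture are evaluated once (memoized).
#'
#' @param families character vector of families to optimize
#' @param X_train,y_train,X_val,y_val inner training / validation split
#' @param L_max maximum hidden-layer count (default 3)
#' @param epochs reduced epoch budget used during search (default 100)
#' @param pop,T swarm size and iterations (defaults 20 and 100; scale
#'   down for quick searches)
#' @param seed integer seed
#' @param base_spec template [learner_spec()] supplying the fixed
#'   hyperparameters
#' @param neuron_range inclusive bounds on neurons per layer (default
#'   `c(1, 100)`); equal values together with `L_max = 1` restrict the
#'   search space to a single architecture
#' @return Named list per family: `spec` (the winning [learner_spec()]),
#'   `fitness`, `history`, and `evaluations` (distinct architectures
#'   scored).
#' @export
search_architecture <- function(families = c("dnn", "lstm_rnn", "dbn"),
                                X_train, y_train, X_val, y_val,
                                L_max = 3L, epochs = 100L,
                                pop = 20L, T = 100L, seed = 1L,
                                base_spec = NULL,
                                neuron_range = c(1L, 100L)) {
  if (length(y_val) == 0) stop("validation split is empty")
  X_train <- as.matrix(X_train); X_val <- as.matrix(X_val)
  out <- list()
  for (fam in families) {
    cache <- new.env(parent = emptyenv())
    n_eval <- 0L
    fitness_fn <- function(position) {
      arch <- decode_architecture(position, L_max)
      key <- paste(arch$neurons, collapse = "-")
      if (!is.null(cache[[key]])) return(cache[[key]])
      spec <- learner_spec(
        family = fam, neurons = arch$neurons,
        lr = if (is.null(base_spec)) 1e-3 else base_spec$lr,
        batch_size = if (is.null(base_spec)) 20L else base_spec$batch_size,
        momentum_beta = if (is.null(base_spec)) 0.9 else base_spec$momentum_beta,
        epochs = epochs
      )
      m <- fit_learner(spec, X_train, y_train,
                       seed = derive_seed(seed, paste0("arch_", fam)))
      pr <- predict_proba(m, X_val)
      pred <- factor(colnames(pr)[max.col(pr, ties.method = "first")],
                     levels = levels(as.factor(y_val)))
      f1 <- macro_metrics(confusion(y_val, pred))$macro_F1
      n_eval <<- n_eval + 1L
      cache[[key]] <- f1
      f1
    }
    cfg <- bboa_config(
      dims = 1L + L_max,
      lower = c(1, rep(neuron_range[1], L_max)),
      upper = c(L_max, rep(neuron_range[2], L_max)),
      pop = pop, T = T, seed = derive_seed(seed, paste0("bboa_", fam))
    )
    res <- bboa_optimize(cfg, fitness_fn)
    arch <- decode_architecture(res$best_position, L_max)
    spec <- learner_spec(
      family = fam, neurons = arch$neurons,
      lr = if (is.null(base_spec)) 1e-3 else base_spec$lr,
      batch_size = if (is.null(base_spec)) 20L else base_spec$batch_size,
      momentum_beta = if (is.null(base_spec)) 0.9 else base_spec$momentum_beta,
      epochs = if (is.null(base_spec)) 1000L else base_spec$epochs
    )
    out[[fam]] <- list(spec = spec, fitness = res$best_fitness,
                       history = res$history, evaluations = n_eval)
  }
  out
}
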