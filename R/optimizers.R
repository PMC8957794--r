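# Population-based binary feature-subset search.
#
# All four algorithms share one framework: agents live in the continuous
# unit hypercube [0,1]^d, are binarized by a strict threshold into feature
# masks, and are scored by the cross-validated KNN fitness. The best
# mask/fitness ever seen is retained outside the population (elitism), so
# the best-so-far trace is monotone non-increasing by construction. A single
# seeded RNG stream drives initialization, update noise and restarts, making
# every run exactly reproducible.

#' Optimizer configuration
#'
#' @param algorithm one of `"sma"` (slime mould), `"pfa"` (pathfinder),
#'   `"hgso"` (Henry gas solubility), `"pso"` (particle swarm).
#' @param pop_size number of agents, default 10.
#' @param max_iter iteration budget (including the initial evaluation),
#'   default 100; convergence on omics matrices is typically reached well
#'   within a few dozen iterations.
#' @param seed integer seed for the run's RNG stream.
#' @param binarize_threshold continuous positions strictly above this value
#'   map to selected features; default 0.5.
#' @param params named list overriding algorithm constants, see
#'   [algorithm_params()].
#' @return an object of class `OptimizerConfig`.
#' @export
optimizer_config <- function(algorithm = c("sma", "pfa", "hgso", "pso"),
                             pop_size = 10, max_iter = 100, seed = 1,
                             binarize_threshold = 0.5, params = list()) {
  algorithm <- match.arg(algorithm)
  if (pop_size < 2) stop_validation("pop_size must be >= 2")
  if (max_iter < 1) stop_validation("max_iter must be >= 1")
  if (binarize_threshold <= 0 || binarize_threshold >= 1)
    stop_validation("binarize_threshold must be in (0, 1)")
  structure(list(algorithm = algorithm, pop_size = as.integer(pop_size),
                 max_iter = as.integer(max_iter), seed = as.integer(seed),
                 binarize_threshold = binarize_threshold,
                 params = utils::modifyList(algorithm_params(algorithm), params)),
            class = "OptimizerConfig")
}

#' Default algorithm constants
#'
#' Constants follow the recommendations of each algorithm's original
#' publication: SMA's random-restart probability `z`; PFA's attraction
#' coefficient ranges and unit perturbation ranges; HGSO's Henry/pressure/
#' temperature-rate initializer scales, solubility and influence constants,
#' and worst-fraction bounds; PSO's linearly decaying inertia, cognitive and
#' social coefficients, and velocity clamp.
#'
#' @param algorithm algorithm name.
#' @return named list of constants.
#' @export
algorithm_params <- function(algorithm) {
  switch(algorithm,
    sma = list(z = 0.03),
    pfa = list(alpha_range = c(1, 2), beta_range = c(1, 2),
               u_range = c(-1, 1)),
    hgso = list(n_clusters = 5, l1 = 5e-3, l2 = 100, l3 = 1e-2,
                K = 1, alpha = 1, beta_h = 1, epsilon = 0.05,
                c1 = 0.1, c2 = 0.2, t_ref = 298.15),
    pso = list(w_start = 0.9, w_end = 0.4, c1 = 2, c2 = 2, v_max = 0.6),
    stop_validation("unknown algorithm '%s'", algorithm)
  )
}

#' Binarize a continuous position into a feature mask
#'
#' Bit `i` is set iff `position[i] > threshold` (strictly). A position whose
#' mask would be empty is repaired by selecting the single largest
#' component, so every agent always encodes a valid non-empty subset.
#'
#' @param position numeric vector in `[0, 1]^d`.
#' @param threshold scalar in `(0, 1)`, default 0.5.
#' @return logical mask of the same length.
#' @export
binarize <- function(position, threshold = 0.5) {
  mask <- position > threshold
  if (!any(mask)) mask[which.max(position)] <- TRUE
  mask
}

clip01 <- function(X) {
  X[X < 0] <- 0
  X[X > 1] <- 1
  X
}

#' Run a swarm-intelligence feature-subset search
#'
#' Initializes `pop_size` positions uniformly in the unit hypercube, then
#' iterates the configured update rule, clipping positions to `[0,1]^d`,
#' binarizing them into masks, and evaluating the fitness of every agent.
#' The globally best mask and fitness are retained across iterations
#' (elitism), giving a monotone non-increasing convergence trace. Fitness
#' folds are drawn once from `fit_cfg$fold_seed` and reused for every
#' evaluation, so the objective is a deterministic function of the mask
#' within a run; evaluations are memoised by mask bits.
#'
#' @param m a [feature_matrix()] without missing values and with at least
#'   two classes.
#' @param fit_cfg a [fitness_config()].
#' @param opt_cfg an [optimizer_config()].
#' @param cache optional fitness cache environment shared across runs on the
#'   same data/configuration (see [new_fitness_cache()]).
#' @return an `OptRun`: list with `best_mask`, `best_fitness`, `trace`
#'   (best-so-far fitness per iteration, length `max_iter`),
#'   `trace_n_selected` (size of the best-so-far mask per iteration),
#'   `n_evaluations`, `seed`, `algorithm`, and `positions` (final population,
#'   for diagnostics).
#' @export
swarm_optimize <- function(m, fit_cfg = fitness_config(),
                           opt_cfg = optimizer_config("sma"),
                           cache = NULL) {
  stopifnot(inherits(m, "FeatureMatrix"))
  if (nlevels(droplevels(factor(m$labels))) < 2)
    stop_validation("optimization needs at least two classes")
  if (any(m$missing_mask))
    stop_validation("matrix still contains missing values; run drop_missing_features() first")
  d <- n_features(m)
  N <- opt_cfg$pop_size
  T_max <- opt_cfg$max_iter
  thr <- opt_cfg$binarize_threshold
  p <- opt_cfg$params
  folds <- fitness_folds(m, fit_cfg)
  cache <- cache %||% new_fitness_cache()

  eval_pop <- function(X) {
    apply(X, 1, function(pos)
      fitness(binarize(pos, thr), m, fit_cfg, folds = folds, cache = cache))
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(opt_cfg$seed)

  X <- matrix(stats::runif(N * d), N, d)
  fit <- eval_pop(X)
  best_i <- which.min(fit)
  best_fitness <- fit[best_i]
  best_pos <- X[best_i, ]
  best_mask <- binarize(best_pos, thr)
  trace <- numeric(T_max)
  trace_n <- integer(T_max)
  trace[1] <- best_fitness
  trace_n[1] <- sum(best_mask)

  # algorithm state
  V <- NULL; pbest_x <- NULL; pbest_f <- NULL       # pso
  path_prev <- NULL                                  # pfa
  hg <- NULL                                         # hgso
  if (opt_cfg$algorithm == "pso") {
    V <- matrix(0, N, d)
    pbest_x <- X
    pbest_f <- fit
  } else if (opt_cfg$algorithm == "pfa") {
    path_prev <- X[which.min(fit), ]
  } else if (opt_cfg$algorithm == "hgso") {
    if (p$n_clusters > N)
      stop_validation("hgso: n_clusters (%d) exceeds pop_size (%d)",
                      p$n_clusters, N)
    cluster <- rep(seq_len(p$n_clusters), length.out = N)
    cluster <- sort(cluster)  # contiguous equal blocks, fixed for the run
    hg <- list(cluster = cluster,
               H = p$l1 * stats::runif(p$n_clusters),
               P = p$l2 * stats::runif(N),
               C = p$l3 * stats::runif(p$n_clusters))
  }

  if (T_max > 1) for (t in 2:T_max) {
    X <- switch(opt_cfg$algorithm,
      sma = update_sma(X, fit, best_pos, best_fitness, t, T_max, p),
      pfa = {
        pf_i <- which.min(fit)
        upd <- update_pfa(X, fit, pf_i, path_prev, t, T_max, p)
        path_prev <- X[pf_i, ]
        upd
      },
      hgso = {
        upd <- update_hgso(X, fit, hg, best_pos, best_fitness, t, T_max, p)
        hg <- upd$state
        upd$X
      },
      pso = {
        upd <- update_pso(X, V, pbest_x, best_pos, t, T_max, p)
        V <- upd$V
        upd$X
      }
    )
    X <- clip01(X)
    fit <- eval_pop(X)
    if (opt_cfg$algorithm == "pso") {
      improved <- fit < pbest_f
      pbest_x[improved, ] <- X[improved, ]
      pbest_f[improved] <- fit[improved]
    }
    it_best <- which.min(fit)
    if (fit[it_best] < best_fitness) {
      best_fitness <- fit[it_best]
      best_pos <- X[it_best, ]
      best_mask <- binarize(best_pos, thr)
    }
    trace[t] <- best_fitness
    trace_n[t] <- sum(best_mask)
  }

  structure(list(best_mask = best_mask, best_fitness = best_fitness,
                 trace = trace, trace_n_selected = trace_n,
                 n_evaluations = N * T_max, seed = opt_cfg$seed,
                 algorithm = opt_cfg$algorithm, positions = X),
            class = "OptRun")
}

#' @export
print.OptRun <- function(x, ...) {
  cat(sprintf("OptRun [%s, seed %d]: best fitness %.6f, %d features selected, %d evaluations\n",
              x$algorithm, x$seed, x$best_fitness, sum(x$best_mask),
              x$n_evaluations))
  invisible(x)
}

#' Write a convergence trace to TSV
#'
#' Columns `iteration`, `best_fitness`, `n_selected`.
#'
#' @param run an `OptRun` from [swarm_optimize()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trace <- function(run, path) {
  df <- data.frame(iteration = seq_along(run$trace),
                   best_fitness = run$trace,
                   n_selected = run$trace_n_selected)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Update rules. Each consumes draws from the current RNG stream and returns
# new (unclipped) positions; the framework clips, binarizes and evaluates.

#' Slime mould algorithm position update
#'
#' With probability `z` an agent is reinitialized uniformly (random
#' restart). Otherwise its fitness-ranked weight `W` (log-scaled between the
#' iteration's best and worst fitness) steers a move either toward a blend
#' of the global best and two random agents, with oscillation factor
#' `vb ~ U(-a, a)`, `a = arctanh(1 - t/T)`, or a contraction `vc * x` with
#' `vc ~ U(-b, b)`, `b = 1 - t/T` shrinking linearly to zero.
#'
#' @param X positions (pop x d).
#' @param fit current fitness per agent.
#' @param best_pos,best_fit global best position and fitness.
#' @param t,T_max current iteration and horizon.
#' @param params list with element `z`.
#' @return new positions (unclipped).
#' @export
update_sma <- function(X, fit, best_pos, best_fit, t, T_max, params) {
  N <- nrow(X); d <- ncol(X)
  a <- atanh(max(1 - t / T_max, 1e-12))
  b <- 1 - t / T_max
  ord <- order(fit)
  bF <- fit[ord[1]]; wF <- fit[ord[N]]
  denom <- (bF - wF)
  W <- matrix(1, N, d)
  for (pos_in_rank in seq_len(N)) {
    i <- ord[pos_in_rank]
    r <- stats::runif(d)
    lg <- log10((bF - fit[i]) / (denom - 1e-12) + 1)
    W[i, ] <- if (pos_in_rank <= ceiling(N / 2)) 1 + r * lg else 1 - r * lg
  }
  Xn <- X
  for (i in seq_len(N)) {
    if (stats::runif(1) < params$z) {
      Xn[i, ] <- stats::runif(d)
    } else {
      pr <- tanh(abs(fit[i] - best_fit))
      vb <- stats::runif(d, -a, a)
      vc <- stats::runif(d, -b, b)
      # the two random agents are redrawn per dimension, which is what
      # gives the rule most of its exploratory power
      A <- sample.int(N, d, replace = TRUE)
      B <- sample.int(N, d, replace = TRUE)
      r <- stats::runif(d)
      j <- seq_len(d)
      move <- best_pos + vb * (W[i, ] * X[cbind(A, j)] - X[cbind(B, j)])
      stay <- vc * X[i, ]
      Xn[i, ] <- ifelse(r < pr, move, stay)
    }
  }
  Xn
}

#' Pathfinder algorithm position update
#'
#' The best agent (pathfinder) moves along its previous displacement with a
#' decaying random perturbation `u2 * exp(-2t/T)`; every follower is
#' attracted to a random neighbour (coefficient `alpha * r1`) and to the
#' pathfinder (coefficient `beta * r2`), plus a distance-scaled perturbation
#' `(1 - t/T) * u1 * ||x_i - x_j||` that vanishes at the horizon.
#'
#' @param X positions (pop x d).
#' @param fit current fitness per agent.
#' @param pathfinder_index row index of the current pathfinder.
#' @param pathfinder_prev the pathfinder's previous position.
#' @param t,T_max current iteration and horizon.
#' @param params list with `alpha_range`, `beta_range`, `u_range`.
#' @return new positions (unclipped).
#' @export
update_pfa <- function(X, fit, pathfinder_index, pathfinder_prev, t, T_max,
                       params) {
  N <- nrow(X); d <- ncol(X)
  pf <- X[pathfinder_index, ]
  Xn <- X
  u2 <- stats::runif(d, params$u_range[1], params$u_range[2])
  r3 <- stats::runif(d)
  Xn[pathfinder_index, ] <- pf + 2 * r3 * (pf - pathfinder_prev) +
    u2 * exp(-2 * t / T_max)
  decay <- 1 - t / T_max
  for (i in setdiff(seq_len(N), pathfinder_index)) {
    j <- sample(setdiff(seq_len(N), i), 1)
    alpha <- stats::runif(1, params$alpha_range[1], params$alpha_range[2])
    beta <- stats::runif(1, params$beta_range[1], params$beta_range[2])
    r1 <- stats::runif(d)
    r2 <- stats::runif(d)
    u1 <- stats::runif(d, params$u_range[1], params$u_range[2])
    dij <- sqrt(sum((X[i, ] - X[j, ])^2))
    Xn[i, ] <- X[i, ] + alpha * r1 * (X[j, ] - X[i, ]) +
      beta * r2 * (pf - X[i, ]) + decay * u1 * dij
  }
  Xn
}

#' Henry gas solubility optimization position update
#'
#' Agents are partitioned into gas-type clusters with per-cluster Henry
#' coefficients that decay under an exponential temperature schedule; each
#' agent's solubility scales its attraction to the global best, and a
#' fitness-ratio factor `gamma` scales attraction to its cluster best. A
#' uniformly drawn fraction (between `c1` and `c2`) of the worst agents is
#' reinitialized each iteration to escape local optima.
#'
#' @param X positions (pop x d).
#' @param fit current fitness per agent.
#' @param state list with `cluster`, `H`, `P`, `C` (see [swarm_optimize()]).
#' @param best_pos,best_fit global best position and fitness.
#' @param t,T_max current iteration and horizon.
#' @param params list with `K`, `alpha`, `beta_h`, `epsilon`, `c1`, `c2`,
#'   `t_ref`.
#' @return list with new positions `X` (unclipped) and updated `state`.
#' @export
update_hgso <- function(X, fit, state, best_pos, best_fit, t, T_max, params) {
  N <- nrow(X); d <- ncol(X)
  temp <- exp(-t / T_max)
  state$H <- state$H * exp(-state$C * (1 / temp - 1 / params$t_ref))
  S <- params$K * state$H[state$cluster] * state$P
  # cluster bests
  cb <- vapply(seq_along(state$H), function(cl) {
    members <- which(state$cluster == cl)
    members[which.min(fit[members])]
  }, integer(1))
  Xn <- X
  for (i in seq_len(N)) {
    gamma <- params$beta_h *
      exp(-(best_fit + params$epsilon) / (fit[i] + params$epsilon))
    Fdir <- if (stats::runif(1) < 0.5) -1 else 1
    r1 <- stats::runif(d)
    r2 <- stats::runif(d)
    xc <- X[cb[state$cluster[i]], ]
    Xn[i, ] <- X[i, ] +
      Fdir * r1 * gamma * (xc - X[i, ]) +
      Fdir * r2 * params$alpha * (S[i] * best_pos - X[i, ])
  }
  # reinitialize a random fraction of the worst agents
  frac <- params$c1 + stats::runif(1) * (params$c2 - params$c1)
  n_worst <- round(N * frac)
  if (n_worst > 0) {
    worst <- order(fit, decreasing = TRUE)[seq_len(n_worst)]
    Xn[worst, ] <- matrix(stats::runif(n_worst * d), n_worst, d)
  }
  list(X = Xn, state = state)
}

#' Particle swarm optimization update
#'
#' `v <- w(t) v + c1 r1 (pbest - x) + c2 r2 (gbest - x)` with the velocity
#' clamped to `[-v_max, v_max]`, then `x <- x + v`. The inertia `w(t)`
#' decays linearly from `w_start` to `w_end` across the run.
#'
#' @param X positions (pop x d).
#' @param V velocities (pop x d).
#' @param pbest_x per-particle best positions.
#' @param gbest_x global best position.
#' @param t,T_max current iteration and horizon.
#' @param params list with `w_start`, `w_end`, `c1`, `c2`, `v_max`.
#' @return list with new `X` (unclipped) and `V`.
#' @export
update_pso <- function(X, V, pbest_x, gbest_x, t, T_max, params) {
  N <- nrow(X); d <- ncol(X)
  w <- pso_inertia(t, T_max, params$w_start, params$w_end)
  R1 <- matrix(stats::runif(N * d), N, d)
  R2 <- matrix(stats::runif(N * d), N, d)
  V <- w * V + params$c1 * R1 * (pbest_x - X) +
    params$c2 * R2 * (sweep(matrix(0, N, d), 2, gbest_x, "+") - X)
  V[V > params$v_max] <- params$v_max
  V[V < -params$v_max] <- -params$v_max
  list(X = X + V, V = V)
}

#' Linearly decaying PSO inertia schedule
#'
#' @param t,T_max current iteration and horizon.
#' @param w_start,w_end endpoints of the schedule, defaults 0.9 and 0.4.
#' @return inertia weight at iteration `t` (`w_start` at `t = 1`, `w_end`
#'   at `t = T_max`).
#' @export
pso_inertia <- function(t, T_max, w_start = 0.9, w_end = 0.4) {
  if (T_max <= 1) return(w_start)
  w_start - (w_start - w_end) * (t - 1) / (T_max - 1)
}
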