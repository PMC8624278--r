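#' Optimiser configuration for EFE minimisation
#'
#' @param method `"nelder-mead"`, `"grid"` or `"both"`. Nelder-Mead
#'   multistart is the default workhorse; the iterative grid search is a
#'   robust cross-check for low-dimensional parameter spaces.
#' @param restarts Number of Nelder-Mead restarts (the first start is a
#'   data-driven heuristic, the rest are seeded uniform draws).
#' @param seed Master seed; all randomness in a fit derives from it.
#' @param max_evaluations Objective-evaluation budget per restart.
#' @param rel_tol Relative convergence tolerance ("improvement becomes
#'   tiny").
#' @param grid_points Grid points per axis for the iterative grid search.
#' @param grid_shrink Factor in (0, 1) by which the grid half-width shrinks
#'   after re-centering on the best point.
#' @param stall_iterations Successive grid iterations without relative
#'   improvement `>= rel_tol` before stopping.
#' @param maxit Nelder-Mead iteration cap per restart.
#' @param eps_tie Tie tolerance for accessible-set counts.
#' @param heuristic_start Use the data-driven first start (absolute node
#'   correlations for `R`, the gray scale for `U`).
#' @return A list of class `efe_control`.
#' @export
efe_control <- function(method = c("nelder-mead", "grid", "both"),
                        restarts = 32L, seed = 1L, max_evaluations = 2e5,
                        rel_tol = 1e-6, grid_points = 5L, grid_shrink = 0.5,
                        stall_iterations = 3L, maxit = 500L, eps_tie = 1e-9,
                        heuristic_start = TRUE) {
  method <- match.arg(method)
  stopifnot(restarts >= 1L, grid_shrink > 0, grid_shrink < 1, rel_tol > 0)
  structure(list(method = method, restarts = as.integer(restarts),
                 seed = as.integer(seed), max_evaluations = max_evaluations,
                 rel_tol = rel_tol, grid_points = as.integer(grid_points),
                 grid_shrink = grid_shrink,
                 stall_iterations = as.integer(stall_iterations),
                 maxit = as.integer(maxit), eps_tie = eps_tie,
                 heuristic_start = isTRUE(heuristic_start)),
            class = "efe_control")
}

clip01 <- function(x) pmin(1, pmax(0, x))

# deterministic per-restart seed substream (kept below 2^31)
restart_seed <- function(master, i) {
  as.integer((as.double(master) %% 2147483647 + i * 1000003) %% 2147483647)
}

#' Iterative grid search over the unit box
#'
#' Evaluates a full factorial grid, re-centres on the best point found,
#' shrinks the grid and repeats until the relative improvement over
#' several successive iterations falls below `rel_tol` or the evaluation
#' budget is spent. Practical for low dimensions only.
#'
#' @param objective Function of a numeric vector in `[0,1]^dimension`.
#' @param dimension Number of free parameters (`>= 1`).
#' @param control An [efe_control()].
#' @return List with `par`, `value`, `evaluations` and `converged`
#'   (`FALSE` means the budget was exhausted first).
#' @export
grid_search <- function(objective, dimension, control = efe_control()) {
  stopifnot(dimension >= 1)
  g <- control$grid_points
  if (g^dimension > 2^20) {
    stop("full grid of ", g, "^", dimension, " points is impractical; ",
         "use Nelder-Mead for this dimension")
  }
  centre <- rep(0.5, dimension)
  half <- 0.5
  best_par <- centre
  best_val <- objective(centre)
  evals <- 1
  stall <- 0L
  converged <- FALSE
  while (evals < control$max_evaluations) {
    axes <- lapply(seq_len(dimension), function(j) {
      unique(clip01(seq(centre[j] - half, centre[j] + half, length.out = g)))
    })
    pts <- as.matrix(do.call(expand.grid, c(axes, KEEP.OUT.ATTRS = FALSE)))
    vals <- apply(pts, 1L, objective)
    evals <- evals + nrow(pts)
    i <- which.min(vals)
    improvement <- (best_val - vals[i]) / max(abs(best_val), 1e-12)
    if (vals[i] < best_val) {
      best_val <- vals[i]
      best_par <- as.numeric(pts[i, ])
    }
    centre <- as.numeric(pts[i, ])
    half <- half * control$grid_shrink
    stall <- if (improvement < control$rel_tol) stall + 1L else 0L
    if (stall >= control$stall_iterations) {
      converged <- TRUE
      break
    }
  }
  list(par = best_par, value = best_val, evaluations = evals,
       converged = converged)
}

#' Multistart Nelder-Mead minimisation over the unit box
#'
#' Runs seeded Nelder-Mead restarts; proposals outside `[0,1]` are clipped
#' before evaluation. Returns the best of all restarts. Given the same
#' control (seed included) the result is bit-identical across runs, and the
#' first `k` restarts of a longer run coincide with a `k`-restart run, so
#' adding restarts never worsens the minimum.
#'
#' @inheritParams grid_search
#' @param starts Optional matrix of extra deterministic starting points
#'   (rows), tried before the random restarts.
#' @return List with `par`, `value`, `per_restart` (minimum of each
#'   restart), `evaluations` and `converged`.
#' @export
nelder_mead_min <- function(objective, dimension, control = efe_control(),
                            starts = NULL) {
  stopifnot(dimension >= 1)
  fn <- function(par) objective(clip01(par))
  n_det <- if (is.null(starts)) 0L else nrow(starts)
  per_restart <- numeric(0)
  best_par <- NULL
  best_val <- Inf
  evals <- 0
  converged <- TRUE
  for (i in seq_len(control$restarts)) {
    if (i <= n_det) {
      p0 <- clip01(as.numeric(starts[i, ]))
    } else {
      set.seed(restart_seed(control$seed, i))
      p0 <- stats::runif(dimension, 0.05, 0.95)
    }
    res <- stats::optim(p0, fn, method = "Nelder-Mead",
                        control = list(maxit = control$maxit,
                                       reltol = control$rel_tol))
    evals <- evals + res$counts[["function"]]
    per_restart <- c(per_restart, res$value)
    if (res$value < best_val) {
      best_val <- res$value
      best_par <- clip01(res$par)
    }
    if (evals >= control$max_evaluations * control$restarts) {
      converged <- FALSE
      break
    }
  }
  list(par = best_par, value = best_val, per_restart = per_restart,
       evaluations = as.numeric(evals), converged = converged)
}

# Deterministic coordinate-descent polish with shrinking step. The EFE
# objective is piecewise constant (float entropies are logs of integer
# counts), so simplex methods can stall on a plateau above the bottom
# step; axis moves with a geometric step ladder reliably walk off such
# plateaus and make independent runs settle on the same discrete optimum.
polish_coordinate <- function(objective, par, value,
                              steps = 0.2 * 0.5^(0:7), budget = 2e4) {
  evals <- 0
  for (step in steps) {
    repeat {
      improved <- FALSE
      for (j in seq_along(par)) {
        for (dir in c(-1, 1)) {
          cand <- par
          cand[j] <- min(1, max(0, cand[j] + dir * step))
          if (cand[j] == par[j]) next
          v <- objective(cand)
          evals <- evals + 1
          if (v < value) {
            value <- v
            par <- cand
            improved <- TRUE
          }
          if (evals >= budget) break
        }
        if (evals >= budget) break
      }
      if (!improved || evals >= budget) break
    }
    if (evals >= budget) break
  }
  list(par = par, value = value, evaluations = evals)
}

# Data-driven heuristic start built from level co-occurrence statistics:
# U0 is the normalised frequency with which two levels appear at the two
# ends of a node pair, and R0 scores each node pair by the U0-similarity
# of the level pairs it realises.
heuristic_par <- function(st, w, k, m) {
  one_hot <- lapply(seq_len(k), function(a) {
    I <- matrix(0, nrow(st), m)
    I[cbind(seq_len(nrow(st)), st[, a] + 1L)] <- 1
    I
  })
  pair_joint <- list()
  S <- matrix(0, m, m)
  for (a in seq_len(k - 1L)) {
    for (b in (a + 1L):k) {
      C <- crossprod(one_hot[[a]] * w, one_hot[[b]])
      C <- (C + t(C)) / 2
      pair_joint[[paste(a, b)]] <- C
      S <- S + C
    }
  }
  dS <- sqrt(pmax(diag(S), .Machine$double.eps))
  U0 <- matrix(clip01(S / outer(dS, dS)), m, m)
  diag(U0) <- 1
  R0 <- diag(1, k)
  for (a in seq_len(k - 1L)) {
    for (b in (a + 1L):k) {
      R0[a, b] <- R0[b, a] <- clip01(sum(pair_joint[[paste(a, b)]] * U0))
    }
  }
  c(R0[upper.tri(R0)], U0[upper.tri(U0)])
}

# Canonical gauge of a dataset. EFE is invariant under simultaneous level
# permutation (of U and the data) and node relabeling (of R and the
# data), so the fit is performed in a canonical gauge chosen from
# label-free statistics: levels ordered by (frequency, sorted
# co-occurrence profile), then nodes ordered by (level distribution,
# sorted agreement rates). Datasets that differ only by such relabelings
# map to the same canonical dataset and therefore receive the identical
# optimisation, making the fitted minimum exactly invariant.
canonical_gauge <- function(sub_states, weight, k, m) {
  freq <- vapply(0:(m - 1L), function(u) {
    sum(weight * rowSums(sub_states == u))
  }, 0) / k
  S <- matrix(0, m, m)
  if (k >= 2L) {
    for (a in 1:(k - 1L)) {
      for (b in (a + 1L):k) {
        cell <- sub_states[, a] * m + sub_states[, b] + 1L
        acc <- rowsum(weight, cell)
        flat <- numeric(m * m)
        flat[as.integer(rownames(acc))] <- acc[, 1]
        C <- matrix(flat, m, m, byrow = TRUE)
        S <- S + (C + t(C)) / 2
      }
    }
  }
  lev_key <- cbind(freq, t(apply(S, 1, sort, decreasing = TRUE)))
  ord_l <- do.call(order, as.data.frame(-lev_key))
  level_perm <- match(seq_len(m), ord_l) - 1L  # old level -> new level
  st2 <- matrix(level_perm[sub_states + 1L], ncol = k)
  marg <- t(vapply(seq_len(k), function(a) {
    vapply(0:(m - 1L), function(u) sum(weight[st2[, a] == u]), 0)
  }, numeric(m)))
  agree <- t(vapply(seq_len(k), function(a) {
    r <- vapply(seq_len(k), function(b) {
      if (a == b) return(NA_real_)
      sum(weight[st2[, a] == st2[, b]])
    }, 0)
    sort(r[!is.na(r)], decreasing = TRUE)
  }, numeric(max(k - 1L, 1L))))
  node_key <- cbind(marg, agree)
  ord_n <- do.call(order, as.data.frame(-node_key))
  list(level_perm = level_perm, node_order = ord_n)
}

# deterministic label-free seed for a fit, derived from the canonical
# data content
content_seed <- function(master, index, weight) {
  h <- sum((as.double(index) %% 9973) * (seq_along(index) %% 97)) %% 100003
  h <- (h + round(sum(weight * seq_along(weight)) * 1e6)) %% 100003
  restart_seed(master, h)
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    for (j in seq_len(nrow(sub))) {
      out[row, ] <- c(i, rest[sub[j, ]])
      row <- row + 1L
    }
  }
  out
}

# Exact EFE minimisation for a two-node context (m <= 4).
#
# With one node pair, d(f) = |r - U(f_1, f_2)|, so the state space splits
# into m(m-1)/2 off-diagonal level-pair groups (2 states each, d free in
# [0, max(r, 1-r)] through the U entry) and one diagonal group (m states
# tied at 1 - r). EFE depends only on the rank order of the group d
# values; merging groups (ties) only enlarges accessible sets, so the
# optimum is attained on a strict total order, and every total order is
# realisable. Enumerating all orders yields the global minimum exactly.
exact_pair_fit <- function(index, weight, m, nodes) {
  states <- enumerate_states(2, m = m)
  n_pairs <- m * (m - 1L) / 2L
  pair_id <- matrix(0L, m, m)
  pid <- 0L
  for (u in 1:(m - 1L)) {
    for (v in (u + 1L):m) {
      pid <- pid + 1L
      pair_id[u, v] <- pair_id[v, u] <- pid
    }
  }
  gid <- ifelse(states[, 1] == states[, 2], n_pairs + 1L,
                pair_id[cbind(states[, 1] + 1L, states[, 2] + 1L)])
  n_g <- n_pairs + 1L
  w_state <- numeric(nrow(states))
  w_state[index] <- weight
  w_g <- as.numeric(rowsum(w_state, gid))
  size_g <- as.numeric(rowsum(rep(1, nrow(states)), gid))
  perms <- all_permutations(n_g)
  best_val <- Inf
  best_perm <- NULL
  for (i in seq_len(nrow(perms))) {
    p <- perms[i, ]
    val <- sum(w_g[p] * log2(cumsum(size_g[p])))
    if (val < best_val) {
      best_val <- val
      best_perm <- p
    }
  }
  rank_g <- match(seq_len(n_g), best_perm)  # rank of each group
  v_target <- 0.04 * rank_g                 # distinct, well separated
  r <- 1 - v_target[n_g]                    # diagonal group sits at 1 - r
  U <- diag(1, m)
  for (u in 1:(m - 1L)) {
    for (v in (u + 1L):m) {
      U[u, v] <- U[v, u] <- r - v_target[pair_id[u, v]]
    }
  }
  list(model = primary_model(make_relation(nodes, r),
                             make_relation(as.character(0:(m - 1L)),
                                           U[upper.tri(U)])),
       value = best_val)
}

#' Fit a primary relational model by EFE minimisation
#'
#' The central fitting function: searches the space of primary models
#' (reflexive symmetric weight matrices `R` over the nodes and `U` over the
#' levels, free parameters in `[0,1]`) for the pair minimising the expected
#' float entropy of the data. The objective is a step function of the
#' parameters (float entropies are logs of integer counts), so derivative-
#' free search with multistart is used; the attainable objective values
#' form a discrete set, which is why independent successful runs agree
#' exactly.
#'
#' @param data An `efe_obs` or `efe_distribution`.
#' @param nodes Optional subsystem to fit (data is restricted onto it).
#' @param control An [efe_control()].
#' @return An object of class `efe_fit` with components `model`
#'   (the fitted [primary_model()]), `efe_min` (bits), `evaluations`,
#'   `per_restart`, `converged`, `degenerate` (single distinct observed
#'   state: the minimiser is non-unique), `spec`, `control` and `call`.
#' @examples
#' obs <- observations(rbind(c(0, 0), c(1, 1)), efe_system(2, 2))
#' fit <- efe_fit(obs, control = efe_control(restarts = 4, seed = 1))
#' fit$efe_min
#' @export
efe_fit <- function(data, nodes = NULL, control = efe_control()) {
  cl <- match.call()
  if (!is.null(nodes)) {
    data <- if (inherits(data, "efe_obs")) restrict_observations(data, nodes)
            else marginalize(data, nodes)
  }
  spec <- data$spec
  k <- length(spec$nodes)
  m <- spec$m
  if (inherits(data, "efe_obs")) {
    agg <- aggregate_observations(data)
    index <- agg$index; weight <- agg$weight
  } else {
    index <- which(data$p > 0); weight <- data$p[index]
  }
  states <- enumerate_states(spec)
  eps <- control$eps_tie
  degenerate <- length(index) == 1L

  if (k == 1L) {
    # no off-diagonal node pairs: every state has zero discontinuity, the
    # accessible set is the whole state space and efe = log2 m exactly
    model <- primary_model(make_relation(spec$nodes, numeric(0)),
                           gray_relation(m))
    out <- list(model = model, efe_min = log2(m), evaluations = 0,
                per_restart = numeric(0), converged = TRUE,
                degenerate = degenerate, closed_form = TRUE, spec = spec,
                control = control, call = cl)
    class(out) <- "efe_fit"
    return(out)
  }

  objective <- function(par) {
    mod <- par_to_model(par, spec$nodes, m)
    efe_eval_cpp(states, mod$R, mod$U, index - 1L, weight, eps)
  }

  if (k == 2L && m <= 4L) {
    # single node pair: solved exactly by rank enumeration
    ex <- exact_pair_fit(index, weight, m, spec$nodes)
    efe_min <- objective(model_to_par(ex$model))
    out <- list(model = ex$model, efe_min = efe_min,
                evaluations = factorial(m * (m - 1L) / 2L + 1L),
                per_restart = numeric(0), converged = TRUE,
                degenerate = degenerate, closed_form = TRUE, spec = spec,
                control = control, call = cl)
    class(out) <- "efe_fit"
    return(out)
  }

  dimension <- k * (k - 1L) / 2L + m * (m - 1L) / 2L

  # fit in the canonical gauge: relabelled datasets receive the identical
  # optimisation, so fitted minima are exactly relabeling-invariant
  sub_states <- states[index, , drop = FALSE]
  gauge <- canonical_gauge(sub_states, weight, k, m)
  st_c <- matrix(gauge$level_perm[sub_states + 1L],
                 ncol = k)[, gauge$node_order, drop = FALSE]
  index_c <- state_index(st_c, m)
  o <- order(index_c)
  index_c <- index_c[o]
  weight_c <- weight[o]
  st_c <- st_c[o, , drop = FALSE]
  dummy_nodes <- paste0("n", seq_len(k))
  objective_c <- function(par) {
    efe_eval_par_cpp(states, par, k, m, index_c - 1L, weight_c, eps)
  }

  # small parameter spaces are cheap to evaluate: spend extra restarts on
  # them, where the step landscape is proportionally more multimodal
  ctl <- control
  ctl$seed <- content_seed(control$seed, index_c, weight_c)
  if (dimension <= 10L) {
    ctl$restarts <- control$restarts * 4L
  } else if (dimension <= 14L) {
    ctl$restarts <- control$restarts * 2L
  }

  starts <- if (control$heuristic_start) {
    matrix(heuristic_par(st_c, weight_c, k, m), nrow = 1)
  } else NULL

  # Each restart runs a full pipeline: Nelder-Mead, then alternating
  # coordinate polish and simplex refinement until stable. The piecewise-
  # constant objective needs both to settle on its bottom step, and which
  # start polishes lowest is not predictable from its pre-polish value, so
  # polishing happens per restart, not only on the pre-polish winner. The
  # final value is a minimum over independent deterministic per-restart
  # pipelines, hence monotone non-increasing in the restart count.
  fn <- function(p) objective_c(clip01(p))
  pipeline_evals <- 0
  pipeline <- function(p0) {
    nm <- stats::optim(p0, fn, method = "Nelder-Mead",
                       control = list(maxit = ctl$maxit,
                                      reltol = ctl$rel_tol))
    evals <- nm$counts[["function"]]
    cur_par <- clip01(nm$par)
    cur_val <- nm$value
    for (cycle in 1:4) {
      pol <- polish_coordinate(objective_c, cur_par, cur_val)
      evals <- evals + pol$evaluations
      improved <- pol$value < cur_val - 1e-12
      cur_par <- pol$par
      cur_val <- pol$value
      nm2 <- stats::optim(cur_par, fn, method = "Nelder-Mead",
                          control = list(maxit = ctl$maxit,
                                         reltol = ctl$rel_tol))
      evals <- evals + nm2$counts[["function"]]
      if (nm2$value < cur_val - 1e-12) {
        cur_val <- nm2$value
        cur_par <- clip01(nm2$par)
        improved <- TRUE
      }
      if (!improved) break
    }
    pipeline_evals <<- pipeline_evals + evals
    list(par = cur_par, value = cur_val)
  }

  per_restart <- numeric(0)
  best_par <- NULL
  best_val <- Inf
  converged <- TRUE
  if (control$method %in% c("nelder-mead", "both")) {
    n_det <- if (is.null(starts)) 0L else nrow(starts)
    for (i in seq_len(ctl$restarts)) {
      if (i <= n_det) {
        p0 <- clip01(as.numeric(starts[i, ]))
      } else {
        set.seed(restart_seed(ctl$seed, i))
        p0 <- stats::runif(dimension, 0.05, 0.95)
      }
      res_i <- pipeline(p0)
      per_restart <- c(per_restart, res_i$value)
      if (res_i$value < best_val) {
        best_val <- res_i$value
        best_par <- res_i$par
      }
      if (pipeline_evals >= ctl$max_evaluations * ctl$restarts) {
        converged <- FALSE
        break
      }
    }
  }
  if (control$method %in% c("grid", "both")) {
    gr <- grid_search(objective_c, dimension, ctl)
    res_g <- pipeline(gr$par)
    pipeline_evals <- pipeline_evals + gr$evaluations
    converged <- converged && gr$converged
    if (res_g$value < best_val) {
      best_val <- res_g$value
      best_par <- res_g$par
    }
  }
  extra_evals <- pipeline_evals
  cur_par <- best_par
  # map the canonical-gauge model back to the original labels
  model_c <- par_to_model(cur_par, dummy_nodes, m)
  node_rank <- match(seq_len(k), gauge$node_order)
  R_o <- model_c$R[node_rank, node_rank]
  dimnames(R_o) <- list(spec$nodes, spec$nodes)
  U_o <- model_c$U[gauge$level_perm + 1L, gauge$level_perm + 1L]
  dimnames(U_o) <- list(0:(m - 1L), 0:(m - 1L))
  model <- primary_model(R_o, U_o)
  efe_min <- objective(model_to_par(model))  # re-evaluate at the final model
  out <- list(model = model, efe_min = efe_min,
              evaluations = extra_evals,
              per_restart = per_restart,
              converged = converged,
              degenerate = degenerate, closed_form = FALSE, spec = spec,
              control = control, call = cl)
  class(out) <- "efe_fit"
  out
}

#' @export
print.efe_fit <- function(x, ...) {
  cat("EFE-minimising primary model\n")
  cat("  system: ", length(x$spec$nodes), " nodes, ", x$spec$m, " levels\n",
      sep = "")
  cat("  efe_min: ", format(x$efe_min, digits = 6), " bits",
      if (x$closed_form) " (closed form)", "\n", sep = "")
  if (x$degenerate) cat("  note: single distinct observed state;",
                        "the minimiser is not unique\n")
  invisible(x)
}

#' @export
summary.efe_fit <- function(object, ...) {
  cat("EFE minimisation over ", length(model_to_par(object$model)),
      " free parameters\n", sep = "")
  print(object)
  cat("  evaluations: ", object$evaluations,
      "; converged: ", object$converged, "\n", sep = "")
  if (length(object$per_restart)) {
    cat("  restart minima: ",
        paste(format(sort(object$per_restart)[seq_len(min(5, length(object$per_restart)))],
                     digits = 6), collapse = ", "),
        if (length(object$per_restart) > 5) ", ...", "\n", sep = "")
  }
  cat("R:\n"); print(round(object$model$R, 4))
  cat("U:\n"); print(round(object$model$U, 4))
  invisible(object)
}

#' @export
coef.efe_fit <- function(object, ...) {
  p <- model_to_par(object$model)
  k <- length(object$spec$nodes); m <- object$spec$m
  pair_names <- function(nms) {
    g <- expand.grid(a = seq_along(nms), b = seq_along(nms))
    g <- g[g$a < g$b, ]
    g <- g[order(g$b, g$a), ]  # column-major upper triangle
    paste(nms[g$a], nms[g$b], sep = ":")
  }
  names(p) <- c(if (k > 1) paste0("R.", pair_names(object$spec$nodes)),
                paste0("U.", pair_names(as.character(0:(m - 1)))))
  p
}

#' Float entropy of observations under a fitted model
#'
#' @param object An `efe_fit`.
#' @param newdata An `efe_obs` over the fitted system (defaults to nothing;
#'   required).
#' @param ... Unused.
#' @return Numeric vector of per-observation float entropies in bits.
#' @export
predict.efe_fit <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "efe_obs"))
  profile <- discontinuity_profile(object$model, object$spec)
  idx <- state_index(newdata$states, object$spec$m)
  counts <- findInterval(profile$d[idx] + object$control$eps_tie,
                         profile$sorted_d)
  log2(counts)
}

#' @export
plot.efe_fit <- function(x, ...) {
  plot_model_graph(x$model, ...)
  invisible(x)
}

#' EFE landscape histogram
#'
#' Evaluates the EFE of the data at uniformly sampled primary models. The
#' gap between the mean and the minimum measures how strongly the data
#' determine their optimal model: structured data produce a minimum well
#' separated from typical models, while unstructured data do not. The
#' all-ones-`U` reference value `log2 |Omega|` (the maximum-entropy model)
#' is included.
#'
#' @param data An `efe_obs` or `efe_distribution`.
#' @param n_random Number of random models.
#' @param seed Seed for the model draws.
#' @param nodes Optional subsystem.
#' @param breaks Passed to [graphics::hist()] binning (computed, not drawn).
#' @param eps_tie Tie tolerance.
#' @return An object of class `efe_histogram` with `values`, `min`, `mean`,
#'   `sd`, `reference` (`log2 |Omega|`) and `histogram` (a `histogram`
#'   object).
#' @export
efe_histogram <- function(data, n_random = 200L, seed = 1L, nodes = NULL,
                          breaks = "Sturges", eps_tie = 1e-9) {
  stopifnot(n_random >= 1L)
  if (!is.null(nodes)) {
    data <- if (inherits(data, "efe_obs")) restrict_observations(data, nodes)
            else marginalize(data, nodes)
  }
  spec <- data$spec
  k <- length(spec$nodes); m <- spec$m
  dimension <- k * (k - 1L) / 2L + m * (m - 1L) / 2L
  set.seed(seed)
  vals <- vapply(seq_len(n_random), function(i) {
    mod <- par_to_model(stats::runif(dimension), spec$nodes, m)
    efe(mod, data, eps_tie = eps_tie)
  }, 0)
  h <- graphics::hist(vals, breaks = breaks, plot = FALSE)
  structure(list(values = vals, min = min(vals), mean = mean(vals),
                 sd = stats::sd(vals),
                 reference = length(spec$nodes) * log2(m),
                 histogram = h, n_random = n_random, seed = seed),
            class = "efe_histogram")
}

#' @export
print.efe_histogram <- function(x, ...) {
  cat("EFE over ", x$n_random, " random models: min ",
      format(x$min, digits = 6), ", mean ", format(x$mean, digits = 6),
      ", sd ", format(x$sd, digits = 4), " bits\n", sep = "")
  cat("  maximum-entropy reference (all-ones U): ", x$reference, " bits\n",
      sep = "")
  cat("  model-determination gap (mean - min): ",
      format(x$mean - x$min, digits = 6), " bits\n", sep = "")
  invisible(x)
}

#' @export
plot.efe_histogram <- function(x, main = "EFE landscape", ...) {
  graphics::plot(x$histogram, main = main, xlab = "EFE (bits)", ...)
  graphics::abline(v = x$min, col = "red", lwd = 2)
  graphics::abline(v = x$reference, col = "grey40", lty = 2)
  invisible(x)
}
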