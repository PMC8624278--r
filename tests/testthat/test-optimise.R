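test_that("grid search localises simple minima and terminates on plateaus", {
  ctl <- efe_control(grid_points = 5)
  res <- grid_search(function(p) (p[1] - 0.3)^2, 1, ctl)
  expect_lt(abs(res$par - 0.3), 1e-4)
  expect_true(res$converged)
  # constant objective: terminates via the stall rule
  res2 <- grid_search(function(p) 1, 2, ctl)
  expect_equal(res2$value, 1)
  expect_true(res2$converged)
  expect_error(grid_search(function(p) 0, 25, ctl), "impractical")
})

test_that("Nelder-Mead multistart finds a 5-d quadratic bowl", {
  target <- c(0.2, 0.4, 0.6, 0.8, 0.5)
  obj <- function(p) sum((p - target)^2)
  ctl <- efe_control(restarts = 4, seed = 3, rel_tol = 1e-10, maxit = 2000)
  res <- nelder_mead_min(obj, 5, ctl)
  expect_lt(max(abs(res$par - target)), 1e-4)
  # determinism: identical control gives bit-identical restart minima
  res2 <- nelder_mead_min(obj, 5, ctl)
  expect_identical(res$per_restart, res2$per_restart)
  # adding restarts never increases the minimum (nested seed streams)
  res8 <- nelder_mead_min(obj, 5, efe_control(restarts = 8, seed = 3,
                                              rel_tol = 1e-10, maxit = 2000))
  expect_identical(res8$per_restart[1:4], res$per_restart)
  expect_lte(res8$value, res$value)
})

test_that("the two-state corpus is fitted to exactly one bit", {
  spec <- efe_system(2, 2)
  obs <- observations(rbind(c(0, 0), c(1, 1)), spec)
  fit <- efe_fit(obs, control = efe_control(restarts = 6, seed = 2))
  expect_equal(fit$efe_min, 1, tolerance = 1e-9)
  # grid search and Nelder-Mead agree on the same 2-d objective
  objective <- function(p) {
    efe(primary_model(make_relation(2, p[1]), make_relation(2, p[2])), obs)
  }
  ctl <- efe_control(restarts = 6, seed = 2, grid_points = 5)
  gs <- grid_search(objective, 2, ctl)
  nm <- nelder_mead_min(objective, 2, ctl)
  expect_lt(abs(gs$value - nm$value), 1e-6)
  expect_equal(gs$value, 1, tolerance = 1e-6)
  # exhaustive 0.01-step scan of the 2-d space as independent oracle
  grid_vals <- seq(0, 1, by = 0.01)
  best <- Inf
  for (r in grid_vals) {
    R <- make_relation(2, r)
    for (u in grid_vals) {
      v <- oracle_efe(R, make_relation(2, u), obs$states, 2)
      if (v < best) best <- v
    }
  }
  expect_lt(abs(fit$efe_min - best), 1e-3)
  # self-consistency: efe of the returned model reproduces efe_min
  expect_equal(efe(fit$model, obs), fit$efe_min, tolerance = 1e-12)
})

test_that("singleton systems are fitted in closed form", {
  obs <- observations(matrix(c(0L, 1L, 3L, 3L), ncol = 1),
                      efe_system("solo", 4))
  fit <- efe_fit(obs)
  expect_equal(fit$efe_min, 2)
  expect_true(fit$closed_form)
})

test_that("degenerate single-state data is flagged and fitted", {
  obs <- observations(rbind(c(0, 1), c(0, 1)), efe_system(2, 2))
  fit <- efe_fit(obs, control = efe_control(restarts = 3, seed = 1))
  expect_true(fit$degenerate)
  expect_gte(fit$efe_min, 0)
})

test_that("fit accessors expose parameters and per-state predictions", {
  obs <- gen_smooth_corpus(n_obs = 40, seed = 14)
  fit <- efe_fit(obs, nodes = obs$spec$nodes[1:2],
                 control = efe_control(restarts = 3, seed = 5))
  cf <- coef(fit)
  expect_length(cf, 1 + 6)  # one node pair + six level pairs
  expect_true(all(cf >= 0 & cf <= 1))
  expect_match(names(cf)[1], "^R\\.")
  sub <- restrict_observations(obs, obs$spec$nodes[1:2])
  pr <- predict(fit, sub)
  expect_length(pr, n_obs(sub))
  expect_true(all(pr >= 0 & pr <= log2(16)))
  expect_equal(mean(pr), fit$efe_min, tolerance = 1e-9)
})

test_that("the EFE histogram separates structured from shuffled data", {
  obs <- gen_smooth_corpus(n_obs = 120, seed = 8)
  h <- efe_histogram(obs, n_random = 60, seed = 4)
  expect_gte(h$mean, h$min)
  expect_equal(h$reference, 12)
  # shuffle each column independently: destroys inter-node structure
  set.seed(99)
  shuf <- apply(obs$states, 2, sample)
  h2 <- efe_histogram(observations(shuf, obs$spec), n_random = 60, seed = 4)
  expect_gt(h$mean - h$min, h2$mean - h2$min)
})
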