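test_that("Bell numbers and partition enumeration agree", {
  expect_equal(bell_number(1), 1)
  expect_equal(bell_number(4), 15)
  expect_equal(bell_number(6), 203)
  expect_length(enumerate_partitions(2), 1)
  expect_length(enumerate_partitions(4), 14)
  expect_length(enumerate_partitions(6), 202)
  for (n in 2:8) {
    expect_length(enumerate_partitions(n), bell_number(n) - 1)
  }
  # blocks disjoint, covering, never the whole set
  parts <- enumerate_partitions(c("a", "b", "c", "d"))
  for (p in parts) {
    expect_gte(length(p), 2)
    expect_setequal(unlist(p), c("a", "b", "c", "d"))
    expect_equal(anyDuplicated(unlist(p)), 0)
  }
  expect_error(enumerate_partitions(1), "2..12")
})

test_that("mu of the two-state corpus matches the closed form", {
  spec <- efe_system(2, 2)
  obs <- observations(rbind(c(0, 0), c(1, 1)), spec)
  ctl <- efe_control(restarts = 5, seed = 7)
  cache <- new.env(parent = emptyenv())
  # singleton efe_min = log2 2 each, whole-system efe_min = 1 bit
  val <- mu(list("node_1", "node_2"), obs, control = ctl, cache = cache)
  expect_equal(val, 1, tolerance = 1e-9)
})

test_that("the all-singleton partition has mu = n log2 m - efe_min >= 0", {
  obs <- gen_smooth_corpus(n_obs = 60, seed = 3)
  ctl <- efe_control(restarts = 3, seed = 5, maxit = 300)
  cache <- new.env(parent = emptyenv())
  singletons <- as.list(obs$spec$nodes)
  val <- mu(singletons, obs, control = ctl, cache = cache)
  whole_key <- efeunity:::subsystem_key(obs$spec$nodes)
  efe_whole <- cache[[whole_key]]$efe_min
  expect_equal(val, 6 * 2 - efe_whole, tolerance = 1e-12)
  expect_gte(val, 0)
})

test_that("mu equals the accessible-set ratio identity on explicit systems", {
  ctl <- efe_control(restarts = 4, seed = 11, maxit = 400)
  battery <- list(
    gen_explicit_distribution("two_state", efe_system(2, 2)),
    gen_explicit_distribution("uniform", efe_system(3, 2)),
    {
      set.seed(41)
      p <- runif(8); distribution(p / sum(p), efe_system(3, 2))
    },
    {
      set.seed(42)
      p <- runif(9); distribution(p / sum(p), efe_system(2, 3))
    },
    {
      set.seed(43)
      p <- runif(16); distribution(p / sum(p), efe_system(4, 2))
    })
  for (P in battery) {
    rep <- unity_analysis(P, control = ctl, lemma1 = FALSE)
    for (i in seq_along(rep$partitions)) {
      expect_equal(mu_ratio(rep, i), unname(rep$mu[i]), tolerance = 1e-9)
    }
  }
})

test_that("point-mass mu reduces to a single log ratio", {
  spec <- efe_system(3, 2)
  P <- gen_explicit_distribution("point", spec, state = c(0, 1, 1))
  rep <- unity_analysis(P, control = efe_control(restarts = 3, seed = 2),
                        lemma1 = FALSE)
  for (i in seq_along(rep$partitions)) {
    cc <- efeunity:::mu_ratio_counts(rep$partitions[[i]], rep$data,
                                     lapply(rep$partitions[[i]], function(b) {
                                       rep$cache[[efeunity:::subsystem_key(b)]]
                                     }), rep$whole$model)
    expect_length(cc$weight, 1)
    expect_equal(unname(rep$mu[i]),
                 log2(prod(cc$block_counts) / cc$whole_counts),
                 tolerance = 1e-9)
  }
})

test_that("all-ones U forces mu = 0 through full accessible sets", {
  # with U == 1 every accessible set is the full block state space, so the
  # ratio identity gives log2(prod |Omega_X| / |Omega|) = 0
  spec <- efe_system(3, 2)
  states <- enumerate_states(spec)
  ones6 <- primary_model(make_relation(3, runif(3)), make_relation(2, 1))
  parts <- enumerate_partitions(spec$nodes)
  set.seed(6)
  P <- {p <- runif(8); distribution(p / sum(p), spec)}
  for (part in parts) {
    entries <- lapply(part, function(b) {
      k <- length(b)
      list(model = primary_model(make_relation(k, rep(0.5, k * (k - 1) / 2)),
                                 make_relation(2, 1)),
           level_map = NULL)
    })
    cc <- efeunity:::mu_ratio_counts(part, P, entries, ones6)
    val <- sum(cc$weight *
                 (rowSums(log2(cc$block_counts)) - log2(cc$whole_counts)))
    expect_equal(val, 0, tolerance = 1e-12)
  }
})

test_that("unity analysis on the two-state system finds unity", {
  obs <- observations(rbind(c(0, 0), c(1, 1)), efe_system(2, 2))
  rep <- unity_analysis(obs, control = efe_control(restarts = 4, seed = 3))
  expect_equal(rep$M, 1, tolerance = 1e-9)
  expect_true(rep$has_unity)
  expect_length(rep$partitions, 1)
  expect_true(rep$lemma1$ok)  # vacuous: only singleton blocks
})

test_that("subsystem unity values are invariant under level permutation", {
  # permuting the levels of the data cannot change any minimised EFE
  obs <- gen_smooth_corpus(n_obs = 80, seed = 21)
  sub <- obs$spec$nodes[1:2]
  ctl <- efe_control(restarts = 8, seed = 9)
  g <- c(1L, 2L, 3L, 0L)
  obs_g <- apply_value_permutation(obs, sub, g)
  fit <- efe_fit(obs, nodes = sub, control = ctl)
  fit_g <- efe_fit(obs_g, nodes = sub, control = ctl)
  expect_equal(fit_g$efe_min, fit$efe_min, tolerance = 1e-6)
})

test_that("maximal subsystems of a unified system are the system itself", {
  obs <- observations(rbind(c(0, 0), c(1, 1)), efe_system(2, 2))
  rep <- unity_analysis(obs, control = efe_control(restarts = 4, seed = 3))
  mx <- maximal_subsystems(rep)
  expect_length(mx$subsystems, 1)
  expect_setequal(mx$subsystems[[1]], obs$spec$nodes)
  expect_true(mx$disjoint)
})

test_that("transitivity scan reports no violations under global unity", {
  obs <- observations(rbind(c(0, 0, 0), c(1, 1, 1), c(0, 0, 1)),
                      efe_system(3, 2))
  rep <- unity_analysis(obs, control = efe_control(restarts = 4, seed = 13))
  tr <- check_transitivity(rep)
  if (rep$has_unity && nrow(tr) > 0) {
    expect_true(all(tr$union_unified))
  }
  expect_true(is.data.frame(tr))
  expect_named(tr, c("X", "Y", "Z", "union_unified"))
})

test_that("mode distance is a pseudometric over mu profiles", {
  ctl <- efe_control(restarts = 3, seed = 17, maxit = 300)
  obs_a <- observations(rbind(c(0, 0), c(1, 1), c(0, 0)), efe_system(2, 2))
  obs_b <- observations(rbind(c(0, 1), c(1, 0), c(0, 0)), efe_system(2, 2))
  d_aa <- mode_distance(obs_a, obs_a, control = ctl)
  expect_equal(as.numeric(d_aa), 0, tolerance = 1e-12)
  d_ab <- mode_distance(obs_a, obs_b, control = ctl)
  d_ba <- mode_distance(obs_b, obs_a, control = ctl)
  expect_equal(as.numeric(d_ab), as.numeric(d_ba), tolerance = 1e-9)
  expect_gte(as.numeric(d_ab), 0)
})

test_that("strict effective-value mode shrinks block state spaces", {
  # node_3 never leaves levels {0, 1}: in strict mode its singleton block
  # contributes log2 2 instead of log2 4
  set.seed(19)
  st <- cbind(sample(0:3, 40, TRUE), sample(0:3, 40, TRUE),
              sample(0:1, 40, TRUE))
  obs <- observations(st, efe_system(3, 4))
  ctl <- efe_control(restarts = 3, seed = 5)
  cache <- new.env(parent = emptyenv())
  fit_default <- efeunity:::subsystem_fit(obs, "node_3", ctl, cache, FALSE)
  fit_strict <- efeunity:::subsystem_fit(obs, "node_3", ctl, cache, TRUE)
  expect_equal(fit_default$efe_min, 2)
  expect_equal(fit_strict$efe_min, 1)
  # strict unity analysis runs end to end and mu still matches its ratio
  rep <- unity_analysis(obs, control = ctl, strict_vx = TRUE, lemma1 = FALSE)
  expect_true(is.finite(rep$M))
  for (i in seq_along(rep$partitions)) {
    expect_equal(mu_ratio(rep, i), unname(rep$mu[i]), tolerance = 1e-9)
  }
})
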