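# 2-node 2-level reference model: R(a,b)=0.9, U(0,1)=0.2.
# Hand enumeration: d(00)=d(11)=0.1, d(01)=d(10)=0.7, so A(00)={00,11}
# (fe 1 bit) and A(01)=all four states (fe 2 bits).
oracle2 <- function() {
  primary_model(make_relation(2, 0.9), make_relation(2, 0.2))
}

test_that("discontinuity matches hand enumeration on the 2-node model", {
  mod <- oracle2()
  expect_equal(discontinuity(mod, c(0, 1)), 0.7)
  expect_equal(discontinuity(mod, c(0, 0)), 0.1)
  # all-ones U: discontinuity is f-independent
  spec <- efe_system(3, 2)
  ones <- primary_model(make_relation(3, c(0.3, 0.6, 0.8)),
                        make_relation(2, 1))
  ds <- apply(enumerate_states(spec), 1, function(f) discontinuity(ones, f))
  expect_equal(max(ds) - min(ds), 0)
})

test_that("float entropy from the profile matches the 2-node enumeration", {
  mod <- oracle2()
  spec <- efe_system(2, 2)
  prof <- discontinuity_profile(mod, spec)
  expect_equal(float_entropy(mod, c(0, 0), profile = prof), 1)
  expect_equal(float_entropy(mod, c(1, 1), profile = prof), 1)
  expect_equal(float_entropy(mod, c(0, 1), profile = prof), 2)
  expect_equal(float_entropy(mod, c(1, 0), profile = prof), 2)
})

test_that("sorted-profile float entropy equals naive pairwise counting", {
  systems <- list(c(2, 2), c(2, 3), c(2, 4), c(3, 2), c(3, 3), c(3, 4),
                  c(4, 2), c(4, 3), c(4, 4))
  set.seed(101)
  for (sys in systems) {
    n <- sys[1]; m <- sys[2]
    spec <- efe_system(n, m)
    states <- enumerate_states(spec)
    for (rep in 1:10) {
      mod <- random_model(n, m)
      prof <- discontinuity_profile(mod, spec)
      dvec <- oracle_profile(mod$R, mod$U, oracle_states(n, m))
      fe_pkg <- log2(findInterval(prof$d + 1e-9, prof$sorted_d))
      fe_naive <- vapply(seq_len(nrow(states)),
                         function(i) oracle_fe(dvec, i), 0)
      expect_identical(fe_pkg, fe_naive)
    }
  }
})

test_that("efe over observations equals efe over the empirical distribution", {
  set.seed(55)
  for (rep in 1:10) {
    n <- sample(2:4, 1); m <- sample(2:3, 1)
    obs <- random_obs(sample(5:60, 1), n, m)
    mod <- random_model(n, m)
    expect_equal(efe(mod, obs), efe(mod, empirical_distribution(obs)),
                 tolerance = 1e-12)
  }
})

test_that("efe has the 2-node closed-form values", {
  mod <- oracle2()
  spec <- efe_system(2, 2)
  unif <- gen_explicit_distribution("uniform", spec)
  expect_equal(efe(mod, unif), 1.5)
  two <- gen_explicit_distribution("two_state", spec)
  expect_equal(efe(mod, two), 1)
  pt <- gen_explicit_distribution("point", spec, state = c(0, 1))
  expect_equal(efe(mod, pt), float_entropy(mod, c(0, 1), spec))
  obs <- observations(rbind(c(0, 0), c(0, 1)), spec)
  expect_equal(efe(mod, obs), 1.5)
})

test_that("all-ones U gives the maximum-entropy limit", {
  spec <- efe_system(6, 4)
  set.seed(2)
  mod <- primary_model(make_relation(6, runif(15)), make_relation(4, 1))
  obs <- gen_smooth_corpus(n_obs = 30, seed = 5)
  expect_equal(efe(mod, obs), 12)
  prof <- discontinuity_profile(mod, spec)
  expect_true(all(log2(findInterval(prof$d + 1e-9, prof$sorted_d)) == 12))
})

test_that("singleton subsystems have efe log2(m) for any model and data", {
  obs <- gen_smooth_corpus(n_obs = 20, seed = 9)
  set.seed(31)
  for (rep in 1:5) {
    mod1 <- primary_model(make_relation(obs$spec$nodes[2], numeric(0)),
                          make_relation(4, runif(6)))
    expect_equal(efe(mod1, obs, nodes = obs$spec$nodes[2]), 2)
  }
})

test_that("efe is invariant under node relabeling and level permutation", {
  set.seed(77)
  for (rep in 1:8) {
    n <- sample(2:4, 1); m <- sample(2:4, 1)
    obs <- random_obs(30, n, m)
    mod <- random_model(n, m)
    base <- efe(mod, obs)
    # simultaneous node relabeling of R and the data
    sigma <- sample(n)
    mod_s <- primary_model(mod$R[sigma, sigma], mod$U)
    obs_s <- observations(obs$states[, sigma], efe_system(n, m))
    expect_equal(efe(mod_s, obs_s), base, tolerance = 1e-12)
    # simultaneous level permutation of U and the data
    g <- sample(0:(m - 1))
    mod_g <- primary_model(mod$R, mod$U[order(g), order(g)])
    obs_g <- observations(matrix(g[obs$states + 1L], nrow = 30),
                          efe_system(n, m))
    expect_equal(efe(mod_g, obs_g), base, tolerance = 1e-12)
  }
})

test_that("per-partition accessible-set products never exceed the state count", {
  # exhaustive over all states, partitions and random block models, n <= 4
  set.seed(13)
  for (rep in 1:6) {
    n <- sample(3:4, 1); m <- 2
    spec <- efe_system(n, m)
    states <- enumerate_states(spec)
    parts <- enumerate_partitions(spec$nodes)
    part <- parts[[sample(length(parts), 1)]]
    counts <- matrix(1, nrow(states), length(part))
    for (bi in seq_along(part)) {
      idx <- match(part[[bi]], spec$nodes)
      bmod <- random_model(length(idx), m)
      bstates <- oracle_states(length(idx), m)
      db <- oracle_profile(bmod$R, bmod$U, bstates)
      bkey <- apply(states[, idx, drop = FALSE], 1, function(f) {
        sum(f * m^((length(idx):1) - 1)) + 1
      })
      counts[, bi] <- vapply(bkey, function(i) sum(db <= db[i] + 1e-9), 0)
    }
    expect_true(all(apply(counts, 1, prod) <= nrow(states)))
  }
})
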