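test_that("state enumeration is a lexicographic bijection", {
  expect_equal(nrow(enumerate_states(efe_system(6, 4))), 4096)
  expect_equal(unname(enumerate_states(efe_system(1, 2))),
               matrix(c(0L, 1L), ncol = 1))
  expect_equal(unname(enumerate_states(efe_system(2, 2))),
               rbind(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L)))
  st <- enumerate_states(efe_system(3, 3))
  expect_equal(nrow(unique(st)), 3^3)
  expect_equal(unname(st), oracle_states(3, 3))
  expect_error(enumerate_states(efe_system(2, 2), cap = 3), "too large")
})

test_that("state restriction is projection", {
  spec <- efe_system(6, 4)
  f <- c(1L, 2L, 3L, 0L, 1L, 2L)
  expect_equal(unname(restrict_state(f, spec, spec$nodes[1:3])), c(1L, 2L, 3L))
  expect_equal(unname(restrict_state(f, spec, spec$nodes)), f)
  # composition of projections
  x <- spec$nodes[c(1, 3, 5)]
  y <- spec$nodes[c(1, 5)]
  sub_spec <- efe_system(x, 4)
  expect_equal(restrict_state(restrict_state(f, spec, x), sub_spec, y),
               restrict_state(f, spec, y))
  expect_error(restrict_state(f, spec, "nope"), "unknown node")
})

test_that("observation restriction preserves order and multiplicity", {
  set.seed(7)
  obs <- random_obs(50, 4, 3)
  sub <- restrict_observations(obs, c(1, 3))
  expect_equal(n_obs(sub), 50)
  expect_equal(unname(sub$states), unname(obs$states[, c(1, 3)]))
  # aggregated counts of result = projected counts of input
  proj_counts <- table(apply(obs$states[, c(1, 3)], 1, paste, collapse = ","))
  sub_counts <- table(apply(sub$states, 1, paste, collapse = ","))
  expect_equal(as.vector(proj_counts[names(sub_counts)]),
               as.vector(sub_counts))
})

test_that("marginalisation sums over extensions and is a tower", {
  spec <- efe_system(c("a", "b"), 2)
  unif <- gen_explicit_distribution("uniform", spec)
  expect_equal(marginalize(unif, "a")$p, c(0.5, 0.5))
  two <- gen_explicit_distribution("two_state", spec)
  expect_equal(marginalize(two, "a")$p, c(0.5, 0.5))
  # product distribution marginalises back to its factor
  pa <- distribution(c(0.3, 0.7), efe_system("a", 2))
  pb <- distribution(c(0.1, 0.9), efe_system("b", 2))
  prod2 <- gen_explicit_distribution("product", parts = list(pa, pb))
  expect_equal(marginalize(prod2, "a")$p, pa$p)
  expect_equal(marginalize(prod2, "b")$p, pb$p)
  # tower property, exhaustive on a random 4-node distribution
  set.seed(11)
  spec4 <- efe_system(4, 2)
  p <- runif(16); p <- p / sum(p)
  P <- distribution(p, spec4)
  x <- spec4$nodes[c(1, 2, 4)]
  y <- spec4$nodes[c(2, 4)]
  direct <- marginalize(P, y)
  via <- marginalize(marginalize(P, x), y)
  expect_equal(via$p, direct$p, tolerance = 1e-14)
})

test_that("empirical distribution counts states and commutes with restriction", {
  spec <- efe_system(2, 2)
  obs <- observations(rbind(c(0, 0), c(0, 0), c(1, 1), c(0, 1)), spec)
  P <- empirical_distribution(obs)
  expect_equal(P$p, c(0.5, 0.25, 0, 0.25))  # canonical order 00,01,10,11
  one <- observations(rbind(c(1, 0)), spec)
  expect_equal(empirical_distribution(one)$p, c(0, 0, 1, 0))
  # empirical o restrict == marginalize o empirical, exactly
  set.seed(3)
  obs4 <- random_obs(40, 4, 3)
  x <- obs4$spec$nodes[c(2, 3)]
  lhs <- empirical_distribution(restrict_observations(obs4, x))
  rhs <- marginalize(empirical_distribution(obs4), x)
  expect_equal(lhs$p, rhs$p, tolerance = 1e-15)
})

test_that("effective value set tracks the support", {
  spec <- efe_system(2, 4)
  obs <- observations(rbind(c(2, 2), c(2, 2)), spec)
  expect_equal(effective_values(obs, spec$nodes[1]), 2)
  set.seed(5)
  obs2 <- random_obs(200, 2, 4)
  ev <- effective_values(obs2, spec$nodes)
  expect_true(all(ev %in% 0:3))
  expect_equal(effective_values(obs2, spec$nodes),
               sort(unique(as.vector(obs2$states))))
})

test_that("product observations realise exact block independence", {
  set.seed(9)
  a <- observations(matrix(sample(0:3, 15, TRUE), ncol = 3,
                           dimnames = list(NULL, paste0("a", 1:3))),
                    efe_system(paste0("a", 1:3), 4))
  b <- observations(matrix(sample(0:3, 21, TRUE), ncol = 3,
                           dimnames = list(NULL, paste0("b", 1:3))),
                    efe_system(paste0("b", 1:3), 4))
  prod_ab <- product_observations(a, b)
  expect_equal(n_obs(prod_ab), 5 * 7)
  # row-major: pair (i, j) at row (i-1)*|T_b| + j
  expect_equal(unname(prod_ab$states[2 * 7 + 3, ]),
               unname(c(a$states[3, ], b$states[3, ])))
  # block marginals equal input empiricals
  expect_identical(
    empirical_distribution(restrict_observations(prod_ab, paste0("a", 1:3)))$p,
    empirical_distribution(a)$p)
  # exactly zero block mutual information
  mi <- block_mutual_information(prod_ab$states, 1:3, 4:6)
  expect_lt(abs(mi), 1e-12)
  expect_error(product_observations(a, a), "overlap")
})

test_that("distribution JSON round-trips", {
  set.seed(23)
  p <- runif(16); p <- p / sum(p)
  P <- distribution(p, efe_system(2, 4, level_labels = c("0", "147.224",
                                                         "294.449",
                                                         "441.673")))
  path <- tempfile(fileext = ".json")
  write_distribution(P, path)
  back <- read_distribution(path)
  expect_equal(back$p, P$p, tolerance = 1e-15)
  expect_identical(back$spec$nodes, P$spec$nodes)
  expect_identical(back$spec$level_labels, P$spec$level_labels)
})

test_that("observation CSV round-trips", {
  obs <- gen_smooth_corpus(n_obs = 25, seed = 42)
  path <- tempfile(fileext = ".csv")
  write_observations(obs, path, extra = c(seed = 42))
  back <- read_observations(path)
  expect_identical(back$states, obs$states)
  expect_equal(back$spec$m, obs$spec$m)
  expect_identical(back$spec$nodes, obs$spec$nodes)
})
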