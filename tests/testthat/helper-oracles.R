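# Independent brute-force oracles: everything here is computed from first
# principles (plain loops over explicitly enumerated states), never through
# the package's profile fast path.

# all states of n nodes with m levels, first node varying slowest
oracle_states <- function(n, m) {
  g <- expand.grid(rep(list(0:(m - 1L)), n))
  st <- as.matrix(g[, rev(seq_len(n)), drop = FALSE])
  dimnames(st) <- NULL
  storage.mode(st) <- "integer"
  st
}

# d1(R, U o f) by direct pair summation
oracle_d <- function(R, U, f) {
  k <- length(f)
  s <- 0
  if (k >= 2) {
    for (a in 1:(k - 1)) {
      for (b in (a + 1):k) s <- s + abs(R[a, b] - U[f[a] + 1, f[b] + 1])
    }
  }
  s
}

oracle_profile <- function(R, U, states) {
  apply(states, 1, function(f) oracle_d(R, U, f))
}

# float entropy of state i by O(|Omega|) counting
oracle_fe <- function(dvec, i, eps = 1e-9) log2(sum(dvec <= dvec[i] + eps))

# expected float entropy of an observation matrix by direct averaging
oracle_efe <- function(R, U, obs_states, m, eps = 1e-9) {
  n <- ncol(obs_states)
  states <- oracle_states(n, m)
  dvec <- oracle_profile(R, U, states)
  key <- function(f) sum(f * m^((n:1) - 1)) + 1
  all_keys <- apply(states, 1, key)
  mean(apply(obs_states, 1, function(f) {
    i <- which(all_keys == key(f))
    oracle_fe(dvec, i, eps)
  }))
}

random_model <- function(k, m) {
  primary_model(make_relation(k, stats::runif(k * (k - 1) / 2)),
                make_relation(m, stats::runif(m * (m - 1) / 2)))
}

# small random observation matrix
random_obs <- function(n_rows, n, m) {
  observations(matrix(sample(0:(m - 1), n_rows * n, replace = TRUE),
                      nrow = n_rows), efe_system(n, m))
}

# empirical mutual information (bits) between two column blocks
block_mutual_information <- function(states, block_a, block_b) {
  lab <- function(cols) apply(states[, cols, drop = FALSE], 1, paste,
                              collapse = ",")
  a <- lab(block_a); b <- lab(block_b); ab <- paste(a, b, sep = ";")
  h <- function(x) {
    p <- table(x) / length(x)
    -sum(p * log2(p))
  }
  h(a) + h(b) - h(ab)
}
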