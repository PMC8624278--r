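#' Define a discrete system
#'
#' A system is a finite ordered set of nodes, each of which can be in one of
#' `m` discrete value levels `0..m-1`. The state space of the system is the
#' set of all assignments of levels to nodes, of size `m^n`.
#'
#' @param nodes Character vector of unique node identifiers, or a single
#'   integer `n` (nodes are then named `node_1..node_n`).
#' @param n_levels Number of value levels `m` (at least 2).
#' @param level_labels Optional character vector of display labels for the
#'   levels (presentation only; all computation uses the integer levels).
#' @return An object of class `efe_system` with elements `nodes`, `m` and
#'   `level_labels`.
#' @examples
#' efe_system(6, 4)
#' @export
efe_system <- function(nodes, n_levels, level_labels = NULL) {
  if (is.numeric(nodes) && length(nodes) == 1L) {
    nodes <- paste0("node_", seq_len(nodes))
  }
  nodes <- as.character(nodes)
  if (length(nodes) < 1L) stop("need at least one node")
  if (anyDuplicated(nodes)) stop("node identifiers must be unique")
  n_levels <- as.integer(n_levels)
  if (n_levels < 2L) stop("need at least two value levels")
  if (!is.null(level_labels) && length(level_labels) != n_levels) {
    stop("level_labels must have length n_levels")
  }
  structure(list(nodes = nodes, m = n_levels, level_labels = level_labels),
            class = "efe_system")
}

#' @export
print.efe_system <- function(x, ...) {
  cat("Discrete system: ", length(x$nodes), " nodes, ", x$m, " levels (",
      format(x$m^length(x$nodes), big.mark = ","), " states)\n", sep = "")
  cat("  nodes: ", paste(x$nodes, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# default cap on enumerated state spaces
.efe_state_cap <- 1e6

.state_cache <- new.env(parent = emptyenv())

#' Enumerate all states of a system
#'
#' Returns the full state space in the canonical order used throughout the
#' package: lexicographic in (node order, level index), with the first node
#' varying slowest. Row `i` of the result is state number `i`.
#'
#' @param spec An [efe_system()] object, or the number of nodes when `m` is
#'   given.
#' @param m Number of levels (only when `spec` is a node count).
#' @param cap Maximum admissible number of states (guards the exhaustive
#'   enumeration every float-entropy computation rests on).
#' @return Integer matrix with `m^n` rows and `n` columns, levels `0..m-1`.
#' @examples
#' enumerate_states(efe_system(2, 2))
#' @export
enumerate_states <- function(spec, m = NULL, cap = .efe_state_cap) {
  if (inherits(spec, "efe_system")) {
    n <- length(spec$nodes); m <- spec$m; nms <- spec$nodes
  } else {
    n <- as.integer(spec); nms <- paste0("node_", seq_len(n))
  }
  n_states <- m^n
  if (n_states > cap) {
    stop("state space too large: ", m, "^", n, " = ", n_states,
         " exceeds cap ", cap)
  }
  key <- paste(n, m, sep = "x")
  if (!is.null(.state_cache[[key]])) {
    st <- .state_cache[[key]]
  } else {
    st <- matrix(0L, nrow = n_states, ncol = n)
    for (j in seq_len(n)) {
      st[, j] <- rep(rep(0:(m - 1L), each = m^(n - j)), times = m^(j - 1L))
    }
    .state_cache[[key]] <- st
  }
  colnames(st) <- nms
  st
}

# canonical 1-based index of states (rows of a matrix, levels 0..m-1)
state_index <- function(states, m) {
  n <- ncol(states)
  idx <- rep(1, nrow(states))
  for (j in seq_len(n)) idx <- idx + states[, j] * m^(n - j)
  as.integer(idx)
}

#' Create an observation set
#'
#' Wraps a matrix of observed system states (one row per numbered
#' observation, one column per node, integer levels `0..m-1`) together with
#' its system definition. Observations form a multiset: repeated states are
#' kept and weighted by multiplicity in every expectation.
#'
#' @param states Integer matrix of observations (rows) by nodes (columns).
#' @param spec An [efe_system()]; defaults to one inferred from the matrix
#'   (`m` = `max(states) + 1` unless given).
#' @return An object of class `efe_obs`.
#' @export
observations <- function(states, spec = NULL) {
  states <- as.matrix(states)
  storage.mode(states) <- "integer"
  if (is.null(spec)) {
    spec <- efe_system(if (!is.null(colnames(states))) colnames(states)
                       else ncol(states),
                       max(states) + 1L)
  }
  stopifnot(inherits(spec, "efe_system"))
  if (ncol(states) != length(spec$nodes)) {
    stop("observation matrix has ", ncol(states), " columns but the system has ",
         length(spec$nodes), " nodes")
  }
  if (nrow(states) < 1L) stop("need at least one observation")
  if (any(states < 0L) || any(states >= spec$m)) {
    stop("levels must lie in 0..", spec$m - 1L)
  }
  colnames(states) <- spec$nodes
  structure(list(spec = spec, states = states), class = "efe_obs")
}

#' @export
print.efe_obs <- function(x, ...) {
  agg <- aggregate_observations(x)
  cat("Observation set: |T| = ", nrow(x$states), " over ",
      length(x$spec$nodes), " nodes, ", x$spec$m, " levels (",
      length(agg$index), " distinct states)\n", sep = "")
  invisible(x)
}

#' Number of observations
#' @param x An `efe_obs` object.
#' @return Integer count `|T|`.
#' @export
n_obs <- function(x) nrow(x$states)

# aggregated (state index, weight) representation; weights sum to 1
aggregate_observations <- function(obs) {
  idx <- state_index(obs$states, obs$spec$m)
  tab <- tabulate(idx, nbins = max(idx))
  keep <- which(tab > 0L)
  list(index = keep, weight = tab[keep] / length(idx), count = tab[keep])
}

# resolve a subsystem given by names or indices to ordered node indices
resolve_subsystem <- function(spec, nodes) {
  if (is.character(nodes)) {
    idx <- match(nodes, spec$nodes)
    if (anyNA(idx)) stop("unknown node(s): ",
                         paste(nodes[is.na(idx)], collapse = ", "))
  } else {
    idx <- as.integer(nodes)
    if (any(idx < 1L) || any(idx > length(spec$nodes))) {
      stop("node index out of range")
    }
  }
  idx <- sort(unique(idx))
  if (length(idx) == 0L) stop("subsystem must be nonempty")
  idx
}

#' Restrict a state to a subsystem
#'
#' @param f Integer state vector over the full system (levels `0..m-1`),
#'   optionally named by node.
#' @param spec The [efe_system()] the state lives on.
#' @param nodes Subsystem: node names or indices.
#' @return The restricted state, named by the subsystem's nodes (spec order).
#' @export
restrict_state <- function(f, spec, nodes) {
  idx <- resolve_subsystem(spec, nodes)
  out <- as.integer(f)[idx]
  names(out) <- spec$nodes[idx]
  out
}

#' Restrict an observation set to a subsystem
#'
#' Applies the restriction observation-wise: the k-th restricted observation
#' is the k-th observation projected onto the subsystem's nodes. Multiset
#' semantics (duplicates) are preserved.
#'
#' @param obs An `efe_obs` object.
#' @param nodes Subsystem: node names or indices.
#' @return An `efe_obs` over the subsystem (same number of observations).
#' @export
restrict_observations <- function(obs, nodes) {
  idx <- resolve_subsystem(obs$spec, nodes)
  sub_spec <- efe_system(obs$spec$nodes[idx], obs$spec$m, obs$spec$level_labels)
  observations(obs$states[, idx, drop = FALSE], sub_spec)
}

#' Explicit probability distribution over a state space
#'
#' @param p Numeric vector of probabilities over all `m^n` states in
#'   canonical order (see [enumerate_states()]).
#' @param spec An [efe_system()].
#' @return An object of class `efe_distribution`.
#' @export
distribution <- function(p, spec) {
  stopifnot(inherits(spec, "efe_system"))
  n_states <- spec$m^length(spec$nodes)
  if (length(p) != n_states) {
    stop("probability vector must have length m^n = ", n_states)
  }
  if (any(p < -1e-15)) stop("probabilities must be non-negative")
  p <- pmax(p, 0)
  if (abs(sum(p) - 1) > 1e-12) stop("probabilities must sum to 1")
  structure(list(spec = spec, p = as.numeric(p)), class = "efe_distribution")
}

#' @export
print.efe_distribution <- function(x, ...) {
  cat("Distribution over ", length(x$p), " states (",
      sum(x$p > 0), " in support)\n", sep = "")
  invisible(x)
}

#' Empirical distribution of an observation set
#'
#' @param obs An `efe_obs` object.
#' @return An `efe_distribution` with `P(f) = multiplicity(f) / |T|`.
#' @export
empirical_distribution <- function(obs) {
  agg <- aggregate_observations(obs)
  p <- numeric(obs$spec$m^length(obs$spec$nodes))
  p[agg$index] <- agg$weight
  distribution(p, obs$spec)
}

#' Marginalise a distribution onto a subsystem
#'
#' `P_X(f_X)` is the sum of `P(f)` over all states `f` restricting to `f_X`.
#'
#' @param dist An `efe_distribution`.
#' @param nodes Subsystem: node names or indices.
#' @return An `efe_distribution` over the subsystem.
#' @export
marginalize <- function(dist, nodes) {
  spec <- dist$spec
  idx <- resolve_subsystem(spec, nodes)
  states <- enumerate_states(spec)
  sub_idx <- state_index(states[, idx, drop = FALSE], spec$m)
  sub_spec <- efe_system(spec$nodes[idx], spec$m, spec$level_labels)
  p_sub <- numeric(spec$m^length(idx))
  acc <- rowsum(dist$p, group = sub_idx)
  p_sub[as.integer(rownames(acc))] <- acc[, 1]
  distribution(p_sub, sub_spec)
}

#' Levels effectively used by a subsystem
#'
#' The set `V_X` of levels appearing in the support of the subsystem's
#' marginal (for a distribution) or anywhere in the restricted observations.
#' Usually `V_X` equals the full level set.
#'
#' @param data An `efe_obs` or `efe_distribution`.
#' @param nodes Subsystem: node names or indices.
#' @return Sorted integer vector of levels.
#' @export
effective_values <- function(data, nodes) {
  if (inherits(data, "efe_obs")) {
    sub <- restrict_observations(data, nodes)
    sort(unique(as.vector(sub$states)))
  } else if (inherits(data, "efe_distribution")) {
    marg <- marginalize(data, nodes)
    states <- enumerate_states(marg$spec)
    sort(unique(as.vector(states[marg$p > 0, , drop = FALSE])))
  } else {
    stop("data must be an efe_obs or efe_distribution")
  }
}

#' Combine two independent observation sets by Cartesian product
#'
#' Builds the observation set of the union system in which the two node
#' blocks are exactly independent: every pairing of an observation of `a`
#' with an observation of `b` occurs once. Row-major order: pair (i, j)
#' lands at row `(i-1)*|T_b| + j`. The empirical block marginals equal the
#' inputs' empirical distributions and the empirical mutual information
#' between the blocks is zero.
#'
#' @param a,b `efe_obs` objects on disjoint node sets with the same number
#'   of levels.
#' @return An `efe_obs` over the concatenated node set with
#'   `|T_a| * |T_b|` observations.
#' @export
product_observations <- function(a, b) {
  stopifnot(inherits(a, "efe_obs"), inherits(b, "efe_obs"))
  if (a$spec$m != b$spec$m) stop("level sets differ")
  if (length(intersect(a$spec$nodes, b$spec$nodes)) > 0L) {
    stop("node sets overlap: ",
         paste(intersect(a$spec$nodes, b$spec$nodes), collapse = ", "))
  }
  na <- nrow(a$states); nb <- nrow(b$states)
  ia <- rep(seq_len(na), each = nb)
  ib <- rep(seq_len(nb), times = na)
  states <- cbind(a$states[ia, , drop = FALSE], b$states[ib, , drop = FALSE])
  spec <- efe_system(c(a$spec$nodes, b$spec$nodes), a$spec$m,
                     a$spec$level_labels)
  observations(states, spec)
}

#' Write observations to CSV
#'
#' The dialect is a plain comma-separated table with header `node` names and
#' one row per observation (integer levels), preceded by `#`-prefixed
#' metadata lines recording the system dimensions and any level labels.
#'
#' @param obs An `efe_obs` object.
#' @param path Output file path.
#' @param extra Optional named character vector of extra metadata lines.
#' @return `path`, invisibly.
#' @export
write_observations <- function(obs, path, extra = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# nodes: %s", paste(obs$spec$nodes, collapse = ",")), con)
  writeLines(sprintf("# levels: %d", obs$spec$m), con)
  if (!is.null(obs$spec$level_labels)) {
    writeLines(sprintf("# level_labels: %s",
                       paste(obs$spec$level_labels, collapse = ",")), con)
  }
  if (!is.null(extra)) {
    writeLines(sprintf("# %s: %s", names(extra), as.character(extra)), con)
  }
  utils::write.table(obs$states, con, sep = ",", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Write an explicit distribution to JSON
#'
#' Stores the system definition and the probability array in canonical
#' state order, at full precision.
#'
#' @param dist An `efe_distribution`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distribution <- function(dist, path) {
  obj <- list(nodes = dist$spec$nodes, levels = dist$spec$m,
              level_labels = dist$spec$level_labels,
              probabilities = dist$p)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read an explicit distribution from JSON
#' @param path Path to a JSON file written by [write_distribution()].
#' @return An `efe_distribution`.
#' @export
read_distribution <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- efe_system(obj$nodes, obj$levels, obj$level_labels)
  distribution(obj$probabilities, spec)
}

#' Read observations from CSV
#'
#' @param path Path to a CSV written by [write_observations()] (or any
#'   comma-separated integer table with a header row; `#` lines are treated
#'   as metadata).
#' @return An `efe_obs` object.
#' @export
read_observations <- function(path) {
  meta <- grep("^#", readLines(path, n = 20L), value = TRUE)
  m <- NULL; labels <- NULL
  lv <- grep("^# levels:", meta, value = TRUE)
  if (length(lv)) m <- as.integer(sub("^# levels:\\s*", "", lv[1]))
  lb <- grep("^# level_labels:", meta, value = TRUE)
  if (length(lb)) {
    labels <- strsplit(sub("^# level_labels:\\s*", "", lb[1]), ",")[[1]]
  }
  tab <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  states <- as.matrix(tab)
  if (is.null(m)) m <- max(states) + 1L
  spec <- efe_system(colnames(states), m, labels)
  observations(states, spec)
}
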