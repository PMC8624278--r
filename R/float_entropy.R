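#' Discontinuity of a state under a primary model
#'
#' `d1(R, U o f)`: how far the node relation induced by the state `f`
#' through the level relation `U` is from the model's node relation `R`.
#' Small values mean the state looks smooth under the model.
#'
#' @param model A [primary_model()].
#' @param f Integer state vector (levels `0..m-1`).
#' @return Non-negative scalar.
#' @export
discontinuity <- function(model, f) {
  d1(model$R, compose_relation(model$U, f))
}

#' Discontinuity profile of a model over a state space
#'
#' Evaluates the discontinuity of every state of the context's state space
#' (canonical order) and keeps an ascending sorted copy. Float entropies
#' are then rank lookups in the sorted profile, the fast path that replaces
#' per-state pairwise counting.
#'
#' @param model A [primary_model()].
#' @param spec An [efe_system()] giving the context (node set and levels);
#'   its node count and level count must match the model.
#' @param cap State-space cap (see [enumerate_states()]).
#' @return An object of class `efe_profile` with elements `d` (canonical
#'   order), `sorted_d`, `spec` and `model`.
#' @export
discontinuity_profile <- function(model, spec, cap = .efe_state_cap) {
  stopifnot(inherits(spec, "efe_system"))
  k <- length(spec$nodes)
  if (nrow(model$R) != k) stop("model R has wrong node count")
  if (nrow(model$U) != spec$m) stop("model U has wrong level count")
  states <- enumerate_states(spec, cap = cap)
  d <- d_profile_cpp(states, model$R, model$U)
  structure(list(d = d, sorted_d = sort(d), spec = spec, model = model),
            class = "efe_profile")
}

#' Float entropy of a state
#'
#' `fe(R, U, f) = log2 |A(R, U, f)|` where `A` is the set of states whose
#' discontinuity does not exceed that of `f` (ties within `eps_tie` count).
#' Always between 0 and `log2 |Omega|`; the state itself is in its own
#' accessible set so the count is at least 1.
#'
#' @param model A [primary_model()] (ignored when `profile` is given).
#' @param f Integer state vector.
#' @param spec The context [efe_system()] (ignored when `profile` is given).
#' @param profile Optionally a precomputed [discontinuity_profile()].
#' @param eps_tie Absolute tolerance for discontinuity ties.
#' @return Float entropy in bits.
#' @export
float_entropy <- function(model, f, spec = NULL, profile = NULL,
                          eps_tie = 1e-9) {
  if (is.null(profile)) {
    if (is.null(spec)) spec <- efe_system(length(f), nrow(model$U))
    profile <- discontinuity_profile(model, spec)
  }
  f <- as.integer(f)
  if (length(f) != length(profile$spec$nodes)) stop("state outside context")
  idx <- state_index(matrix(f, nrow = 1), profile$spec$m)
  count <- findInterval(profile$d[idx] + eps_tie, profile$sorted_d)
  log2(count)
}

# shared core: weighted-mean float entropy at aggregated state indices
efe_core <- function(model, spec, index, weight, eps_tie, cap = .efe_state_cap) {
  states <- enumerate_states(spec, cap = cap)
  efe_eval_cpp(states, model$R, model$U, as.integer(index) - 1L,
               as.numeric(weight), eps_tie)
}

#' Expected float entropy
#'
#' The probability-weighted (for a distribution) or multiplicity-weighted
#' (for an observation set) mean float entropy of the system's states under
#' a primary model. The two routes agree exactly on an observation set and
#' its empirical distribution.
#'
#' @param model A [primary_model()].
#' @param data An `efe_obs` or `efe_distribution`.
#' @param nodes Optional subsystem (node names or indices): the data is
#'   restricted/marginalised onto it and the model read over it.
#' @param eps_tie Tie tolerance for the accessible-set counts.
#' @return Expected float entropy in bits.
#' @examples
#' spec <- efe_system(2, 2)
#' mod <- primary_model(make_relation(2, 0.9), make_relation(2, 0.2))
#' efe(mod, observations(rbind(c(0, 0), c(0, 1)), spec))
#' @export
efe <- function(model, data, nodes = NULL, eps_tie = 1e-9) {
  if (!is.null(nodes)) {
    data <- if (inherits(data, "efe_obs")) restrict_observations(data, nodes)
            else marginalize(data, nodes)
  }
  if (inherits(data, "efe_obs")) {
    agg <- aggregate_observations(data)
    efe_core(model, data$spec, agg$index, agg$weight, eps_tie)
  } else if (inherits(data, "efe_distribution")) {
    keep <- which(data$p > 0)
    efe_core(model, data$spec, keep, data$p[keep], eps_tie)
  } else {
    stop("data must be an efe_obs or efe_distribution")
  }
}
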