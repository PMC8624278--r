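#' Build a reflexive symmetric weighted relation
#'
#' A weighted relation on a finite set is a symmetric matrix of weights in
#' `[0,1]` with unit diagonal. The `k*(k-1)/2` off-diagonal upper-triangle
#' entries are its free parameters, taken in R's column-major upper-triangle
#' order (the same order [relation_to_vector()] returns).
#'
#' @param domain Character vector of element names, or an integer count.
#' @param off_diagonal Numeric vector of the free weights (length
#'   `k*(k-1)/2`), or a single value recycled. Defaults to all ones.
#' @return A `k x k` symmetric matrix with `dimnames` set.
#' @examples
#' make_relation(3, c(0.9, 0.5, 0.2))
#' @export
make_relation <- function(domain, off_diagonal = 1) {
  if (is.numeric(domain) && length(domain) == 1L) {
    domain <- as.character(seq_len(domain) - 1L)
  }
  k <- length(domain)
  n_free <- k * (k - 1L) / 2L
  if (length(off_diagonal) == 1L) off_diagonal <- rep(off_diagonal, n_free)
  if (length(off_diagonal) != n_free) {
    stop("need ", n_free, " off-diagonal weights, got ", length(off_diagonal))
  }
  if (any(off_diagonal < 0) || any(off_diagonal > 1)) {
    stop("weights must lie in [0, 1]")
  }
  W <- diag(1, k)
  W[upper.tri(W)] <- off_diagonal
  W[lower.tri(W)] <- t(W)[lower.tri(W)]
  dimnames(W) <- list(domain, domain)
  W
}

#' Free parameters of a weighted relation
#' @param W A symmetric relation matrix.
#' @return Upper-triangle weights in column-major order (the inverse of
#'   [make_relation()]).
#' @export
relation_to_vector <- function(W) W[upper.tri(W)]

# validate a reflexive symmetric [0,1] relation
check_relation <- function(W, what = "relation") {
  if (!is.matrix(W) || nrow(W) != ncol(W)) stop(what, " must be square")
  if (any(abs(diag(W) - 1) > 1e-12)) stop(what, " must have unit diagonal")
  if (max(abs(W - t(W))) > 1e-12) stop(what, " must be symmetric")
  if (any(W < -1e-12) || any(W > 1 + 1e-12)) stop(what, " weights must lie in [0,1]")
  invisible(TRUE)
}

#' Compose a level relation with a system state
#'
#' For a relation `U` on the levels and a state `f`, the composition
#' `U o f` is the node relation `(a, b) -> U(f(a), f(b))`. It is reflexive
#' and symmetric whenever `U` is.
#'
#' @param U Relation matrix over the levels (`m x m`).
#' @param f Integer state vector (levels `0..m-1`).
#' @return A `length(f) x length(f)` relation matrix over the nodes.
#' @export
compose_relation <- function(U, f) {
  f <- as.integer(f)
  if (any(f < 0L) || any(f >= nrow(U))) stop("state uses levels outside U's domain")
  U[f + 1L, f + 1L, drop = FALSE]
}

#' d1 distance between weighted relations
#'
#' The sum over unordered off-diagonal pairs of absolute weight differences;
#' the diagonal contributes nothing for reflexive relations. This is the
#' discontinuity metric all float-entropy computations use.
#'
#' @param W1,W2 Relation matrices on the same domain.
#' @return Non-negative scalar.
#' @export
d1 <- function(W1, W2) {
  if (!identical(dim(W1), dim(W2))) stop("domain mismatch")
  sum(abs(W1 - W2)[upper.tri(W1)])
}

#' The canonical gray-scale relation
#'
#' Weights decrease linearly with level distance:
#' `U(i, j) = 1 - |i - j| / (m - 1)`. Any strictly distance-decreasing
#' weighting has the same automorphism group (identity and reversal), which
#' is all the permutation checks depend on.
#'
#' @param m Number of levels.
#' @return An `m x m` relation matrix.
#' @export
gray_relation <- function(m) {
  i <- seq_len(m) - 1L
  W <- 1 - abs(outer(i, i, "-")) / (m - 1)
  dimnames(W) <- list(i, i)
  W
}

#' Test whether a level permutation preserves a relation
#'
#' @param g Integer permutation of `0..m-1` given as the image vector:
#'   `g[i + 1]` is the image of level `i`.
#' @param U Relation matrix over the levels.
#' @return `TRUE` iff `U(g(u), g(v)) = U(u, v)` for all pairs.
#' @export
is_relation_automorphism <- function(g, U) {
  m <- nrow(U)
  g <- as.integer(g)
  if (length(g) != m || !setequal(g, 0:(m - 1L))) {
    stop("g must be a permutation of 0..", m - 1L)
  }
  max(abs(U[g + 1L, g + 1L] - U)) <= 1e-12
}

#' Validate a value permutation for subsystem scrambling
#'
#' A permutation qualifies iff it is a derangement (no fixed points) and is
#' not an automorphism of the reference gray-scale relation, so that
#' applying it to a subsystem genuinely changes the subsystem's
#' distribution rather than merely relabelling the gray scale.
#'
#' @param g Integer permutation image vector over `0..m-1`.
#' @param U_ref Reference relation; defaults to [gray_relation()] on
#'   `length(g)` levels.
#' @return `TRUE` or `FALSE`, with a `reason` attribute when `FALSE`.
#' @export
is_valid_value_permutation <- function(g, U_ref = gray_relation(length(g))) {
  g <- as.integer(g)
  if (any(g == seq_along(g) - 1L)) {
    return(structure(FALSE, reason = "has a fixed point (not a derangement)"))
  }
  if (is_relation_automorphism(g, U_ref)) {
    return(structure(FALSE, reason = "is an automorphism of the gray scale"))
  }
  TRUE
}

#' Create a primary relational model
#'
#' A primary model pairs a node relation `R` with a level relation `U`; its
#' EFE-minimising choice interprets the system's states.
#'
#' @param R Relation matrix over the nodes.
#' @param U Relation matrix over the levels.
#' @return An object of class `primary_model`.
#' @export
primary_model <- function(R, U) {
  check_relation(R, "R")
  check_relation(U, "U")
  structure(list(R = R, U = U), class = "primary_model")
}

#' @export
print.primary_model <- function(x, digits = 5, ...) {
  cat("Primary relational model: ", nrow(x$R), " nodes, ", nrow(x$U),
      " levels\n", sep = "")
  cat("R:\n"); print(round(x$R, digits))
  cat("U:\n"); print(round(x$U, digits))
  invisible(x)
}

# free parameter vector of a model: R upper triangle then U upper triangle
model_to_par <- function(model) {
  c(relation_to_vector(model$R), relation_to_vector(model$U))
}

# rebuild a model from a free parameter vector
par_to_model <- function(par, nodes, m) {
  k <- length(nodes)
  n_r <- k * (k - 1L) / 2L
  R <- make_relation(nodes, if (n_r > 0) par[seq_len(n_r)] else numeric(0))
  U <- make_relation(as.character(0:(m - 1L)), par[n_r + seq_len(m * (m - 1L) / 2L)])
  primary_model(R, U)
}

#' Write a primary model to JSON
#'
#' Stores the node and level identifiers, both full weight matrices
#' (authoritative) and the free-parameter vector, with full precision.
#'
#' @param model A `primary_model`.
#' @param path Output path.
#' @param extra Optional named list merged into the JSON object.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, extra = NULL) {
  obj <- list(nodes = rownames(model$R),
              levels = rownames(model$U),
              R = unname(model$R),
              U = unname(model$U),
              parameters = model_to_par(model))
  if (!is.null(extra)) obj <- c(obj, extra)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a primary model from JSON
#' @param path Path to a JSON file written by [write_model()].
#' @return A `primary_model`.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  R <- as.matrix(obj$R); U <- as.matrix(obj$U)
  dimnames(R) <- list(obj$nodes, obj$nodes)
  dimnames(U) <- list(obj$levels, obj$levels)
  primary_model(R, U)
}
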