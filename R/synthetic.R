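# Synthetic corpus generators.
#
# The smooth-field process emulates the statistical structure of everyday
# photographs: Gaussian-blurred white noise carries the same adjacency
# structure (nearby pixels correlate, nearby gray levels co-occur) that the
# study's image corpora owe to regularities in the world. Fields are
# rendered to 8-bit gray, contrast-stretched, posterized and grid-sampled
# with the same pipeline real images go through.

# row-smoothing matrices for a separable Gaussian blur of length scale sigma
blur_operator <- function(size, sigma) {
  i <- seq_len(size)
  K <- exp(-outer(i, i, "-")^2 / (2 * sigma^2))
  K / rowSums(K)
}

# one smooth random field, already posterized to m levels
smooth_field <- function(h, w, sigma, m) {
  Ky <- blur_operator(h, sigma)
  Kx <- blur_operator(w, sigma)
  f <- Ky %*% matrix(stats::rnorm(h * w), h, w) %*% t(Kx)
  rng <- range(f)
  img <- round((f - rng[1]) * 255 / (rng[2] - rng[1]))
  posterize(img, m)
}

#' Generate a smooth-source observation corpus
#'
#' Each observation samples an independent smooth random field on the node
#' grid, emulating a corpus of photographs of everyday scenes: spatially
#' adjacent nodes correlate and adjacent gray levels co-occur. Seeded and
#' bit-reproducible.
#'
#' @param n_obs Number of observations (default 410, the study's corpus
#'   size).
#' @param seed Integer seed.
#' @param layout A [grid_layout()] (default the six-node 2 x 3 grid).
#' @param m Number of levels (default 4).
#' @param smoothness Blur length scale in pixels; defaults to twice the
#'   node spacing so that adjacent samples usually fall in one smooth
#'   region.
#' @return An `efe_obs`.
#' @export
gen_smooth_corpus <- function(n_obs = 410L, seed = 1L,
                              layout = grid_layout(), m = 4L,
                              smoothness = 2 * layout$spacing) {
  stopifnot(n_obs >= 1L)
  dm <- layout_image_dim(layout)
  n <- layout$rows * layout$cols
  set.seed(seed)
  states <- matrix(NA_integer_, n_obs, n)
  for (i in seq_len(n_obs)) {
    states[i, ] <- sample_grid(smooth_field(dm["height"], dm["width"],
                                            smoothness, m), layout)
  }
  observations(states, efe_system(n, m))
}

# a single-row sub-layout of `layout` (row index 0-based)
row_layout <- function(layout, row) {
  grid_layout(rows = 1L, cols = layout$cols,
              anchor = c(layout$anchor[1],
                         layout$anchor[2] + row * layout$spacing),
              spacing = layout$spacing)
}

# a corpus over one row of the grid, nodes named by the caller
gen_row_corpus <- function(n_obs, seed, layout, m, smoothness, row,
                           node_names) {
  dm <- layout_image_dim(layout)
  rl <- row_layout(layout, row)
  set.seed(seed)
  states <- matrix(NA_integer_, n_obs, layout$cols)
  for (i in seq_len(n_obs)) {
    states[i, ] <- sample_grid(smooth_field(dm["height"], dm["width"],
                                            smoothness, m), rl)
  }
  observations(states, efe_system(node_names, m))
}

#' Generate two independent, similarly distributed row subsystems
#'
#' Draws a top-row corpus and a bottom-row corpus from independent smooth
#' fields and combines them with [product_observations()], the sample
#' analogue of taking a product distribution: the two three-node blocks
#' have exactly zero empirical mutual information. With the default sizes
#' the product has `200^2 = 40,000` observations.
#'
#' @param n_a,n_b Base corpus sizes (default 200 each).
#' @inheritParams gen_smooth_corpus
#' @return An `efe_obs` over the six-node system.
#' @export
gen_independent_pair <- function(n_a = 200L, n_b = 200L, seed = 1L,
                                 layout = grid_layout(), m = 4L,
                                 smoothness = 2 * layout$spacing) {
  stopifnot(layout$rows == 2L)
  n <- layout$rows * layout$cols
  top_names <- paste0("node_", seq_len(layout$cols))
  bot_names <- paste0("node_", layout$cols + seq_len(layout$cols))
  ta <- gen_row_corpus(n_a, restart_seed(seed, 1L), layout, m, smoothness,
                       row = 0L, node_names = top_names)
  tb <- gen_row_corpus(n_b, restart_seed(seed, 2L), layout, m, smoothness,
                       row = 1L, node_names = bot_names)
  product_observations(ta, tb)
}

#' Generate a mismatched-source pair corpus
#'
#' Each observation pairs the top-row sample of one smooth field with the
#' bottom-row sample of an independently drawn field: the two rows are
#' similarly distributed but lack joint regularity (and, unlike the
#' product construction, are not exactly independent as samples — a rare
#' top-row state pins its paired bottom-row state within the corpus).
#'
#' @inheritParams gen_smooth_corpus
#' @return An `efe_obs` over the six-node system.
#' @export
gen_mismatched_pair <- function(n_obs = 410L, seed = 1L,
                                layout = grid_layout(), m = 4L,
                                smoothness = 2 * layout$spacing) {
  stopifnot(layout$rows == 2L)
  dm <- layout_image_dim(layout)
  top <- row_layout(layout, 0L)
  bottom <- row_layout(layout, 1L)
  set.seed(seed)
  n <- layout$rows * layout$cols
  states <- matrix(NA_integer_, n_obs, n)
  for (i in seq_len(n_obs)) {
    f1 <- smooth_field(dm["height"], dm["width"], smoothness, m)
    f2 <- smooth_field(dm["height"], dm["width"], smoothness, m)
    states[i, ] <- c(sample_grid(f1, top), sample_grid(f2, bottom))
  }
  observations(states, efe_system(n, m))
}

#' Apply a value permutation to a subsystem's observations
#'
#' Maps the levels of the named nodes through the permutation `g`, which
#' must be a derangement and must not be an automorphism of the gray-scale
#' relation (otherwise it would amount to a relabelling rather than a
#' genuine change of the subsystem's distribution).
#'
#' @param obs An `efe_obs`.
#' @param nodes Subsystem whose values to permute.
#' @param g Integer permutation image vector over `0..m-1`.
#' @param U_ref Reference relation for the automorphism check.
#' @return An `efe_obs` of the same size.
#' @export
apply_value_permutation <- function(obs, nodes, g,
                                    U_ref = gray_relation(obs$spec$m)) {
  ok <- is_valid_value_permutation(g, U_ref)
  if (!isTRUE(ok)) {
    stop("invalid value permutation: ", attr(ok, "reason"))
  }
  idx <- resolve_subsystem(obs$spec, nodes)
  st <- obs$states
  st[, idx] <- matrix(as.integer(g)[st[, idx, drop = FALSE] + 1L],
                      nrow = nrow(st))
  observations(st, obs$spec)
}

#' Generate a value-permuted pair corpus
#'
#' A mismatched-source corpus whose bottom-row values are scrambled by a
#' qualifying permutation (default the 4-cycle `0->1->2->3->0`), making the
#' two subsystems differently distributed as well as jointly irregular.
#'
#' @inheritParams gen_mismatched_pair
#' @param g Value permutation (image vector); must pass
#'   [is_valid_value_permutation()].
#' @return An `efe_obs` over the six-node system.
#' @export
gen_permuted_pair <- function(n_obs = 410L, seed = 1L,
                              layout = grid_layout(), m = 4L,
                              smoothness = 2 * layout$spacing,
                              g = c(seq_len(m - 1L), 0L)) {
  obs <- gen_mismatched_pair(n_obs, seed, layout, m, smoothness)
  bottom <- paste0("node_", layout$cols + seq_len(layout$cols))
  apply_value_permutation(obs, bottom, g)
}

#' Construct small explicit distributions
#'
#' Named constructions for exact small-system work: a point mass, the
#' uniform distribution, the two-state symmetric distribution
#' (`P(00..0) = P(11..1) = 1/2`), a product of given block distributions,
#' or an arbitrary normalised table.
#'
#' @param kind One of `"point"`, `"uniform"`, `"two_state"`, `"product"`,
#'   `"table"`.
#' @param spec An [efe_system()] (ignored for `"product"`).
#' @param state For `"point"`: the supported state (integer vector).
#' @param parts For `"product"`: list of `efe_distribution`s over disjoint
#'   systems (combined in order).
#' @param p For `"table"`: probability vector in canonical state order.
#' @return An `efe_distribution`.
#' @export
gen_explicit_distribution <- function(kind = c("uniform", "point",
                                               "two_state", "product",
                                               "table"),
                                      spec = NULL, state = NULL,
                                      parts = NULL, p = NULL) {
  kind <- match.arg(kind)
  if (kind == "product") {
    stopifnot(length(parts) >= 2L)
    acc <- parts[[1L]]
    for (q in parts[-1L]) {
      spec2 <- efe_system(c(acc$spec$nodes, q$spec$nodes), acc$spec$m)
      stopifnot(acc$spec$m == q$spec$m,
                !length(intersect(acc$spec$nodes, q$spec$nodes)))
      # canonical order: first block's nodes are most significant
      acc <- distribution(as.numeric(t(outer(acc$p, q$p))), spec2)
    }
    return(acc)
  }
  stopifnot(inherits(spec, "efe_system"))
  n_states <- spec$m^length(spec$nodes)
  if (kind == "uniform") {
    distribution(rep(1 / n_states, n_states), spec)
  } else if (kind == "point") {
    stopifnot(!is.null(state))
    pv <- numeric(n_states)
    pv[state_index(matrix(as.integer(state), 1), spec$m)] <- 1
    distribution(pv, spec)
  } else if (kind == "two_state") {
    pv <- numeric(n_states)
    pv[1L] <- 0.5
    pv[n_states] <- 0.5
    distribution(pv, spec)
  } else {
    distribution(p, spec)
  }
}
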