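#' Draw a primary model as a graph
#'
#' Nodes at their grid positions joined by solid edges where `R` exceeds
#' the strong threshold and dashed edges in the intermediate band; the
#' levels on a line below, likewise for `U`. The default bands are the
#' ones useful for six-node four-level fits (strong/intermediate 0.87/0.74
#' for `R`, 0.4/0.05 for `U`).
#'
#' @param model A [primary_model()].
#' @param r_thresholds,u_thresholds Numeric `c(strong, intermediate)`
#'   with `strong > intermediate`.
#' @param layout A [grid_layout()] giving node positions (defaults to a
#'   row-major grid sized to the node count).
#' @param main Plot title.
#' @return The model, invisibly.
#' @export
plot_model_graph <- function(model, r_thresholds = c(0.87, 0.74),
                             u_thresholds = c(0.4, 0.05), layout = NULL,
                             main = "primary model") {
  stopifnot(r_thresholds[1] > r_thresholds[2],
            u_thresholds[1] > u_thresholds[2])
  k <- nrow(model$R); m <- nrow(model$U)
  if (is.null(layout)) {
    cols <- ceiling(sqrt(k)); rows <- ceiling(k / cols)
    if (k == 6) { rows <- 2; cols <- 3 }
    layout <- grid_layout(rows, cols, anchor = c(0, 0), spacing = 1)
  }
  xy <- layout_coords(layout)[seq_len(k), , drop = FALSE]
  pos_x <- xy[, "x"]; pos_y <- -xy[, "y"]
  u_x <- seq(min(pos_x), max(pos_x), length.out = m)
  u_y <- rep(min(pos_y) - 1.5 * layout$spacing, m)
  graphics::plot(NA, xlim = range(c(pos_x, u_x)) + c(-0.5, 0.5),
                 ylim = range(c(pos_y, u_y)) + c(-0.5, 0.5),
                 axes = FALSE, xlab = "", ylab = "", main = main, asp = 1)
  draw_edges <- function(W, px, py, thresholds) {
    for (a in seq_len(nrow(W) - 1L)) {
      for (b in (a + 1L):nrow(W)) {
        wt <- W[a, b]
        if (wt > thresholds[1]) {
          graphics::segments(px[a], py[a], px[b], py[b], lwd = 2)
        } else if (wt > thresholds[2]) {
          graphics::segments(px[a], py[a], px[b], py[b], lty = 2)
        }
      }
    }
  }
  draw_edges(model$R, pos_x, pos_y, r_thresholds)
  draw_edges(model$U, u_x, u_y, u_thresholds)
  graphics::points(pos_x, pos_y, pch = 21, bg = "white", cex = 3)
  graphics::text(pos_x, pos_y, seq_len(k), cex = 0.8)
  lv <- if (!is.null(rownames(model$U))) rownames(model$U)
        else as.character(0:(m - 1))
  graphics::points(u_x, u_y, pch = 22,
                   bg = grDevices::gray(seq(0, 1, length.out = m)), cex = 3)
  graphics::text(u_x, u_y - 0.06 * diff(range(c(pos_y, u_y)) + c(-1, 1)),
                 lv, cex = 0.7, pos = 1)
  invisible(model)
}

#' Write a model graph to a PNG file
#'
#' @inheritParams plot_model_graph
#' @param path Output PNG path.
#' @param ... Passed to [plot_model_graph()].
#' @return `path`, invisibly.
#' @export
write_model_graph <- function(model, path, ...) {
  grDevices::png(path, width = 700, height = 600)
  on.exit(grDevices::dev.off())
  plot_model_graph(model, ...)
  invisible(path)
}

#' Run a complete synthetic investigation
#'
#' Reproduces the structure of the four study designs on seeded synthetic
#' corpora: (1) a single smooth source over all six nodes, (2) two
#' independent row subsystems combined by Cartesian product, (3) two rows
#' sampling different sources per observation, (4) design 3 with the
#' bottom row's values scrambled by a qualifying permutation. Generates
#' the corpus, fits the whole-system model, runs the unity analysis, and
#' writes the corpus CSV, the fitted model JSON, a JSON report, a mu
#' profile plot and a model graph into `out_dir`.
#'
#' @param example_id 1, 2, 3 or 4.
#' @param seed Master seed for generation and optimisation.
#' @param out_dir Output directory (created if missing); `NULL` skips all
#'   file output.
#' @param control An [efe_control()].
#' @param g Value permutation for design 4.
#' @return A list with the corpus, the whole-system `efe_fit`, the
#'   `unity_report`, and (designs 2-4) per-row sub-reports.
#' @export
run_example_analog <- function(example_id, seed = 1L, out_dir = NULL,
                               control = efe_control(restarts = 8L,
                                                     seed = seed),
                               g = c(1L, 2L, 3L, 0L)) {
  stopifnot(example_id %in% 1:4)
  if (example_id == 4) {
    ok <- is_valid_value_permutation(g, gray_relation(4))
    if (!isTRUE(ok)) stop("invalid value permutation: ", attr(ok, "reason"))
  }
  obs <- switch(example_id,
                gen_smooth_corpus(seed = seed),
                gen_independent_pair(seed = seed),
                gen_mismatched_pair(seed = seed),
                gen_permuted_pair(seed = seed, g = g))
  report <- unity_analysis(obs, control = control)
  fit <- list(model = report$whole$model, efe_min = report$whole$efe_min)
  rows <- NULL
  if (example_id >= 2) {
    top <- paste0("node_", 1:3); bottom <- paste0("node_", 4:6)
    rows <- list(
      top = unity_analysis(obs, nodes = top, control = control,
                           cache = report$cache, lemma1 = FALSE),
      bottom = unity_analysis(obs, nodes = bottom, control = control,
                              cache = report$cache, lemma1 = FALSE))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_observations(obs, file.path(out_dir, "obs.csv"),
                       extra = c(seed = seed, design = example_id))
    write_model(report$whole$model, file.path(out_dir, "model.json"),
                extra = list(efe_min = report$whole$efe_min))
    json <- list(design = example_id, seed = seed,
                 efe_min = report$whole$efe_min, M = report$M,
                 has_unity = report$has_unity,
                 argmin = lapply(report$argmin[[1]], as.character),
                 lemma1_ok = if (!is.null(report$lemma1)) report$lemma1$ok,
                 mu = as.list(report$mu))
    if (!is.null(rows)) {
      json$rows <- list(top = list(M = rows$top$M,
                                   efe_min = rows$top$whole$efe_min),
                        bottom = list(M = rows$bottom$M,
                                      efe_min = rows$bottom$whole$efe_min))
    }
    jsonlite::write_json(json, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    try({
      grDevices::png(file.path(out_dir, "mu_profile.png"), 700, 500)
      plot(report, main = sprintf("mu profile (design %d)", example_id))
      grDevices::dev.off()
      write_model_graph(report$whole$model,
                        file.path(out_dir, "model_graph.png"))
    }, silent = TRUE)
  }
  list(obs = obs, fit = fit, report = report, rows = rows)
}
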