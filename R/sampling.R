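#' Node grid layout for image sampling
#'
#' Nodes are numbered row-major (node 1 top-left). Node `(row, col)` reads
#' the pixel at `(x0 + col*spacing, y0 + row*spacing)` with 0-based pixel
#' coordinates, x rightward, y downward.
#'
#' @param rows,cols Grid shape (default the 2 x 3 six-node grid).
#' @param anchor Pixel coordinate `c(x0, y0)` of node 1.
#' @param spacing Pixels between adjacent nodes.
#' @return A list of class `grid_layout`.
#' @export
grid_layout <- function(rows = 2L, cols = 3L, anchor = c(4L, 4L),
                        spacing = 6L) {
  stopifnot(rows >= 1, cols >= 1, spacing >= 1, length(anchor) == 2)
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 anchor = as.integer(anchor), spacing = as.integer(spacing)),
            class = "grid_layout")
}

layout_coords <- function(layout) {
  # row-major node order; returns 0-based (x, y) per node
  g <- expand.grid(col = 0:(layout$cols - 1L), row = 0:(layout$rows - 1L))
  cbind(x = layout$anchor[1] + g$col * layout$spacing,
        y = layout$anchor[2] + g$row * layout$spacing)
}

# smallest image (width, height) that contains the layout with symmetric
# margins equal to the anchor
layout_image_dim <- function(layout) {
  c(width = 2L * layout$anchor[1] + (layout$cols - 1L) * layout$spacing + 1L,
    height = 2L * layout$anchor[2] + (layout$rows - 1L) * layout$spacing + 1L)
}

#' Desaturate an image to 8-bit gray
#'
#' RGB images are converted with the ITU-R BT.601 luminance weights
#' (0.299, 0.587, 0.114); gray input passes through. Pixel values are
#' integers in `0..255`.
#'
#' @param img Numeric matrix (gray, `0..255`) or `h x w x 3` array.
#' @return Integer-valued gray matrix.
#' @export
desaturate <- function(img) {
  if (is.matrix(img)) {
    out <- img
  } else if (length(dim(img)) == 3L && dim(img)[3] >= 3L) {
    out <- matrix(0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3],
                  nrow = dim(img)[1])
  } else {
    stop("unsupported image shape")
  }
  if (min(out) < 0 || max(out) > 255) stop("pixel values must lie in 0..255")
  round(out)
}

#' Linear min-max contrast stretch
#'
#' When enabled, maps the gray range linearly onto `[0, 255]`; disabled
#' (the default elsewhere in the pipeline) it is the identity. A constant
#' image cannot be stretched and passes through with a warning.
#'
#' @param img Gray matrix, `0..255`.
#' @param enabled Apply the stretch?
#' @return Gray matrix.
#' @export
enhance_contrast <- function(img, enabled = TRUE) {
  if (!enabled) return(img)
  rng <- range(img)
  if (rng[1] == rng[2]) {
    warning("constant image: contrast stretch skipped")
    return(img)
  }
  round((img - rng[1]) * 255 / (rng[2] - rng[1]))
}

#' Posterize a gray image to m levels
#'
#' Equal-width bins on `[0, 256)`: `level = floor(gray * m / 256)`, so for
#' `m = 4` the bins are `[0,64), [64,128), [128,192), [192,256)`.
#' Monotone in the gray value.
#'
#' @param img Gray matrix, `0..255`.
#' @param m Number of levels (2..256).
#' @return Integer matrix of levels `0..m-1`.
#' @export
posterize <- function(img, m = 4L) {
  stopifnot(m >= 2, m <= 256)
  lv <- floor(img * m / 256)
  matrix(as.integer(pmin(lv, m - 1L)), nrow = nrow(img))
}

#' Sample a level image on a node grid
#'
#' By default each node reads the single pixel at its grid coordinate;
#' `patch_radius > 0` instead averages the `(2r+1) x (2r+1)` window
#' around it (rounded to the nearest level).
#'
#' @param level_img Integer matrix of levels (from [posterize()]).
#' @param layout A [grid_layout()].
#' @param patch_radius Half-width of the averaging window in pixels
#'   (0 = point sample, the default).
#' @return Integer state vector, one level per node in row-major node
#'   order.
#' @export
sample_grid <- function(level_img, layout, patch_radius = 0L) {
  xy <- layout_coords(layout)
  h <- nrow(level_img); w <- ncol(level_img)
  r <- as.integer(patch_radius)
  if (any(xy[, "x"] < r) || any(xy[, "x"] >= w - r) ||
      any(xy[, "y"] < r) || any(xy[, "y"] >= h - r)) {
    stop("sampling coordinate outside the image")
  }
  if (r == 0L) {
    return(level_img[cbind(xy[, "y"] + 1L, xy[, "x"] + 1L)])
  }
  vapply(seq_len(nrow(xy)), function(i) {
    win <- level_img[xy[i, "y"] + 1L + (-r:r), xy[i, "x"] + 1L + (-r:r)]
    as.integer(round(mean(win)))
  }, 0L)
}

#' Read a PNG or TIFF image as an 8-bit array
#'
#' @param path Image file path (`.png` or `.tif(f)`).
#' @return Gray matrix or RGB array with values `0..255`.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE)) stop("package 'png' needed")
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) stop("package 'tiff' needed")
    tiff::readTIFF(path)
  } else {
    stop("unsupported image format: ", ext)
  }
  if (length(dim(img)) == 3L && dim(img)[3] == 4L) img <- img[, , 1:3]
  round(img * 255)
}

#' Sample a corpus of images into an observation set
#'
#' Runs the full protocol on every image with identical settings:
#' desaturate, optionally contrast-stretch, posterize to `m` levels, then
#' read one pixel per node on the grid. One observation per image, in
#' input order. Any per-image failure aborts the run (the protocol demands
#' uniform processing) with all failures reported.
#'
#' @param images List of in-memory images (matrices/arrays, `0..255`) or a
#'   character vector of file paths.
#' @param layout A [grid_layout()].
#' @param m Number of posterization levels.
#' @param contrast Apply the contrast stretch (default off; it is not
#'   needed, but can reduce the number of samples required).
#' @return An `efe_obs` with `|T| =` number of images.
#' @export
sample_corpus <- function(images, layout = grid_layout(), m = 4L,
                          contrast = FALSE) {
  if (is.character(images)) images <- as.list(images)
  stopifnot(length(images) >= 1L)
  n <- layout$rows * layout$cols
  states <- matrix(NA_integer_, nrow = length(images), ncol = n)
  failures <- character(0)
  for (i in seq_along(images)) {
    res <- tryCatch({
      img <- images[[i]]
      if (is.character(img)) img <- read_image(img)
      sample_grid(posterize(enhance_contrast(desaturate(img), contrast), m),
                  layout)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("image %d: %s", i, conditionMessage(res)))
    } else {
      states[i, ] <- res
    }
  }
  if (length(failures)) {
    stop("sampling failed for ", length(failures), " image(s):\n  ",
         paste(utils::head(failures, 5L), collapse = "\n  "))
  }
  observations(states, efe_system(n, m))
}
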