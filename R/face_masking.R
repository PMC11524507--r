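#' Lower-face mask region from 68 landmarks
#'
#' Traces the mask polygon along the jaw landmarks (0-based indices 2
#' through 14 by default) and closes it across the face through the
#' mid-nose-bridge landmark 29, giving a simple polygon that covers the
#' nose tip and all mouth landmarks while excluding every eye landmark —
#' the functional definition of wide-medium lower-face coverage. The vertex
#' recipe is configurable.
#'
#' @param lm A [landmarks68()] object.
#' @param recipe Integer vector of 0-based landmark indices tracing the
#'   polygon in order; default `c(2:14, 29)`.
#' @return Object of class `mask_region`: list with `vertices` (n x 2),
#'   `coverage`, `width`, `height`.
#' @export
mask_polygon <- function(lm, recipe = c(2:14, 29)) {
  stopifnot(inherits(lm, "landmarks68"))
  v <- lm$points[recipe + 1L, , drop = FALSE]
  bad <- polygon_self_intersection(v)
  if (!is.null(bad)) {
    stop(sprintf("mask polygon self-intersects: segments %d-%d and %d-%d cross",
                 bad[1], bad[1] %% nrow(v) + 1L, bad[2], bad[2] %% nrow(v) + 1L),
         call. = FALSE)
  }
  structure(list(vertices = v, coverage = "wide-medium",
                 width = lm$width, height = lm$height),
            class = "mask_region")
}

# first pair of non-adjacent edges that properly intersect, or NULL
polygon_self_intersection <- function(v) {
  n <- nrow(v)
  seg <- cbind(v, v[c(2:n, 1), ])
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    for (j in (i + 2):jmax) {
      d1 <- cross(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 1], seg[j, 2])
      d2 <- cross(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 3], seg[j, 4])
      d3 <- cross(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 1], seg[i, 2])
      d4 <- cross(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 3], seg[i, 4])
      if (((d1 > 0) != (d2 > 0)) && ((d3 > 0) != (d4 > 0)) &&
          d1 != 0 && d2 != 0 && d3 != 0 && d4 != 0) {
        return(c(i, j))
      }
    }
  }
  NULL
}

#' Even-odd point-in-polygon test
#'
#' Crossing-number test with the half-open convention (an edge's lower
#' endpoint is inclusive, its upper exclusive), so rasterisation is
#' deterministic for points on edges.
#'
#' @param px,py Point coordinates (vectorised).
#' @param vertices Polygon vertex matrix (n x 2).
#' @return Logical vector, `TRUE` for interior points.
#' @export
point_in_polygon <- function(px, py, vertices) {
  vx <- vertices[, 1]; vy <- vertices[, 2]
  n <- length(vx)
  jx <- vx[c(n, seq_len(n - 1))]
  jy <- vy[c(n, seq_len(n - 1))]
  inside <- logical(length(px))
  for (k in seq_len(n)) {
    crosses <- ((vy[k] > py) != (jy[k] > py)) &
      (px < (jx[k] - vx[k]) * (py - vy[k]) / (jy[k] - vy[k]) + vx[k])
    inside <- xor(inside, crosses)
  }
  inside
}

#' Composite a mask onto a face raster
#'
#' Fills every pixel whose centre lies strictly inside the mask polygon
#' with pure white (1) or pure black (0); all other pixels are untouched.
#' With `color = "random"` the fill is white with probability 0.5, drawn
#' from `seed`, emulating per-face random mask colouring.
#'
#' @param image Numeric matrix (grayscale) or h x w x c array with values
#'   in \[0, 1\] (as from [png::readPNG()]); dimensions must match the
#'   landmark frame of the region.
#' @param region A [mask_polygon()] result.
#' @param color `"random"`, `"white"` or `"black"`.
#' @param seed Integer seed used when `color = "random"`.
#' @return The masked image, same shape; attribute `fill` records the
#'   colour used.
#' @export
apply_mask <- function(image, region, color = c("random", "white", "black"),
                       seed = 1) {
  color <- match.arg(color)
  stopifnot(inherits(region, "mask_region"))
  d <- dim(image)
  h <- d[1]; w <- d[2]
  if (h != region$height || w != region$width) {
    stop(sprintf("image is %dx%d but the landmark frame is %dx%d",
                 w, h, region$width, region$height), call. = FALSE)
  }
  if (color == "random") {
    set.seed(as.integer(seed))
    color <- if (stats::runif(1) < 0.5) "white" else "black"
  }
  fill <- if (color == "white") 1 else 0
  # pixel (row r, col c) has centre (c - 0.5, r - 0.5), origin top-left
  cx <- rep(seq_len(w) - 0.5, each = h)
  cy <- rep(seq_len(h) - 0.5, times = w)
  inside <- matrix(point_in_polygon(cx, cy, region$vertices), h, w)
  if (length(d) == 2) {
    image[inside] <- fill
  } else {
    for (ch in seq_len(d[3])) {
      plane <- image[, , ch]
      plane[inside] <- fill
      image[, , ch] <- plane
    }
  }
  attr(image, "fill") <- color
  image
}

#' Read / write face rasters as PNG
#'
#' Thin wrappers over [png::readPNG()] and [png::writePNG()] used by the
#' masking stage.
#'
#' @param path PNG file path.
#' @param image Numeric matrix or array with values in \[0, 1\].
#' @return `read_face_png` returns the image; `write_face_png` invisibly
#'   returns `path`.
#' @export
read_face_png <- function(path) png::readPNG(path)

#' @rdname read_face_png
#' @export
write_face_png <- function(image, path) {
  attr(image, "fill") <- NULL
  png::writePNG(image, path)
  invisible(path)
}
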