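#' Construct a 68-point landmark object
#'
#' Standard 68-point facial annotation in pixel coordinates (origin top
#' left, x rightward, y downward, 0-based index convention: jaw 0-16,
#' eyebrows 17-26, nose 27-35, right eye 36-41, left eye 42-47,
#' mouth 48-67).
#'
#' @param face_id Face identifier.
#' @param points 68x2 numeric matrix of (x, y) pixel coordinates.
#' @param width,height Image frame size in pixels.
#' @return Object of class `landmarks68`.
#' @export
landmarks68 <- function(face_id, points, width = 48, height = 48) {
  points <- as.matrix(points)
  if (!identical(dim(points), c(68L, 2L)) || !all(is.finite(points))) {
    stop("points must be a finite 68x2 matrix", call. = FALSE)
  }
  colnames(points) <- c("x", "y")
  structure(list(face_id = as.character(face_id), points = points,
                 width = width, height = height),
            class = "landmarks68")
}

#' Canonical 68-point template face
#'
#' A parametric face in a 48x48-pixel frame (the size of the face-crop
#' images the vote data describe): an elliptical jaw arc, straight brows,
#' nose bridge and base, six-point eyes whose lid separation is set so the
#' raw eye-opening value equals `eye_raw` exactly, and elliptical outer and
#' inner lips. Eye corners sit at the standard indices with the outer corner
#' first on the right eye (36) and the inner corner first on the left
#' eye (42), following the usual detector convention.
#'
#' @param eye_raw Target raw eye-opening value, in (0, 0.6\]; 0 gives a
#'   closed eye with coincident lid points.
#' @param width,height Frame size in pixels.
#' @return A 68x2 coordinate matrix.
#' @export
landmark_template <- function(eye_raw = 0.25, width = 48, height = 48) {
  sx <- width / 48
  sy <- height / 48
  pt <- matrix(NA_real_, 68, 2, dimnames = list(NULL, c("x", "y")))
  # jaw 0-16: ellipse arc, left ear -> chin -> right ear
  t <- seq(0, pi, length.out = 17)
  pt[1:17, ] <- cbind(24 - 18 * cos(t), 16 + 28 * sin(t))
  # eyebrows 17-26
  pt[18:22, ] <- cbind(seq(9, 21, length.out = 5), 13 - c(0, 1, 1.4, 1, 0))
  pt[23:27, ] <- cbind(seq(27, 39, length.out = 5), 13 - c(0, 1, 1.4, 1, 0))
  # nose bridge 27-30 and base 31-35
  pt[28:31, ] <- cbind(24, c(18, 21, 24, 27))
  pt[32:36, ] <- cbind(c(20, 22, 24, 26, 28), 30)
  # eyes: width 9 px, lid separation d chosen so raw opening = d / 9
  d <- eye_raw * 9
  eye <- function(x0, x3) {
    xm1 <- x0 + (x3 - x0) / 3
    xm2 <- x0 + 2 * (x3 - x0) / 3
    rbind(c(x0, 20),            # p0 corner
          c(xm1, 20 - d / 2),   # p1 upper
          c(xm2, 20 - d / 2),   # p2 upper
          c(x3, 20),            # p3 corner
          c(xm2, 20 + d / 2),   # p4 lower
          c(xm1, 20 + d / 2))   # p5 lower
  }
  pt[37:42, ] <- eye(11, 20)   # right eye 36-41, outer corner first
  pt[43:48, ] <- eye(28, 37)   # left eye 42-47, inner corner first
  # mouth: outer lip 48-59 (12 pts), inner lip 60-67 (8 pts)
  a <- seq(0, 2 * pi, length.out = 13)[-13]
  pt[49:60, ] <- cbind(24 + 7 * cos(a), 36 + 3 * sin(a))
  b <- seq(0, 2 * pi, length.out = 9)[-9]
  pt[61:68, ] <- cbind(24 + 4.5 * cos(b), 36 + 1.5 * sin(b))
  cbind(pt[, 1] * sx, pt[, 2] * sy)
}

#' Generate synthetic 68-point landmark sets
#'
#' Produces one landmark set per face from the canonical template, with the
#' raw eye-opening value of each face drawn uniformly from
#' `eye_opening_raw_range` (both eyes identical before jitter) and optional
#' isotropic Gaussian jitter added to every point. The requested raw values
#' are stored in the `eye_raw_target` attribute so zero-jitter round trips
#' can be verified exactly.
#'
#' @param n_faces Number of faces, or a character vector of face ids.
#' @param eye_opening_raw_range Length-2 interval inside (0, 0.6\] (a
#'   degenerate `c(r, r)` interval is allowed, including `c(0, 0)` for
#'   closed eyes).
#' @param jitter_sd Standard deviation, in pixels, of the additive
#'   Gaussian jitter (0 disables it).
#' @param seed Integer seed.
#' @param width,height Frame size in pixels.
#' @return A list of [landmarks68()] objects with attribute
#'   `eye_raw_target`.
#' @export
generate_landmarks <- function(n_faces, eye_opening_raw_range = c(0.15, 0.40),
                               jitter_sd = 0.25, seed = 1,
                               width = 48, height = 48) {
  r <- eye_opening_raw_range
  if (length(r) != 2 || any(is.na(r)) || r[1] > r[2] || r[1] < 0 || r[2] > 0.6) {
    stop("eye_opening_raw_range must be an interval within [0, 0.6]",
         call. = FALSE)
  }
  if (jitter_sd < 0) stop("jitter_sd must be >= 0", call. = FALSE)
  ids <- if (is.character(n_faces)) n_faces else
    sprintf("face%03d", seq_len(n_faces))
  set.seed(as.integer(seed))
  raw <- stats::runif(length(ids), r[1], r[2])
  out <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    p <- landmark_template(raw[k], width, height)
    if (jitter_sd > 0) {
      p <- p + matrix(stats::rnorm(136, 0, jitter_sd), 68, 2)
    }
    out[[k]] <- landmarks68(ids[k], p, width, height)
  }
  names(out) <- ids
  attr(out, "eye_raw_target") <- stats::setNames(raw, ids)
  out
}

#' Generate the study-shaped landmark fixture
#'
#' One landmark set per face of a [stimulus_design()], with the raw
#' eye-opening range depending on the face's design category: fear and
#' surprise faces are given wide-open eyes, all other categories a narrower
#' range, emulating the stimulus property that links those two labels to
#' eye opening.
#'
#' @param design A [stimulus_design()].
#' @param range_wide Raw-opening interval for fear/surprise faces.
#' @param range_narrow Raw-opening interval for the other categories.
#' @param jitter_sd,seed,width,height As in [generate_landmarks()].
#' @return A named list of [landmarks68()] objects.
#' @export
generate_study_landmarks <- function(design, range_wide = c(0.30, 0.40),
                                     range_narrow = c(0.15, 0.25),
                                     jitter_sd = 0.25, seed = 1,
                                     width = 48, height = 48) {
  wide <- design$category %in% c("fear", "surprise")
  lm_w <- generate_landmarks(design$face_id[wide], range_wide, jitter_sd,
                             seed = seed, width = width, height = height)
  lm_n <- generate_landmarks(design$face_id[!wide], range_narrow, jitter_sd,
                             seed = seed + 1L, width = width, height = height)
  out <- c(lm_w, lm_n)[design$face_id]
  attr(out, "eye_raw_target") <-
    c(attr(lm_w, "eye_raw_target"), attr(lm_n, "eye_raw_target"))[design$face_id]
  out
}

#' Write landmark sets to JSON
#'
#' One JSON array with an object per face:
#' `{"face_id": ..., "width": ..., "height": ..., "points": [[x, y] x 68]}`,
#' full double precision.
#'
#' @param landmarks A list of [landmarks68()] objects.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_landmarks_json <- function(landmarks, path) {
  recs <- lapply(landmarks, function(lm) {
    list(face_id = lm$face_id, width = lm$width, height = lm$height,
         points = unname(lm$points))
  })
  jsonlite::write_json(unname(recs), path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read landmark sets from JSON
#' @param path JSON path written by [write_landmarks_json()].
#' @return A named list of [landmarks68()] objects.
#' @export
read_landmarks_json <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = TRUE)
  out <- lapply(seq_len(nrow(recs)), function(i) {
    landmarks68(recs$face_id[i], recs$points[[i]],
                width = recs$width[i], height = recs$height[i])
  })
  names(out) <- recs$face_id
  out
}
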