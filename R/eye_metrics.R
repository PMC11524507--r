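#' Raw eye-opening value from six eye points
#'
#' The aspect-ratio-like statistic
#' `R_raw = (||p5 - p1|| + ||p4 - p2||) / (2 ||p3 - p0||)`: the mean of the
#' two vertical lid distances over twice the eye width (Euclidean
#' distances). p0 and p3 are the eye corners, p1/p2 the upper lid, p5/p4
#' the lower lid, in the standard six-point eye annotation. The value is
#' invariant to translation, rotation, and uniform scaling.
#'
#' @param e 6x2 numeric matrix of (x, y) coordinates, rows p0..p5.
#' @return Non-negative scalar; errors with an undefined-metric condition
#'   when the eye width is zero.
#' @export
#' @examples
#' e <- rbind(c(0, 0), c(1, 0.5), c(3, 0.5), c(4, 0), c(3, -0.5), c(1, -0.5))
#' eye_opening_raw(e)  # 0.25
eye_opening_raw <- function(e) {
  e <- as.matrix(e)
  stopifnot(identical(dim(e), c(6L, 2L)))
  width <- sqrt(sum((e[4, ] - e[1, ])^2))
  if (width == 0) {
    stop(structure(class = c("fervote_undefined_metric", "error", "condition"),
                   list(message = "eye width is zero: R_raw undefined",
                        call = sys.call(-1))))
  }
  v1 <- sqrt(sum((e[6, ] - e[2, ])^2))
  v2 <- sqrt(sum((e[5, ] - e[3, ])^2))
  (v1 + v2) / (2 * width)
}

#' Eye-opening rate from the raw value
#'
#' Affine rescaling `R_rate = (R_raw - 0.15) * 3`, clamped to \[0, 1\] so
#' the statistic reads as a rate; the unclamped value and a clamping flag
#' are retained.
#'
#' @param r_raw Non-negative raw opening value (vectorised).
#' @return Data frame with columns `r_raw`, `r_rate`, `r_unclamped`,
#'   `clamped`.
#' @export
#' @examples
#' eye_opening_rate(0.25)$r_rate  # 0.3
eye_opening_rate <- function(r_raw) {
  stopifnot(all(r_raw >= 0))
  u <- (r_raw - 0.15) * 3
  r <- pmin(pmax(u, 0), 1)
  data.frame(r_raw = r_raw, r_rate = r, r_unclamped = u, clamped = u != r)
}

eye_indices <- function(which) {
  switch(which, right = 37:42, left = 43:48,
         stop("eye must be 'left' or 'right'", call. = FALSE))
}

#' Per-face eye-opening rate from 68 landmarks
#'
#' Extracts the six points of each eye (0-based landmark indices 36-41 and
#' 42-47), computes each eye's opening rate, and combines them: by default
#' the mean of the two eyes; a single eye can be selected instead. If one
#' eye is degenerate (zero width) the other is used with a warning; if both
#' are degenerate an undefined-metric error is raised.
#'
#' @param lm A [landmarks68()] object.
#' @param eye `"mean"` (default), `"left"` or `"right"`.
#' @return List with `r_rate`, `r_raw_left`, `r_raw_right`.
#' @export
face_eye_rate <- function(lm, eye = c("mean", "left", "right")) {
  eye <- match.arg(eye)
  stopifnot(inherits(lm, "landmarks68"))
  raw_of <- function(which) {
    tryCatch(eye_opening_raw(lm$points[eye_indices(which), ]),
             fervote_undefined_metric = function(e) NA_real_)
  }
  raw <- c(left = raw_of("left"), right = raw_of("right"))
  want <- switch(eye, mean = c("left", "right"), left = "left", right = "right")
  use <- raw[want]
  if (all(is.na(raw))) {
    stop(structure(class = c("fervote_undefined_metric", "error", "condition"),
                   list(message = sprintf("face %s: both eyes degenerate, eye metric undefined",
                                          lm$face_id),
                        call = sys.call(-1))))
  }
  if (anyNA(use)) {
    warning(sprintf("face %s: degenerate eye, falling back to the defined eye",
                    lm$face_id), call. = FALSE)
    use <- raw[!is.na(raw)]
  }
  rate <- mean(eye_opening_rate(use[!is.na(use)])$r_rate)
  list(r_rate = rate,
       r_raw_left = unname(raw["left"]),
       r_raw_right = unname(raw["right"]))
}

#' Eye-opening rates for a set of faces
#'
#' @param landmarks A list of [landmarks68()] objects (e.g. from
#'   [generate_landmarks()] or [read_landmarks_json()]).
#' @param eye Passed to [face_eye_rate()].
#' @return Data frame with columns `face_id`, `r_raw_left`, `r_raw_right`,
#'   `r_rate`.
#' @export
eye_rates <- function(landmarks, eye = "mean") {
  rows <- lapply(landmarks, function(lm) {
    r <- face_eye_rate(lm, eye)
    data.frame(face_id = lm$face_id, r_raw_left = r$r_raw_left,
               r_raw_right = r$r_raw_right, r_rate = r$r_rate,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Eye-opening statistics per majority label
#'
#' Groups faces by their majority label, reports mean / SD / n of the
#' per-face eye-opening rate per label, and runs pairwise Tukey-Kramer
#' comparisons between labels. Labels with fewer than 2 faces are excluded
#' from the test (flagged) but still summarised.
#'
#' @param rates Data frame from [eye_rates()] (columns `face_id`,
#'   `r_rate`).
#' @param labels A `majority_labeling` over the same faces.
#' @return Object of class `label_eye_stats`: list with `stats` (per-label
#'   data frame), `p_map` (7x7 Tukey-Kramer p matrix, NA for excluded
#'   labels), `excluded`.
#' @export
label_eye_stats <- function(rates, labels) {
  if (!setequal(rates$face_id, labels$face_id)) {
    stop("rates and labels cover different face sets", call. = FALSE)
  }
  lv <- emotion_levels()
  lab <- labels$label[match(rates$face_id, labels$face_id)]
  lab <- factor(lab, levels = lv)
  stats_df <- data.frame(
    label = lv,
    n = as.integer(table(lab)),
    mean = as.numeric(tapply(rates$r_rate, lab, mean)),
    sd = as.numeric(tapply(rates$r_rate, lab, stats::sd)),
    stringsAsFactors = FALSE
  )
  excluded <- stats_df$label[stats_df$n < 2]
  keep <- !(as.character(lab) %in% excluded)
  p_map <- matrix(NA_real_, 7, 7, dimnames = list(lv, lv))
  if (length(unique(lab[keep])) >= 2) {
    tk <- tukey_kramer(rates$r_rate[keep], as.character(lab[keep]))
    g <- rownames(tk$p)
    p_map[g, g] <- tk$p
  }
  structure(list(stats = stats_df, p_map = p_map, excluded = excluded),
            class = "label_eye_stats")
}
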