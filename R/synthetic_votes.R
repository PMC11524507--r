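#' Stimulus design for a balanced forced-choice study
#'
#' Builds the face set shown to every rater: `n_per_category` faces per
#' emotion category, 7 categories, in canonical label order. The default of
#' 14 faces per category yields the 98-face design used throughout the
#' package's worked examples.
#'
#' @param n_per_category Positive integer; faces per emotion category.
#' @param prefix Prefix for generated face identifiers.
#' @return A data frame with columns `face_id` (unique character) and
#'   `category` (emotion label), one row per face.
#' @export
#' @examples
#' nrow(stimulus_design())  # 98
stimulus_design <- function(n_per_category = 14, prefix = "face") {
  if (length(n_per_category) != 1 || n_per_category < 1 ||
      n_per_category != round(n_per_category)) {
    stop("n_per_category must be a positive integer", call. = FALSE)
  }
  n <- as.integer(n_per_category)
  cats <- rep(emotion_levels(), each = n)
  ids <- sprintf("%s%03d", prefix, seq_along(cats))
  data.frame(face_id = ids, category = cats, stringsAsFactors = FALSE)
}

#' Specify a rater panel
#'
#' A panel is a named group of raters assumed to share one confusion kernel
#' per viewing condition; raters are modelled i.i.d. within the panel.
#'
#' @param group Panel name, e.g. `"western"` or `"east_asian"`.
#' @param n_raters Number of raters (positive integer).
#' @param kernels Named list of confusion kernels keyed by condition, e.g.
#'   `list("non-masked" = k1, "masked" = k2)`.
#' @return An object of class `panel_spec`.
#' @export
panel_spec <- function(group, n_raters, kernels) {
  if (length(n_raters) != 1 || n_raters < 1 || n_raters != round(n_raters)) {
    stop("n_raters must be a positive integer", call. = FALSE)
  }
  if (!is.list(kernels) || is.null(names(kernels)) || any(names(kernels) == "")) {
    stop("kernels must be a named list keyed by condition", call. = FALSE)
  }
  for (k in kernels) validate_kernel(k)
  structure(list(group = as.character(group), n_raters = as.integer(n_raters),
                 kernels = kernels),
            class = "panel_spec")
}

panel_kernel <- function(panel, condition) {
  k <- panel$kernels[[condition]]
  if (is.null(k)) {
    stop(sprintf("panel '%s' has no kernel for condition '%s'",
                 panel$group, condition), call. = FALSE)
  }
  k
}

#' Simulate per-rater forced-choice labels
#'
#' Draws one label per rater and face, independently, from the panel's
#' confusion kernel row for the face's design category. This is the raw
#' (long-format) synthetic analogue of a questionnaire record.
#'
#' @param design Stimulus design from [stimulus_design()].
#' @param panel A [panel_spec()].
#' @param condition Viewing condition; must name a kernel of the panel.
#' @param seed Integer seed; identical seeds give identical draws.
#' @return A data frame with columns `face_id`, `group`, `condition`,
#'   `rater_id`, `label`.
#' @export
simulate_rater_labels <- function(design, panel, condition, seed) {
  kernel <- panel_kernel(panel, condition)
  validate_kernel(kernel)
  lv <- emotion_levels()
  set.seed(as.integer(seed))
  ci <- match_emotion(design$category)
  n_face <- nrow(design)
  nr <- panel$n_raters
  # one multinomial stream per face, rater-major within face
  labels <- character(n_face * nr)
  for (f in seq_len(n_face)) {
    labels[(f - 1L) * nr + seq_len(nr)] <-
      sample(lv, nr, replace = TRUE, prob = kernel[ci[f], ])
  }
  data.frame(
    face_id = rep(design$face_id, each = nr),
    group = panel$group,
    condition = condition,
    rater_id = rep(sprintf("%s_r%02d", panel$group, seq_len(nr)), times = n_face),
    label = labels,
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic vote table
#'
#' Aggregates simulated per-rater labels ([simulate_rater_labels()]) into a
#' [vote_table()]: per face, the count of votes for each of the seven
#' emotions. Every face receives exactly `panel$n_raters` votes.
#'
#' @inheritParams simulate_rater_labels
#' @param labels Optional precomputed result of [simulate_rater_labels()];
#'   when supplied, `seed` is ignored and the counts are tabulated from it.
#' @return A [vote_table()] with one row per face.
#' @export
#' @examples
#' des <- stimulus_design(2)
#' pan <- panel_spec("demo", 5, list("non-masked" = confusion_kernel(diag(7))))
#' generate_votes(des, pan, "non-masked", seed = 1)
generate_votes <- function(design, panel, condition, seed, labels = NULL) {
  if (is.null(labels)) {
    labels <- simulate_rater_labels(design, panel, condition, seed)
  }
  lv <- emotion_levels()
  tab <- table(factor(labels$face_id, levels = design$face_id),
               factor(labels$label, levels = lv))
  counts <- matrix(as.integer(tab), nrow = nrow(design),
                   dimnames = list(NULL, lv))
  vote_table(
    face_id = design$face_id,
    counts = counts,
    group = panel$group,
    condition = condition,
    n_raters = panel$n_raters
  )
}
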