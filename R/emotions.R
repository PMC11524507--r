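#' Canonical emotion labels
#'
#' The seven forced-choice emotion categories in their canonical order:
#' anger, disgust, fear, happiness, sadness, surprise, neutral. This order is
#' used everywhere a deterministic ordering matters, in particular for
#' breaking ties in majority voting (the earliest label in this order wins).
#'
#' @return Character vector of length 7.
#' @export
#' @examples
#' emotion_levels()
emotion_levels <- function() {
  c("anger", "disgust", "fear", "happiness", "sadness", "surprise", "neutral")
}

#' Column order of the FERPlus CSV dialect
#'
#' The crowd-vote CSV layout stores the seven emotion counts in a different
#' order than the canonical one, followed by three extra-label columns
#' (contempt, unknown, NF = not-a-face) whose votes are dropped from the
#' seven-emotion analysis.
#'
#' @return Character vector of the ten vote-count column names, in file order.
#' @export
ferplus_vote_columns <- function() {
  c("neutral", "happiness", "surprise", "sadness", "anger", "disgust", "fear",
    "contempt", "unknown", "NF")
}

ferplus_extra_columns <- function() c("contempt", "unknown", "NF")

#' @keywords internal
match_emotion <- function(x) {
  lv <- emotion_levels()
  i <- match(x, lv)
  if (anyNA(i)) {
    stop("unknown emotion label(s): ", paste(unique(x[is.na(i)]), collapse = ", "),
         call. = FALSE)
  }
  i
}
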