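#' Confusion kernels for synthetic rater panels
#'
#' A confusion kernel is a row-stochastic 7x7 matrix: entry (i, j) is the
#' probability that a rater from the modelled group reports label j for a
#' face whose design (stimulus) category is i. Kernels drive the synthetic
#' vote generator and let recovery experiments plant known perception shifts
#' (e.g. extra fear-to-surprise confusion in one group).
#'
#' @param x A 7x7 numeric matrix; rows and columns follow
#'   [emotion_levels()]. Dimnames are added if missing.
#' @return The validated kernel matrix with emotion dimnames.
#' @export
#' @examples
#' k <- confusion_kernel(diag(7))
#' rowSums(k)
confusion_kernel <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x) || !identical(dim(x), c(7L, 7L))) {
    stop("a confusion kernel must be a numeric 7x7 matrix", call. = FALSE)
  }
  dimnames(x) <- list(emotion_levels(), emotion_levels())
  validate_kernel(x)
  x
}

#' Validate a confusion kernel
#'
#' Checks that every entry is non-negative and every row sums to 1 within
#' `tol`. Errors name the first offending row.
#'
#' @param kernel 7x7 numeric matrix.
#' @param tol Row-sum tolerance (default `1e-9`).
#' @return Invisibly, the kernel.
#' @export
validate_kernel <- function(kernel, tol = 1e-9) {
  if (!is.matrix(kernel) || !identical(dim(kernel), c(7L, 7L))) {
    stop("kernel must be a 7x7 matrix", call. = FALSE)
  }
  if (any(kernel < 0)) {
    bad <- which(rowSums(kernel < 0) > 0)[1L]
    stop(sprintf("kernel row '%s' has negative entries", emotion_levels()[bad]),
         call. = FALSE)
  }
  rs <- rowSums(kernel)
  off <- abs(rs - 1) > tol
  if (any(off)) {
    bad <- which(off)[1L]
    stop(sprintf("kernel row '%s' sums to %.12g, not 1", emotion_levels()[bad],
                 rs[bad]), call. = FALSE)
  }
  invisible(kernel)
}

#' Plant a confusion shift in a kernel
#'
#' Moves `magnitude` probability mass in row `from` off the diagonal cell
#' (`from`, `from`) into cell (`from`, `to`). Used to construct group kernels
#' that differ by a single, known perception shift (the classic example being
#' fear faces reported as surprise), so downstream shift-map analyses can be
#' checked for parameter recovery.
#'
#' @param kernel 7x7 row-stochastic matrix.
#' @param from,to Emotion labels (see [emotion_levels()]).
#' @param magnitude Probability mass to move; must not exceed the diagonal
#'   mass `kernel[from, from]`.
#' @return A new kernel with the shift applied; rows still sum to 1.
#' @export
#' @examples
#' k <- inject_shift(confusion_kernel(diag(7)), "fear", "surprise", 0.4)
#' k["fear", c("fear", "surprise")]
inject_shift <- function(kernel, from, to, magnitude) {
  validate_kernel(kernel)
  i <- match_emotion(from)
  j <- match_emotion(to)
  if (magnitude < 0 || magnitude > kernel[i, i] + 1e-12) {
    stop(sprintf("shift magnitude %.4g exceeds diagonal mass %.4g of row '%s'",
                 magnitude, kernel[i, i], from), call. = FALSE)
  }
  kernel[i, i] <- kernel[i, i] - magnitude
  kernel[i, j] <- kernel[i, j] + magnitude
  kernel
}

#' Blend a kernel towards uniform guessing
#'
#' Returns `lambda * kernel + (1 - lambda) * U` where U is the uniform
#' kernel (all entries 1/7). Models a global loss of discriminability, e.g.
#' when the lower face is occluded by a mask.
#'
#' @param kernel 7x7 row-stochastic matrix.
#' @param lambda Retention weight in \[0, 1\]; 1 returns the kernel unchanged.
#' @return A row-stochastic kernel.
#' @export
mix_kernel <- function(kernel, lambda) {
  validate_kernel(kernel)
  stopifnot(lambda >= 0, lambda <= 1)
  lambda * kernel + (1 - lambda) / 7
}

#' Study-shaped default kernels
#'
#' Kernels for the two rater groups and two masking conditions emulated by
#' the synthetic generator. The Western non-masked kernel has diagonal
#' reliability around 0.6-0.9 with the characteristic confusions of
#' forced-choice emotion labelling (fear reported as surprise, sadness as
#' neutral, disgust as anger). The East-Asian non-masked kernel strengthens
#' the fear-to-surprise confusion and replaces most of the sadness-to-neutral
#' drift with sadness-to-disgust. The East-Asian masked kernel additionally
#' degrades reliability towards uniform guessing and adds mask-specific
#' drift of fear to surprise and happiness to neutral.
#'
#' @return Named list with elements `western_nonmasked`, `east_nonmasked`,
#'   `east_masked`, each a 7x7 row-stochastic matrix.
#' @export
study_kernels <- function() {
  lv <- emotion_levels()
  w <- matrix(c(
    # an    di    fe    ha    sa    su    ne
    0.78, 0.06, 0.02, 0.02, 0.05, 0.02, 0.05,  # anger
    0.12, 0.70, 0.02, 0.02, 0.06, 0.02, 0.06,  # disgust
    0.02, 0.02, 0.68, 0.02, 0.04, 0.17, 0.05,  # fear
    0.01, 0.01, 0.01, 0.88, 0.02, 0.03, 0.04,  # happiness
    0.04, 0.05, 0.03, 0.02, 0.62, 0.03, 0.21,  # sadness
    0.02, 0.01, 0.08, 0.04, 0.02, 0.78, 0.05,  # surprise
    0.03, 0.02, 0.02, 0.04, 0.06, 0.02, 0.81   # neutral
  ), nrow = 7, byrow = TRUE, dimnames = list(lv, lv))
  validate_kernel(w)

  e <- w
  e["fear", ]    <- c(0.02, 0.02, 0.59, 0.02, 0.04, 0.26, 0.05)
  e["sadness", ] <- c(0.05, 0.13, 0.03, 0.02, 0.64, 0.03, 0.10)
  validate_kernel(e)

  m <- mix_kernel(e, 0.75)
  m <- inject_shift(m, "fear", "surprise", 0.08)
  m <- inject_shift(m, "happiness", "neutral", 0.10)
  m <- inject_shift(m, "disgust", "neutral", 0.08)

  list(western_nonmasked = w, east_nonmasked = e, east_masked = m)
}
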