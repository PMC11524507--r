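#' Two-dimensional embedding of vote-rate vectors
#'
#' Projects the per-image 7-dimensional vote-rate vectors to 2-D for visual
#' inspection of label structure (which emotions raters keep apart, which
#' overlap). The projection is a deterministic metric embedding delegated to
#' classical multidimensional scaling ([stats::cmdscale()]) on Euclidean
#' distances: identical inputs always give identical coordinates, duplicate
#' rate vectors map to coincident points, and the output has exactly one 2-D
#' point per input vector.
#'
#' @param rates A [rate_matrix][rate_encode()] or a numeric matrix of
#'   7-vectors (one row per image).
#' @param perplexity Neighbourhood-size control retained from the usual
#'   stochastic-embedding interface; used only to enforce the minimum input
#'   size `nrow >= 3 * perplexity`.
#' @param seed Integer seed; the embedding is deterministic, the seed is
#'   consumed so callers can treat this stage like the stochastic ones.
#' @return Matrix with one `(x, y)` row per input vector; attribute
#'   `method` records the embedding used.
#' @export
embed_rates <- function(rates, perplexity = 30, seed = 1) {
  x <- if (inherits(rates, "rate_matrix")) rate_values(rates) else as.matrix(rates)
  n <- nrow(x)
  if (n < 3 * perplexity) {
    stop(sprintf("too few points (%d) for perplexity %g: need at least %d",
                 n, perplexity, ceiling(3 * perplexity)), call. = FALSE)
  }
  set.seed(as.integer(seed))
  y <- stats::cmdscale(stats::dist(x), k = 2)
  if (ncol(y) < 2) y <- cbind(y, matrix(0, n, 2 - ncol(y)))
  dimnames(y) <- list(rownames(x), c("x", "y"))
  attr(y, "method") <- "cmdscale"
  y
}
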