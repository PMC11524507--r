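#' Construct a vote table
#'
#' The central container for crowd-vote data: one row per (face, group,
#' condition) with seven integer vote counts in canonical label order, the
#' panel size, the three extra-label counts of the FERPlus CSV dialect
#' (contempt / unknown / NF), and their sum `dropped_votes`. Votes for the
#' extra labels are dropped from the seven-emotion analysis at the vote
#' level; faces are retained.
#'
#' @param face_id Character vector of unique face identifiers.
#' @param counts Integer matrix, one row per face, columns the seven
#'   emotions in canonical order (see [emotion_levels()]).
#' @param group Rater-group name (recycled).
#' @param condition Viewing condition, `"masked"` or `"non-masked"`
#'   (recycled).
#' @param n_raters Panel size (recycled).
#' @param extras Optional integer matrix with columns contempt, unknown, NF;
#'   defaults to zeros.
#' @param usage Optional split tag column (e.g. `"Training"`); kept for
#'   byte-faithful round-trips of the CSV dialect.
#' @return A data frame of class `vote_table`.
#' @export
vote_table <- function(face_id, counts, group, condition, n_raters,
                       extras = NULL, usage = NULL) {
  lv <- emotion_levels()
  counts <- as.matrix(counts)
  colnames(counts) <- lv
  n <- length(face_id)
  if (nrow(counts) != n) stop("counts must have one row per face", call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("vote counts must be non-negative integers", call. = FALSE)
  }
  if (is.null(extras)) {
    extras <- matrix(0L, n, 3, dimnames = list(NULL, ferplus_extra_columns()))
  }
  extras <- as.matrix(extras)
  colnames(extras) <- ferplus_extra_columns()
  out <- data.frame(
    face_id = as.character(face_id),
    group = rep_len(as.character(group), n),
    condition = rep_len(as.character(condition), n),
    n_raters = rep_len(as.integer(n_raters), n),
    stringsAsFactors = FALSE
  )
  if (!is.null(usage)) out$usage <- rep_len(as.character(usage), n)
  out <- cbind(out, as.data.frame(counts), as.data.frame(extras))
  out$dropped_votes <- as.integer(rowSums(extras))
  bad <- rowSums(counts) + out$dropped_votes > out$n_raters
  if (any(bad)) {
    stop("total votes exceed panel size for face(s): ",
         paste(out$face_id[bad], collapse = ", "), call. = FALSE)
  }
  class(out) <- c("vote_table", "data.frame")
  out
}

vote_counts <- function(votes) {
  m <- as.matrix(as.data.frame(votes)[, emotion_levels(), drop = FALSE])
  rownames(m) <- votes$face_id
  storage.mode(m) <- "integer"
  m
}

#' Read crowd votes from a FERPlus-dialect CSV
#'
#' Parses the standard crowd-vote layout: a header row, a split/usage
#' column, an image-name column, and ten vote-count columns in the dialect
#' order (neutral, happiness, surprise, sadness, anger, disgust, fear,
#' contempt, unknown, NF). Counts are reordered into canonical label order
#' and the three extra-label counts are summed into `dropped_votes`.
#'
#' @param path CSV file path.
#' @param group,condition Metadata attached to every row.
#' @param n_raters Panel size; defaults to the maximum row total over all
#'   ten vote columns.
#' @return A [vote_table()].
#' @export
read_ferplus_votes <- function(path, group = "western", condition = "non-masked",
                               n_raters = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  cols <- ferplus_vote_columns()
  name_col <- intersect(c("Image name", "image name", "image"), names(df))
  usage_col <- intersect(c("Usage", "usage"), names(df))
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols) || length(name_col) == 0) {
    stop("missing column(s): ",
         paste(c(missing_cols, if (length(name_col) == 0) "Image name"),
               collapse = ", "), call. = FALSE)
  }
  votes <- as.matrix(df[, cols])
  if (!is.numeric(votes) || any(is.na(votes)) || any(votes != round(votes))) {
    bad <- which(apply(df[, cols], 1, function(r) {
      v <- suppressWarnings(as.numeric(r))
      any(is.na(v)) || any(v != round(v))
    }))[1L]
    stop(sprintf("non-integer vote count in row %d", bad), call. = FALSE)
  }
  ids <- as.character(df[[name_col[1L]]])
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate face_id '%s' in row %d",
                 ids[anyDuplicated(ids)], anyDuplicated(ids)), call. = FALSE)
  }
  if (is.null(n_raters)) n_raters <- max(rowSums(votes))
  vote_table(
    face_id = ids,
    counts = votes[, emotion_levels(), drop = FALSE],
    group = group, condition = condition, n_raters = n_raters,
    extras = votes[, ferplus_extra_columns(), drop = FALSE],
    usage = if (length(usage_col)) df[[usage_col[1L]]] else NULL
  )
}

#' Write a vote table in the FERPlus CSV dialect
#'
#' Inverse of [read_ferplus_votes()]: emits the usage column, the image
#' name, and the ten vote columns in the exact dialect order, so that
#' reading a written file reproduces the vote table.
#'
#' @param votes A [vote_table()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_ferplus_votes <- function(votes, path) {
  df <- as.data.frame(votes)
  out <- data.frame(
    Usage = if ("usage" %in% names(df)) df$usage else "Training",
    `Image name` = df$face_id,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  for (col in ferplus_vote_columns()) out[[col]] <- df[[col]]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write votes or labels as tidy long CSV
#'
#' @param x A [vote_table()] (written as face_id, group, condition, label,
#'   count) or a per-rater label data frame from [simulate_rater_labels()]
#'   (written as is).
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_votes_long <- function(x, path) {
  if (inherits(x, "vote_table")) {
    cnt <- vote_counts(x)
    x <- data.frame(
      face_id = rep(x$face_id, times = 7),
      group = rep(x$group, times = 7),
      condition = rep(x$condition, times = 7),
      label = rep(emotion_levels(), each = nrow(cnt)),
      count = as.integer(cnt),
      stringsAsFactors = FALSE
    )
  }
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' One-hot majority encoding of a vote table
#'
#' For each face the label with the most votes wins; when several labels tie
#' for the maximum, the earliest in canonical order (anger, disgust, fear,
#' happiness, sadness, surprise, neutral) is chosen and `tie_flag` is set.
#'
#' @param votes A [vote_table()].
#' @return A data frame of class `majority_labeling` with columns `face_id`,
#'   `group`, `condition`, `label`, `tie_flag`.
#' @export
#' @examples
#' v <- vote_table("f1", matrix(c(5, 1, 0, 2, 1, 1, 0), 1), "g", "non-masked", 10)
#' majority_encode(v)$label  # "anger"
majority_encode <- function(votes) {
  cnt <- vote_counts(votes)
  zero <- rowSums(cnt) == 0
  if (any(zero)) {
    stop("cannot majority-encode all-zero vote counts for face(s): ",
         paste(votes$face_id[zero], collapse = ", "), call. = FALSE)
  }
  idx <- max.col(cnt, ties.method = "first")
  mx <- cnt[cbind(seq_len(nrow(cnt)), idx)]
  tie <- rowSums(cnt == mx) > 1L
  out <- data.frame(
    face_id = votes$face_id,
    group = votes$group,
    condition = votes$condition,
    label = emotion_levels()[idx],
    tie_flag = tie,
    stringsAsFactors = FALSE
  )
  class(out) <- c("majority_labeling", "data.frame")
  out
}

#' Vote-rate (soft label) encoding of a vote table
#'
#' Divides each face's seven vote counts by a denominator: by default the
#' panel size, so dropped extra-label votes make the rate vector sum to less
#' than 1; alternatively by the number of retained votes, which renormalises
#' to sum 1.
#'
#' @param votes A [vote_table()].
#' @param denominator `"panel_size"` (default) or `"retained_votes"`.
#' @return A data frame of class `rate_matrix` with columns `face_id`,
#'   `group`, `condition`, `denominator`, and seven rate columns.
#' @export
#' @examples
#' v <- vote_table("f1", matrix(c(5, 1, 0, 2, 1, 1, 0), 1), "g", "non-masked", 10)
#' rate_encode(v)[, emotion_levels()]
rate_encode <- function(votes, denominator = c("panel_size", "retained_votes")) {
  denominator <- match.arg(denominator)
  cnt <- vote_counts(votes)
  den <- switch(denominator,
                panel_size = votes$n_raters,
                retained_votes = rowSums(cnt))
  if (any(den <= 0)) {
    stop("zero denominator for face(s): ",
         paste(votes$face_id[den <= 0], collapse = ", "), call. = FALSE)
  }
  rates <- cnt / den
  out <- data.frame(
    face_id = votes$face_id,
    group = votes$group,
    condition = votes$condition,
    denominator = as.integer(den),
    stringsAsFactors = FALSE
  )
  out <- cbind(out, as.data.frame(rates))
  class(out) <- c("rate_matrix", "data.frame")
  out
}

rate_values <- function(rates) {
  m <- as.matrix(as.data.frame(rates)[, emotion_levels(), drop = FALSE])
  rownames(m) <- rates$face_id
  m
}

#' Write a rate matrix as CSV with canonical-order headers
#' @param rates A [rate_matrix][rate_encode()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_rates_csv <- function(rates, path) {
  utils::write.csv(as.data.frame(rates), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
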