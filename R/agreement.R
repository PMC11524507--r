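#' Build a confusion matrix between a reference labeling and responses
#'
#' Columns are the reference (majority) category, rows the response
#' category. When `responses` is a majority labeling each face contributes
#' one count; when it is a [vote_table()] every individual vote contributes
#' one count (extra-label votes having been dropped upstream). The
#' probability matrix divides each column by its raw column total, so every
#' nonzero column sums to 1.
#'
#' @param reference A `majority_labeling` (see [majority_encode()]).
#' @param responses A `majority_labeling` or a [vote_table()] over the same
#'   face set.
#' @return An object of class `confusion_matrix`: list with `raw` (7x7
#'   integer counts), `prob` (column-normalised), `n_total`.
#' @export
build_confusion <- function(reference, responses) {
  lv <- emotion_levels()
  ref_ids <- reference$face_id
  resp_ids <- responses$face_id
  miss_a <- setdiff(ref_ids, resp_ids)
  miss_b <- setdiff(resp_ids, ref_ids)
  if (length(miss_a) || length(miss_b)) {
    stop("face sets differ between axes; missing from responses: [",
         paste(miss_a, collapse = ", "), "]; missing from reference: [",
         paste(miss_b, collapse = ", "), "]", call. = FALSE)
  }
  ref_lab <- reference$label[match(resp_ids, ref_ids)]
  raw <- matrix(0L, 7, 7, dimnames = list(response = lv, reference = lv))
  if (inherits(responses, "vote_table")) {
    cnt <- vote_counts(responses)
    for (j in seq_len(7)) {
      raw[j, ] <- as.integer(tapply(cnt[, j],
                                    factor(ref_lab, levels = lv), sum,
                                    default = 0L))
    }
  } else if (!is.null(responses$label)) {
    tab <- table(factor(responses$label, levels = lv),
                 factor(ref_lab, levels = lv))
    raw[] <- as.integer(tab)
  } else {
    stop("responses must be a majority labeling or a vote_table", call. = FALSE)
  }
  confusion_from_counts(raw)
}

#' Construct a confusion matrix object from raw counts
#' @param raw 7x7 matrix of non-negative counts (rows = response,
#'   columns = reference).
#' @return A `confusion_matrix` object.
#' @export
confusion_from_counts <- function(raw) {
  raw <- as.matrix(raw)
  if (!identical(dim(raw), c(7L, 7L)) || any(raw < 0)) {
    stop("raw counts must be a non-negative 7x7 matrix", call. = FALSE)
  }
  dimnames(raw) <- list(response = emotion_levels(),
                        reference = emotion_levels())
  cs <- colSums(raw)
  prob <- sweep(raw, 2, ifelse(cs > 0, cs, 1), "/")
  structure(list(raw = raw, prob = prob, n_total = sum(raw)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("confusion matrix (n = %d)  P = %.3f  K = %.3f\n",
              x$n_total, precision(x), kappa_multiclass(x)))
  print(round(x$prob, 3))
  invisible(x)
}

#' Precision of a confusion matrix
#'
#' The proportion of judgements on the main diagonal: the label agreement
#' rate between the two axes, `P = sum(diag(raw)) / n_total`.
#'
#' @param cm A `confusion_matrix`.
#' @return Numeric scalar in \[0, 1\].
#' @export
precision <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (cm$n_total == 0) stop("empty confusion matrix", call. = FALSE)
  sum(diag(cm$raw)) / cm$n_total
}

#' One-vs-rest cell counts for a label
#'
#' Collapses a 7x7 confusion matrix to the 2x2 table of one label against
#' the rest: TP (response = reference = label), FP (response = label,
#' reference differs), FN (reference = label, response differs), TN.
#'
#' @param cm A `confusion_matrix`.
#' @param label An emotion label.
#' @return Named integer vector `c(TP, FP, FN, TN)`.
#' @export
one_vs_rest <- function(cm, label) {
  i <- match_emotion(label)
  tp <- cm$raw[i, i]
  fp <- sum(cm$raw[i, ]) - tp
  fn <- sum(cm$raw[, i]) - tp
  tn <- cm$n_total - tp - fp - fn
  c(TP = tp, FP = fp, FN = fn, TN = tn)
}

#' Binary (one-vs-rest) Cohen's kappa
#'
#' Chance-corrected agreement for a 2x2 table in the closed form
#' `K = 2 (TP*TN - FN*FP) / ((TP+FP)(FP+TN) + (TP+FN)(FN+TN))`, which is
#' algebraically identical to the usual `(po - pe) / (1 - pe)` binary
#' kappa. Returns `NA` (the undefined-kappa signal) when the denominator is
#' zero, i.e. for degenerate margins.
#'
#' @param tp,fp,fn,tn Non-negative counts; vectorised.
#' @return Numeric kappa in \[-1, 1\], or `NA` where undefined.
#' @export
#' @examples
#' kappa_eq2(50, 0, 0, 50)  # 1
kappa_eq2 <- function(tp, fp, fn, tn) {
  num <- 2 * (tp * tn - fn * fp)
  den <- (tp + fp) * (fp + tn) + (tp + fn) * (fn + tn)
  ifelse(den == 0, NA_real_, num / den)
}

#' Multiclass Cohen's kappa of a confusion matrix
#'
#' `K = (po - pe) / (1 - pe)` with observed agreement `po` the diagonal
#' proportion and expected agreement `pe` the sum of products of row and
#' column marginal proportions. Returns `NA` when `pe = 1`.
#'
#' @param cm A `confusion_matrix`.
#' @return Numeric kappa, or `NA` where undefined.
#' @export
kappa_multiclass <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (cm$n_total == 0) stop("empty confusion matrix", call. = FALSE)
  n <- cm$n_total
  po <- sum(diag(cm$raw)) / n
  pe <- sum(rowSums(cm$raw) * colSums(cm$raw)) / n^2
  if (abs(1 - pe) < 1e-12) return(NA_real_)
  (po - pe) / (1 - pe)
}

#' Cell-wise Fisher exact tests on a confusion matrix
#'
#' For every off-diagonal cell (r, c), tests whether responses of label r
#' are enriched in reference column c relative to the rest of the matrix:
#' the 2x2 table is {this cell vs rest of column c} x {column c vs all other
#' columns}, tested two-sided with Fisher's exact test. P-values are
#' corrected across the 42 off-diagonal cells with the Benjamini-Hochberg
#' FDR procedure.
#'
#' @param cm A `confusion_matrix`.
#' @param q FDR threshold used for the `significant` flag (default 0.05).
#' @return Data frame with one row per off-diagonal cell: `response`,
#'   `reference`, `count`, `odds_ratio`, `p`, `p_adj`, `significant`.
#' @export
cell_fisher_tests <- function(cm, q = 0.05) {
  stopifnot(inherits(cm, "confusion_matrix"))
  lv <- emotion_levels()
  rs <- rowSums(cm$raw)
  cs <- colSums(cm$raw)
  n <- cm$n_total
  rows <- list()
  for (ci in seq_len(7)) {
    for (ri in seq_len(7)) {
      if (ri == ci) next
      a <- cm$raw[ri, ci]
      b <- cs[ci] - a
      cc <- rs[ri] - a
      d <- n - a - b - cc
      ft <- stats::fisher.test(matrix(c(a, b, cc, d), 2), alternative = "two.sided")
      rows[[length(rows) + 1L]] <- data.frame(
        response = lv[ri], reference = lv[ci], count = a,
        odds_ratio = unname(ft$estimate), p = ft$p.value,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p_adj < q
  out[order(out$p_adj, out$p), ]
}

kappa_labels <- function(a, b) {
  lv <- emotion_levels()
  a <- factor(a, levels = lv)
  b <- factor(b, levels = lv)
  n <- length(a)
  po <- mean(a == b)
  pe <- sum((table(a) / n) * (table(b) / n))
  if (abs(1 - pe) < 1e-12) return(NA_real_)
  (po - pe) / (1 - pe)
}

#' Average pairwise Cohen's kappa between two rater groups
#'
#' Computes the multiclass kappa for every cross-group pair of raters (one
#' rater from each group, over the common face set) and averages the
#' |A| x |B| values. This is the group-agreement summary appropriate when
#' both axes are panels of individual raters rather than single labelings.
#'
#' @param labels_a,labels_b Per-rater label data frames with columns
#'   `face_id`, `rater_id`, `label` (as from [simulate_rater_labels()]).
#' @return List of class `pairwise_kappa`: `k_avg` (mean over defined
#'   pairs), `k_values` (matrix raters A x raters B), `n_pairs`.
#' @export
mean_pairwise_kappa <- function(labels_a, labels_b) {
  faces <- sort(unique(labels_a$face_id))
  if (!setequal(faces, unique(labels_b$face_id))) {
    stop("the two groups label different face sets", call. = FALSE)
  }
  spread <- function(d, who) {
    raters <- sort(unique(d$rater_id))
    m <- matrix(NA_character_, length(faces), length(raters),
                dimnames = list(faces, raters))
    m[cbind(match(d$face_id, faces), match(d$rater_id, raters))] <- d$label
    bad <- colSums(is.na(m)) > 0
    if (any(bad)) {
      stop(sprintf("rater(s) %s in group %s are missing faces",
                   paste(raters[bad], collapse = ", "), who), call. = FALSE)
    }
    m
  }
  ma <- spread(labels_a, "A")
  mb <- spread(labels_b, "B")
  kv <- matrix(NA_real_, ncol(ma), ncol(mb),
               dimnames = list(colnames(ma), colnames(mb)))
  for (i in seq_len(ncol(ma))) {
    for (j in seq_len(ncol(mb))) {
      kv[i, j] <- kappa_labels(ma[, i], mb[, j])
    }
  }
  structure(list(k_avg = mean(kv, na.rm = TRUE), k_values = kv,
                 n_pairs = length(kv)),
            class = "pairwise_kappa")
}

#' Export a confusion matrix as CSV
#' @param cm A `confusion_matrix`.
#' @param path Output path; raw counts and normalised probabilities are
#'   written stacked with a `matrix` column distinguishing them.
#' @return Invisibly, `path`.
#' @export
write_confusion_csv <- function(cm, path) {
  raw <- data.frame(matrix = "raw", response = rownames(cm$raw),
                    as.data.frame(cm$raw), check.names = FALSE)
  prob <- data.frame(matrix = "prob", response = rownames(cm$prob),
                     as.data.frame(cm$prob), check.names = FALSE)
  utils::write.csv(rbind(raw, prob), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
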