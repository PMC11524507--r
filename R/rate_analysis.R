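#' Order per-image vote-rate vectors into a category-blocked heatmap
#'
#' Arranges the faces (columns) by their reference-group majority category
#' in canonical label order, breaking ties by `face_id`, so each category
#' forms one contiguous block. Rows are the seven emotion labels.
#'
#' @param rates A [rate_matrix][rate_encode()].
#' @param reference A `majority_labeling` over the same faces, defining the
#'   column order (typically the reference group's non-masked majority).
#' @return Object of class `rate_heatmap`: list with `values` (7 x n matrix),
#'   `face_id`, `reference` (the ordered reference labels).
#' @export
order_heatmap <- function(rates, reference) {
  if (!setequal(rates$face_id, reference$face_id)) {
    stop("rates and reference cover different face sets; symmetric difference: ",
         paste(c(setdiff(rates$face_id, reference$face_id),
                 setdiff(reference$face_id, rates$face_id)), collapse = ", "),
         call. = FALSE)
  }
  ref_lab <- reference$label[match(rates$face_id, reference$face_id)]
  ord <- order(match(ref_lab, emotion_levels()), rates$face_id)
  vals <- t(rate_values(rates))[, ord, drop = FALSE]
  structure(list(values = vals,
                 face_id = rates$face_id[ord],
                 reference = ref_lab[ord]),
            class = "rate_heatmap")
}

#' Signed per-image difference of two rate heatmaps
#'
#' Elementwise `B - A` for heatmaps sharing the same face ordering; since
#' both groups rated the very same images, differencing cancels any bias
#' common to a group.
#'
#' @param b,a `rate_heatmap` objects with identical face order and
#'   reference labels.
#' @return Object of class `c("difference_map", "rate_heatmap")`, entries
#'   in \[-1, 1\].
#' @export
difference_map <- function(b, a) {
  stopifnot(inherits(b, "rate_heatmap"), inherits(a, "rate_heatmap"))
  if (!identical(b$face_id, a$face_id) || !identical(b$reference, a$reference)) {
    stop("heatmaps must share the same face ordering and reference labels",
         call. = FALSE)
  }
  structure(list(values = b$values - a$values,
                 face_id = b$face_id,
                 reference = b$reference),
            class = c("difference_map", "rate_heatmap"))
}

#' Category-averaged shift map with FDR-corrected t tests
#'
#' Averages a signed difference map within each reference-category block,
#' giving the 7x7 map of mean vote-rate shifts (rows = reference category,
#' columns = perceived label). Each cell's per-image differences are tested
#' against zero with a one-sample t test; p-values are corrected across all
#' testable cells with the Benjamini-Hochberg FDR procedure.
#'
#' Cells from categories with fewer than 2 images, or with zero variance,
#' are flagged untestable and excluded from the FDR family (their mean is
#' still reported).
#'
#' @param d A `difference_map`.
#' @param q FDR threshold for the `significant` matrix (default 0.05).
#' @return Object of class `category_shift_map`: list of 7x7 matrices
#'   `mean`, `stat`, `p`, `p_adj`, `n_images` (logical `untestable`,
#'   `significant`).
#' @export
category_shift_map <- function(d, q = 0.05) {
  stopifnot(inherits(d, "difference_map"))
  lv <- emotion_levels()
  mk <- function(x) matrix(x, 7, 7, dimnames = list(reference = lv, perceived = lv))
  mean_m <- mk(NA_real_); stat_m <- mk(NA_real_); p_m <- mk(NA_real_)
  n_m <- mk(0L); untest <- mk(TRUE)
  for (i in seq_len(7)) {
    in_cat <- d$reference == lv[i]
    for (j in seq_len(7)) {
      x <- d$values[j, in_cat]
      n <- length(x)
      n_m[i, j] <- n
      if (n == 0) next
      mean_m[i, j] <- mean(x)
      s <- stats::sd(x)
      if (n >= 2 && s > 0) {
        tt <- mean(x) / (s / sqrt(n))
        stat_m[i, j] <- tt
        p_m[i, j] <- 2 * stats::pt(-abs(tt), df = n - 1)
        untest[i, j] <- FALSE
      }
    }
  }
  p_adj <- mk(NA_real_)
  testable <- !untest
  p_adj[testable] <- stats::p.adjust(p_m[testable], method = "BH")
  structure(list(mean = mean_m, stat = stat_m, p = p_m, p_adj = p_adj,
                 n_images = n_m, untestable = untest,
                 significant = !untest & p_adj < q, q = q),
            class = "category_shift_map")
}

#' Top shift cell of a category shift map
#'
#' The cell with the largest positive mean shift, optionally restricted to
#' significant off-diagonal cells.
#'
#' @param m A `category_shift_map`.
#' @param off_diagonal_only Consider only cells with reference != perceived.
#' @param significant_only Consider only FDR-significant cells.
#' @return List with `reference`, `perceived`, `mean`, `p_adj`; or `NULL`
#'   if no eligible cell exists.
#' @export
top_shift_cell <- function(m, off_diagonal_only = TRUE, significant_only = FALSE) {
  stopifnot(inherits(m, "category_shift_map"))
  vals <- m$mean
  elig <- !is.na(vals)
  if (off_diagonal_only) elig <- elig & (row(vals) != col(vals))
  if (significant_only) elig <- elig & m$significant %in% TRUE
  if (!any(elig)) return(NULL)
  vals[!elig] <- -Inf
  ij <- which(vals == max(vals), arr.ind = TRUE)[1, ]
  list(reference = emotion_levels()[ij[1]],
       perceived = emotion_levels()[ij[2]],
       mean = m$mean[ij[1], ij[2]],
       p_adj = m$p_adj[ij[1], ij[2]])
}

#' Per-emotion Pearson correlation of vote rates between two groups
#'
#' For each emotion label, the Pearson correlation across faces between the
#' two groups' per-image rates for that label (all faces pooled regardless
#' of category). Labels with zero variance in either group are returned
#' with `r = NA` and `defined = FALSE`.
#'
#' @param rates_a,rates_b [rate_matrix][rate_encode()] objects over the
#'   same face set.
#' @return Data frame with columns `label`, `r`, `n`, `defined`.
#' @export
per_emotion_correlation <- function(rates_a, rates_b) {
  if (!setequal(rates_a$face_id, rates_b$face_id)) {
    stop("rate matrices cover different face sets", call. = FALSE)
  }
  if (nrow(rates_a) < 3) stop("need at least 3 faces", call. = FALSE)
  va <- rate_values(rates_a)
  vb <- rate_values(rates_b)[match(rates_a$face_id, rates_b$face_id), , drop = FALSE]
  lv <- emotion_levels()
  out <- data.frame(label = lv, r = NA_real_, n = nrow(va), defined = FALSE,
                    stringsAsFactors = FALSE)
  for (j in seq_len(7)) {
    if (stats::sd(va[, j]) > 0 && stats::sd(vb[, j]) > 0) {
      out$r[j] <- stats::cor(va[, j], vb[, j])
      out$defined[j] <- TRUE
    }
  }
  out
}

#' Compare two correlation coefficients via Fisher's r-to-z transform
#'
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, with a
#' two-sided normal p-value.
#'
#' @param r1,r2 Correlations, strictly inside (-1, 1).
#' @param n1,n2 Sample sizes, at least 4.
#' @return List with `z` and `p`.
#' @export
#' @examples
#' compare_correlations(0.9, 98, 0.3, 98)
compare_correlations <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1) {
    stop("correlations of magnitude 1 have an infinite r-to-z transform",
         call. = FALSE)
  }
  if (n1 < 4 || n2 < 4) stop("need n >= 4 in both samples", call. = FALSE)
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Tukey-Kramer pairwise comparisons
#'
#' Studentised-range pairwise comparisons of group means, honouring unequal
#' group sizes (the Tukey-Kramer extension), via an ANOVA fit. Groups with
#' fewer than 2 observations are dropped with a flag.
#'
#' @param values Numeric vector of observations (e.g. per-image mean rates).
#' @param groups Factor or character vector of group membership, same
#'   length.
#' @return Object of class `tukey_kramer`: list with `p` (symmetric matrix,
#'   unit diagonal), `diff` (mean differences), `means`, `dropped` (names of
#'   degenerate groups).
#' @export
tukey_kramer <- function(values, groups) {
  groups <- factor(groups)
  sizes <- table(groups)
  dropped <- names(sizes)[sizes < 2]
  if (length(dropped)) {
    keep <- !(groups %in% dropped)
    values <- values[keep]
    groups <- droplevels(groups[keep])
  }
  g <- levels(groups)
  if (length(g) < 2) stop("need at least 2 groups with >= 2 observations",
                          call. = FALSE)
  p <- matrix(1, length(g), length(g), dimnames = list(g, g))
  dmat <- matrix(0, length(g), length(g), dimnames = list(g, g))
  means <- tapply(values, groups, mean)
  resid_sd <- sqrt(sum(tapply(values, groups, function(x) sum((x - mean(x))^2))) /
                     (length(values) - length(g)))
  if (resid_sd < 1e-12) {
    # degenerate: no within-group variation; equal means agree trivially
    for (i in seq_along(g)) for (j in seq_along(g)) {
      dmat[i, j] <- means[i] - means[j]
      p[i, j] <- if (abs(dmat[i, j]) < 1e-12) 1 else 0
    }
  } else {
    # safe level codes so group names containing '-' parse unambiguously
    gcode <- factor(paste0("g", as.integer(groups)),
                    levels = paste0("g", seq_along(g)))
    fit <- stats::aov(values ~ gcode, data = data.frame(values, gcode))
    th <- stats::TukeyHSD(fit)$gcode
    pair <- strsplit(rownames(th), "-", fixed = TRUE)
    for (k in seq_len(nrow(th))) {
      i <- as.integer(sub("^g", "", pair[[k]][1]))
      j <- as.integer(sub("^g", "", pair[[k]][2]))
      p[i, j] <- p[j, i] <- th[k, "p adj"]
      dmat[i, j] <- th[k, "diff"]
      dmat[j, i] <- -th[k, "diff"]
    }
  }
  structure(list(p = p, diff = dmat, means = means, dropped = dropped),
            class = "tukey_kramer")
}

#' Plot a rate heatmap or difference map
#' @param x A `rate_heatmap`.
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, `x`.
#' @export
plot.rate_heatmap <- function(x, ...) {
  v <- x$values
  sym <- inherits(x, "difference_map")
  zl <- if (sym) c(-1, 1) * max(abs(v), 1e-9) else c(0, 1)
  col <- if (sym) grDevices::hcl.colors(64, "Blue-Red") else
    grDevices::hcl.colors(64, "YlOrRd", rev = TRUE)
  graphics::image(seq_len(ncol(v)), seq_len(nrow(v)), t(v), zlim = zl,
                  col = col, xlab = "face (category-blocked)", ylab = "",
                  yaxt = "n", ...)
  graphics::axis(2, at = seq_len(7), labels = rownames(v), las = 2, cex.axis = 0.8)
  invisible(x)
}
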