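make_majority <- function(ids, labels, group = "g", condition = "non-masked") {
  out <- data.frame(face_id = ids, group = group, condition = condition,
                    label = labels, tie_flag = FALSE, stringsAsFactors = FALSE)
  class(out) <- c("majority_labeling", "data.frame")
  out
}

test_that("confusion matrix against itself is the identity in probability", {
  m <- make_majority(sprintf("f%d", 1:14), rep(emotion_levels(), 2))
  cm <- build_confusion(m, m)
  expect_equal(unname(cm$prob), diag(7))
  expect_equal(precision(cm), 1)
  expect_equal(kappa_multiclass(cm), 1)
})

test_that("individual votes distribute counts within the reference column", {
  # 2 anger-majority faces: 10x anger and 5 anger + 5 fear -> column (.75, 0, .25, ...)
  ref <- make_majority(c("a1", "a2"), c("anger", "anger"))
  v <- vote_table(c("a1", "a2"),
                  rbind(c(10, 0, 0, 0, 0, 0, 0), c(5, 0, 5, 0, 0, 0, 0)),
                  "g", "non-masked", 10)
  cm <- build_confusion(ref, v)
  expect_equal(unname(cm$prob[, "anger"]), c(0.75, 0, 0.25, 0, 0, 0, 0))
  expect_equal(precision(cm), 0.75)
  expect_equal(cm$n_total, 20L)
  # nonzero columns of any confusion matrix sum to 1
  expect_true(all(abs(colSums(cm$prob)[colSums(cm$raw) > 0] - 1) < 1e-9))
})

test_that("mismatched face sets raise an alignment error naming the faces", {
  ref <- make_majority(c("a1", "a2"), c("anger", "fear"))
  resp <- make_majority(c("a1", "a3"), c("anger", "fear"))
  expect_error(build_confusion(ref, resp), "a2")
  expect_error(build_confusion(ref, resp), "a3")
})

test_that("precision equals the diagonal count ratio on hand-built matrices", {
  uni <- confusion_from_counts(matrix(3L, 7, 7))
  expect_equal(precision(uni), 1 / 7)
  raw <- matrix(0L, 7, 7); diag(raw) <- c(5L, 3L, 2L, 8L, 1L, 4L, 7L)
  raw[2, 1] <- 10L
  expect_equal(precision(confusion_from_counts(raw)), 30 / 40)
})

test_that("closed-form binary kappa agrees with the po/pe oracle exhaustively", {
  # every 2x2 table with n_total <= 40
  grid <- expand.grid(tp = 0:40, fp = 0:40, fn = 0:40)
  keep <- grid$tp + grid$fp + grid$fn <= 40
  grid <- grid[keep, ]
  for (n in c(10L, 25L, 40L)) {
    g <- grid[grid$tp + grid$fp + grid$fn <= n, ]
    tn <- n - g$tp - g$fp - g$fn
    got <- kappa_eq2(g$tp, g$fp, g$fn, tn)
    want <- mapply(binary_kappa_oracle, g$tp, g$fp, g$fn, tn)
    expect_equal(got, unname(want), tolerance = 1e-12)
  }
  expect_equal(kappa_eq2(50, 0, 0, 50), 1)
  expect_equal(kappa_eq2(40, 10, 10, 40), binary_kappa_oracle(40, 10, 10, 40))
  expect_equal(kappa_eq2(20, 10, 10, 5), 2 * (20 * 5 - 100) / (30 * 15 + 30 * 15))
  # independence (tp*tn = fn*fp) gives zero; degenerate margins give NA
  expect_equal(kappa_eq2(6, 3, 4, 2), 0)
  expect_true(is.na(kappa_eq2(0, 0, 0, 0)))
})

test_that("multiclass kappa is near zero for independent random labels", {
  set.seed(42)
  n <- 10000
  a <- sample(emotion_levels(), n, TRUE)
  b <- sample(emotion_levels(), n, TRUE)
  raw <- unclass(table(factor(a, levels = emotion_levels()),
                       factor(b, levels = emotion_levels())))
  k <- kappa_multiclass(confusion_from_counts(raw))
  expect_lt(abs(k), 0.05)
})

test_that("one-vs-rest collapse links multiclass and binary kappa", {
  des <- stimulus_design(7)
  pan <- panel_spec("g", 11, list(nm = flat_kernel(0.65)))
  v <- generate_votes(des, pan, "nm", seed = 9)
  cm <- build_confusion(majority_encode(v), v)
  for (lab in c("anger", "fear", "neutral")) {
    cc <- one_vs_rest(cm, lab)
    expect_equal(sum(cc), cm$n_total)
    # collapsed 2x2 evaluated by both routes
    collapsed <- binary_kappa_oracle(cc["TP"], cc["FP"], cc["FN"], cc["TN"])
    expect_equal(unname(kappa_eq2(cc["TP"], cc["FP"], cc["FN"], cc["TN"])),
                 unname(collapsed))
  }
})

test_that("cell-wise Fisher tests rank a planted enrichment first", {
  raw <- matrix(2L, 7, 7)
  diag(raw) <- 30L
  raw[6, 3] <- 50L  # fear column responses concentrated in the surprise row
  res <- cell_fisher_tests(confusion_from_counts(raw))
  expect_equal(res$response[1], "surprise")
  expect_equal(res$reference[1], "fear")
  expect_true(res$significant[1])
  # BH-adjusted p is monotone in raw-p rank and bounded by [p, 1]
  ord <- order(res$p)
  expect_true(all(diff(res$p_adj[ord]) > -1e-12))
  expect_true(all(res$p_adj >= res$p - 1e-12 & res$p_adj <= 1))
  expect_equal(nrow(res), 42L)
})

test_that("identity confusion matrix has no significant off-diagonal cell", {
  raw <- matrix(0L, 7, 7); diag(raw) <- 20L
  res <- cell_fisher_tests(confusion_from_counts(raw))
  expect_false(any(res$significant))
})

test_that("mean pairwise kappa is 1 for copied groups and ~0 at random", {
  faces <- sprintf("f%02d", 1:21)
  consistent <- data.frame(
    face_id = rep(faces, times = 3),
    rater_id = rep(c("r1", "r2", "r3"), each = 21),
    label = rep(rep(emotion_levels(), each = 3), times = 3),
    stringsAsFactors = FALSE
  )
  pk <- mean_pairwise_kappa(consistent, transform(consistent,
                                                  rater_id = paste0("b_", rater_id)))
  expect_equal(pk$k_avg, 1)
  expect_equal(dim(pk$k_values), c(3L, 3L))

  # permutation within a group leaves the average unchanged
  shuf <- consistent[sample(nrow(consistent)), ]
  expect_equal(mean_pairwise_kappa(shuf, consistent)$k_avg, 1)

  # uniformly random labelers agree only at chance level
  set.seed(7)
  mean_k <- replicate(100, {
    rand_lab <- function(g) data.frame(
      face_id = rep(sprintf("f%02d", 1:98), times = 2),
      rater_id = rep(paste0(g, 1:2), each = 98),
      label = sample(emotion_levels(), 196, TRUE),
      stringsAsFactors = FALSE
    )
    mean_pairwise_kappa(rand_lab("a"), rand_lab("b"))$k_avg
  })
  expect_lt(abs(mean(mean_k)), 0.05)
})

test_that("raters with missing faces trigger an alignment error", {
  a <- data.frame(face_id = c("f1", "f2", "f1"), rater_id = c("r1", "r1", "r2"),
                  label = "anger", stringsAsFactors = FALSE)
  b <- data.frame(face_id = c("f1", "f2"), rater_id = "s1",
                  label = "fear", stringsAsFactors = FALSE)
  expect_error(mean_pairwise_kappa(a, b), "missing faces")
})
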