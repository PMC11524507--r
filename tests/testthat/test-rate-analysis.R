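fixture_rates <- function(seed, n_per_category = 14, diagonal = 0.75,
                          n_raters = 12) {
  des <- stimulus_design(n_per_category)
  pan <- panel_spec("g", n_raters, list(nm = flat_kernel(diagonal)))
  v <- generate_votes(des, pan, "nm", seed = seed)
  list(votes = v, rates = rate_encode(v), majority = majority_encode(v),
       design = des)
}

test_that("heatmap columns form contiguous category blocks in canonical order", {
  fx <- fixture_rates(1)
  h <- order_heatmap(fx$rates, fx$majority)
  expect_equal(dim(h$values), c(7L, 98L))
  expect_equal(h$reference, h$reference[order(match(h$reference, emotion_levels()))])
  expect_equal(h$face_id, h$face_id[order(match(h$reference, emotion_levels()),
                                          h$face_id)])
  # deterministic: rebuilding from shuffled rows gives the same ordering
  shuffled <- fx$rates[sample(nrow(fx$rates)), ]
  class(shuffled) <- class(fx$rates)
  h2 <- order_heatmap(shuffled, fx$majority)
  expect_identical(h$values, h2$values)
  # single face reduces to its own rate vector
  one <- fx$rates[1, ]; class(one) <- class(fx$rates)
  mone <- fx$majority[1, ]; class(mone) <- class(fx$majority)
  h1 <- order_heatmap(one, mone)
  expect_equal(unname(h1$values[, 1]), unname(rate_values(fx$rates)[1, ]))
})

test_that("difference maps are antisymmetric and vanish for identical groups", {
  fx <- fixture_rates(2)
  fy <- fixture_rates(3)
  hA <- order_heatmap(fx$rates, fx$majority)
  hB <- order_heatmap(fy$rates, fx$majority)
  expect_equal(difference_map(hA, hA)$values, hA$values * 0)
  d1 <- difference_map(hB, hA)
  d2 <- difference_map(hA, hB)
  expect_equal(d1$values, -d2$values)
  expect_true(all(d1$values >= -1 & d1$values <= 1))
})

test_that("shift map of the zero difference map is identically zero with no hits", {
  fx <- fixture_rates(4)
  h <- order_heatmap(fx$rates, fx$majority)
  sh <- category_shift_map(difference_map(h, h))
  expect_equal(unname(sh$mean), matrix(0, 7, 7))
  expect_false(any(sh$significant, na.rm = TRUE))
  expect_true(all(sh$untestable))  # zero variance everywhere
  expect_equal(unname(rowSums(sh$n_images)), rep(7 * 14, 7))
})

test_that("a planted rate shift is estimated within 3 SE and flagged significant", {
  kA <- flat_kernel(0.8)
  kB <- inject_shift(kA, "fear", "surprise", 0.3)
  des <- stimulus_design(14)
  pA <- panel_spec("A", 17, list(nm = kA))
  pB <- panel_spec("B", 17, list(nm = kB))
  n_rep <- 100
  means <- numeric(n_rep); sig <- logical(n_rep)
  for (s in seq_len(n_rep)) {
    vA <- generate_votes(des, pA, "nm", seed = 900 + 2 * s)
    vB <- generate_votes(des, pB, "nm", seed = 901 + 2 * s)
    mA <- majority_encode(vA)
    sh <- category_shift_map(difference_map(order_heatmap(rate_encode(vB), mA),
                                            order_heatmap(rate_encode(vA), mA)))
    means[s] <- sh$mean["fear", "surprise"]
    sig[s] <- isTRUE(sh$significant["fear", "surprise"])
  }
  # binomial SE of a rate difference at p ~ .47/.17, n = 17 raters x 14 faces
  se <- sqrt((0.47 * 0.53 + 0.17 * 0.83) / (17 * 14)) / sqrt(n_rep)
  expect_lt(abs(mean(means) - 0.3), 3 * se)
  expect_gte(mean(sig), 0.95)
})

test_that("per-emotion correlations behave like Pearson r", {
  fx <- fixture_rates(5)
  same <- per_emotion_correlation(fx$rates, fx$rates)
  expect_equal(same$r[same$defined], rep(1, sum(same$defined)))
  # permuting faces in one group destroys the correlation
  set.seed(8)
  perm <- fx$rates
  rv <- rate_values(perm)[sample(nrow(perm)), ]
  perm[, emotion_levels()] <- rv
  class(perm) <- class(fx$rates)
  rp <- per_emotion_correlation(fx$rates, perm)
  expect_lt(max(abs(rp$r), na.rm = TRUE), 0.35)
  # adding a constant to one label's rates leaves r unchanged
  shifted <- fx$rates
  shifted$fear <- shifted$fear + 0.05
  class(shifted) <- class(fx$rates)
  rs <- per_emotion_correlation(fx$rates, shifted)
  expect_equal(rs$r[rs$label == "fear"], 1)
  # zero-variance series is flagged undefined
  flat <- fx$rates
  flat$anger <- 0.2
  class(flat) <- class(fx$rates)
  rf <- per_emotion_correlation(fx$rates, flat)
  expect_false(rf$defined[rf$label == "anger"])
  expect_true(is.na(rf$r[rf$label == "anger"]))
})

test_that("r-to-z comparison matches the closed form and is antisymmetric", {
  expect_equal(compare_correlations(0.5, 50, 0.5, 50), list(z = 0, p = 1))
  z_hand <- (atanh(0.9) - atanh(0.3)) / sqrt(1 / 95 + 1 / 95)
  got <- compare_correlations(0.9, 98, 0.3, 98)
  expect_equal(got$z, z_hand)
  expect_equal(got$p, 2 * pnorm(-abs(z_hand)))
  expect_equal(compare_correlations(0.3, 98, 0.9, 98)$z, -z_hand)
  expect_error(compare_correlations(1, 98, 0.3, 98), "infinite")
  expect_error(compare_correlations(0.5, 3, 0.5, 98), "n >= 4")
})

test_that("Tukey-Kramer controls familywise error and detects separation", {
  set.seed(11)
  hits <- 0
  n_rep <- 1000
  g <- rep(emotion_levels(), times = c(10, 14, 14, 14, 14, 14, 18))  # unequal n
  for (i in seq_len(n_rep)) {
    x <- rnorm(length(g))
    tk <- tukey_kramer(x, g)
    if (min(tk$p[upper.tri(tk$p)]) < 0.05) hits <- hits + 1
  }
  expect_lte(hits / n_rep, 0.07)
  # two groups ten pooled SDs apart are detected decisively
  x <- c(rnorm(14, 0, 1), rnorm(14, 10, 1))
  gg <- rep(c("a", "b"), each = 14)
  expect_lt(tukey_kramer(x, gg)$p["a", "b"], 0.001)
  # p matrix is symmetric with unit diagonal
  tk <- tukey_kramer(rnorm(42), rep(c("a", "b", "c"), each = 14))
  expect_equal(tk$p, t(tk$p))
  expect_equal(unname(diag(tk$p)), rep(1, 3))
  expect_error(tukey_kramer(rnorm(3), c("a", "a", "b")), "at least 2 groups")
})

test_that("rate embedding is deterministic and keeps duplicates together", {
  fx <- fixture_rates(6)
  y1 <- embed_rates(fx$rates, perplexity = 30, seed = 4)
  y2 <- embed_rates(fx$rates, perplexity = 30, seed = 4)
  expect_identical(y1, y2)
  expect_equal(nrow(y1), 98L)
  expect_equal(ncol(y1), 2L)
  # duplicated input vectors land closer than the 5th percentile of distances
  rv <- rate_values(fx$rates)
  rv[2, ] <- rv[1, ]
  y <- embed_rates(rv, perplexity = 30, seed = 4)
  d_all <- as.matrix(dist(y))
  expect_lte(d_all[1, 2], quantile(d_all[upper.tri(d_all)], 0.05))
  expect_error(embed_rates(rv[1:20, ], perplexity = 30), "too few points")
})
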