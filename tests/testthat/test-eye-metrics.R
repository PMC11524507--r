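toy_eye <- function() {
  rbind(p0 = c(0, 0), p1 = c(1, 0.5), p2 = c(3, 0.5),
        p3 = c(4, 0), p4 = c(3, -0.5), p5 = c(1, -0.5))
}

test_that("raw eye opening matches hand computation and degenerates to zero", {
  expect_equal(eye_opening_raw(toy_eye()), (1 + 1) / (2 * 4))
  closed <- toy_eye()
  closed[c(2, 3), 2] <- 0; closed[c(5, 6), 2] <- 0
  expect_equal(eye_opening_raw(closed), 0)
  zero_width <- toy_eye(); zero_width[4, ] <- zero_width[1, ]
  expect_error(eye_opening_raw(zero_width), class = "fervote_undefined_metric")
})

test_that("raw eye opening is invariant to rigid motion and uniform scale", {
  e <- toy_eye()
  base <- eye_opening_raw(e)
  for (theta in c(0.3, 1.2, pi / 2)) {
    rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
    for (s in c(0.5, 1, 13)) {
      moved <- s * e %*% rot + rep(c(7, -3), each = 6)
      expect_equal(eye_opening_raw(moved), base, tolerance = 1e-12)
    }
  }
})

test_that("eye-opening rate applies the affine transform with clamping", {
  expect_equal(eye_opening_rate(0.25)$r_rate, 0.30)
  expect_equal(eye_opening_rate(0.15)$r_rate, 0)
  r <- eye_opening_rate(0.60)
  expect_equal(r$r_rate, 1)
  expect_true(r$clamped)
  expect_equal(r$r_unclamped, 1.35)
  expect_equal(eye_opening_rate(0)$r_rate, 0)
  # monotone nondecreasing in the raw value
  grid <- eye_opening_rate(seq(0, 0.6, by = 0.01))
  expect_true(all(diff(grid$r_rate) >= 0))
})

test_that("per-face rate averages the two eyes and survives mirroring", {
  lm <- landmarks68("s", landmark_template(0.3))
  r <- face_eye_rate(lm)
  expect_equal(r$r_rate, eye_opening_rate(0.3)$r_rate)
  expect_equal(face_eye_rate(lm, "left")$r_rate, face_eye_rate(lm, "right")$r_rate)
  # asymmetric eyes: rate is the mean of the two per-eye rates
  p <- landmark_template(0.25)
  d4 <- 0.4 * 9  # widen only the left eye to raw 0.4
  p[44:45, 2] <- 20 - d4 / 2  # p1, p2 upper lid
  p[47:48, 2] <- 20 + d4 / 2  # p4, p5 lower lid
  asym <- landmarks68("a", p)
  expect_equal(face_eye_rate(asym)$r_rate,
               mean(c(eye_opening_rate(0.25)$r_rate, eye_opening_rate(0.4)$r_rate)))
  # horizontal mirroring leaves the value unchanged
  q <- landmark_template(0.3)
  q[, 1] <- 48 - q[, 1]
  expect_equal(face_eye_rate(landmarks68("m", q))$r_rate, r$r_rate)
})

test_that("degenerate eyes fall back or signal an undefined metric", {
  p <- landmark_template(0.3)
  p[40, ] <- p[37, ]  # right eye width collapses
  expect_warning(r <- face_eye_rate(landmarks68("d", p)), "degenerate")
  expect_equal(r$r_rate, eye_opening_rate(0.3)$r_rate)
  p[46, ] <- p[43, ]  # left eye too
  expect_error(suppressWarnings(face_eye_rate(landmarks68("d2", p))),
               class = "fervote_undefined_metric")
})

test_that("label-level eye statistics separate wide-eyed categories", {
  des <- stimulus_design(14)
  lms <- generate_study_landmarks(des, seed = 31)
  er <- eye_rates(lms)
  lab <- data.frame(face_id = des$face_id, group = "g", condition = "nm",
                    label = des$category, tie_flag = FALSE,
                    stringsAsFactors = FALSE)
  class(lab) <- c("majority_labeling", "data.frame")
  st <- label_eye_stats(er, lab)
  expect_equal(st$stats$n, rep(14L, 7))
  expect_true(all(st$stats$mean >= 0 & st$stats$mean <= 1))
  wide <- c("fear", "surprise")
  for (w in wide) {
    for (o in setdiff(emotion_levels(), wide)) {
      expect_lt(st$p_map[w, o], 0.01)
    }
  }
  expect_equal(unname(diag(st$p_map)), rep(1, 7))
})

test_that("identical eye rates give flat statistics with unit p-values", {
  er <- data.frame(face_id = sprintf("f%d", 1:28),
                   r_rate = 0.4, stringsAsFactors = FALSE)
  lab <- data.frame(face_id = er$face_id, group = "g", condition = "nm",
                    label = rep(emotion_levels()[1:4], each = 7),
                    tie_flag = FALSE, stringsAsFactors = FALSE)
  class(lab) <- c("majority_labeling", "data.frame")
  st <- label_eye_stats(er, lab)
  used <- emotion_levels()[1:4]
  expect_true(all(st$p_map[used, used] == 1))
  expect_setequal(st$excluded, emotion_levels()[5:7])
})

test_that("wide-vs-narrow eye separation is detected consistently across seeds", {
  des <- stimulus_design(14)
  hits <- 0
  n_rep <- 100
  for (s in seq_len(n_rep)) {
    lms <- generate_study_landmarks(des, range_wide = c(0.30, 0.40),
                                    range_narrow = c(0.15, 0.25),
                                    jitter_sd = 0.25, seed = 4000 + s)
    er <- eye_rates(lms)
    lab <- data.frame(face_id = des$face_id, group = "g", condition = "nm",
                      label = des$category, tie_flag = FALSE,
                      stringsAsFactors = FALSE)
    class(lab) <- c("majority_labeling", "data.frame")
    st <- label_eye_stats(er, lab)
    others <- setdiff(emotion_levels(), c("fear", "surprise"))
    ok <- all(st$p_map[c("fear", "surprise"), others] < 0.01) &&
      all(st$stats$mean[st$stats$label %in% c("fear", "surprise")] >
            max(st$stats$mean[st$stats$label %in% others]))
    if (ok) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.95)
})
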