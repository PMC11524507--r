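# shared fixtures built in code

lv <- emotion_levels()

# uniform-confusion kernel with a given diagonal
flat_kernel <- function(diagonal = 0.8) {
  off <- (1 - diagonal) / 6
  confusion_kernel(matrix(off, 7, 7) + diag(7) * (diagonal - off))
}

# the two printed worked-example faces: counts in canonical order
table2_votes <- function() {
  vote_table(
    face_id = c("35320", "34791"),
    counts = rbind(c(5, 1, 0, 2, 1, 1, 0),
                   c(0, 0, 5, 1, 0, 4, 0)),
    group = "western", condition = "non-masked", n_raters = 10
  )
}

# independent po/pe oracle for binary kappa on a 2x2 table
binary_kappa_oracle <- function(tp, fp, fn, tn) {
  n <- tp + fp + fn + tn
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  if (abs(1 - pe) < 1e-12) return(NA_real_)
  (po - pe) / (1 - pe)
}

study_fixture_panels <- function(kernels = study_kernels()) {
  list(
    west = panel_spec("western", 10,
                      list("non-masked" = kernels$western_nonmasked)),
    east = panel_spec("east_asian", 17,
                      list("non-masked" = kernels$east_nonmasked,
                           "masked" = kernels$east_masked))
  )
}
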