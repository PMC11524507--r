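#' Configuration for a full study-shaped run
#'
#' Bundles every tunable of the end-to-end pipeline. The defaults reproduce
#' the study design the synthetic generator emulates: 98 faces (14 per
#' category), a 17-rater panel rating both masked and non-masked
#' conditions, a 10-rater reference panel rating non-masked faces only, the
#' study-shaped kernels of [study_kernels()], panel-size rate denominators,
#' and an FDR threshold of 0.05. One global seed fans out to per-stage
#' seeds by fixed offsets.
#'
#' @param seed Global integer seed.
#' @param n_per_category Faces per emotion category.
#' @param n_east,n_west Panel sizes of the experimental (two-condition) and
#'   reference (non-masked only) groups.
#' @param kernels Named list as returned by [study_kernels()].
#' @param denominator Rate denominator rule, see [rate_encode()].
#' @param q FDR threshold for shift-map and cell tests.
#' @param mask_color Mask fill policy: `"random"`, `"white"` or `"black"`.
#' @param embed Also compute the 2-D embedding stage (slowest stage).
#' @param out_dir Optional directory; when given, all artifacts (CSV, JSON,
#'   masked PNGs) are written under it.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1, n_per_category = 14, n_east = 17, n_west = 10,
                       kernels = study_kernels(),
                       denominator = "panel_size", q = 0.05,
                       mask_color = "random", embed = FALSE, out_dir = NULL) {
  if (length(seed) != 1 || seed != round(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  needed <- c("western_nonmasked", "east_nonmasked", "east_masked")
  if (!all(needed %in% names(kernels))) {
    stop("kernels must contain: ", paste(needed, collapse = ", "), call. = FALSE)
  }
  for (k in kernels[needed]) validate_kernel(k)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  structure(list(seed = as.integer(seed), n_per_category = n_per_category,
                 n_east = n_east, n_west = n_west, kernels = kernels,
                 denominator = denominator, q = q, mask_color = mask_color,
                 embed = embed, out_dir = out_dir),
            class = "run_config")
}

stage_seed <- function(config, offset) config$seed * 1000L + offset

#' Run the full analysis pipeline on synthetic study data
#'
#' Executes every stage in dependency order: synthesise rater votes for the
#' two panels (the experimental panel rates the masked condition first,
#' then non-masked, mirroring the questionnaire order; the reference panel
#' rates non-masked only); encode majorities and vote rates; build the four
#' confusion-matrix comparisons (reference majority vs individual,
#' experimental majority vs individual, group vs group majority, masked vs
#' non-masked majority) with precision, kappa and cell-wise Fisher tests;
#' compute the cross-group difference heatmap, category shift map,
#' per-emotion correlations with r-to-z comparisons, and mean pairwise
#' kappa; synthesise landmarks, eye-opening statistics and masked stimuli;
#' optionally embed the rate vectors in 2-D.
#'
#' @param config A [run_config()].
#' @return A list of class `run_report` with one element per stage plus a
#'   config echo and the seed fan-out; written as `report.json` under
#'   `config$out_dir` when set.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  lv <- emotion_levels()
  design <- stimulus_design(config$n_per_category)

  west <- panel_spec("western", config$n_west,
                     list("non-masked" = config$kernels$western_nonmasked))
  east <- panel_spec("east_asian", config$n_east,
                     list("non-masked" = config$kernels$east_nonmasked,
                          "masked" = config$kernels$east_masked))

  seeds <- c(east_masked = stage_seed(config, 1L),
             east_nonmasked = stage_seed(config, 2L),
             west_nonmasked = stage_seed(config, 3L),
             landmarks = stage_seed(config, 4L),
             mask = stage_seed(config, 5L),
             embed = stage_seed(config, 6L))

  # --- vote synthesis (masked condition first, as in the questionnaire)
  lab_em <- simulate_rater_labels(design, east, "masked", seeds["east_masked"])
  lab_en <- simulate_rater_labels(design, east, "non-masked", seeds["east_nonmasked"])
  lab_wn <- simulate_rater_labels(design, west, "non-masked", seeds["west_nonmasked"])
  v_em <- generate_votes(design, east, "masked", labels = lab_em)
  v_en <- generate_votes(design, east, "non-masked", labels = lab_en)
  v_wn <- generate_votes(design, west, "non-masked", labels = lab_wn)

  # --- encodings
  m_em <- majority_encode(v_em)
  m_en <- majority_encode(v_en)
  m_wn <- majority_encode(v_wn)
  r_en <- rate_encode(v_en, config$denominator)
  r_wn <- rate_encode(v_wn, config$denominator)
  r_em <- rate_encode(v_em, config$denominator)

  summarise_cm <- function(cm) {
    tests <- cell_fisher_tests(cm, q = config$q)
    list(P = precision(cm), K = kappa_multiclass(cm),
         n_total = cm$n_total, raw = cm$raw,
         top_cells = utils::head(tests, 3))
  }
  agreement <- list(
    west_majority_vs_individual = summarise_cm(build_confusion(m_wn, v_wn)),
    east_majority_vs_individual = summarise_cm(build_confusion(m_en, v_en)),
    west_vs_east_majority = summarise_cm(build_confusion(m_wn, m_en)),
    nonmasked_vs_masked_majority = summarise_cm(build_confusion(m_en, m_em)),
    masked_individual = summarise_cm(build_confusion(m_en, v_em))
  )

  # --- rate analysis: cross-group shift, ordered by the reference majority
  h_wn <- order_heatmap(r_wn, m_wn)
  h_en <- order_heatmap(r_en, m_wn)
  dmap <- difference_map(h_en, h_wn)
  shift <- category_shift_map(dmap, q = config$q)
  corr_nm <- per_emotion_correlation(r_wn, r_en)
  corr_mk <- per_emotion_correlation(r_wn, r_em)
  fear_vs_happy <- compare_correlations(
    corr_nm$r[corr_nm$label == "fear"], corr_nm$n[corr_nm$label == "fear"],
    corr_nm$r[corr_nm$label == "happiness"], corr_nm$n[corr_nm$label == "happiness"]
  )
  kappa_nm <- mean_pairwise_kappa(lab_wn, lab_en)
  kappa_mk <- mean_pairwise_kappa(lab_wn, lab_em)

  # --- eye metrics on study-shaped landmarks
  lms <- generate_study_landmarks(design, seed = seeds["landmarks"])
  eyes <- eye_rates(lms)
  eye_stats <- label_eye_stats(eyes, m_wn)

  # --- mask synthesis on a neutral gray frame per face (first 5 faces)
  mask_ids <- design$face_id[seq_len(min(5, nrow(design)))]
  fills <- character(0)
  for (i in seq_along(mask_ids)) {
    lm <- lms[[mask_ids[i]]]
    img <- matrix(0.5, lm$height, lm$width)
    masked <- apply_mask(img, mask_polygon(lm), color = config$mask_color,
                         seed = seeds["mask"] + i)
    fills[i] <- attr(masked, "fill")
    if (!is.null(config$out_dir)) {
      write_face_png(masked, file.path(config$out_dir,
                                       paste0(mask_ids[i], "_masked.png")))
    }
  }

  embedding <- NULL
  if (isTRUE(config$embed)) {
    embedding <- embed_rates(r_en, perplexity = 30, seed = seeds["embed"])
  }

  report <- structure(list(
    version = as.character(utils::packageVersion("fervote")),
    config = config[setdiff(names(config), "kernels")],
    seeds = as.list(seeds),
    design = list(n_faces = nrow(design),
                  n_votes_east = sum(vote_counts(v_en)),
                  n_votes_west = sum(vote_counts(v_wn))),
    agreement = agreement,
    shift_map = list(mean = shift$mean, p_adj = shift$p_adj,
                     significant = shift$significant,
                     top_cell = top_shift_cell(shift)),
    correlations = list(nonmasked = corr_nm, masked = corr_mk,
                        fear_vs_happiness_z = fear_vs_happy),
    mean_pairwise_kappa = list(nonmasked = kappa_nm$k_avg,
                               masked = kappa_mk$k_avg),
    eye = list(stats = eye_stats$stats, p_map = eye_stats$p_map),
    mask_fills = fills,
    embedding = if (!is.null(embedding)) list(n = nrow(embedding),
                                              method = attr(embedding, "method"))
  ), class = "run_report")

  if (!is.null(config$out_dir)) {
    write_ferplus_votes(v_wn, file.path(config$out_dir, "votes_western.csv"))
    write_votes_long(rbind(lab_em, lab_en, lab_wn),
                     file.path(config$out_dir, "labels_long.csv"))
    write_rates_csv(r_en, file.path(config$out_dir, "rates_east_nonmasked.csv"))
    write_landmarks_json(lms, file.path(config$out_dir, "landmarks.json"))
    jsonlite::write_json(report_to_json(report),
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

# flatten matrices so the report serialises cleanly
report_to_json <- function(report) {
  flatten <- function(x) {
    if (is.matrix(x)) {
      return(list(dimnames = dimnames(x), values = unname(as.data.frame(x))))
    }
    if (inherits(x, "run_config")) x <- unclass(x)
    if (is.list(x)) return(lapply(x, flatten))
    x
  }
  flatten(unclass(report))
}

#' @export
print.run_report <- function(x, ...) {
  cat("fervote run report (version ", x$version, ")\n", sep = "")
  cat(sprintf("  faces: %d, votes: %d east / %d west per condition\n",
              x$design$n_faces, x$design$n_votes_east, x$design$n_votes_west))
  for (nm in names(x$agreement)) {
    a <- x$agreement[[nm]]
    cat(sprintf("  %-32s P = %.3f  K = %.3f\n", nm, a$P, a$K))
  }
  tc <- x$shift_map$top_cell
  if (!is.null(tc)) {
    cat(sprintf("  top shift cell: %s -> %s (mean %+.3f, adj p %.2g)\n",
                tc$reference, tc$perceived, tc$mean, tc$p_adj))
  }
  cat(sprintf("  mean pairwise kappa: %.3f (non-masked), %.3f (masked)\n",
              x$mean_pairwise_kappa$nonmasked, x$mean_pairwise_kappa$masked))
  invisible(x)
}
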