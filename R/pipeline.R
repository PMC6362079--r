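#' Run configuration for the full simulated study
#'
#' Bundles everything one study run needs: the factorial design, camera and
#' grader profiles, the reference chart, metric and statistics options, and
#' the master seed from which all per-stage and per-record seeds are derived.
#' A serialized copy is written into the output directory by [run_study()].
#'
#' @param design a [study_design()].
#' @param profiles named list of [camera_profile()]s keyed
#'   `"<camera>.<lighting>"`.
#' @param graders list of [grader_profile()]s.
#' @param chart a [chart_definition()].
#' @param chart_patch_px patch size used when photographing the chart.
#' @param red_band,chroma_floor,saturation_threshold metric options (see
#'   [score_redness()] and [build_roi()]).
#' @param affine_ccm fit a 3 x 4 affine color transform instead of 3 x 3.
#' @param master_seed integer; overrides the design's seed when given.
#' @return an object of class `run_config`.
#' @export
run_config <- function(design = study_design(),
                       profiles = default_camera_profiles(
                         design$cameras, design$lighting_levels),
                       graders = default_grader_profiles(),
                       chart = default_chart(),
                       chart_patch_px = 16L,
                       red_band = c(330, 30),
                       chroma_floor = 0.01,
                       saturation_threshold = 0.99,
                       affine_ccm = FALSE,
                       master_seed = NULL) {
  if (!is.null(master_seed)) design$seed <- as.integer(master_seed)
  structure(
    list(design = design, profiles = profiles, graders = graders,
         chart = chart, chart_patch_px = as.integer(chart_patch_px),
         red_band = red_band, chroma_floor = chroma_floor,
         saturation_threshold = saturation_threshold,
         affine_ccm = affine_ccm),
    class = "run_config"
  )
}

config_as_list <- function(config) {
  d <- config$design
  list(
    design = list(subjects = d$subjects, cameras = d$cameras,
                  lighting_levels = d$lighting_levels,
                  magnifications = d$magnifications,
                  replicates = d$replicates,
                  redness_range = d$redness_range,
                  image_size = d$image_size, seed = d$seed),
    profiles = lapply(config$profiles, function(p) {
      list(camera_id = p$camera_id, lighting_id = p$lighting_id,
           mixing_matrix = apply(p$mixing_matrix, 1L, c, simplify = FALSE),
           illuminant_gains = p$illuminant_gains,
           lighting_scale = p$lighting_scale,
           vignette_strength = p$vignette_strength,
           peripheral_hue_shift = p$peripheral_hue_shift,
           gamma = p$gamma, noise_sd = p$noise_sd,
           clip_level = p$clip_level)
    }),
    graders = lapply(config$graders, function(g) {
      list(grader_id = g$grader_id, bias = g$bias, noise_sd = g$noise_sd)
    }),
    chart = list(patch_colors = apply(config$chart$patch_colors, 1L, c,
                                      simplify = FALSE),
                 neutral_patch_index = config$chart$neutral_patch_index),
    options = list(chart_patch_px = config$chart_patch_px,
                   red_band = config$red_band,
                   chroma_floor = config$chroma_floor,
                   saturation_threshold = config$saturation_threshold,
                   affine_ccm = config$affine_ccm)
  )
}

#' Read a run configuration from YAML
#'
#' @param path YAML file as written by [run_study()] (`config.yaml`), or
#'   hand-authored with the same structure; absent sections fall back to the
#'   package defaults.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  d <- y$design %||% list()
  design <- study_design(
    subjects = d$subjects %||% sprintf("S%d", 1:4),
    cameras = d$cameras %||% c("camA", "camB", "camC"),
    lighting_levels = d$lighting_levels %||% c("high", "low"),
    magnifications = d$magnifications %||% c(6, 10),
    replicates = d$replicates %||% 2L,
    redness_range = unlist(d$redness_range %||% c(0.05, 0.6)),
    image_size = d$image_size %||% 128L,
    seed = d$seed %||% 1L)
  profiles <- if (is.null(y$profiles)) {
    default_camera_profiles(design$cameras, design$lighting_levels)
  } else {
    lapply(y$profiles, function(p) {
      camera_profile(camera_id = p$camera_id, lighting_id = p$lighting_id,
                     mixing_matrix = do.call(rbind, p$mixing_matrix),
                     illuminant_gains = unlist(p$illuminant_gains),
                     lighting_scale = p$lighting_scale,
                     vignette_strength = p$vignette_strength %||% 0,
                     peripheral_hue_shift = p$peripheral_hue_shift %||% 0,
                     gamma = p$gamma %||% 1, noise_sd = p$noise_sd %||% 0,
                     clip_level = p$clip_level %||% 1)
    })
  }
  graders <- if (is.null(y$graders)) default_grader_profiles() else {
    lapply(y$graders, function(g) {
      grader_profile(bias = g$bias %||% 0, noise_sd = g$noise_sd %||% 0,
                     grader_id = g$grader_id %||% "rater")
    })
  }
  chart <- if (is.null(y$chart)) default_chart() else {
    chart_definition(do.call(rbind, y$chart$patch_colors),
                     y$chart$neutral_patch_index)
  }
  o <- y$options %||% list()
  run_config(design = design, profiles = profiles, graders = graders,
             chart = chart,
             chart_patch_px = o$chart_patch_px %||% 16L,
             red_band = unlist(o$red_band %||% c(330, 30)),
             chroma_floor = o$chroma_floor %||% 0.01,
             saturation_threshold = o$saturation_threshold %||% 0.99,
             affine_ccm = isTRUE(o$affine_ccm))
}

star <- function(p) ifelse(is.finite(p) & p < 0.05, "*", "")

# correlation of each metric against a grade column, overall and grouped by
# processing arm x camera (the study's Table-2-style surface)
correlation_table <- function(scores, grade_col) {
  metrics <- c("relative_redness", "rg_diff", "rb_diff", "red_hue")
  one <- function(sub, group) {
    do.call(rbind, lapply(metrics, function(m) {
      pc <- tryCatch(pearson_cor(sub[[m]], sub[[grade_col]]),
                     error = function(e) list(r = NA_real_, p = NA_real_,
                                              n = nrow(sub)))
      data.frame(group = group, metric = m, r = pc$r, p = pc$p, n = pc$n)
    }))
  }
  out <- one(scores, "all")
  for (arm in unique(scores$processing_arm)) {
    for (cam in unique(scores$camera)) {
      sub <- scores[scores$processing_arm == arm & scores$camera == cam, ]
      out <- rbind(out, one(sub, paste(arm, cam, sep = ".")))
    }
  }
  out$significant <- star(out$p)
  rownames(out) <- NULL
  out
}

#' Run the full simulated study
#'
#' Executes the whole pipeline from one configuration: generate the synthetic
#' dataset (scenes, camera observations, grades), calibrate every
#' camera/lighting condition from its photographed chart, produce the
#' post-calibration arm, write and score all image records, and run the
#' statistics (per-metric and subjective 4-way repeated-measures ANOVA,
#' objective-subjective correlations, clinician repeatability, Bland-Altman
#' agreement, clinician ANOVA, and between-camera spread by arm). All outputs
#' are written under `out_dir`; the run is deterministic given the design's
#' master seed.
#'
#' @param config a [run_config()] (or a path to a YAML config).
#' @param out_dir output directory (created if absent).
#' @return invisibly, the report bundle: a list with the metadata, scores,
#'   calibration models, statistics tables and output paths.
#' @export
run_study <- function(config = run_config(), out_dir = tempfile("redcam_")) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (sub in c("images", "masks", "calibration", "stats")) {
    dir.create(file.path(out_dir, sub), showWarnings = FALSE)
  }
  manifest <- list(package_version = as.character(utils::packageVersion("redcam")),
                   r_version = as.character(getRversion()),
                   master_seed = config$design$seed,
                   stages = list())
  note <- function(stage, status) {
    manifest$stages[[stage]] <<- status
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  fail <- function(stage, e) {
    note(stage, paste("failed:", conditionMessage(e)))
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  }

  yaml::write_yaml(config_as_list(config), file.path(out_dir, "config.yaml"))

  # ---- generate --------------------------------------------------------
  study <- tryCatch(
    generate_study(config$design, config$profiles, config$graders),
    error = function(e) fail("generate", e))
  note("generate", "ok")

  # ---- calibrate per (camera, lighting) --------------------------------
  models <- tryCatch({
    chart_scene <- render_chart(config$chart, config$chart_patch_px)
    ms <- list()
    for (key in names(config$profiles)) {
      prof <- config$profiles[[key]]
      chart_img <- apply_camera(chart_scene, prof, magnification = 1,
                                seed = seed_child(config$design$seed,
                                                  "chart", key))
      ms[[key]] <- calibrate_condition(
        chart_img, config$chart, affine = config$affine_ccm,
        saturation_threshold = config$saturation_threshold)
      write_calibration(ms[[key]], file.path(out_dir, "calibration",
                                             paste0(key, ".json")))
    }
    ms
  }, error = function(e) fail("calibrate", e))
  note("calibrate", "ok")

  # ---- write both processing arms and the metadata ---------------------
  records <- tryCatch({
    rec <- study$records
    rec$image_path <- file.path(out_dir, "images",
                                paste0(rec$record_id, ".tif"))
    rec$mask_path <- file.path(out_dir, "masks",
                               paste0(rec$acquisition_id, ".png"))
    for (i in seq_len(nrow(study$acquisitions))) {
      aid <- study$acquisitions$acquisition_id[i]
      obs <- study$images[[aid]]
      key <- paste(study$acquisitions$camera[i],
                   study$acquisitions$lighting[i], sep = ".")
      cal <- apply_calibration(obs, models[[key]])
      write_linear_image(obs, file.path(out_dir, "images",
                                        paste0(aid, "_pre.tif")))
      write_linear_image(cal, file.path(out_dir, "images",
                                        paste0(aid, "_post.tif")))
      write_mask(obs$roi_mask, file.path(out_dir, "masks",
                                         paste0(aid, ".png")))
    }
    utils::write.csv(rec, file.path(out_dir, "metadata.csv"),
                     row.names = FALSE)
    rec
  }, error = function(e) fail("write_images", e))
  note("write_images", "ok")

  # ---- score -----------------------------------------------------------
  scored <- tryCatch({
    sb <- score_batch(records,
                      saturation_threshold = config$saturation_threshold,
                      red_band = config$red_band,
                      chroma_floor = config$chroma_floor)
    if (nrow(sb$failures) > 0L) {
      utils::write.csv(sb$failures, file.path(out_dir, "score_failures.csv"),
                       row.names = FALSE)
    }
    utils::write.csv(sb$scores, file.path(out_dir, "scores.csv"),
                     row.names = FALSE)
    sb$scores
  }, error = function(e) fail("score", e))
  note("score", "ok")

  # ---- statistics ------------------------------------------------------
  stats_out <- tryCatch({
    metrics <- c("relative_redness", "rg_diff", "rb_diff", "red_hue")
    factors <- c("calibration", "camera", "lighting", "magnification")
    long <- scored
    long$calibration <- long$processing_arm
    anovas <- list()
    for (m in metrics) {
      anovas[[m]] <- rm_anova(long, response = m, factors = factors,
                              subject = "subject")
      utils::write.csv(anovas[[m]],
                       file.path(out_dir, "stats",
                                 paste0("anova_", m, ".csv")),
                       row.names = FALSE)
    }
    grade_cols <- grep("^grade_", names(long), value = TRUE)
    anovas[["subjective"]] <- rm_anova(long, response = grade_cols[1],
                                       factors = factors,
                                       subject = "subject")
    utils::write.csv(anovas[["subjective"]],
                     file.path(out_dir, "stats", "anova_subjective.csv"),
                     row.names = FALSE)

    # clinician repeatability over duplicate photographs, per rater
    # (undefined when the design takes a single photograph per condition)
    cell <- interaction(long$subject, long$camera, long$lighting,
                        long$magnification, long$processing_arm)
    repeatability <- data.frame(
      rater = sub("^grade_", "", grade_cols),
      sw = if (config$design$replicates >= 2L) {
        vapply(grade_cols, function(g) within_subject_sd(long[[g]], cell),
               numeric(1))
      } else NA_real_)
    utils::write.csv(repeatability,
                     file.path(out_dir, "stats", "repeatability.csv"),
                     row.names = FALSE)

    # agreement between clinicians (Bland-Altman per rater pair)
    ba <- list()
    if (length(grade_cols) >= 2L) {
      for (pr in utils::combn(grade_cols, 2L, simplify = FALSE)) {
        nm <- paste(sub("^grade_", "", pr), collapse = "_vs_")
        b <- bland_altman(long[[pr[1]]], long[[pr[2]]])
        ba[[nm]] <- b[c("mean_diff", "sd_diff", "loa_low", "loa_high",
                        "ci_low_pair", "ci_high_pair", "n")]
      }
      jsonlite::write_json(ba, file.path(out_dir, "stats",
                                         "bland_altman.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }

    cl_long <- do.call(rbind, lapply(grade_cols, function(g) {
      data.frame(image = long$record_id, rater = sub("^grade_", "", g),
                 grade = long[[g]])
    }))
    clin <- clinician_anova(cl_long)
    utils::write.csv(clin, file.path(out_dir, "stats",
                                     "anova_clinicians.csv"),
                     row.names = FALSE)

    correlations <- correlation_table(long, grade_cols[1])
    utils::write.csv(correlations,
                     file.path(out_dir, "stats", "correlations.csv"),
                     row.names = FALSE)

    # between-camera spread of each metric, per arm: sd over cameras within
    # each subject x lighting x magnification x replicate cell, averaged
    spread <- do.call(rbind, lapply(metrics, function(m) {
      agg <- stats::aggregate(
        long[[m]],
        by = list(arm = long$processing_arm, subject = long$subject,
                  lighting = long$lighting,
                  magnification = long$magnification,
                  replicate = long$replicate),
        FUN = stats::sd)
      res <- stats::aggregate(agg$x, by = list(arm = agg$arm), FUN = mean)
      data.frame(metric = m, arm = res$arm, between_camera_sd = res$x)
    }))
    utils::write.csv(spread, file.path(out_dir, "stats",
                                       "between_camera_spread.csv"),
                     row.names = FALSE)

    list(anovas = anovas, repeatability = repeatability,
         bland_altman = ba, clinician_anova = clin,
         correlations = correlations, between_camera_spread = spread)
  }, error = function(e) fail("stats", e))
  note("stats", "ok")

  bundle <- structure(
    list(out_dir = out_dir, config = config, records = records,
         scores = scored, models = models,
         anovas = stats_out$anovas,
         repeatability = stats_out$repeatability,
         bland_altman = stats_out$bland_altman,
         clinician_anova = stats_out$clinician_anova,
         correlations = stats_out$correlations,
         between_camera_spread = stats_out$between_camera_spread),
    class = "study_bundle")

  report <- tryCatch(render_report(bundle), error = function(e)
    fail("report", e))
  writeLines(report, file.path(out_dir, "report.txt"))
  note("report", "ok")

  invisible(bundle)
}

#' Render a study bundle as a text report
#'
#' A human-readable summary of one simulated run: the design, clinician
#' repeatability and agreement, objective-subjective correlations, the five
#' repeated-measures ANOVA tables (four objective metrics plus the
#' subjective grades; 15 effect rows each for the 4-factor design) with
#' significance stars at 0.05, and the between-camera spread by processing
#' arm. The header states that all numbers come from synthetic data.
#'
#' @param bundle the list returned by [run_study()].
#' @return character vector of report lines.
#' @export
render_report <- function(bundle) {
  need <- c("anovas", "correlations", "repeatability",
            "between_camera_spread", "scores")
  absent <- need[vapply(need, function(f)
    is.null(bundle[[f]]) ||
      (is.data.frame(bundle[[f]]) && nrow(bundle[[f]]) == 0L) ||
      (is.list(bundle[[f]]) && length(bundle[[f]]) == 0L), logical(1))]
  if (length(absent)) {
    stop("cannot render report; missing: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  d <- bundle$config$design
  out <- c(
    "Simulated conjunctival-redness camera study - SYNTHETIC DATA",
    strrep("=", 62),
    sprintf("Design: %d subjects x %d cameras x %d lighting x %d magnifications x %d replicates",
            length(d$subjects), length(d$cameras), length(d$lighting_levels),
            length(d$magnifications), d$replicates),
    sprintf("Records scored: %d (2 processing arms)", nrow(bundle$scores)),
    sprintf("Master seed: %d", d$seed),
    ""
  )
  out <- c(out, "Clinician repeatability (within-subject sd of duplicate grades):",
           sprintf("  %-8s Sw = %.3f", bundle$repeatability$rater,
                   bundle$repeatability$sw), "")
  if (length(bundle$bland_altman)) {
    out <- c(out, "Clinician agreement (Bland-Altman 95% limits):")
    for (nm in names(bundle$bland_altman)) {
      b <- bundle$bland_altman[[nm]]
      out <- c(out, sprintf("  %-20s mean diff %+.3f, LoA [%+.3f, %+.3f]",
                            nm, b$mean_diff, b$loa_low, b$loa_high))
    }
    ca <- bundle$clinician_anova
    out <- c(out, sprintf("  Clinician RM-ANOVA: F = %.2f, p = %.3g%s",
                          ca$F[1], ca$p[1], star(ca$p[1])), "")
  }
  out <- c(out, "Objective vs subjective Pearson correlations:",
           sprintf("  %-14s %-18s r = %+.3f%s (n = %d)",
                   bundle$correlations$group, bundle$correlations$metric,
                   bundle$correlations$r, bundle$correlations$significant,
                   bundle$correlations$n), "")
  for (nm in names(bundle$anovas)) {
    a <- bundle$anovas[[nm]]
    out <- c(out, sprintf("Repeated-measures ANOVA - %s:", nm),
             sprintf("  %-48s F(%d, %d) = %10.3f  p = %.4g%s",
                     a$effect, a$df, a$error_df, a$F, a$p, star(a$p)),
             "")
  }
  out <- c(out, "Between-camera spread of each metric (mean within-cell sd):")
  sp <- bundle$between_camera_spread
  for (m in unique(sp$metric)) {
    pre <- sp$between_camera_sd[sp$metric == m & sp$arm == "pre"]
    post <- sp$between_camera_sd[sp$metric == m & sp$arm == "post"]
    out <- c(out, sprintf("  %-18s pre = %.5g, post = %.5g (%s)",
                          m, pre, post,
                          if (post < pre) "reduced by calibration"
                          else "not reduced"))
  }
  out
}
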