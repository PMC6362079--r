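#' Factorial study design
#'
#' The within-subjects factorial design of the simulated study: every subject
#' is imaged under every combination of camera, lighting level and
#' magnification, twice (duplicate photographs), and every captured image is
#' processed both uncalibrated and calibrated. The default design — 3 cameras
#' x 2 lighting levels x 2 magnifications x 2 replicates — enumerates 24
#' acquisition cells per subject and, after the two processing arms, 192
#' image records over 4 subjects.
#'
#' @param subjects subject identifiers (default 4 subjects).
#' @param cameras camera identifiers (default 3).
#' @param lighting_levels lighting identifiers, high first (default 2).
#' @param magnifications slit-lamp magnification labels, low first
#'   (default 6x and 10x; they are mapped to relative zooms
#'   `magnifications / min(magnifications)`).
#' @param replicates duplicate photographs per condition (default 2).
#' @param redness_range range of the per-subject true vessel-coverage
#'   fraction, drawn once per subject and held fixed across conditions.
#' @param image_size side length of the rendered eye scenes, pixels.
#' @param seed master seed for the design's randomization and draws.
#' @return an object of class `study_design`.
#' @export
study_design <- function(subjects = sprintf("S%d", 1:4),
                         cameras = c("camA", "camB", "camC"),
                         lighting_levels = c("high", "low"),
                         magnifications = c(6, 10),
                         replicates = 2L,
                         redness_range = c(0.05, 0.6),
                         image_size = 128L,
                         seed = 1L) {
  stopifnot(length(subjects) >= 1, length(cameras) >= 1,
            length(lighting_levels) >= 1, length(magnifications) >= 1,
            replicates >= 1, length(redness_range) == 2,
            redness_range[1] >= 0, redness_range[2] <= 1,
            redness_range[1] <= redness_range[2])
  structure(
    list(subjects = subjects, cameras = cameras,
         lighting_levels = lighting_levels,
         magnifications = sort(as.numeric(magnifications)),
         replicates = as.integer(replicates),
         redness_range = as.numeric(redness_range),
         image_size = as.integer(image_size),
         seed = as.integer(seed)),
    class = "study_design"
  )
}

#' @export
print.study_design <- function(x, ...) {
  cells <- length(x$cameras) * length(x$lighting_levels) *
    length(x$magnifications) * x$replicates
  cat(sprintf(paste0("<study_design: %d subjects x %d cameras x %d lighting",
                     " x %d magnifications x %d replicates = %d cells/subject,",
                     " %d records>\n"),
              length(x$subjects), length(x$cameras), length(x$lighting_levels),
              length(x$magnifications), x$replicates, cells,
              cells * 2L * length(x$subjects)))
  invisible(x)
}

#' Enumerate the acquisition and record tables of a design
#'
#' `enumerate_design` lists one row per acquisition (a physical photograph:
#' subject x camera x lighting x magnification x replicate) in a seeded
#' randomized order; `generate_study` additionally renders the eye scenes,
#' images every acquisition through its camera profile, and simulates the
#' clinician grades, returning the full synthetic dataset. Each acquisition
#' yields two records, one per processing arm (`pre` / `post` calibration);
#' the post-arm image itself is produced later by the calibration stage.
#'
#' @param design a [study_design()].
#' @return `enumerate_design`: data.frame of acquisitions with randomization
#'   order. `generate_study`: list with elements `design`, `scenes` (one
#'   [scene_truth()] per subject), `acquisitions`, `images` (named list of
#'   [linear_image()]s keyed by acquisition id), and `records` (one row per
#'   record with grades).
#' @export
enumerate_design <- function(design) {
  stopifnot(inherits(design, "study_design"))
  acq <- expand.grid(
    replicate = seq_len(design$replicates),
    magnification = design$magnifications,
    lighting = design$lighting_levels,
    camera = design$cameras,
    subject = design$subjects,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )[, c("subject", "camera", "lighting", "magnification", "replicate")]
  acq$acquisition_id <- sprintf("%s_%s_%s_m%g_r%d", acq$subject, acq$camera,
                                acq$lighting, acq$magnification, acq$replicate)
  # randomized acquisition order within each subject's session
  ord <- with_seed(seed_child(design$seed, "order"), {
    unlist(lapply(split(seq_len(nrow(acq)), acq$subject), sample))
  })
  acq$order <- NA_integer_
  acq$order[ord] <- seq_len(nrow(acq))
  rownames(acq) <- NULL
  acq
}

#' @rdname enumerate_design
#' @param profiles named list of [camera_profile()]s keyed
#'   `"<camera>.<lighting>"`, covering every pair in the design.
#' @param graders list of [grader_profile()]s.
#' @export
generate_study <- function(design,
                           profiles = default_camera_profiles(
                             design$cameras, design$lighting_levels),
                           graders = default_grader_profiles()) {
  stopifnot(inherits(design, "study_design"))
  needed <- as.vector(outer(design$cameras, design$lighting_levels,
                            paste, sep = "."))
  missing <- setdiff(needed, names(profiles))
  if (length(missing) > 0L) {
    stop("missing camera profiles for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }

  redness <- with_seed(seed_child(design$seed, "redness"),
    stats::runif(length(design$subjects),
                 design$redness_range[1], design$redness_range[2]))
  names(redness) <- design$subjects

  scenes <- lapply(design$subjects, function(s) {
    render_eye(subject_id = s, true_redness = redness[[s]],
               size = design$image_size,
               seed = seed_child(design$seed, "scene", s))
  })
  names(scenes) <- design$subjects

  acq <- enumerate_design(design)
  zoom <- acq$magnification / min(design$magnifications)
  images <- vector("list", nrow(acq))
  names(images) <- acq$acquisition_id
  for (i in seq_len(nrow(acq))) {
    prof <- profiles[[paste(acq$camera[i], acq$lighting[i], sep = ".")]]
    images[[i]] <- apply_camera(scenes[[acq$subject[i]]], prof,
                                magnification = zoom[i],
                                seed = seed_child(design$seed, "noise",
                                                  acq$acquisition_id[i]))
  }

  arms <- c("pre", "post")
  records <- acq[rep(seq_len(nrow(acq)), each = length(arms)), ]
  records$processing_arm <- rep(arms, times = nrow(acq))
  records$record_id <- paste(records$acquisition_id, records$processing_arm,
                             sep = "_")
  records$true_redness <- vapply(records$subject,
    function(s) scenes[[s]]$true_redness, numeric(1))
  grade_mat <- do.call(rbind, lapply(seq_len(nrow(records)), function(i) {
    simulate_graders(records$true_redness[i], graders,
                     seed = seed_child(design$seed, "grade",
                                       records$record_id[i]))
  }))
  colnames(grade_mat) <- paste0("grade_",
    vapply(graders, `[[`, character(1), "grader_id"))
  records <- cbind(records, as.data.frame(grade_mat))
  rownames(records) <- NULL

  list(design = design, scenes = scenes, acquisitions = acq,
       images = images, records = records,
       profiles = profiles, graders = graders)
}
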