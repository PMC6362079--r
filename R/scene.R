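#' Ground-truth scene container
#'
#' Holds the ideal (pre-camera) reflectance of a scene together with, for eye
#' scenes, the ROI mask and the true vessel-coverage fraction. This is the
#' ground truth that a real photographic study does not have: downstream
#' recovery and monotonicity tests compare measurements against it.
#'
#' @param reflectance linear RGB array, values in \code{[0, 1]}.
#' @param roi_mask optional logical mask (eye scenes only).
#' @param true_redness achieved vessel-coverage fraction within the ROI
#'   (`NA` for charts).
#' @param scene_id,subject_id identifiers.
#' @return an object of class `scene_truth`.
#' @export
scene_truth <- function(reflectance, roi_mask = NULL, true_redness = NA_real_,
                        scene_id = NULL, subject_id = NULL) {
  reflectance <- as_pixel_array(reflectance)
  if (min(reflectance) < 0 || max(reflectance) > 1) {
    stop("reflectance must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(roi_mask)) {
    roi_mask <- as_mask(roi_mask)
    stopifnot(identical(dim(roi_mask), dim(reflectance)[1:2]))
  }
  structure(
    list(reflectance = reflectance, roi_mask = roi_mask,
         true_redness = true_redness, scene_id = scene_id,
         subject_id = subject_id),
    class = "scene_truth"
  )
}

#' Generate a synthetic conjunctiva scene
#'
#' Draws a whitish sclera background with a red vessel network of controlled
#' density, emulating a photograph of the temporal bulbar conjunctiva. The
#' ROI mask excludes an iris disc (on the nasal edge of the frame) and
#' eyelid bands at top and bottom, mirroring the manual cropping a clinical
#' image would receive. Vessels are seeded random-walk polylines drawn until
#' the fraction of ROI pixels covered equals the requested `true_redness`
#' (the achieved fraction, recorded on the scene, lands within one pixel of
#' the request).
#'
#' @param subject_id identifier stored on the scene.
#' @param true_redness requested vessel-coverage fraction in \code{[0, 1]}.
#' @param size image side length in pixels (square scene).
#' @param seed integer seed; the generator is a pure function of its
#'   arguments and this seed.
#' @param sclera_color,vessel_color linear RGB triplets.
#' @param iris_color,lid_color linear RGB for the excluded regions (cosmetic;
#'   never scored).
#' @return a [scene_truth()] with `roi_mask` and achieved `true_redness`.
#' @export
render_eye <- function(subject_id, true_redness, size = 128L, seed = 1L,
                       sclera_color = c(0.92, 0.90, 0.86),
                       vessel_color = c(0.62, 0.15, 0.15),
                       iris_color = c(0.30, 0.22, 0.15),
                       lid_color = c(0.72, 0.52, 0.44)) {
  if (true_redness < 0 || true_redness > 1) {
    stop("true_redness must lie in [0, 1]", call. = FALSE)
  }
  size <- as.integer(size)
  h <- w <- size

  # ROI geometry: eyelid bands and an iris disc at the left (nasal) edge.
  lid <- max(1L, round(0.16 * h))
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  iris_c <- c(h / 2, 0.06 * w)
  iris_r <- 0.30 * h
  iris <- (rows - iris_c[1])^2 + (cols - iris_c[2])^2 <= iris_r^2
  roi <- rows > lid & rows <= h - lid & !iris

  px <- array(rep(sclera_color, each = h * w), dim = c(h, w, 3L))
  for (ch in 1:3) {
    plane <- px[, , ch]
    plane[rows <= lid | rows > h - lid] <- lid_color[ch]
    plane[iris] <- iris_color[ch]
    px[, , ch] <- plane
  }

  roi_n <- sum(roi)
  needed <- round(true_redness * roi_n)
  vessel <- matrix(FALSE, h, w)

  if (needed > 0L) {
    roi_idx <- which(roi)
    with_seed(seed, {
      painted <- 0L
      walks <- 0L
      while (painted < needed) {
        walks <- walks + 1L
        if (walks > 20000L) {
          stop("unreachable vessel coverage: requested ", true_redness,
               call. = FALSE)
        }
        start <- roi_idx[sample.int(roi_n, 1L)]
        r <- ((start - 1L) %% h) + 1L
        c <- ((start - 1L) %/% h) + 1L
        theta <- stats::runif(1, 0, 2 * pi)
        len <- min(150L, needed - painted + 10L)
        rr <- r; cc <- c
        for (s in seq_len(len)) {
          theta <- theta + stats::rnorm(1, 0, 0.35)
          rr <- rr + sin(theta)
          cc <- cc + cos(theta)
          ri <- round(rr); ci <- round(cc)
          if (ri < 1 || ri > h || ci < 1 || ci > w || !roi[ri, ci]) break
          if (!vessel[ri, ci]) {
            vessel[ri, ci] <- TRUE
            painted <- painted + 1L
            if (painted >= needed) break
          }
        }
      }
    })
    for (ch in 1:3) {
      plane <- px[, , ch]
      plane[vessel] <- vessel_color[ch]
      px[, , ch] <- plane
    }
  }

  scene_truth(reflectance = px, roi_mask = roi,
              true_redness = sum(vessel & roi) / roi_n,
              scene_id = sprintf("eye_%s", subject_id),
              subject_id = subject_id)
}
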