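#' Parametric camera forward model
#'
#' A `camera_profile` describes how one simulated smartphone camera under one
#' lighting condition turns scene reflectance into recorded pixel values:
#' channel cross-talk (`mixing_matrix`), an illuminant color cast
#' (`illuminant_gains`), an overall intensity factor (`lighting_scale`, the
#' high/low slit-lamp illumination levels), a radial vignette standing in for
#' the slit lamp's inhomogeneous light field, a peripheral hue rotation
#' standing in for magnification-dependent color distortion of the optics,
#' optional gamma encoding, additive Gaussian sensor noise, and channel
#' clipping. The profile is the ground truth that calibration-recovery tests
#' measure against.
#'
#' @param camera_id,lighting_id identifiers for the condition the profile
#'   represents.
#' @param mixing_matrix invertible 3 x 3 channel-mixing matrix.
#' @param illuminant_gains per-channel multipliers (length 3).
#' @param lighting_scale positive scalar intensity factor.
#' @param vignette_strength coefficient of the radial falloff field
#'   \code{V(r) = 1 - vignette_strength * r^2}, with r the radius normalized
#'   to 1 at the image corner; must be < 1.
#' @param peripheral_hue_shift hue rotation, in degrees at r = 1, applied
#'   about the neutral axis with angle proportional to r.
#' @param gamma encoding exponent applied as \code{x^(1/gamma)} (1 = linear
#'   raw output).
#' @param noise_sd standard deviation of additive Gaussian sensor noise
#'   (linear units).
#' @param clip_level saturation ceiling.
#' @return an object of class `camera_profile`.
#' @export
camera_profile <- function(camera_id = "cam", lighting_id = "light",
                           mixing_matrix = diag(3),
                           illuminant_gains = c(1, 1, 1),
                           lighting_scale = 1,
                           vignette_strength = 0,
                           peripheral_hue_shift = 0,
                           gamma = 1,
                           noise_sd = 0,
                           clip_level = 1) {
  mixing_matrix <- unname(as.matrix(mixing_matrix))
  stopifnot(identical(dim(mixing_matrix), c(3L, 3L)),
            length(illuminant_gains) == 3L)
  if (!is.finite(kappa(mixing_matrix)) || abs(det(mixing_matrix)) < 1e-12) {
    stop("mixing_matrix must be invertible", call. = FALSE)
  }
  if (lighting_scale <= 0) stop("lighting_scale must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (vignette_strength < 0 || vignette_strength >= 1) {
    stop("vignette_strength must lie in [0, 1)", call. = FALSE)
  }
  if (gamma <= 0) stop("gamma must be > 0", call. = FALSE)
  structure(
    list(camera_id = camera_id, lighting_id = lighting_id,
         mixing_matrix = mixing_matrix,
         illuminant_gains = as.numeric(illuminant_gains),
         lighting_scale = lighting_scale,
         vignette_strength = vignette_strength,
         peripheral_hue_shift = peripheral_hue_shift,
         gamma = gamma, noise_sd = noise_sd, clip_level = clip_level),
    class = "camera_profile"
  )
}

#' @rdname camera_profile
#' @export
identity_profile <- function(camera_id = "ideal", lighting_id = "none") {
  camera_profile(camera_id = camera_id, lighting_id = lighting_id)
}

#' Default camera profiles for the simulated study
#'
#' Three cameras with distinct channel mixing, crossed with two lighting
#' levels (high/low intensity, the low level carrying a warmer color cast),
#' giving one profile per (camera, lighting) pair as the calibration module
#' expects. Sensor noise and vignetting are off by default; a shared mild
#' peripheral hue shift models the slit-lamp optics. Gains and scales are
#' chosen so no channel of the default scenes reaches clipping.
#'
#' @param cameras camera identifiers (3 by default).
#' @param lighting_levels lighting identifiers, high first.
#' @param noise_sd,vignette_strength overrides applied to every profile.
#' @return named list of [camera_profile()]s, keyed `"<camera>.<lighting>"`.
#' @export
default_camera_profiles <- function(cameras = c("camA", "camB", "camC"),
                                    lighting_levels = c("high", "low"),
                                    noise_sd = 0, vignette_strength = 0) {
  # positive off-diagonal cross-talk (spectral overlap of the color filter
  # array) desaturates every camera, so the uncalibrated arm shares a
  # common bias that calibration removes; the amount differs per camera
  mix <- list(
    camA = rbind(c(0.86, 0.10, 0.04),
                 c(0.07, 0.85, 0.08),
                 c(0.03, 0.10, 0.87)),
    camB = rbind(c(0.92, 0.06, 0.02),
                 c(0.10, 0.82, 0.08),
                 c(0.04, 0.12, 0.84)),
    camC = rbind(c(0.80, 0.13, 0.07),
                 c(0.05, 0.89, 0.06),
                 c(0.08, 0.06, 0.86))
  )
  cam_gain <- list(camA = c(1.00, 0.98, 0.96),
                   camB = c(1.04, 0.97, 0.92),
                   camC = c(0.95, 1.00, 1.02))
  light_gain <- list(high = c(1.00, 1.00, 1.00),
                     low  = c(1.05, 0.97, 0.88))
  light_scale <- list(high = 1.0, low = 0.5)

  profiles <- list()
  for (i in seq_along(cameras)) {
    cam <- cameras[i]
    base <- names(mix)[((i - 1L) %% 3L) + 1L]
    for (lt in lighting_levels) {
      lt_base <- if (lt == lighting_levels[1]) "high" else "low"
      profiles[[paste(cam, lt, sep = ".")]] <- camera_profile(
        camera_id = cam, lighting_id = lt,
        mixing_matrix = mix[[base]],
        illuminant_gains = cam_gain[[base]] * light_gain[[lt_base]],
        lighting_scale = light_scale[[lt_base]],
        vignette_strength = vignette_strength,
        peripheral_hue_shift = 9,
        gamma = 1, noise_sd = noise_sd, clip_level = 1
      )
    }
  }
  profiles
}

# Normalized radius field: 0 at image center, 1 at the corners.
radius_field <- function(h, w) {
  cy <- (h + 1) / 2
  cx <- (w + 1) / 2
  dr <- (matrix(seq_len(h), h, w) - cy)
  dc <- (matrix(seq_len(w), h, w, byrow = TRUE) - cx)
  sqrt(dr^2 + dc^2) / sqrt((h - cy)^2 + (w - cx)^2)
}

# Central crop by 1/zoom followed by nearest-neighbour resampling back to the
# original size. zoom = 1 is an exact no-op.
crop_resample_indices <- function(n, zoom) {
  nc <- max(1L, round(n / zoom))
  off <- (n - nc) %/% 2L
  off + pmin(nc, pmax(1L, ceiling((seq_len(n) - 0.5) * nc / n)))
}

# Rotate pixel colors about the neutral (gray) axis by per-pixel angles
# (degrees). Preserves R+G+B; output clamped to [0, 1].
rotate_hue_field <- function(px, angle_deg) {
  theta <- angle_deg * pi / 180
  h <- dim(px)[1]; w <- dim(px)[2]
  m <- pixel_matrix(px)
  ct <- as.vector(cos(theta)); st <- as.vector(sin(theta))
  s3 <- sqrt(3)
  dot <- (m[, 1] + m[, 2] + m[, 3]) / 3          # k (k . p), k = 1/sqrt(3)
  crs <- cbind(m[, 3] - m[, 2], m[, 1] - m[, 3], m[, 2] - m[, 1]) / s3
  out <- m * ct + crs * st + (1 - ct) * dot
  matrix_to_image(pmin(1, pmax(0, out)), h, w)
}

#' Image a scene through a camera profile
#'
#' Applies the full forward model: central crop-and-resample by the relative
#' magnification, radial hue rotation, channel mixing, illuminant gains and
#' lighting scale, vignetting, additive Gaussian noise, gamma encoding, and
#' clipping to \code{[0, clip_level]}. The ROI mask (if present) undergoes the
#' same geometric transform only. An identity profile at magnification 1
#' returns the scene reflectance unchanged.
#'
#' @param scene a [scene_truth()].
#' @param profile a [camera_profile()].
#' @param magnification relative zoom factor >= 1 (1 = the scene's native
#'   field of view; the study maps its 6x/10x slit-lamp settings to relative
#'   zooms 1 and 10/6).
#' @param seed integer seed for the sensor noise draw (ignored when
#'   `noise_sd = 0`).
#' @return a [linear_image()] tagged with the profile's camera/lighting ids.
#' @export
apply_camera <- function(scene, profile, magnification = 1, seed = 1L) {
  stopifnot(inherits(scene, "scene_truth"), inherits(profile, "camera_profile"))
  if (magnification < 1) stop("magnification must be >= 1", call. = FALSE)
  px <- scene$reflectance
  h <- dim(px)[1]; w <- dim(px)[2]
  mask <- scene$roi_mask

  if (magnification != 1) {
    ri <- crop_resample_indices(h, magnification)
    ci <- crop_resample_indices(w, magnification)
    px <- px[ri, ci, , drop = FALSE]
    if (!is.null(mask)) mask <- mask[ri, ci, drop = FALSE]
  }

  if (profile$peripheral_hue_shift != 0) {
    px <- rotate_hue_field(px, profile$peripheral_hue_shift * radius_field(h, w))
  }

  A <- diag(profile$illuminant_gains) %*% profile$mixing_matrix
  out <- pixel_matrix(px) %*% t(A) * profile$lighting_scale

  if (profile$vignette_strength > 0) {
    v <- 1 - profile$vignette_strength * radius_field(h, w)^2
    out <- out * as.vector(v)
  }

  if (profile$noise_sd > 0) {
    out <- out + with_seed(seed,
      matrix(stats::rnorm(length(out), 0, profile$noise_sd), nrow(out), 3L))
  }

  if (profile$gamma != 1) {
    out <- pmax(out, 0)^(1 / profile$gamma)
  }

  out <- pmin(pmax(out, 0), profile$clip_level)
  linear_image(matrix_to_image(out, h, w), roi_mask = mask,
               camera_id = profile$camera_id,
               lighting_id = profile$lighting_id)
}
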