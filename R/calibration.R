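#' Measure chart patches in a photographed chart image
#'
#' Samples the interior of each of the 24 patches of a photographed chart,
#' pairing the camera's mean linear RGB with the chart's ground-truth values.
#' A border margin is discarded on every side of each patch (patch edges mix
#' colors through optical blur and misregistration in real photographs);
#' saturated pixels (any channel at or above the threshold) are excluded from
#' the mean, and a patch is flagged as saturated when more than half of its
#' interior pixels are (its mean then falls back to all interior pixels).
#'
#' @param chart_image a [linear_image()] (or pixel array) of the photographed
#'   chart; its dimensions must be a whole multiple of the chart layout.
#' @param chart the [chart_definition()] that was photographed.
#' @param border_margin fraction of the patch side discarded on each side
#'   (default 0.2).
#' @param saturation_threshold channel ceiling above which a pixel counts as
#'   saturated (default 0.99).
#' @return data.frame with one row per patch: `patch_index`, measured and
#'   reference RGB, `saturated_fraction` and the `saturated` flag.
#' @export
measure_patches <- function(chart_image, chart, border_margin = 0.2,
                            saturation_threshold = 0.99) {
  stopifnot(inherits(chart, "chart_definition"))
  px <- as_pixel_array(chart_image)
  h <- dim(px)[1]; w <- dim(px)[2]
  if (h %% chart$rows != 0L || w %% chart$cols != 0L ||
      h %/% chart$rows != w %/% chart$cols) {
    stop("chart image dimensions inconsistent with the 4 x 6 layout",
         call. = FALSE)
  }
  patch_px <- h %/% chart$rows
  margin <- floor(border_margin * patch_px)
  if (patch_px - 2L * margin < 1L) {
    stop("border margin leaves no interior pixels", call. = FALSE)
  }

  out <- lapply(seq_len(24L), function(k) {
    ext <- patch_extent(chart, k, patch_px)
    rows <- ext$rows[(margin + 1L):(patch_px - margin)]
    cols <- ext$cols[(margin + 1L):(patch_px - margin)]
    block <- px[rows, cols, , drop = FALSE]
    m <- matrix(block, ncol = 3L)
    sat <- rowSums(m >= saturation_threshold) > 0L
    sat_frac <- mean(sat)
    flagged <- sat_frac > 0.5
    keep <- if (flagged || !any(sat)) rep(TRUE, nrow(m)) else !sat
    mu <- colMeans(m[keep, , drop = FALSE])
    data.frame(patch_index = k,
               measured_r = mu[1], measured_g = mu[2], measured_b = mu[3],
               reference_r = chart$patch_colors[k, 1],
               reference_g = chart$patch_colors[k, 2],
               reference_b = chart$patch_colors[k, 3],
               saturated_fraction = sat_frac, saturated = flagged)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

measured_mat <- function(measurements) {
  as.matrix(measurements[, c("measured_r", "measured_g", "measured_b")])
}
reference_mat <- function(measurements) {
  as.matrix(measurements[, c("reference_r", "reference_g", "reference_b")])
}

#' Estimate white-balance gains from the neutral patch
#'
#' Per-channel gains \code{g_c = reference_c / measured_c} of the designated
#' neutral patch; after applying them the neutral patch renders exactly
#' neutral (equal channels at the reference level).
#'
#' @param measurements output of [measure_patches()].
#' @param neutral_patch_index 1-based index of the neutral patch.
#' @return numeric length-3 gain vector.
#' @export
estimate_white_balance <- function(measurements, neutral_patch_index) {
  row <- measurements[measurements$patch_index == neutral_patch_index, ]
  if (nrow(row) != 1L) stop("neutral patch not found", call. = FALSE)
  if (row$saturated) {
    stop("neutral patch is saturated; white balance impossible",
         call. = FALSE)
  }
  meas <- as.numeric(measured_mat(row))
  if (any(meas <= 0)) {
    stop("neutral patch has a zero measured channel", call. = FALSE)
  }
  as.numeric(reference_mat(row)) / meas
}

#' Fit a color-correction matrix over chart patches
#'
#' Least-squares fit of \code{reference = CCM \%*\% (wb_gains * measured)}
#' (plus an offset when `affine = TRUE`) over the unflagged patches,
#' minimizing the total squared channel residual. For a noiseless linear
#' camera with mixing matrix M and unit gains, the fit recovers `solve(M)`
#' exactly.
#'
#' @param measurements output of [measure_patches()].
#' @param wb_gains white-balance gains applied to the measured values before
#'   the fit (default none).
#' @param affine fit a 3 x 4 affine transform instead of a 3 x 3 matrix.
#' @param camera_id,lighting_id identifiers stored on the model.
#' @return an object of class `calibration_model` with fields `wb_gains`,
#'   `ccm`, `offset`, `residual_rmse`, `affine`, `camera_id`, `lighting_id`.
#' @export
estimate_ccm <- function(measurements, wb_gains = c(1, 1, 1), affine = FALSE,
                         camera_id = NULL, lighting_id = NULL) {
  if (any(wb_gains <= 0)) stop("wb_gains must be > 0", call. = FALSE)
  keep <- !measurements$saturated
  n_min <- if (affine) 5L else 4L
  if (sum(keep) < n_min) {
    stop("need at least ", n_min, " unflagged patches", call. = FALSE)
  }
  X <- sweep(measured_mat(measurements)[keep, , drop = FALSE], 2L, wb_gains,
             `*`)
  Y <- reference_mat(measurements)[keep, , drop = FALSE]
  D <- if (affine) cbind(X, 1) else X
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    stop("rank-deficient patch set; cannot fit a color-correction matrix",
         call. = FALSE)
  }
  B <- qr.coef(qrD, Y)                       # ncol(D) x 3
  resid <- D %*% B - Y
  model <- structure(
    list(wb_gains = as.numeric(wb_gains),
         ccm = unname(t(B[1:3, , drop = FALSE])),
         offset = if (affine) as.numeric(B[4, ]) else c(0, 0, 0),
         affine = affine,
         residual_rmse = sqrt(mean(resid^2)),
         camera_id = camera_id, lighting_id = lighting_id),
    class = "calibration_model"
  )
  model
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model %s/%s: wb = (%.3f, %.3f, %.3f), RMSE = %.3g>\n",
              x$camera_id %||% "?", x$lighting_id %||% "?",
              x$wb_gains[1], x$wb_gains[2], x$wb_gains[3], x$residual_rmse))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply a calibration model to an image
#'
#' Per-pixel \code{CCM \%*\% (wb_gains * rgb) (+ offset)}, clipped to
#' \code{[0, 1]}; the ROI mask is unchanged. When both the image and the
#' model carry camera/lighting identifiers they must match, unless
#' `override = TRUE` — calibration is only valid for the condition whose
#' chart produced the model.
#'
#' @param image a [linear_image()] or pixel array.
#' @param model a `calibration_model`.
#' @param override skip the metadata consistency check.
#' @return a calibrated [linear_image()].
#' @export
apply_calibration <- function(image, model, override = FALSE) {
  stopifnot(inherits(model, "calibration_model"))
  is_li <- inherits(image, "linear_image")
  if (is_li && !override) {
    for (f in c("camera_id", "lighting_id")) {
      if (!is.null(image[[f]]) && !is.null(model[[f]]) &&
          !identical(image[[f]], model[[f]])) {
        stop("image ", f, " (", image[[f]], ") does not match the model (",
             model[[f]], "); use override = TRUE to force", call. = FALSE)
      }
    }
  }
  px <- as_pixel_array(image)
  h <- dim(px)[1]; w <- dim(px)[2]
  m <- sweep(pixel_matrix(px), 2L, model$wb_gains, `*`) %*% t(model$ccm)
  if (model$affine) m <- sweep(m, 2L, model$offset, `+`)
  out <- matrix_to_image(pmin(1, pmax(0, m)), h, w)
  linear_image(out,
               roi_mask = if (is_li) image$roi_mask else NULL,
               camera_id = if (is_li) image$camera_id else NULL,
               lighting_id = if (is_li) image$lighting_id else NULL)
}

#' Calibrate one camera/lighting condition from a photographed chart
#'
#' Convenience wrapper chaining [measure_patches()],
#' [estimate_white_balance()] and [estimate_ccm()].
#'
#' @inheritParams measure_patches
#' @inheritParams estimate_ccm
#' @param neutral_patch_index overrides the chart's neutral patch.
#' @return a `calibration_model`.
#' @export
calibrate_condition <- function(chart_image, chart,
                                neutral_patch_index = chart$neutral_patch_index,
                                border_margin = 0.2,
                                saturation_threshold = 0.99,
                                affine = FALSE,
                                camera_id = NULL, lighting_id = NULL) {
  if (inherits(chart_image, "linear_image")) {
    camera_id <- camera_id %||% chart_image$camera_id
    lighting_id <- lighting_id %||% chart_image$lighting_id
  }
  meas <- measure_patches(chart_image, chart, border_margin,
                          saturation_threshold)
  wb <- estimate_white_balance(meas, neutral_patch_index)
  estimate_ccm(meas, wb_gains = wb, affine = affine,
               camera_id = camera_id, lighting_id = lighting_id)
}

#' Serialize calibration models as JSON
#'
#' @param model a `calibration_model`.
#' @param path JSON file path.
#' @return `read_calibration` returns the `calibration_model`.
#' @export
write_calibration <- function(model, path) {
  stopifnot(inherits(model, "calibration_model"))
  obj <- list(camera_id = model$camera_id, lighting_id = model$lighting_id,
              wb_gains = model$wb_gains,
              ccm_row_major = as.vector(t(model$ccm)),
              offset = model$offset, affine = model$affine,
              residual_rmse = model$residual_rmse)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(wb_gains = as.numeric(obj$wb_gains),
         ccm = matrix(as.numeric(obj$ccm_row_major), 3L, 3L, byrow = TRUE),
         offset = as.numeric(obj$offset), affine = isTRUE(obj$affine),
         residual_rmse = as.numeric(obj$residual_rmse),
         camera_id = obj$camera_id, lighting_id = obj$lighting_id),
    class = "calibration_model"
  )
}
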