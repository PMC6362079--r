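#' Color reference chart definition
#'
#' A 24-patch reference chart in the style of the standard photographic
#' ColorChecker: a 4 x 6 grid of patches with known linear-RGB reflectances,
#' photographed under each camera/lighting condition to anchor white balance
#' and color-correction fitting. The built-in default ([default_chart()]) uses
#' the package's own patch values (18 chromatic patches spanning the RGB cube
#' plus a 6-step neutral ramp); real measured chart values can be supplied
#' instead.
#'
#' @param patch_colors numeric 24 x 3 matrix of linear RGB values in
#'   \code{[0, 1]}, patches in row-major grid order.
#' @param neutral_patch_index 1-based index of the neutral (gray) patch used
#'   for white balance; that patch must have R = G = B.
#' @param rows,cols grid layout (fixed 4 x 6).
#' @return an object of class `chart_definition`.
#' @export
chart_definition <- function(patch_colors, neutral_patch_index,
                             rows = 4L, cols = 6L) {
  patch_colors <- as.matrix(patch_colors)
  if (!identical(dim(patch_colors), c(24L, 3L))) {
    stop("a chart has exactly 24 patches (24 x 3 matrix)", call. = FALSE)
  }
  if (rows * cols != 24L) {
    stop("chart layout must cover 24 patches", call. = FALSE)
  }
  if (min(patch_colors) < 0 || max(patch_colors) > 1) {
    stop("patch values must lie in [0, 1]", call. = FALSE)
  }
  np <- patch_colors[neutral_patch_index, ]
  if (stats::sd(np) > 1e-12) {
    stop("the neutral patch must satisfy R = G = B", call. = FALSE)
  }
  structure(
    list(patch_colors = unname(patch_colors),
         neutral_patch_index = as.integer(neutral_patch_index),
         rows = as.integer(rows), cols = as.integer(cols)),
    class = "chart_definition"
  )
}

#' @rdname chart_definition
#' @export
default_chart <- function() {
  chromatic <- rbind(
    c(0.35, 0.22, 0.16), c(0.70, 0.55, 0.48), c(0.30, 0.40, 0.60),
    c(0.25, 0.35, 0.15), c(0.45, 0.45, 0.70), c(0.35, 0.65, 0.60),
    c(0.75, 0.40, 0.12), c(0.25, 0.25, 0.60), c(0.70, 0.25, 0.30),
    c(0.35, 0.20, 0.42), c(0.55, 0.70, 0.20), c(0.80, 0.60, 0.15),
    c(0.12, 0.18, 0.55), c(0.20, 0.55, 0.22), c(0.65, 0.12, 0.14),
    c(0.85, 0.75, 0.12), c(0.70, 0.25, 0.55), c(0.15, 0.50, 0.65)
  )
  neutral <- cbind(c(0.90, 0.70, 0.50, 0.30, 0.15, 0.05))[, c(1, 1, 1)]
  # white balance is anchored on the mid-gray (patch 21, value 0.5)
  chart_definition(rbind(chromatic, neutral), neutral_patch_index = 21L)
}

#' Render a chart definition to an ideal reflectance image
#'
#' Produces the scene a perfect camera would see: every pixel of patch k
#' equals `patch_colors[k, ]` exactly, with no mask (the whole chart is used).
#'
#' @param chart a [chart_definition()].
#' @param patch_px side length of one patch in pixels (>= 1).
#' @return a [scene_truth()] whose reflectance is a
#'   \code{4*patch_px x 6*patch_px} image.
#' @export
render_chart <- function(chart, patch_px = 16L) {
  stopifnot(inherits(chart, "chart_definition"))
  patch_px <- as.integer(patch_px)
  if (patch_px < 1L) stop("patch_px must be >= 1", call. = FALSE)
  h <- chart$rows * patch_px
  w <- chart$cols * patch_px
  px <- array(0, dim = c(h, w, 3L))
  for (k in seq_len(24L)) {
    r0 <- ((k - 1L) %/% chart$cols) * patch_px
    c0 <- ((k - 1L) %% chart$cols) * patch_px
    for (ch in 1:3) {
      px[r0 + seq_len(patch_px), c0 + seq_len(patch_px), ch] <-
        chart$patch_colors[k, ch]
    }
  }
  scene_truth(reflectance = px, scene_id = "chart")
}

# Row/column pixel extent of patch k (1-based, row-major).
patch_extent <- function(chart, k, patch_px) {
  r0 <- ((k - 1L) %/% chart$cols) * patch_px
  c0 <- ((k - 1L) %% chart$cols) * patch_px
  list(rows = r0 + seq_len(patch_px), cols = c0 + seq_len(patch_px))
}
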