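#' Build the scoring region of interest
#'
#' Combines the conjunctiva mask with saturated-zone exclusion: a pixel is
#' scored only if the mask includes it and every channel lies strictly below
#' the saturation threshold. Saturated zones carry no usable color and are
#' never counted.
#'
#' @param image a [linear_image()] or pixel array.
#' @param mask logical inclusion mask; defaults to the image's own ROI mask.
#' @param saturation_threshold channel ceiling (default 0.99 linear,
#'   about 253/255 in 8-bit units).
#' @return an object of class `roi_selection` with fields `include_mask`,
#'   `n_pixels` and `saturation_threshold`.
#' @export
build_roi <- function(image, mask = NULL, saturation_threshold = 0.99) {
  px <- as_pixel_array(image)
  if (is.null(mask) && inherits(image, "linear_image")) mask <- image$roi_mask
  if (is.null(mask)) mask <- matrix(TRUE, dim(px)[1], dim(px)[2])
  mask <- as_mask(mask)
  if (!identical(dim(mask), dim(px)[1:2])) {
    stop("mask dimensions must match the image", call. = FALSE)
  }
  unsat <- px[, , 1] < saturation_threshold &
    px[, , 2] < saturation_threshold &
    px[, , 3] < saturation_threshold
  include <- mask & unsat
  n <- sum(include)
  if (n == 0L) {
    if (!any(mask)) stop("empty ROI: the mask includes no pixels",
                         call. = FALSE)
    stop("empty ROI: all masked pixels are saturated", call. = FALSE)
  }
  structure(list(include_mask = include, n_pixels = n,
                 saturation_threshold = saturation_threshold),
            class = "roi_selection")
}

#' HSL hue of linear RGB values
#'
#' Standard HSL hue in degrees \code{[0, 360)}. Hue is undefined (returned as
#' `NA`) when the chroma \code{max - min} falls below `chroma_floor`:
#' near-gray pixels have no meaningful hue and must never count as red.
#'
#' @param rgb length-3 vector or N x 3 matrix of values in \code{[0, 1]}.
#' @param chroma_floor minimum chroma for a defined hue (default 0.01).
#' @return numeric vector of hues in degrees, `NA` where undefined.
#' @export
hue_degrees <- function(rgb, chroma_floor = 0.01) {
  m <- if (is.matrix(rgb)) rgb else matrix(rgb, ncol = 3L)
  mx <- pmax(m[, 1], m[, 2], m[, 3])
  mn <- pmin(m[, 1], m[, 2], m[, 3])
  ch <- mx - mn
  h <- rep(NA_real_, nrow(m))
  def <- ch >= chroma_floor
  is_r <- def & m[, 1] >= mx
  is_g <- def & !is_r & m[, 2] >= mx
  is_b <- def & !is_r & !is_g
  h[is_r] <- 60 * (((m[is_r, 2] - m[is_r, 3]) / ch[is_r]) %% 6)
  h[is_g] <- 60 * ((m[is_g, 3] - m[is_g, 1]) / ch[is_g] + 2)
  h[is_b] <- 60 * ((m[is_b, 1] - m[is_b, 2]) / ch[is_b] + 4)
  h %% 360
}

hue_in_band <- function(h, band) {
  lo <- band[1]; hi <- band[2]
  if (lo <= hi) !is.na(h) & h >= lo & h <= hi
  else !is.na(h) & (h >= lo | h <= hi)
}

#' Score the four objective redness metrics
#'
#' Computes, over the N included ROI pixels:
#' \describe{
#'   \item{relative_redness}{\eqn{\sum R/(R+G+B)} — a sum, not a mean, so the
#'     value is directly proportional to the conjunctival area considered
#'     (pixels with R+G+B = 0 contribute 0);}
#'   \item{rg_diff}{\eqn{(1/N)\sum (R-G)};}
#'   \item{rb_diff}{\eqn{(1/N)\sum (R-B)};}
#'   \item{red_hue}{the fraction of ROI pixels whose HSL hue is defined and
#'     falls in the red band (default \eqn{[330°, 360) \cup [0°, 30°]}).}
#' }
#'
#' @param image a [linear_image()] or pixel array.
#' @param roi an [build_roi()] selection (built from the image's own mask
#'   when omitted).
#' @param red_band length-2 hue band in degrees; `lo > hi` wraps through 0.
#' @param chroma_floor minimum chroma for a defined hue.
#' @return an object of class `redness_scores`: `relative_redness`,
#'   `rg_diff`, `rb_diff`, `red_hue`, `n_pixels`.
#' @export
score_redness <- function(image, roi = NULL, red_band = c(330, 30),
                          chroma_floor = 0.01) {
  px <- as_pixel_array(image)
  if (is.null(roi)) roi <- build_roi(image)
  stopifnot(inherits(roi, "roi_selection"))
  idx <- which(roi$include_mask)
  n <- length(idx)
  if (n < 1L) stop("empty ROI", call. = FALSE)
  m <- pixel_matrix(px)[idx, , drop = FALSE]

  s <- m[, 1] + m[, 2] + m[, 3]
  share <- ifelse(s > 0, m[, 1] / s, 0)
  h <- hue_degrees(m, chroma_floor)
  structure(
    list(relative_redness = sum(share),
         rg_diff = mean(m[, 1] - m[, 2]),
         rb_diff = mean(m[, 1] - m[, 3]),
         red_hue = sum(hue_in_band(h, red_band)) / n,
         n_pixels = n),
    class = "redness_scores"
  )
}

#' @export
print.redness_scores <- function(x, ...) {
  cat(sprintf(paste0("<redness_scores: relative_redness = %.3f, rg_diff =",
                     " %.4f, rb_diff = %.4f, red_hue = %.4f, N = %d>\n"),
              x$relative_redness, x$rg_diff, x$rb_diff, x$red_hue,
              x$n_pixels))
  invisible(x)
}

#' Score a batch of image records
#'
#' Reads each record's image and mask from disk, scores it, and joins the
#' four metrics to the record metadata. A failing record (unreadable file,
#' empty ROI, ...) is logged and skipped; the batch continues.
#'
#' @param records data.frame with at least `image_path` and `mask_path`
#'   columns; all other columns are carried through.
#' @param gamma encoding exponent of the stored images (see
#'   [read_linear_image()]).
#' @param saturation_threshold,red_band,chroma_floor scoring options.
#' @return list with `scores` (metadata + metric columns, one row per
#'   successful record) and `failures` (record index, image path, message).
#' @export
score_batch <- function(records, gamma = 1, saturation_threshold = 0.99,
                        red_band = c(330, 30), chroma_floor = 0.01) {
  stopifnot(all(c("image_path", "mask_path") %in% names(records)))
  rows <- vector("list", nrow(records))
  fails <- list()
  for (i in seq_len(nrow(records))) {
    res <- tryCatch({
      img <- read_linear_image(records$image_path[i], gamma = gamma)
      mask <- read_mask(records$mask_path[i])
      roi <- build_roi(img, mask, saturation_threshold)
      sc <- score_redness(img, roi, red_band, chroma_floor)
      cbind(records[i, , drop = FALSE],
            data.frame(relative_redness = sc$relative_redness,
                       rg_diff = sc$rg_diff, rb_diff = sc$rb_diff,
                       red_hue = sc$red_hue, n_pixels = sc$n_pixels))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      fails[[length(fails) + 1L]] <- data.frame(
        row = i, image_path = records$image_path[i],
        message = conditionMessage(res))
    } else {
      rows[[i]] <- res
    }
  }
  scores <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(scores)) scores <- records[0, , drop = FALSE]
  rownames(scores) <- NULL
  list(scores = scores,
       failures = if (length(fails)) do.call(rbind, fails)
                  else data.frame(row = integer(), image_path = character(),
                                  message = character()))
}
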