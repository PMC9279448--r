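#' Quality thresholds on the continuous FD scale
#'
#' Image quality lives on a continuous scale from 0 to about 1.7 (the
#' largest FD observed on a high-quality normal fundus). The recommended
#' rejection band is 1.45--1.50; high-quality images typically score
#' 1.60--1.70. Defaults: reject below 1.50, good at or above 1.60.
#'
#' @param reject_below FD below which an image is rejected.
#' @param good_at_or_above FD at or above which an image is good.
#' @param labels ordered class names, worst first.
#' @return an object of class `quality_thresholds`.
#' @export
quality_thresholds <- function(reject_below = 1.50, good_at_or_above = 1.60,
                               labels = c("Reject", "Usable", "Good")) {
  stopifnot(reject_below < good_at_or_above,
            reject_below >= 0, good_at_or_above <= 1.7 + 1e-9,
            length(labels) == 3L)
  structure(list(reject_below = reject_below,
                 good_at_or_above = good_at_or_above,
                 labels = labels),
            class = "quality_thresholds")
}

#' Binary quality decision from an FD value
#'
#' An image is of insufficient quality when its FD falls below the
#' threshold; an undefined FD (`NaN`, empty vessel mask) is always
#' insufficient.
#'
#' @param fd fractal dimension (numeric, possibly `NaN`) or a
#'   `fractal_dimension` object.
#' @param threshold decision threshold in (0, 2).
#' @return `"sufficient"` or `"insufficient"` (vectorized over `fd`).
#' @export
classify_binary <- function(fd, threshold = 1.50) {
  stopifnot(threshold > 0, threshold < 2)
  if (inherits(fd, "fractal_dimension")) fd <- fd$value
  ifelse(is.nan(fd) | fd < threshold, "insufficient", "sufficient")
}

#' Three-class quality decision from an FD value
#'
#' Reject if `fd < reject_below`; Good if `fd >= good_at_or_above`;
#' Usable in between. Boundaries belong to the upper class; `NaN` maps
#' to the lowest class.
#'
#' @param fd fractal dimension value(s) or a `fractal_dimension` object.
#' @param thresholds a [quality_thresholds()] object.
#' @return class label(s), a factor ordered worst to best.
#' @export
classify_multiclass <- function(fd, thresholds = quality_thresholds()) {
  stopifnot(inherits(thresholds, "quality_thresholds"))
  if (inherits(fd, "fractal_dimension")) fd <- fd$value
  lab <- ifelse(is.nan(fd) | fd < thresholds$reject_below,
                thresholds$labels[1],
                ifelse(fd >= thresholds$good_at_or_above,
                       thresholds$labels[3], thresholds$labels[2]))
  factor(lab, levels = thresholds$labels, ordered = TRUE)
}

#' Assess the quality of one fundus image end to end
#'
#' Runs the full pipeline: standardize, segment vessels, binarize the
#' probability map, estimate the box-counting fractal dimension, and
#' classify on the continuous quality scale. Stage failures on a
#' readable image are captured into a structured report (FD `NaN`, class
#' lowest) rather than raised.
#'
#' @param image a file path, `raw_fundus`, or `standardized_image`.
#' @param backend segmentation backend, `"vesselness"` (default, no
#'   weights needed) or `"cnn"`.
#' @param model trained model for the `"cnn"` backend.
#' @param thresholds a [quality_thresholds()] object.
#' @param out_side standardized side length (skipped if `image` is
#'   already standardized).
#' @param bin_threshold probability threshold for [binarize()].
#' @param sizes optional box-size ladder for [fd_of_mask()].
#' @return an object of class `quality_report`: list with `fd`, `fit_r2`,
#'   `class`, `vessel_pixels`, `backend`, `thresholds`, `source` and
#'   `error` (message or `NA`).
#' @export
assess <- function(image, backend = c("vesselness", "cnn"), model = NULL,
                   thresholds = quality_thresholds(), out_side = 1024L,
                   bin_threshold = 0.5, sizes = NULL) {
  backend <- match.arg(backend)
  src <- if (is.character(image)) image
         else if (inherits(image, "raw_fundus")) image$source else "memory"
  report <- tryCatch({
    std <- if (inherits(image, "standardized_image")) image
           else standardize(image, out_side = out_side)
    probs <- segment(std, backend = backend, model = model)
    mask <- binarize(probs, threshold = bin_threshold)
    fd <- fd_of_mask(mask, sizes)
    list(fd = fd$value, fit_r2 = fd$fit_r2,
         vessel_pixels = sum(mask), error = NA_character_)
  }, error = function(e) {
    list(fd = NaN, fit_r2 = NA_real_, vessel_pixels = 0L,
         error = conditionMessage(e))
  })
  structure(list(fd = report$fd, fit_r2 = report$fit_r2,
                 class = as.character(classify_multiclass(report$fd,
                                                          thresholds)),
                 vessel_pixels = report$vessel_pixels,
                 backend = backend, thresholds = thresholds,
                 source = src, error = report$error),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat("<quality_report>\n")
  cat(sprintf("  source:  %s\n", x$source))
  cat(sprintf("  FD:      %s (fit R2 %s, %d vessel px, backend %s)\n",
              formatC(x$fd, digits = 4, format = "f"),
              formatC(x$fit_r2, digits = 3, format = "f"),
              x$vessel_pixels, x$backend))
  cat(sprintf("  class:   %s  (reject < %.2f, good >= %.2f)\n", x$class,
              x$thresholds$reject_below, x$thresholds$good_at_or_above))
  if (!is.na(x$error)) cat(sprintf("  error:   %s\n", x$error))
  invisible(x)
}
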