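#' Read a color fundus photograph
#'
#' Loads a PNG/JPEG/TIFF file into the package's internal representation:
#' a numeric `[rows, cols, 3]` array with intensities in `[0, 1]`.
#' Grayscale files are replicated to three channels; an alpha channel is
#' dropped.
#'
#' @param path path to an image file.
#' @return an object of class `raw_fundus`: list with `pixels` (the array)
#'   and `source` (the path).
#' @export
read_fundus <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), c(dim(a), 3L))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
  if (dim(a)[3] == 1L) a <- array(rep(a, 3L), c(dim(a)[1:2], 3L))
  raw_fundus(aperm(a, c(2L, 1L, 3L)), source = path)
}

#' Construct a raw fundus image object
#'
#' @param pixels numeric `[rows, cols, 3]` array, values in `[0, 1]`.
#' @param source free-text source identifier.
#' @return an object of class `raw_fundus`.
#' @export
raw_fundus <- function(pixels, source = "memory") {
  stopifnot_color(pixels)
  if (dim(pixels)[1] < 64L || dim(pixels)[2] < 64L)
    stop("fundus image must be at least 64 x 64 pixels")
  structure(list(pixels = clamp01(pixels), source = source),
            class = "raw_fundus")
}

#' @export
print.raw_fundus <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<raw_fundus> %d x %d, source: %s\n", d[1], d[2], x$source))
  invisible(x)
}

#' Extract the circular field-of-view mask
#'
#' Fundus photographs show a bright circular field of view (FOV) on a
#' black background. The mask is found by thresholding the grayscale
#' intensity at `threshold_fraction` of its maximum, closing small gaps
#' with a disc structuring element (radius 1% of the smaller image
#' dimension), and keeping the largest connected component. The FOV
#' diameter is the larger of the component's row and column extents, so a
#' circle clipped at the frame's top/bottom still reports its full
#' diameter from the uncut horizontal chord.
#'
#' @param image a `raw_fundus` object (or bare `[rows, cols, 3]` array).
#' @param threshold_fraction fraction of the maximum intensity used as the
#'   foreground threshold; default 0.06.
#' @return an object of class `fov_mask`: list with `mask` (0/1 matrix),
#'   `centroid` (row, col) and `diameter` (pixels).
#' @export
extract_fov_mask <- function(image, threshold_fraction = 0.06) {
  px <- if (inherits(image, "raw_fundus")) image$pixels else image
  stopifnot_color(px)
  stopifnot(threshold_fraction > 0, threshold_fraction < 1)
  gray <- (px[, , 1] + px[, , 2] + px[, , 3]) / 3
  thr <- threshold_fraction * max(gray)
  bw <- gray > thr
  if (max(gray) <= 0 || !any(bw)) stop("no FOV found")
  brush_r <- max(1L, round(0.01 * min(dim(bw))))
  brush <- EBImage::makeBrush(2L * brush_r + 1L, shape = "disc")
  closed <- from_ebimage(EBImage::closing(as_ebimage(bw * 1), brush)) > 0.5
  if (!any(closed)) closed <- bw
  lab <- from_ebimage(EBImage::bwlabel(as_ebimage(closed * 1)))
  sizes <- tabulate(lab[lab > 0])
  if (length(sizes) == 0L) stop("no FOV found")
  keep <- which.max(sizes)
  mask <- (lab == keep) * 1L
  idx <- which(mask == 1L, arr.ind = TRUE)
  extent_r <- diff(range(idx[, 1])) + 1L
  extent_c <- diff(range(idx[, 2])) + 1L
  structure(list(mask = mask,
                 centroid = c(mean(idx[, 1]), mean(idx[, 2])),
                 diameter = max(extent_r, extent_c)),
            class = "fov_mask")
}

#' Locate the square bounding box of the field of view
#'
#' The box side equals the FOV diameter rounded up to the next even
#' integer and is centered on the mask centroid, so the FOV circle is
#' inscribed in the box. Coordinates are 0-based, half-open
#' `[top, bottom) x [left, right)`, and may extend beyond the raw frame
#' (those regions are padded black by [crop_and_pad()]); this restores the
#' invisible segments of a circle clipped by the frame edges.
#'
#' @param fov a `fov_mask` object.
#' @return an object of class `bounding_box`: list with integer `top`,
#'   `left`, `bottom`, `right` and `side`.
#' @export
locate_bounding_box <- function(fov) {
  stopifnot(inherits(fov, "fov_mask"), fov$diameter > 0)
  side <- as.integer(ceiling(fov$diameter))
  if (side %% 2L == 1L) side <- side + 1L
  # centroid in 0-based pixel-center coordinates
  cr0 <- fov$centroid[1] - 1
  cc0 <- fov$centroid[2] - 1
  top <- round_half_down(cr0 + 0.5 - side / 2)
  left <- round_half_down(cc0 + 0.5 - side / 2)
  structure(list(top = as.integer(top), left = as.integer(left),
                 bottom = as.integer(top + side),
                 right = as.integer(left + side), side = side),
            class = "bounding_box")
}

#' Crop a square box out of an image, padding with black
#'
#' Regions of the box outside the raw frame are filled with black pixels.
#'
#' @param image a `raw_fundus` object or `[rows, cols(, 3)]` array/matrix.
#' @param box a `bounding_box` (0-based half-open coordinates).
#' @return square array (or matrix) of side `box$side`.
#' @export
crop_and_pad <- function(image, box) {
  px <- if (inherits(image, "raw_fundus")) image$pixels else image
  stopifnot(inherits(box, "bounding_box"))
  if (box$side <= 0L) stop("bounding box side must be positive")
  d <- dim(px)
  nch <- if (length(d) == 3L) d[3] else 1L
  out <- array(0, c(box$side, box$side, nch))
  # overlap between the box and the frame, in 0-based coords
  r0 <- max(box$top, 0L); r1 <- min(box$bottom, d[1])
  c0 <- max(box$left, 0L); c1 <- min(box$right, d[2])
  if (r1 > r0 && c1 > c0) {
    src <- if (length(d) == 3L) px[(r0 + 1):r1, (c0 + 1):c1, , drop = FALSE]
           else array(px[(r0 + 1):r1, (c0 + 1):c1], c(r1 - r0, c1 - c0, 1L))
    out[(r0 - box$top + 1):(r1 - box$top),
        (c0 - box$left + 1):(c1 - box$left), ] <- src
  }
  if (length(d) == 2L) out[, , 1L] else out
}

#' Standardize a fundus image to fixed square geometry
#'
#' Composition of the four standardization steps: extract the FOV mask,
#' locate its square bounding box, crop (padding any clipped circular
#' segment with black), and resize to `out_side` x `out_side` (bilinear
#' for the color image, nearest-neighbor for the mask). The result has
#' the FOV circle inscribed and centered, equal left/right and top/bottom
#' margins, and black pixels outside the FOV.
#'
#' @param image a `raw_fundus` object, a bare `[rows, cols, 3]` array, or
#'   a file path.
#' @param out_side output side length in pixels (default 1024).
#' @param fov_threshold threshold fraction for [extract_fov_mask()].
#' @return an object of class `standardized_image`: list with `pixels`
#'   (`out_side^2 x 3` array), `fov_mask` (0/1 matrix) and `side`.
#' @export
standardize <- function(image, out_side = 1024L, fov_threshold = 0.06) {
  if (is.character(image)) image <- read_fundus(image)
  px <- if (inherits(image, "raw_fundus")) image$pixels else image
  stopifnot_color(px)
  fov <- extract_fov_mask(px, fov_threshold)
  box <- locate_bounding_box(fov)
  cropped <- crop_and_pad(px, box)
  cropped_mask <- crop_and_pad(fov$mask, box)
  out <- resize_array(cropped, out_side)
  out_mask <- (resize_array(cropped_mask, out_side, nearest = TRUE) > 0.5) * 1L
  out <- clamp01(out * as.vector(out_mask))  # recycles over the 3 channels
  standardized_image(out, out_mask)
}

#' Construct a standardized image object
#'
#' @param pixels `[side, side, 3]` array in `[0,1]`.
#' @param fov_mask 0/1 matrix of the same side; defaults to the inscribed
#'   disc.
#' @return an object of class `standardized_image`.
#' @export
standardized_image <- function(pixels, fov_mask = NULL) {
  stopifnot_color(pixels)
  side <- dim(pixels)[1]
  stopifnot(dim(pixels)[2] == side)
  if (is.null(fov_mask)) fov_mask <- inscribed_fov(side)
  stopifnot(all(dim(fov_mask) == c(side, side)))
  structure(list(pixels = pixels, fov_mask = fov_mask, side = side),
            class = "standardized_image")
}

#' @export
print.standardized_image <- function(x, ...) {
  cat(sprintf("<standardized_image> %d x %d, FOV coverage %.1f%%\n",
              x$side, x$side, 100 * mean(x$fov_mask)))
  invisible(x)
}

#' Write an image (or mask) to a PNG/JPEG/TIFF file
#'
#' @param x a `standardized_image`, `raw_fundus`, numeric array `[rows,
#'   cols, 3]` or matrix (grayscale/mask).
#' @param path output file; format from extension.
#' @return `path`, invisibly.
#' @export
write_image <- function(x, path) {
  px <- if (inherits(x, c("standardized_image", "raw_fundus"))) x$pixels else x
  EBImage::writeImage(as_ebimage(clamp01(px)), path)
  invisible(path)
}
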