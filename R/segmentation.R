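#' Pixelwise binary cross-entropy loss
#'
#' Mean over all pixels of `-gt*log(pred) - (1-gt)*log(1-pred)`, with
#' predictions clipped to `[eps, 1-eps]` for numerical safety of the
#' logarithm. This is the loss minimized when training the segmentation
#' network.
#'
#' @param gt 0/1 ground-truth matrix.
#' @param pred prediction matrix in `[0, 1]`, same dimensions.
#' @param eps clipping epsilon, default `1e-7`.
#' @return non-negative scalar loss.
#' @export
bce_loss <- function(gt, pred, eps = 1e-7) {
  if (!all(dim(gt) == dim(pred)))
    stop("ground truth and prediction dimensions differ")
  p <- pmin(pmax(pred, eps), 1 - eps)
  mean(-gt * log(p) - (1 - gt) * log(1 - p))
}

# rotate an array/matrix about its center by `angle` degrees
# (counterclockwise in row/col space); output has the same dimensions,
# exposed regions are 0. Bilinear for images, nearest for masks.
rotate_array <- function(a, angle, nearest = FALSE) {
  d <- dim(a)
  is3 <- length(d) == 3L
  h <- d[1]; w <- d[2]
  th <- angle * pi / 180
  cr <- (h + 1) / 2; cc <- (w + 1) / 2
  r <- matrix(seq_len(h), h, w) - cr
  c <- matrix(seq_len(w), h, w, byrow = TRUE) - cc
  # inverse mapping: source coordinates of each output pixel
  sr <- cos(th) * r + sin(th) * c + cr
  sc <- -sin(th) * r + cos(th) * c + cc
  sample_plane <- function(m) {
    if (nearest) {
      ri <- round(sr); ci <- round(sc)
      ok <- ri >= 1 & ri <= h & ci >= 1 & ci <= w
      out <- matrix(0, h, w)
      out[ok] <- m[cbind(ri[ok], ci[ok])]
      return(out)
    }
    r0 <- floor(sr); c0 <- floor(sc)
    fr <- sr - r0; fc <- sc - c0
    gv <- function(ri, ci) {
      ok <- ri >= 1 & ri <= h & ci >= 1 & ci <= w
      v <- matrix(0, h, w)
      v[ok] <- m[cbind(ri[ok], ci[ok])]
      v
    }
    gv(r0, c0) * (1 - fr) * (1 - fc) + gv(r0 + 1, c0) * fr * (1 - fc) +
      gv(r0, c0 + 1) * (1 - fr) * fc + gv(r0 + 1, c0 + 1) * fr * fc
  }
  if (!is3) return(sample_plane(a))
  out <- array(0, d)
  for (ch in seq_len(d[3])) out[, , ch] <- sample_plane(a[, , ch])
  out
}

flip_array <- function(a, horizontal = FALSE, vertical = FALSE) {
  d <- dim(a)
  ri <- if (vertical) rev(seq_len(d[1])) else seq_len(d[1])
  ci <- if (horizontal) rev(seq_len(d[2])) else seq_len(d[2])
  if (length(d) == 3L) a[ri, ci, , drop = FALSE] else a[ri, ci]
}

apply_pair_transform <- function(pair, tr) {
  px <- if (inherits(pair$image, "standardized_image")) pair$image$pixels
        else pair$image
  px <- rotate_array(px, tr$angle, nearest = FALSE)
  mk <- rotate_array(pair$mask, tr$angle, nearest = TRUE)
  px <- flip_array(px, tr$flip_h, tr$flip_v)
  mk <- flip_array(mk, tr$flip_h, tr$flip_v)
  list(image = px, mask = mk)
}

#' Augment image/mask training pairs by rotation and flipping
#'
#' Expands the pair list to `n_out` pairs by applying random rotations
#' (bilinear for the image, nearest-neighbor for the mask, so masks stay
#' binary) and horizontal/vertical flips, the image and mask always
#' transformed identically. The originals are kept; each generated pair
#' records its source index and transform in attribute `"transform"`.
#' Deterministic given `seed`.
#'
#' @param pairs list of pairs, each a list with `image` and `mask`.
#' @param n_out desired number of output pairs (`>=` input count).
#' @param seed integer seed.
#' @return list of `n_out` pairs.
#' @export
augment <- function(pairs, n_out, seed = 1L) {
  stopifnot(length(pairs) >= 1, n_out >= length(pairs))
  n_new <- n_out - length(pairs)
  if (n_new == 0L) return(pairs)
  new <- with_seed(seed, {
    lapply(seq_len(n_new), function(i) {
      tr <- list(source = sample.int(length(pairs), 1L),
                 angle = runif(1, 0, 360),
                 flip_h = runif(1) < 0.5,
                 flip_v = runif(1) < 0.5)
      out <- apply_pair_transform(pairs[[tr$source]], tr)
      attr(out, "transform") <- tr
      out
    })
  })
  c(pairs, new)
}

#' Binarize a vessel probability map
#'
#' @param pred probability matrix in `[0, 1]`.
#' @param threshold decision threshold in (0, 1); pixels with `pred >=
#'   threshold` become foreground.
#' @return 0/1 integer matrix.
#' @export
binarize <- function(pred, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  m <- (pred >= threshold) * 1L
  dim(m) <- dim(pred)
  m
}

#' Segment vessels in a standardized image
#'
#' Maps a standardized color image to a vessel probability map. The
#' `"vesselness"` backend (default) is a multiscale Hessian ridge filter
#' requiring no trained weights; the `"cnn"` backend runs a forward pass
#' of a trained encoder-decoder model.
#'
#' @param image a `standardized_image`.
#' @param backend `"vesselness"` or `"cnn"`.
#' @param model a trained `segmentation_model`, required for `"cnn"`.
#' @param scales vesselness scales (see [segment_vesselness]).
#' @return probability matrix in `[0, 1]`, same side as the input.
#' @export
segment <- function(image, backend = c("vesselness", "cnn"), model = NULL,
                    scales = NULL) {
  backend <- match.arg(backend)
  stopifnot(inherits(image, "standardized_image"))
  if (backend == "vesselness") return(segment_vesselness(image, scales))
  if (is.null(model))
    stop("weights required: the cnn backend needs a trained model")
  if (model$config$input_side != image$side)
    stop("model input side ", model$config$input_side,
         " does not match image side ", image$side)
  unet_forward(model, image$pixels)$probs
}

#' Dice overlap between two binary masks
#'
#' @param a,b 0/1 matrices of equal dimension.
#' @return `2|A n B| / (|A| + |B|)`; 1 when both are empty.
#' @export
dice <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  sa <- sum(a != 0); sb <- sum(b != 0)
  if (sa + sb == 0) return(1)
  2 * sum(a != 0 & b != 0) / (sa + sb)
}
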