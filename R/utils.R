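# Internal helpers. Pixel convention throughout the package: numeric arrays
# indexed [row, col(, channel)], intensities in [0,1], row 1 = top of image.
# EBImage stores (x = col, y = row); transpose only at the EBImage boundary.

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# round half down: 0.5 -> 0, 1.5 -> 1 (deterministic centering offsets)
round_half_down <- function(x) ceiling(x - 0.5)

is_color_array <- function(px) {
  is.array(px) && length(dim(px)) == 3L && dim(px)[3] == 3L
}

stopifnot_color <- function(px) {
  if (!is_color_array(px)) stop("expected an [rows, cols, 3] color array")
}

# [row, col(, ch)] array -> EBImage Image (x = col, y = row)
as_ebimage <- function(px) {
  if (length(dim(px)) == 3L) {
    EBImage::Image(aperm(px, c(2L, 1L, 3L)), colormode = "Color")
  } else {
    EBImage::Image(t(px), colormode = "Grayscale")
  }
}

from_ebimage <- function(img) {
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 3L) aperm(a, c(2L, 1L, 3L)) else t(a)
}

# bilinear (color) / nearest (mask) resize to side x side
resize_array <- function(px, side, nearest = FALSE) {
  img <- as_ebimage(px)
  filt <- if (nearest) "none" else "bilinear"
  from_ebimage(EBImage::resize(img, w = side, h = side, filter = filt))
}

# filled disc raster on an n x n grid; center in 1-based pixel coords
disc_mask <- function(side, center_row, center_col, radius) {
  r <- matrix(seq_len(side), side, side)
  c <- matrix(seq_len(side), side, side, byrow = TRUE)
  ((r - center_row)^2 + (c - center_col)^2 <= radius^2) * 1L
}

# inscribed field-of-view disc of a standardized square image
inscribed_fov <- function(side, shrink = 0) {
  ctr <- (side + 1) / 2
  disc_mask(side, ctr, ctr, side / 2 - shrink)
}

# stamp a 1-px polyline segment into a logical matrix (by reference-ish:
# returns updated matrix). Endpoints in (row, col), 1-based, fractional ok.
draw_segment <- function(m, r0, c0, r1, c1) {
  len <- sqrt((r1 - r0)^2 + (c1 - c0)^2)
  n <- max(2L, ceiling(len * 2))
  t <- seq(0, 1, length.out = n)
  rr <- round(r0 + t * (r1 - r0))
  cc <- round(c0 + t * (c1 - c0))
  keep <- rr >= 1 & rr <= nrow(m) & cc >= 1 & cc <= ncol(m)
  m[cbind(rr[keep], cc[keep])] <- 1
  m
}

# linear indices of the 1-px raster of a segment on a side x side grid
segment_pixel_index <- function(side, r0, c0, r1, c1) {
  len <- sqrt((r1 - r0)^2 + (c1 - c0)^2)
  n <- max(2L, ceiling(len * 2))
  t <- seq(0, 1, length.out = n)
  rr <- round(r0 + t * (r1 - r0))
  cc <- round(c0 + t * (c1 - c0))
  keep <- rr >= 1 & rr <= side & cc >= 1 & cc <= side
  (cc[keep] - 1) * side + rr[keep]
}

# Deterministic counter-based pseudo-random stream (splitmix-style), used
# where reproducibility must survive structural recursion (tree generator):
# the value at a given key never depends on how many other keys were drawn.
hash_unit <- function(seed, key) {
  z <- (as.numeric(seed) * 2654435761 + as.numeric(key) * 40503 + 12345) %%
    2147483647
  for (i in 1:3) z <- (z * 48271) %% 2147483647
  z / 2147483647
}

gaussian_kernel <- function(sigma, order = c(0, 0)) {
  # separable 2-D Gaussian-derivative kernel, orders (row, col) in {0,1,2}
  half <- max(1L, ceiling(3 * sigma))
  x <- (-half):half
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  d1 <- -x / sigma^2 * g
  d2 <- (x^2 / sigma^4 - 1 / sigma^2) * g
  pick <- function(o) switch(o + 1L, g, d1, d2)
  outer(pick(order[1]), pick(order[2]))
}

filter2_rep <- function(m, k) {
  from_ebimage(EBImage::filter2(as_ebimage(m), t(k), boundary = "replicate"))
}
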