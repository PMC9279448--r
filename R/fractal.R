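#' Box counts of a binary mask over a grid of box sizes
#'
#' For each box size `eps`, an evenly spaced grid of `eps` x `eps` cells
#' anchored at the top-left corner is overlaid on the mask and the number
#' of cells containing at least one foreground pixel is counted. Cells at
#' the right/bottom edges may be partial.
#'
#' @param mask 0/1 matrix (any nonzero value counts as foreground).
#' @param sizes integer box sizes, each between 1 and the mask side.
#' @return an object of class `box_count_curve`: list with `sizes` and
#'   aligned integer `counts`.
#' @export
box_counts <- function(mask, sizes) {
  stopifnot(is.matrix(mask), length(sizes) >= 1)
  sizes <- as.integer(sizes)
  if (any(sizes < 1L)) stop("box sizes must be >= 1")
  if (any(sizes > max(dim(mask)))) stop("box size exceeds mask extent")
  fg <- which(mask != 0, arr.ind = TRUE)
  counts <- vapply(sizes, function(e) {
    if (nrow(fg) == 0L) return(0L)
    cell_r <- (fg[, 1] - 1L) %/% e
    cell_c <- (fg[, 2] - 1L) %/% e
    length(unique(cell_r * (ncol(mask) %/% e + 2L) + cell_c))
  }, integer(1))
  structure(list(sizes = sizes, counts = counts), class = "box_count_curve")
}

#' Estimate the box-counting fractal dimension from a count curve
#'
#' The fractal dimension is the exponent of the power law relating the
#' occupied box count `N(eps)` to the box size: the ordinary
#' least-squares slope of `log N(eps)` against `log(1/eps)` over all
#' sizes with `N(eps) > 0`. With fewer than two usable points the
#' dimension cannot be calculated and `NaN` is returned with the
#' `undefined` flag set.
#'
#' @param curve a `box_count_curve`.
#' @return an object of class `fractal_dimension`: list with `value`
#'   (slope, or `NaN`), `fit_r2` (OLS R-squared diagnostic), `undefined`
#'   flag and the `curve`.
#' @export
estimate_fd <- function(curve) {
  stopifnot(inherits(curve, "box_count_curve"))
  ok <- curve$counts > 0
  if (sum(ok) < 2L) {
    return(structure(list(value = NaN, fit_r2 = NA_real_, undefined = TRUE,
                          curve = curve), class = "fractal_dimension"))
  }
  x <- log(1 / curve$sizes[ok])
  y <- log(curve$counts[ok])
  fit <- lm(y ~ x)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(fit$residuals^2) / ss_tot
  structure(list(value = unname(coef(fit)[2]), fit_r2 = r2,
                 undefined = FALSE, curve = curve),
            class = "fractal_dimension")
}

#' @export
print.fractal_dimension <- function(x, ...) {
  if (x$undefined) cat("<fractal_dimension> NaN (cannot be calculated)\n")
  else cat(sprintf("<fractal_dimension> %.4f (fit R2 = %.4f, %d sizes)\n",
                   x$value, x$fit_r2, length(x$curve$sizes)))
  invisible(x)
}

#' Default box-size ladder for a mask of a given side
#'
#' Powers of two from 2 up to `side / 2`.
#' @param side mask side length in pixels.
#' @return integer vector of box sizes.
#' @export
default_box_sizes <- function(side) {
  stopifnot(side >= 4)
  2L^(1:floor(log2(side / 2)))
}

#' Fractal dimension of a binary vessel mask
#'
#' Applies [box_counts()] with the default power-of-two size ladder and
#' [estimate_fd()]. An empty mask yields `NaN` (flagged), never an error.
#'
#' @param mask square 0/1 matrix.
#' @param sizes optional box sizes; default [default_box_sizes()].
#' @return a `fractal_dimension` object.
#' @export
fd_of_mask <- function(mask, sizes = NULL) {
  stopifnot(is.matrix(mask), nrow(mask) == ncol(mask))
  if (is.null(sizes)) sizes <- default_box_sizes(nrow(mask))
  estimate_fd(box_counts(mask, sizes))
}
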