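# Multiscale Hessian ridge ("vesselness") filter: a weights-free
# segmentation backend. Vessels are dark, elongated structures on the
# bright retinal background, so ridges are detected on the inverted green
# channel (the channel with the strongest vessel contrast).

frangi_response <- function(darkness, scales, beta = 0.5,
                            contrast_scale = 0.035) {
  best <- matrix(0, nrow(darkness), ncol(darkness))
  for (s in scales) {
    hrr <- s^2 * filter2_rep(darkness, gaussian_kernel(s, c(2, 0)))
    hcc <- s^2 * filter2_rep(darkness, gaussian_kernel(s, c(0, 2)))
    hrc <- s^2 * filter2_rep(darkness, gaussian_kernel(s, c(1, 1)))
    tmp <- sqrt(((hrr - hcc) / 2)^2 + hrc^2)
    mid <- (hrr + hcc) / 2
    ea <- mid + tmp
    eb <- mid - tmp
    # order by magnitude: |l1| <= |l2|
    swap <- abs(ea) > abs(eb)
    l1 <- ifelse(swap, eb, ea)
    l2 <- ifelse(swap, ea, eb)
    rb2 <- (l1 / ifelse(l2 == 0, 1e-12, l2))^2
    s2 <- l1^2 + l2^2
    v <- exp(-rb2 / (2 * beta^2)) *
      (1 - exp(-s2 / (2 * contrast_scale^2)))
    v[l2 > 0] <- 0   # bright ridges on the darkness map have l2 < 0
    best <- pmax(best, v)
  }
  best
}

#' Vesselness probability map of a standardized image
#'
#' Multiscale Hessian ridge filter (scales 1, 2, 4, 8 px by default,
#' scaled with image side) on the inverted green channel, restricted to
#' the field of view. The structure-magnitude term uses a fixed contrast
#' scale rather than a per-image one, deliberately: a globally faded
#' image (blur, overexposure veil) then produces genuinely weaker vessel
#' probabilities instead of being renormalized back, which is the
#' behavior a quality metric needs.
#'
#' @param std a `standardized_image`.
#' @param scales Gaussian scales in pixels; default `c(1, 2, 4, 8) *
#'   side / 1024`, floored at 1.
#' @param contrast_scale absolute Hessian-magnitude scale at which a
#'   ridge is considered strong (intensity units; default 0.035).
#' @return matrix of values in `[0, 1]`, zero outside the FOV.
#' @keywords internal
segment_vesselness <- function(std, scales = NULL, contrast_scale = 0.035) {
  stopifnot(inherits(std, "standardized_image"))
  if (is.null(scales)) scales <- pmax(1, c(1, 2, 4, 8) * std$side / 1024)
  green <- std$pixels[, , 2]
  darkness <- (1 - green) * std$fov_mask
  # shrink the FOV rim: the black exterior creates a huge artificial edge
  rim <- inscribed_fov(std$side, shrink = max(5, 3 * max(scales)))
  frangi_response(darkness, scales, contrast_scale = contrast_scale) *
    std$fov_mask * rim
}
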