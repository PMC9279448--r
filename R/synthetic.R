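#' Parameters of the synthetic branching vessel tree
#'
#' The generator grows `n_roots` recursive binary trees from the FOV
#' boundary toward the center, emulating the branching geometry that
#' makes retinal vasculature a fractal. Strokes taper with branching
#' depth. All randomness comes from a counter-based hash of the seed and
#' the node index, so a deeper tree is a pixel superset of a shallower
#' one with the same seed.
#'
#' @param depth number of branching generations (>= 1).
#' @param branch_angle full angle between sibling branches, degrees.
#' @param length_ratio child/parent segment length ratio, in (0, 1).
#' @param initial_width root stroke width, pixels.
#' @param width_taper per-generation width multiplier, in (0, 1].
#' @param n_roots number of root vessels entering the FOV.
#' @param seed integer seed.
#' @return an object of class `tree_params`.
#' @export
tree_params <- function(depth = 9L, branch_angle = 40, length_ratio = 0.72,
                        initial_width = 5, width_taper = 0.78,
                        n_roots = 4L, seed = 1L) {
  stopifnot(depth >= 1, length_ratio > 0, length_ratio < 1,
            width_taper > 0, width_taper <= 1, n_roots >= 1,
            initial_width >= 1)
  structure(list(depth = as.integer(depth), branch_angle = branch_angle,
                 length_ratio = length_ratio,
                 initial_width = initial_width, width_taper = width_taper,
                 n_roots = as.integer(n_roots), seed = as.integer(seed)),
            class = "tree_params")
}

#' Generate a synthetic binary vessel tree
#'
#' @param params a [tree_params()].
#' @param side output mask side, pixels.
#' @return 0/1 matrix: the ground-truth vessel mask, fully inside the
#'   inscribed FOV circle.
#' @export
generate_vessel_tree <- function(params = tree_params(), side = 512L) {
  stopifnot(inherits(params, "tree_params"), side >= 64)
  ctr <- (side + 1) / 2
  R <- side / 2
  segs <- vector("list", 50000L)   # (level, r0, c0, r1, c1) rows
  nseg <- 0L
  u <- function(root, node, slot)   # deterministic per-node uniform
    hash_unit(params$seed, root * 67108864 + node * 8 + slot)
  grow <- function(root, node, level, r, c, theta, len) {
    if (level > params$depth) return(invisible())
    r1 <- r + len * sin(theta)
    c1 <- c + len * cos(theta)
    nseg <<- nseg + 1L
    segs[[nseg]] <<- c(level, r, c, r1, c1)
    half <- params$branch_angle / 2 * pi / 180
    spread1 <- half * (0.6 + 0.8 * u(root, node, 1))
    spread2 <- half * (0.6 + 0.8 * u(root, node, 2))
    len1 <- len * params$length_ratio * (0.8 + 0.4 * u(root, node, 3))
    len2 <- len * params$length_ratio * (0.8 + 0.4 * u(root, node, 4))
    grow(root, 2 * node, level + 1, r1, c1, theta - spread1, len1)
    grow(root, 2 * node + 1, level + 1, r1, c1, theta + spread2, len2)
  }
  for (root in seq_len(params$n_roots)) {
    phi <- 2 * pi * (root - 1) / params$n_roots +
      0.5 * (u(root, 0, 5) - 0.5)
    r0 <- ctr + 0.92 * R * sin(phi)
    c0 <- ctr + 0.92 * R * cos(phi)
    # head inward with some jitter
    theta <- phi + pi + 0.6 * (u(root, 0, 6) - 0.5)
    len0 <- R * (0.32 + 0.12 * u(root, 0, 7))
    grow(root, 1, 1, r0, c0, theta, len0)
  }
  seg_mat <- do.call(rbind, segs[seq_len(nseg)])
  out <- matrix(0L, side, side)
  for (l in seq_len(params$depth)) {
    w <- max(1, round(params$initial_width * params$width_taper^(l - 1)))
    stroke <- matrix(0L, side, side)
    lv <- seg_mat[seg_mat[, 1] == l, , drop = FALSE]
    idx <- unlist(lapply(seq_len(nrow(lv)), function(i)
      segment_pixel_index(side, lv[i, 2], lv[i, 3], lv[i, 4], lv[i, 5])))
    stroke[idx] <- 1L
    if (w > 1) {
      brush <- EBImage::makeBrush(2L * (w %/% 2L) + 1L, shape = "disc")
      stroke <- (from_ebimage(EBImage::dilate(as_ebimage(stroke),
                                              brush)) > 0.5) * 1L
    }
    out <- pmax(out, stroke)
  }
  out * inscribed_fov(side, shrink = 2)
}

#' Render a fundus phantom around a vessel tree
#'
#' Produces a standardized-geometry color phantom: an orange-hued retinal
#' background disc with mild radial shading and smooth seeded texture, a
#' bright optic-disc (OD) disc nasally, dark vessel strokes from the
#' ground-truth tree, and an exactly black exterior. The macula sits at
#' the image center with the OD one third of a side away, so the
#' associated retinal field geometry is returned alongside.
#'
#' @param tree 0/1 vessel mask from [generate_vessel_tree()] (defines the
#'   side).
#' @param seed integer seed for the background texture.
#' @return list with `image` (a `standardized_image`), `mask` (the
#'   ground-truth tree) and `geometry` (a `retinal_field_geometry`).
#' @export
render_phantom <- function(tree, seed = 1L) {
  stopifnot(is.matrix(tree))
  side <- nrow(tree)
  ctr <- (side + 1) / 2
  fov <- inscribed_fov(side)
  rr <- matrix(seq_len(side), side, side) - ctr
  cc <- matrix(seq_len(side), side, side, byrow = TRUE) - ctr
  rad2 <- (rr^2 + cc^2) / (side / 2)^2
  shade <- 1 - 0.22 * rad2
  texture <- with_seed(seed, {
    coarse <- matrix(runif(64, -1, 1), 8, 8)
    resize_array(coarse, side) * 0.04
  })
  base <- c(0.82, 0.47, 0.20)
  px <- array(0, c(side, side, 3))
  for (ch in 1:3) px[, , ch] <- base[ch] * shade + texture
  od_center <- c(ctr, ctr + side / 3)
  od_radius <- 0.065 * side
  od <- disc_mask(side, od_center[1], od_center[2], od_radius)
  od_col <- c(0.95, 0.85, 0.55)
  for (ch in 1:3) px[, , ch] <- px[, , ch] * (1 - od) + od_col[ch] * od
  # darker macular pigmentation at the center
  mac_spot <- exp(-rad2 * 18)
  for (ch in 1:3) px[, , ch] <- px[, , ch] * (1 - 0.25 * mac_spot)
  vessel_col <- c(0.38, 0.10, 0.04)
  for (ch in 1:3)
    px[, , ch] <- px[, , ch] * (1 - 0.9 * tree) + vessel_col[ch] * 0.9 * tree
  px <- clamp01(px * as.vector(fov))
  geometry <- retinal_field_geometry(od_center = od_center,
                                     od_radius = od_radius,
                                     macula_center = c(ctr, ctr))
  list(image = standardized_image(px, fov), mask = tree,
       geometry = geometry)
}

#' Specification of a synthetic quality degradation
#'
#' @param kind one of `"blur"`, `"overexposure"`,
#'   `"uneven_illumination"`, `"crop_fov"`, `"thin_vessels"`.
#' @param severity in `[0, 1]`; 0 is the identity transform.
#' @param seed integer seed (reserved for stochastic degradations).
#' @return an object of class `degradation_spec`.
#' @export
degradation_spec <- function(kind = c("blur", "overexposure",
                                      "uneven_illumination", "crop_fov",
                                      "thin_vessels"),
                             severity, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(severity >= 0, severity <= 1)
  structure(list(kind = kind, severity = severity, seed = as.integer(seed)),
            class = "degradation_spec")
}

#' Apply a quality degradation to a standardized image
#'
#' Emulates common fundus quality failures: defocus `blur`;
#' `overexposure` as a milky-white veil growing from the periphery toward
#' the center; `uneven_illumination` as a lateral gain ramp; `crop_fov`
#' shrinking the visible field; `thin_vessels` washing vessel contrast
#' toward the local background. Severity 0 returns the input pixel for
#' pixel.
#'
#' @param image a `standardized_image`.
#' @param spec a [degradation_spec()].
#' @return a degraded `standardized_image`.
#' @export
degrade <- function(image, spec) {
  stopifnot(inherits(image, "standardized_image"),
            inherits(spec, "degradation_spec"))
  if (spec$severity == 0) return(image)
  side <- image$side
  px <- image$pixels
  fov <- image$fov_mask
  s <- spec$severity
  ctr <- (side + 1) / 2
  rad <- sqrt((matrix(seq_len(side), side, side) - ctr)^2 +
                (matrix(seq_len(side), side, side, byrow = TRUE) - ctr)^2) /
    (side / 2)
  if (spec$kind == "blur") {
    sigma <- s * 8 * side / 512
    px <- from_ebimage(EBImage::gblur(as_ebimage(px), sigma = sigma))
  } else if (spec$kind == "overexposure") {
    veil <- s * (0.45 + 0.55 * pmin(rad, 1))
    for (ch in 1:3) px[, , ch] <- px[, , ch] + veil * (1 - px[, , ch])
  } else if (spec$kind == "uneven_illumination") {
    gain <- 1 - s * 0.7 * (matrix(seq_len(side), side, side,
                                  byrow = TRUE) - 1) / (side - 1)
    for (ch in 1:3) px[, , ch] <- px[, , ch] * gain
  } else if (spec$kind == "crop_fov") {
    keep <- disc_mask(side, ctr, ctr, (1 - 0.5 * s) * side / 2)
    fov <- fov * keep
    px <- px * as.vector(fov)
  } else if (spec$kind == "thin_vessels") {
    bg <- from_ebimage(EBImage::gblur(as_ebimage(px), sigma = side / 32))
    px <- bg + (px - bg) * (1 - 0.85 * s)
  }
  px <- clamp01(px * as.vector(fov))
  standardized_image(px, fov)
}

#' Deterministic rasterizations of sets with known fractal dimension
#'
#' Oracle fixtures for the box-counting estimator: a 1-px `line`
#' (dimension 1), a filled `disc` (2), a single `point` (0), the
#' `sierpinski` triangle (log 3 / log 2 ~ 1.585) and the `koch` curve
#' (log 4 / log 3 ~ 1.2619).
#'
#' @param name which fixture.
#' @param side mask side; >= 256 for `sierpinski`/`koch` (and a power of
#'   two for `sierpinski`).
#' @return 0/1 matrix.
#' @export
known_fractal <- function(name = c("line", "disc", "point", "sierpinski",
                                   "koch"), side = 1024L) {
  name <- match.arg(name)
  m <- matrix(0L, side, side)
  if (name == "line") {
    m[side %/% 2L, ] <- 1L
  } else if (name == "disc") {
    m <- disc_mask(side, (side + 1) / 2, (side + 1) / 2,
                   round(0.39 * side))
  } else if (name == "point") {
    m[side %/% 2L, side %/% 2L] <- 1L
  } else if (name == "sierpinski") {
    stopifnot(side >= 256, bitwAnd(side, side - 1L) == 0L)
    i <- matrix(0:(side - 1L), side, side)
    j <- matrix(0:(side - 1L), side, side, byrow = TRUE)
    m <- matrix((bitwAnd(as.vector(i), as.vector(j)) == 0L) * 1L,
                side, side)
  } else if (name == "koch") {
    stopifnot(side >= 256)
    depth <- max(4L, ceiling(log(side) / log(3)) - 1L)
    segs <- matrix(c(0, 0, 1, 0), 1)   # unit segment, (x0,y0,x1,y1)
    for (d in seq_len(depth)) {
      out <- matrix(0, 4 * nrow(segs), 4)
      for (i in seq_len(nrow(segs))) {
        p <- segs[i, 1:2]; q <- segs[i, 3:4]
        v <- (q - p) / 3
        a <- p + v; b <- p + 2 * v
        # peak of the equilateral bump
        pk <- a + c(v[1] * 0.5 - v[2] * sqrt(3) / 2,
                    v[1] * sqrt(3) / 2 + v[2] * 0.5)
        out[4 * i - 3, ] <- c(p, a)
        out[4 * i - 2, ] <- c(a, pk)
        out[4 * i - 1, ] <- c(pk, b)
        out[4 * i, ] <- c(b, q)
      }
      segs <- out
    }
    scale <- side - 2
    base_row <- round(side * 0.7)
    for (i in seq_len(nrow(segs))) {
      m <- draw_segment(m,
                        base_row - segs[i, 2] * scale,
                        1 + segs[i, 1] * scale,
                        base_row - segs[i, 4] * scale,
                        1 + segs[i, 3] * scale)
    }
  }
  m
}
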