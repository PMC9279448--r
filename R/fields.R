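#' Retinal field geometry
#'
#' Six retinal fields tile the field of view: the optic disc (OD), the
#' macula (M, a disc whose radius is 0.6 times the OD-to-macula distance
#' `d`), and the nasal (N), superior (S), temporal (T) and inferior (I)
#' quadrants around the macula center, bounded by the two 45-degree
#' diagonals through it. The nasal side is the side facing the optic
#' disc, so laterality follows from the OD position relative to the
#' macula.
#'
#' @param od_center optic disc center, `c(row, col)` pixels.
#' @param od_radius optic disc radius, pixels.
#' @param macula_center macula center, `c(row, col)` pixels.
#' @return an object of class `retinal_field_geometry` with the inputs
#'   plus derived `d` (center distance) and `macula_radius = 0.6 * d`.
#' @export
retinal_field_geometry <- function(od_center, od_radius, macula_center) {
  d <- sqrt(sum((od_center - macula_center)^2))
  if (d <= 0) stop("OD and macula centers must differ")
  stopifnot(od_radius > 0)
  structure(list(od_center = od_center, od_radius = od_radius,
                 macula_center = macula_center, d = d,
                 macula_radius = 0.6 * d),
            class = "retinal_field_geometry")
}

FIELD_LABELS <- c("OD", "M", "N", "S", "T", "I")

#' Rasterize one retinal field as a binary mask
#'
#' `OD` is the optic disc; `M` the macular disc minus the OD; each
#' quadrant (`N`/`S`/`T`/`I`) is its diagonal wedge around the macula
#' center minus the OD and M discs. All fields are clipped to the
#' inscribed FOV circle, so the six masks are pairwise disjoint and their
#' union is the whole FOV.
#'
#' @param geometry a `retinal_field_geometry`.
#' @param field one of `"OD"`, `"M"`, `"N"`, `"S"`, `"T"`, `"I"`.
#' @param side mask side length in pixels.
#' @return 0/1 matrix of dimension `side` x `side`.
#' @export
field_mask <- function(geometry, field, side) {
  stopifnot(inherits(geometry, "retinal_field_geometry"))
  if (!field %in% FIELD_LABELS)
    stop("unknown retinal field: ", field)
  fov <- inscribed_fov(side)
  od <- disc_mask(side, geometry$od_center[1], geometry$od_center[2],
                  geometry$od_radius)
  if (field == "OD") return(od * fov)
  mac <- disc_mask(side, geometry$macula_center[1], geometry$macula_center[2],
                   geometry$macula_radius)
  if (field == "M") return(mac * (1 - od) * fov)
  dr <- matrix(seq_len(side), side, side) - geometry$macula_center[1]
  dc <- matrix(seq_len(side), side, side, byrow = TRUE) -
    geometry$macula_center[2]
  # nasal = toward the optic disc along the horizontal axis
  nasal_sign <- sign(geometry$od_center[2] - geometry$macula_center[2])
  if (nasal_sign == 0) nasal_sign <- 1
  horiz <- abs(dc) >= abs(dr)                # N/T pair; S/I otherwise
  wedge <- switch(field,
    N = horiz & (dc * nasal_sign > 0),
    T = horiz & (dc * nasal_sign <= 0),
    S = !horiz & (dr < 0),                   # superior = smaller row (up)
    I = !horiz & (dr >= 0))
  (wedge * 1L) * (1 - od) * (1 - mac) * fov
}

#' Fractal dimension after removing one retinal field
#'
#' Zeroes the vessel pixels inside the given field, then estimates the
#' box-counting dimension of the remainder. Removing any vessel-bearing
#' region can only lower box counts, so the FD never increases; removing
#' all fields leaves an empty mask and an `NaN` dimension.
#'
#' @param mask square 0/1 vessel mask.
#' @param geometry a `retinal_field_geometry` aligned with `mask`.
#' @param field field label, or a character vector of labels to remove
#'   together.
#' @param sizes optional box sizes passed to [fd_of_mask()].
#' @return a `fractal_dimension` object.
#' @export
fd_with_field_removed <- function(mask, geometry, field, sizes = NULL) {
  stopifnot(is.matrix(mask))
  removed <- mask
  for (f in field) {
    fm <- field_mask(geometry, f, nrow(mask))
    removed[fm == 1L] <- 0L
  }
  fd_of_mask(removed, sizes)
}
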