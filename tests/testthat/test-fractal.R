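test_that("box counts match hand cases: empty, single pixel, filled grid", {
  empty <- matrix(0L, 64, 64)
  expect_equal(box_counts(empty, 16L)$counts, 0L)
  single <- empty; single[20, 41] <- 1L
  expect_equal(box_counts(single, c(1L, 3L, 16L, 64L))$counts,
               c(1L, 1L, 1L, 1L))
  filled <- matrix(1L, 64, 64)
  expect_equal(box_counts(filled, 16L)$counts, 16L)
  expect_error(box_counts(filled, 0L), ">= 1")
})

test_that("box counting equals the naive per-cell oracle on random masks", {
  set.seed(7)
  for (i in 1:25) {
    mask <- matrix(rbinom(64 * 64, 1, runif(1, 0.005, 0.3)), 64, 64)
    sizes <- c(1L, 2L, 3L, 5L, 8L, 16L, 64L)
    fast <- box_counts(mask, sizes)$counts
    slow <- vapply(sizes, function(e) naive_box_count(mask, e), integer(1))
    expect_identical(fast, slow)
  }
})

test_that("box counts are monotone under mask subsets", {
  set.seed(11)
  for (i in 1:10) {
    b <- matrix(rbinom(64 * 64, 1, 0.2), 64, 64)
    a <- b * matrix(rbinom(64 * 64, 1, 0.6), 64, 64)  # a subset of b
    sizes <- c(2L, 4L, 8L, 16L)
    expect_true(all(box_counts(a, sizes)$counts <=
                      box_counts(b, sizes)$counts))
  }
})

test_that("the FD estimator recovers analytic dimensions", {
  sq <- matrix(1L, 1024, 1024)
  fd_sq <- estimate_fd(box_counts(sq, 2L^(1:9)))
  expect_equal(fd_sq$value, 2, tolerance = 0.02 / 2)
  expect_equal(fd_of_mask(known_fractal("line", 1024))$value, 1,
               tolerance = 0.03)
  expect_lt(abs(fd_of_mask(known_fractal("point", 1024))$value), 0.01)
  expect_equal(fd_of_mask(known_fractal("sierpinski", 1024))$value,
               log(3) / log(2), tolerance = 0.05 / 1.585)
  expect_equal(fd_of_mask(known_fractal("koch", 1024))$value,
               log(4) / log(3), tolerance = 0.08 / 1.262)
})

test_that("an empty mask yields the NaN sentinel, not an error", {
  fd <- fd_of_mask(matrix(0L, 256, 256))
  expect_true(is.nan(fd$value))
  expect_true(fd$undefined)
  # fewer than two usable points also yields NaN
  one_pt <- structure(list(sizes = c(2L, 4L), counts = c(5L, 0L)),
                      class = "box_count_curve")
  expect_true(is.nan(estimate_fd(one_pt)$value))
})

test_that("FD is stable across rendering resolutions", {
  fd512 <- fd_of_mask(generate_vessel_tree(tree_params(seed = 5L), 512L))
  fd1024 <- fd_of_mask(generate_vessel_tree(tree_params(seed = 5L), 1024L))
  expect_lt(abs(fd512$value - fd1024$value), 0.05)
})

test_that("retinal field geometry derives the macular radius from the OD distance", {
  g <- retinal_field_geometry(od_center = c(512, 300), od_radius = 60,
                              macula_center = c(512, 650))
  expect_equal(g$d, 350)
  expect_equal(g$macula_radius, 210)
  expect_error(retinal_field_geometry(c(1, 1), 10, c(1, 1)), "differ")
  expect_error(field_mask(g, "X", 64), "unknown retinal field")
})

test_that("the six retinal fields partition the FOV", {
  side <- 256L
  g <- retinal_field_geometry(od_center = c(128.5, 128.5 + side / 3),
                              od_radius = 0.065 * side,
                              macula_center = c(128.5, 128.5))
  masks <- lapply(c("OD", "M", "N", "S", "T", "I"), field_mask,
                  geometry = g, side = side)
  total <- Reduce(`+`, masks)
  fov <- retinafd:::inscribed_fov(side)
  expect_true(all(total[fov == 1] == 1))   # union covers, no overlap
  expect_true(all(total[fov == 0] == 0))
})

test_that("field removal lowers box counts and FD on vessel-rich fields", {
  for (s in c(2L, 3L)) {
    ph <- small_phantom(seed = s, side = 256L)
    full_fd <- fd_of_mask(ph$mask)
    sizes <- default_box_sizes(256L)
    full_counts <- box_counts(ph$mask, sizes)$counts
    for (f in c("M", "N")) {   # the fields carrying major vasculature
      fm <- field_mask(ph$geometry, f, 256L)
      expect_gt(sum(ph$mask[fm == 1]), 0)
      removed <- ph$mask
      removed[fm == 1] <- 0L
      expect_true(all(box_counts(removed, sizes)$counts <= full_counts))
      expect_lt(fd_with_field_removed(ph$mask, ph$geometry, f)$value,
                full_fd$value)
    }
    # removing a field with no vessels is a no-op on the FD
    empty_field <- matrix(0L, 256, 256)
    expect_equal(fd_with_field_removed(ph$mask * 0L + ph$mask,
                                       ph$geometry, character(0))$value,
                 full_fd$value)
    # removing every field empties the FOV: NaN sentinel
    all_removed <- fd_with_field_removed(ph$mask, ph$geometry,
                                         c("OD", "M", "N", "S", "T", "I"))
    expect_true(is.nan(all_removed$value))
  }
})
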