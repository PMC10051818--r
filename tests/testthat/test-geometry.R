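test_that("trajectory length is the Euclidean entry-target distance", {
  expect_equal(segment_length(segment(c(0, 0, 0), c(0, 0, 60))), 60)
  ## 3-4-12-13 Pythagorean quadruple
  expect_equal(segment_length(segment(c(3, 4, 0), c(0, 0, 12))), 13)
  expect_error(segment(c(1, 2, 3), c(1, 2, 3)), "degenerate")
})

test_that("segment-to-streamline distance handles crossing, parallel and empty cases", {
  straight <- streamline_bundle(list(cbind(seq(-10, 10, 2), 5, 0)), "CST")
  ## crossing at right angles -> 0
  crossing <- segment(c(0, 5, -4), c(0, 5, 4))
  expect_equal(min_distance_to_streamlines(crossing, straight), 0)
  ## parallel at 5 mm offset
  par <- segment(c(-10, 0, 0), c(10, 0, 0))
  expect_equal(min_distance_to_streamlines(par, straight), 5)
  expect_error(min_distance_to_streamlines(par, list(streamlines = list())),
               "empty")
})

test_that("segment-to-mask distance uses voxel centres and detects pass-through", {
  single <- box_mask(dims = c(1, 1, 1), lo = c(1, 1, 1), hi = c(1, 1, 1),
                     origin = c(10, 0, 0))
  axisz <- segment(c(0, 0, -5), c(0, 0, 5))
  expect_equal(min_distance_to_mask(axisz, single), 10)
  through <- segment(c(5, 0, 0), c(15, 0, 0))
  expect_equal(min_distance_to_mask(through, single), 0)
  empty <- volumetric_mask(array(0L, c(3, 3, 3)), diag(4), "vessel")
  expect_error(min_distance_to_mask(axisz, empty), "empty")
})

test_that("transgression is exact segment/voxel-box intersection", {
  cube <- box_mask(dims = c(9, 9, 9), lo = c(3, 3, 3), hi = c(7, 7, 7))
  expect_true(transgresses_mask(segment(c(-5, 4, 4), c(15, 4, 4)), cube))
  expect_false(transgresses_mask(segment(c(-5, -5, -5), c(-5, -5, 20)), cube))
  ## grazing the box face plane of the outermost voxel layer
  expect_true(transgresses_mask(segment(c(-5, 4, 6.4), c(15, 4, 6.4)), cube))
  expect_false(transgresses_mask(segment(c(-5, 4, 6.6), c(15, 4, 6.6)), cube))
})

test_that("midline distance is the segment minimum, zero when crossing", {
  pl <- midline_plane(c(0, 2, 0), c(0, -24, 0))
  par <- segment(c(16.8, 5, 10), c(16.8, -30, 55))
  expect_equal(distance_to_midline(par, pl), 16.8)
  expect_equal(distance_to_midline(segment(c(-4, 0, 0), c(9, 2, 1)), pl), 0)
  ## same side: minimum of the endpoint distances
  expect_equal(distance_to_midline(segment(c(5, 0, 0), c(25, 8, 3)), pl), 5)
})

test_that("distances are symmetric under entry/target swap and non-negative", {
  set.seed(31)
  mask <- random_blob_mask()
  bund <- streamline_bundle(lapply(1:3, function(i) random_polyline()), "CST")
  pl <- midline_plane(c(0, 2, 0), c(0, -24, 0))
  for (k in 1:25) {
    a <- runif(3, -15, 25); b <- runif(3, -15, 25)
    s1 <- segment(a, b); s2 <- segment(b, a)
    for (f in list(function(s) min_distance_to_streamlines(s, bund),
                   function(s) min_distance_to_mask(s, mask),
                   function(s) distance_to_midline(s, pl))) {
      d1 <- f(s1)
      expect_gte(d1, 0)
      expect_equal(d1, f(s2), tolerance = 1e-12)
    }
    expect_identical(transgresses_mask(s1, mask), transgresses_mask(s2, mask))
  }
})

test_that("adding streamlines never increases the bundle distance", {
  set.seed(57)
  seg <- segment(c(0, 0, 0), c(30, 20, 10))
  sls <- lapply(1:6, function(i) random_polyline())
  d_prev <- Inf
  for (k in 1:6) {
    d <- min_distance_to_streamlines(seg, streamline_bundle(sls[1:k], "CST"))
    expect_lte(d, d_prev + 1e-12)
    d_prev <- d
  }
})

test_that("dilating a mask never increases distance nor clears transgression", {
  set.seed(91)
  dilate <- function(mask) {
    g <- mask$grid; d <- dim(g); out <- g
    shift <- function(arr, k, by) {
      idx <- rep(list(quote(expr = )), 3L)
      src <- pmin(pmax(seq_len(d[k]) - by, 1L), d[k])
      idx[[k]] <- src
      do.call(`[`, c(list(arr), idx))
    }
    for (k in 1:3) for (by in c(-1L, 1L)) out <- out | shift(g, k, by)
    volumetric_mask(array(as.integer(out), d), mask$affine, mask$label)
  }
  for (rep in 1:10) {
    mask <- random_blob_mask()
    big <- dilate(mask)
    seg <- segment(runif(3, -10, 25), runif(3, -10, 25))
    expect_lte(min_distance_to_mask(seg, big),
               min_distance_to_mask(seg, mask) + 1e-12)
    if (transgresses_mask(seg, mask)) expect_true(transgresses_mask(seg, big))
  }
})
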