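test_that("mean-gray-level threshold segments the colony", {
  expect_error(segment_colony(image2d(matrix(0, 32, 32), cal1(1))),
               "variance")
  # disk on dark background: mask equals the direct mean+comparison oracle
  img <- disk_image(size = 64, R = 16, fg = 100)
  mask <- segment_colony(img)
  oracle <- img$pixels >= mean(img$pixels)
  expect_equal(mask$mask, oracle)
  # two components: only the larger is retained
  two <- img$pixels
  two[3:6, 3:6] <- 100  # small blob, area 16 << disk
  m2 <- segment_colony(image2d(two, cal1(1)))
  expect_equal(sum(m2$mask), sum(two >= mean(two)) - 16)
  expect_false(any(m2$mask[3:6, 3:6]))
  # interior holes are filled
  holed <- disk_image(size = 64, R = 20, fg = 100)$pixels
  holed[30:34, 30:34] <- 0
  mh <- segment_colony(image2d(holed, cal1(1)))
  expect_true(all(mh$mask[30:34, 30:34]))
})

test_that("base area scales with pixel size and is rotation invariant", {
  img <- disk_image(size = 80, R = 20, fg = 100, px_um = 0.5)
  mask <- segment_colony(img)
  expect_equal(base_area(mask), sum(mask$mask) * 0.25)
  # analytic circle area within 2% despite rasterisation
  big <- disk_image(size = 256, R = 100, fg = 100, px_um = 0.5)
  area <- base_area(segment_colony(big))
  expect_lt(abs(area / (pi * 50^2) - 1), 0.02)
  # 90 degree rotation
  rot <- image2d(t(big$pixels[nrow(big$pixels):1, ]), cal1(0.5))
  expect_equal(base_area(segment_colony(rot)), area)
  # whole frame (uniform bright block; an interior dark pixel gives
  # variance and is filled as a hole)
  m <- matrix(100, 32, 32); m[16, 16] <- 0
  wf <- segment_colony(image2d(m, cal1(2)))
  expect_equal(base_area(wf), 32 * 32 * 4)
})

test_that("centre estimation is the mask centroid and translation-equivariant", {
  img <- disk_image(size = 101, R = 30, cx = 51, cy = 51)
  ctr <- estimate_centre(segment_colony(img))
  expect_lt(abs(ctr[["x_px"]] - 51), 0.5)
  expect_lt(abs(ctr[["y_px"]] - 51), 0.5)
  sh <- disk_image(size = 101, R = 30, cx = 51 + 7, cy = 51 - 4)
  ctr2 <- estimate_centre(segment_colony(sh))
  expect_equal(ctr2[["x_px"]] - ctr[["x_px"]], 7, tolerance = 1e-8)
  expect_equal(ctr2[["y_px"]] - ctr[["y_px"]], -4, tolerance = 1e-8)
  # axis-aligned ellipse: centroid at the ellipse centre by symmetry
  xs <- matrix(seq_len(101), 101, 101, byrow = TRUE)
  ys <- matrix(seq_len(101), 101, 101)
  ell <- matrix(0, 101, 101)
  ell[((xs - 40) / 30)^2 + ((ys - 60) / 18)^2 <= 1] <- 100
  ce <- estimate_centre(segment_colony(image2d(ell, cal1(1))))
  expect_lt(abs(ce[["x_px"]] - 40), 0.5)
  expect_lt(abs(ce[["y_px"]] - 60), 0.5)
})

test_that("largest full-circumference radius follows mask geometry", {
  px_um <- 2
  img <- disk_image(size = 201, R = 80, cx = 101, cy = 101, px_um = px_um)
  mask <- segment_colony(img)
  ctr <- estimate_centre(mask)
  r <- max_full_circumference_radius(mask, ctr, n_angular = 1440)
  expect_lt(abs(r - 80 * px_um), 1.5 * px_um)
  # off-centre by d: largest full circle has radius R - d
  d <- 25
  img2 <- disk_image(size = 201, R = 80, cx = 101 + d, cy = 101,
                     px_um = px_um)
  mask2 <- segment_colony(img2)
  ctr2 <- c(x_px = 101, y_px = 101)  # probe from the frame centre
  r2 <- max_full_circumference_radius(mask2, ctr2, n_angular = 1440)
  expect_lt(abs(r2 - (80 - d) * px_um), 1.5 * px_um)
  # centre on the mask border: no full circle fits
  border_pt <- c(x_px = 101 - 80, y_px = 101)
  expect_equal(max_full_circumference_radius(mask, border_pt, 1440), 0)
  # never beyond the centroid-to-boundary maximum (here: the disk radius)
  expect_lte(r, (80 + 1) * px_um)
  # centre outside the mask errors
  expect_error(max_full_circumference_radius(mask, c(x_px = 3, y_px = 3)),
               "outside")
})

test_that("biofilm thickness is the distance between the two lowest z-profile minima", {
  cal <- calibration(1, z_step_um = 3)
  mk <- function(vals) zstack(lapply(vals, function(v) matrix(v, 16, 16)),
                              cal)
  # minima at slices 1 and 71 (0-based 0 and 70): 70 * 3 = 210 um
  inner <- 60 + 40 * sin(seq(0, pi, length.out = 69))
  prof <- c(10, inner, 12, 50, 60)  # second minimum at index 71
  expect_equal(biofilm_thickness(mk(prof), smooth = FALSE), 210)
  # monotone profile: no two minima
  expect_error(biofilm_thickness(mk(seq(10, 100, length.out = 20)),
                                 smooth = FALSE), "thickness undefined")
  # symmetric U: minima at both ends give the full stack depth
  u <- 10 + 90 * sin(seq(0, pi, length.out = 21))
  expect_equal(biofilm_thickness(mk(u), smooth = FALSE), 20 * 3)
  expect_equal(biofilm_thickness(mk(u), smooth = TRUE), 20 * 3)
  # z-step is required
  expect_error(biofilm_thickness(zstack(lapply(1:5, function(i)
    matrix(i, 16, 16)), cal1(1))), "z_step")
})
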