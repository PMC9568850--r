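test_that("generation is deterministic for a fixed seed", {
  spec <- synthetic_spec(image_size_px = 400, colony_radius_um = 220,
                         n_channels = 8, seed = 3)
  g1 <- synth_colony(spec)
  g2 <- synth_colony(spec)
  expect_identical(g1$image$pixels, g2$image$pixels)
  g3 <- synth_colony(synthetic_spec(image_size_px = 400,
                                    colony_radius_um = 220,
                                    n_channels = 8, seed = 4))
  expect_false(identical(g1$image$pixels, g3$image$pixels))
  # the generator restores the caller's RNG state
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(synth_colony(spec)); after <- runif(3)
  expect_identical(before, after)
})

test_that("spec validation enforces packing, positivity and fit", {
  expect_error(synthetic_spec(n_channels = 200), "overlap")
  expect_error(synthetic_spec(width_law = "linear", slope = -0.02),
               "positive")
  expect_error(synthetic_spec(image_size_px = 400, colony_radius_um = 900),
               "fit")
  expect_error(synthetic_spec(axis_ratio = 1.2))
})

test_that("plain dome colonies give accurate mean-threshold segmentation", {
  for (q in c(0.7, 1)) {
    g <- synth_colony(synthetic_spec(image_size_px = 640,
                                     colony_radius_um = 420,
                                     axis_ratio = q, n_channels = 0,
                                     seed = 5))
    area <- base_area(segment_colony(g$image))
    expect_lt(abs(area / g$truth$base_area_um2 - 1), 0.02)
    ctr <- estimate_centre(segment_colony(g$image))
    expect_lt(abs(ctr[["x_px"]] - g$truth$centre_px[["x_px"]]), 1)
    expect_lt(abs(ctr[["y_px"]] - g$truth$centre_px[["y_px"]]), 1)
  }
})

test_that("rendered channel cross-sections have the programmed FWHM", {
  # noise-free, blur-free constant-width colony: the measured angular FWHM
  # equals the programmed width within one angular sample equivalent
  spec <- synthetic_spec(image_size_px = 800, colony_radius_um = 500,
                         n_channels = 12, blur_sigma_px = 0, noise_sd = 0,
                         seed = 7)
  g <- synth_colony(spec)
  ctr <- estimate_centre(segment_colony(g$image))
  polar <- invert_image(to_polar(g$image, ctr, 3600, max_radius_px = 235))
  for (r in c(200, 300, 450)) {
    prof <- extract_profile(polar, r)
    pk <- detect_peaks(prof, min_distance_px = 9)
    expect_equal(length(pk), 12)
    w_px <- vapply(pk, function(p) peak_fwhm(prof, p), 0)
    w_um <- arc_length_um(w_px, prof$radius_um, 3600)
    one_px_um <- arc_length_um(1, prof$radius_um, 3600)
    expect_true(all(abs(w_um - 12) <= pmax(one_px_um, 0.35)))
  }
})

test_that("blur biases measured width upward, modestly for resolved channels", {
  widths <- vapply(c(0, 0.5, 1), function(bl) {
    g <- synth_colony(synthetic_spec(image_size_px = 800,
                                     pixel_size_um = 1,
                                     colony_radius_um = 350,
                                     n_channels = 10, blur_sigma_px = bl,
                                     noise_sd = 0, seed = 13))
    ctr <- estimate_centre(segment_colony(g$image))
    polar <- invert_image(to_polar(g$image, ctr, 3600, max_radius_px = 340))
    prof <- extract_profile(polar, 250)
    pk <- detect_peaks(prof, min_distance_px = 9)
    mean(arc_length_um(vapply(pk, function(p) peak_fwhm(prof, p), 0),
                       prof$radius_um, 3600))
  }, 0)
  # monotone increase with blur; < 15% bias at sigma = 1 px for a 12 um
  # (12 px) channel
  expect_true(all(diff(widths) > 0))
  expect_lt(widths[3] / 12 - 1, 0.15)
})

test_that("ground truth series evaluates the programmed law", {
  sp <- synthetic_spec(width_law = "exponential", w0_um = 8, rate = 0.001,
                       n_channels = 6, seed = 1)
  g <- synth_colony(sp)
  gt <- ground_truth_series(g$truth, c(200, 500))
  expect_equal(gt$true_width_um[1], 8 * exp(0.2))
  expect_equal(gt$true_width_um[1], 9.77, tolerance = 1e-3)
  # constant law: constant series; linear with slope 0 reduces to constant
  sc <- synthetic_spec(width_law = "constant", w0_um = 10, seed = 1)
  sl <- synthetic_spec(width_law = "linear", w0_um = 10, slope = 0, seed = 1)
  r <- seq(200, 800, 100)
  expect_equal(ground_truth_series(synth_colony(sc)$truth, r)$true_width_um,
               rep(10, length(r)))
  expect_equal(ground_truth_series(synth_colony(sl)$truth, r)$true_width_um,
               ground_truth_series(synth_colony(sc)$truth, r)$true_width_um)
})

test_that("meandering channels still carry the programmed local width", {
  g <- synth_colony(synthetic_spec(image_size_px = 800,
                                   colony_radius_um = 500,
                                   n_channels = 8, meander_amplitude = 0.06,
                                   blur_sigma_px = 0, noise_sd = 0,
                                   seed = 19))
  gs <- synth_colony(synthetic_spec(image_size_px = 800,
                                    colony_radius_um = 500,
                                    n_channels = 8, meander_amplitude = 0,
                                    blur_sigma_px = 0, noise_sd = 0,
                                    seed = 19))
  expect_false(identical(g$image$pixels, gs$image$pixels))
  ctr <- estimate_centre(segment_colony(g$image))
  polar <- invert_image(to_polar(g$image, ctr, 3600, max_radius_px = 235))
  prof <- extract_profile(polar, 300)
  pk <- detect_peaks(prof, min_distance_px = 9)
  w_um <- arc_length_um(vapply(pk, function(p) peak_fwhm(prof, p), 0),
                        prof$radius_um, 3600)
  # widths measured along the circumference stay within 10% of programmed
  expect_lt(abs(mean(w_um) / 12 - 1), 0.10)
})
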