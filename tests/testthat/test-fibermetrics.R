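test_that("scale calibration averages the per-measurement ratios", {
  # twenty identical reference measurements
  cal <- calibrate_scale(cbind(rep(100, 20), rep(1000, 20)))
  expect_equal(cal$um_per_px, 10)
  expect_equal(cal$sd, 0)
  expect_equal(cal$n_measurements, 20)
  # mixed measurements: mean of {10, 9.0909...} (direct arithmetic oracle)
  cal2 <- calibrate_scale(rbind(c(100, 1000), c(110, 1000)))
  expect_equal(cal2$um_per_px, mean(c(1000 / 100, 1000 / 110)))
  expect_equal(cal2$um_per_px, 9.54545, tolerance = 1e-6)
  # single measurement: ratio kept, sd reported 0 and flagged
  cal1 <- calibrate_scale(cbind(80, 1000))
  expect_equal(cal1$um_per_px, 12.5)
  expect_true(cal1$single)
  expect_equal(cal1$sd, 0)
  expect_error(calibrate_scale(cbind(0, 1000)), "positive")
})

test_that("point-pair measurement converts pixel pairs through the scale", {
  pairs <- rbind(c(0, 0, 0, 5), c(10, 10, 13, 14))
  rep <- measure_point_pairs(pairs, fixed_scale(10))
  expect_equal(rep$diameters, c(50, 50))
  expect_equal(rep$mean, 50)
})

test_that("fiber report uses the sample SD and the mean +/- SD format", {
  r <- fiber_report(c(40, 48, 56))
  expect_equal(r$mean, 48)
  expect_equal(r$sd, stats::sd(c(40, 48, 56)))
  expect_match(format_fiber_report(r), "48 ± 8 µm")
  expect_match(format_fiber_report(r), "mean ± S.D.")
  expect_true(fiber_report(numeric(0))$empty)
  expect_error(fiber_report(c(10, -1)))
})

test_that("synthetic micrographs are seed-reproducible with ground truth", {
  a <- synth_micrograph(n_fibers = 8, um_per_px = 10, seed = 7)
  b <- synth_micrograph(n_fibers = 8, um_per_px = 10, seed = 7)
  expect_identical(a$image, b$image)
  expect_identical(a$truth, b$truth)
  expect_equal(nrow(a$truth), 8)
  c1 <- synth_micrograph(n_fibers = 8, um_per_px = 10, seed = 8)
  expect_false(identical(a$image, c1$image))
  expect_error(synth_micrograph(n_fibers = 2, um_per_px = 10),
               "seed")
  expect_error(synth_micrograph(widths_um = 4, um_per_px = 10, seed = 1),
               "below 1 pixel")
})

test_that("noise-free single fiber is recovered exactly (closed loop)", {
  syn <- synth_micrograph(widths_um = 50, um_per_px = 10, noise = 0,
                          n_pores = c(2, 2), seed = 1)
  expect_equal(syn$truth$width_px, 5)
  r <- measure_fibers(syn$image, fixed_scale(10))
  expect_equal(r$n, 1)
  expect_equal(r$diameters, 50)   # 5 px times 10 um/px, exactly
})

test_that("blank and lattice-only images yield empty flagged reports", {
  expect_true(measure_fibers(matrix(0.1, 80, 80), fixed_scale(10))$empty)
  lattice <- synth_micrograph(widths_um = numeric(0), um_per_px = 10,
                              noise = 0, n_pores = c(2, 2), seed = 3)
  r <- measure_fibers(lattice$image, fixed_scale(10))
  expect_true(r$empty)
  expect_equal(nrow(attr(r, "fibers")), 0)
})

test_that("fibers drawn at 48 um measure within 5% at 10 um/px", {
  syn <- synth_micrograph(widths_um = rep(48, 10), um_per_px = 10,
                          noise = 0.02, seed = 2)
  r <- measure_fibers(syn$image, fixed_scale(10))
  expect_equal(r$n, 10)
  expect_lt(abs(r$mean - 48) / 48, 0.05)
})

test_that("measurement is invariant to a 90-degree image rotation", {
  syn <- synth_micrograph(n_fibers = 6, um_per_px = 10, noise = 0.02,
                          seed = 5)
  r0 <- measure_fibers(syn$image, fixed_scale(10))
  rot <- t(syn$image)[, rev(seq_len(nrow(syn$image)))]
  r90 <- measure_fibers(rot, fixed_scale(10))
  expect_equal(r90$n, r0$n)
  expect_equal(sort(r90$diameters), sort(r0$diameters), tolerance = 1e-6)
})

test_that("micrograph PNG round-trips through disk", {
  syn <- synth_micrograph(n_fibers = 3, um_per_px = 10, noise = 0, seed = 9)
  path <- withr::local_tempfile(fileext = ".png")
  write_micrograph(syn$image, path)
  img <- read_micrograph(path)
  expect_equal(dim(img), dim(syn$image))
  expect_lt(max(abs(img - syn$image)), 1 / 255)
  r_disk <- measure_fibers(path, fixed_scale(10))
  r_mem <- measure_fibers(syn$image, fixed_scale(10))
  expect_equal(r_disk$diameters, r_mem$diameters)
})

test_that("truncated-normal fiber population is recovered (closed loop)", {
  syn <- synth_micrograph(n_fibers = 50, width_mean = 48, width_sd = 12,
                          um_per_px = 5, n_pores = c(4, 4), noise = 0.02,
                          seed = 101)
  r <- measure_fibers(syn$image, fixed_scale(5))
  expect_equal(r$n, 50)
  # against rendered ground truth: pixel-exact per fiber
  expect_equal(sort(r$diameters), sort(syn$truth$width_um_rendered),
               tolerance = 1e-6)
  # against the generating distribution
  se <- 12 / sqrt(50)
  expect_lt(abs(r$mean - 48), 2 * se)
  expect_lt(abs(r$sd - 12) / 12, 0.25)
})
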