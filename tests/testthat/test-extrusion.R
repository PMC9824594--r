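test_that("stadium cross-section matches the numeric-integration oracle", {
  cases <- rbind(c(0.2, 0.2), c(0.4, 0.2), c(0.68, 0.2), c(1.0, 0.3))
  for (i in seq_len(nrow(cases))) {
    w <- cases[i, 1]; h <- cases[i, 2]
    expect_equal(cross_section_area(w, h), stadium_area_numeric(w, h),
                 tolerance = 1e-8)
  }
  # w = h degenerates to a circle of diameter h
  expect_equal(cross_section_area(0.2, 0.2), pi * 0.01)
  expect_error(cross_section_area(0.1, 0.2), "w must be >=")
})

test_that("extrusion length solves the volume balance in both conventions", {
  # oracle: E such that pi (d/2)^2 E = A * L, via uniroot
  A <- cross_section_area(0.4, 0.2)
  for (conv in c("nozzle", "filament")) {
    p <- extrusion_params(w = 0.4, h = 0.2, d_nozzle = 0.4,
                          d_filament = 1.75, f = 1,
                          e_denominator = conv)
    d <- if (conv == "nozzle") 0.4 else 1.75
    oracle <- stats::uniroot(function(E) pi * (d / 2)^2 * E - A * 20,
                             c(0, 1000), tol = 1e-12)$root
    expect_equal(extrusion_length(A, 20, p), oracle, tolerance = 1e-9)
  }
  # frozen oracle values
  p_noz <- extrusion_params(w = 0.4, h = 0.2)
  expect_equal(extrusion_length(0.0714159, 20, p_noz), 11.366180,
               tolerance = 1e-5)
  p_fil <- extrusion_params(w = 0.4, h = 0.2, e_denominator = "filament")
  expect_equal(extrusion_length(0.0714159, 20, p_fil), 0.593825,
               tolerance = 1e-5)
  # f = 0 extrudes nothing; E linear in f
  p0 <- extrusion_params(w = 0.4, h = 0.2, f = 0)
  expect_equal(extrusion_length(A, 123, p0), 0)
})

test_that("assign_extrusion accumulates E over extruding segments only", {
  tp <- data.frame(x = c(0, 0, 10, 20), y = c(0, 5, 5, 5),
                   z = 0.2, kind = c("travel", "travel", "extrude",
                                     "extrude"),
                   e = NA_real_, f = NA_real_)
  class(tp) <- c("toolpath", "data.frame")
  p <- extrusion_params(w = 0.4, h = 0.2)
  out <- assign_extrusion(tp, p)
  A <- cross_section_area(0.4, 0.2)
  expect_equal(max(out$e), extrusion_length(A, 20, p))
  expect_equal(out$e[1:2], c(0, 0))
  expect_false(is.unsorted(out$e))
  # all-travel path ends at E = 0
  tt <- tp; tt$kind <- "travel"
  expect_equal(max(assign_extrusion(tt, p)$e), 0)
  # halving f halves final E exactly
  p_half <- p; p_half$f <- 0.5
  expect_equal(max(assign_extrusion(tp, p_half)$e), max(out$e) / 2)
})

test_that("re-assignment without reset is refused", {
  tp <- assign_extrusion(build_toolpath(ref_spec(2)), extrusion_params())
  expect_error(assign_extrusion(tp, extrusion_params()), "reset")
  expect_silent(assign_extrusion(reset_extrusion(tp), extrusion_params()))
})

test_that("volume is conserved at f = 1 for randomized toolpaths", {
  set.seed(11)
  p <- extrusion_params(w = 0.45, h = 0.2, f = 1)
  A <- cross_section_area(p$w, p$h)
  for (i in 1:25) {
    tp <- assign_extrusion(random_toolpath(n_moves = 40), p)
    fa <- flow_account(tp, p)
    expect_equal(fa$V_out, sum(A * extrude_lengths_of(tp)))
    expect_lt(abs(fa$V_in - fa$V_out) / fa$V_out, 1e-9)
  }
})

test_that("effective strand width: fixed point, fiber regime, monotonicity", {
  p1 <- extrusion_params(w = 0.68, h = 0.2, f = 1)
  expect_equal(effective_strand_width(p1)$width, 0.68)
  expect_false(effective_strand_width(p1)$fiber_regime)

  # under-extrusion: oracle via uniroot on the area equation; when no
  # root with w_eff >= h exists the equivalent circular diameter applies
  p2 <- extrusion_params(w = 0.68, h = 0.2, f = 0.20)
  A_t <- 0.20 * cross_section_area(0.68, 0.2)
  expect_true(A_t < pi * 0.01)   # cannot fill the caps -> fiber regime
  r2 <- effective_strand_width(p2)
  expect_true(r2$fiber_regime)
  d_oracle <- stats::uniroot(function(d) pi * (d / 2)^2 - A_t,
                             c(1e-6, 1), tol = 1e-12)$root
  expect_equal(r2$width, d_oracle, tolerance = 1e-8)
  expect_equal(r2$width, 0.1801, tolerance = 1e-3)

  # strand regime root agrees with uniroot on the stadium equation
  p3 <- extrusion_params(w = 0.68, h = 0.2, f = 0.6)
  r3 <- effective_strand_width(p3)
  w_oracle <- stats::uniroot(
    function(w) (w - 0.2) * 0.2 + pi * 0.01 - 0.6 * cross_section_area(0.68, 0.2),
    c(0.2, 2), tol = 1e-12)$root
  expect_false(r3$fiber_regime)
  expect_equal(r3$width, w_oracle, tolerance = 1e-8)

  widths <- vapply(seq(0.05, 1.5, by = 0.05), function(f) {
    p <- extrusion_params(w = 0.68, h = 0.2, f = f)
    effective_strand_width(p)$width
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
  expect_error(effective_strand_width(extrusion_params(f = 0)), "f = 0")
})
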