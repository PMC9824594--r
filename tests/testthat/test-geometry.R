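test_that("rectilinear strand counts match the enumeration oracle", {
  # oracle: enumerate positions 0, d, 2d, ..., L when L/d divides evenly
  cases <- list(list(L = 20, d1 = 1.0, layer = 1, axis = "x"),
                list(L = 20, d1 = 2.5, layer = 1, axis = "x"),
                list(L = 10, d1 = 0.5, layer = 1, axis = "x"))
  for (cs in cases) {
    spec <- scaffold_spec(L = cs$L, d1 = cs$d1, d2 = 2.5, n_layers = 2)
    lp <- generate_rectilinear_layer(spec, cs$layer)
    xs <- unique(lp$vertices[, "x"])
    expect_equal(sort(xs), seq(0, cs$L, by = cs$d1))
    expect_length(xs, round(cs$L / cs$d1) + 1)
  }
  # even layer runs along X, spaced d2 in Y
  spec <- scaffold_spec(L = 20, d1 = 1.0, d2 = 2.5, n_layers = 2)
  lp2 <- generate_rectilinear_layer(spec, 2)
  expect_equal(sort(unique(lp2$vertices[, "y"])), seq(0, 20, by = 2.5))
  expect_length(unique(lp2$vertices[, "y"]), 9)
})

test_that("layer z equals layer_index times layer height", {
  spec <- scaffold_spec(L = 20, d1 = 1.0, h = 0.2, n_layers = 4)
  for (i in 1:4)
    expect_equal(generate_rectilinear_layer(spec, i)$z, i * 0.2)
  expect_error(generate_rectilinear_layer(spec, 5), "out of range")
  expect_error(generate_rectilinear_layer(spec, 0), "out of range")
})

test_that("extruded bounding box is exactly L x L, origin offset applied", {
  for (pat in c("rectilinear", "triangular")) {
    spec <- scaffold_spec(pattern = pat, L = 20, d1 = 2, d2 = 2,
                          n_layers = 2, origin = c(5, 7))
    for (i in 1:2) {
      lp <- switch(pat,
                   rectilinear = generate_rectilinear_layer(spec, i),
                   triangular = generate_triangular_layer(spec, i))
      v <- lp$vertices
      ex <- which(lp$segment_kinds == "extrude")
      pts <- rbind(v[ex, , drop = FALSE], v[ex + 1L, , drop = FALSE])
      expect_equal(range(pts[, "x"]), c(5, 25))
      expect_equal(range(pts[, "y"]), c(7, 27))
    }
  }
})

test_that("rectilinear extruded path length matches the closed form", {
  spec <- scaffold_spec(L = 20, d1 = 1.0, d2 = 2.5, n_layers = 2)
  for (i in 1:2) {
    lp <- generate_rectilinear_layer(spec, i)
    spacing <- if (i == 1) spec$d1 else spec$d2
    n <- round(spec$L / spacing) + 1
    seglen <- sqrt(rowSums(diff(lp$vertices)^2))
    expect_equal(sum(seglen[lp$segment_kinds == "extrude"]),
                 n * spec$L + (n - 1) * spacing)
  }
})

test_that("boustrophedon links can be travel moves instead", {
  spec <- scaffold_spec(L = 20, d1 = 2)
  lp <- generate_rectilinear_layer(spec, 1, links = "travel")
  expect_equal(sum(lp$segment_kinds == "travel"),
               round(spec$L / spec$d1))
  seglen <- sqrt(rowSums(diff(lp$vertices)^2))
  expect_equal(sum(seglen[lp$segment_kinds == "extrude"]),
               (round(spec$L / spec$d1) + 1) * spec$L)
})

test_that("triangular extruded segments all carry slope 2*d2/d1", {
  spec <- scaffold_spec(pattern = "triangular", L = 20, d1 = 2, d2 = 2)
  lp <- generate_triangular_layer(spec, 1)
  dv <- diff(lp$vertices)
  ex <- lp$segment_kinds == "extrude"
  slopes <- abs(dv[ex, "y"] / dv[ex, "x"])
  expect_equal(unname(slopes), rep(2 * 2 / 2, sum(ex)))
  # degenerate d1 = L: one triangle per row
  spec1 <- scaffold_spec(pattern = "triangular", L = 20, d1 = 20, d2 = 20)
  lp1 <- generate_triangular_layer(spec1, 1)
  expect_equal(nrow(lp1$vertices), 3)
  expect_equal(lp1$vertices[, "x"], c(0, 10, 20))
})

test_that("stacking layers yields the arithmetic Z progression", {
  spec <- ref_spec(n_layers = 4)
  tp <- stack_layers(spec, generate_layers(spec))
  expect_equal(sort(unique(tp$z)), c(0.2, 0.4, 0.6, 0.8))
  tp1 <- build_toolpath(ref_spec(n_layers = 1))
  expect_equal(max(tp1$z), 0.2)
  expect_error(stack_layers(spec, list()), "empty")
  # per-layer extruded XY extent for the reference model
  for (z in unique(tp$z)) {
    sub <- tp[tp$z == z, ]
    expect_equal(diff(range(sub$x)), 20)
    expect_equal(diff(range(sub$y)), 20)
  }
})

test_that("pattern generation is deterministic", {
  spec <- scaffold_spec(pattern = "triangular", L = 17, d1 = 1.7, d2 = 2.1,
                        n_layers = 3)
  expect_identical(build_toolpath(spec), build_toolpath(spec))
  spec2 <- ref_spec()
  expect_identical(generate_rectilinear_layer(spec2, 1),
                   generate_rectilinear_layer(spec2, 1))
})

test_that("scaffold_spec rejects invalid geometry", {
  expect_error(scaffold_spec(L = -1))
  expect_error(scaffold_spec(d1 = 25, L = 20))
  expect_error(scaffold_spec(n_layers = 0))
  expect_error(scaffold_spec(h = 0))
})
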