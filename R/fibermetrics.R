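#' Calibrate the image scale from ruler measurements
#'
#' Mirrors the micrometric-ruler calibration workflow: a set of reference
#' measurements of known physical lengths is taken on a photo of a
#' calibration ruler acquired at the same working distance as the
#' specimen photos, and the scale is the average of the per-measurement
#' ratios (the reference protocol averages n = 20 of them).
#'
#' @param measurements two-column matrix or data frame: pixel length and
#'   known length in micrometres, one row per reference measurement.
#' @return An object of class \code{calibration_scale}: \code{um_per_px}
#'   (mean of known/pixels over measurements), \code{sd} (SD of the
#'   ratios; 0 with \code{single = TRUE} when only one measurement is
#'   given) and \code{n_measurements}.
#' @examples
#' calibrate_scale(cbind(px = rep(100, 20), um = rep(1000, 20)))
#' @export
calibrate_scale <- function(measurements) {
  m <- as.matrix(measurements)
  stopifnot(ncol(m) == 2, nrow(m) >= 1)
  if (any(m[, 1] <= 0)) stop("pixel lengths must be positive")
  ratios <- m[, 2] / m[, 1]
  single <- nrow(m) == 1L
  structure(list(um_per_px = mean(ratios),
                 sd = if (single) 0 else stats::sd(ratios),
                 n_measurements = nrow(m), single = single),
            class = "calibration_scale")
}

#' Fixed calibration scale
#'
#' Shortcut when the scale is already known (e.g. from instrument
#' metadata).
#'
#' @param um_per_px micrometres per pixel.
#' @return A \code{calibration_scale} with one implied measurement.
#' @export
fixed_scale <- function(um_per_px) {
  stopifnot(um_per_px > 0)
  structure(list(um_per_px = um_per_px, sd = 0, n_measurements = 1L,
                 single = TRUE), class = "calibration_scale")
}

#' @export
print.calibration_scale <- function(x, ...) {
  cat(sprintf("Calibration: %.4f um/px (n = %d, sd %.4f)%s\n",
              x$um_per_px, x$n_measurements, x$sd,
              if (x$single) " [single measurement]" else ""))
  invisible(x)
}

#' Fiber diameter report
#'
#' @param diameters per-fiber diameters, micrometres (all > 0).
#' @return An object of class \code{fiber_report}: the diameters with
#'   their mean and sample standard deviation (n - 1 denominator). An
#'   empty vector yields an empty, flagged report.
#' @export
fiber_report <- function(diameters = numeric(0)) {
  stopifnot(all(diameters > 0))
  n <- length(diameters)
  structure(list(diameters = as.numeric(diameters),
                 mean = if (n) mean(diameters) else NA_real_,
                 sd = if (n > 1) stats::sd(diameters) else
                   if (n == 1) 0 else NA_real_,
                 n = n, empty = n == 0L),
            class = "fiber_report")
}

#' Format a fiber report as "mean +/- S.D."
#'
#' @param report a \code{fiber_report}.
#' @param digits decimals shown.
#' @return Character scalar, e.g. \code{"48 ± 12 µm (mean
#'   ± S.D., n = 50)"}.
#' @export
format_fiber_report <- function(report, digits = 0) {
  if (report$empty) return("no fibers measured")
  sprintf("%.*f ± %.*f µm (mean ± S.D., n = %d)",
          digits, report$mean, digits, report$sd, report$n)
}

#' @export
print.fiber_report <- function(x, ...) {
  cat("Fiber diameters:", format_fiber_report(x, digits = 1), "\n")
  invisible(x)
}

#' Manual-equivalent point-pair measurement
#'
#' Computes fiber diameters from caliper-style point pairs placed on the
#' two edges of a fiber (the manual measurement workflow of image-analysis
#' tools), converted to micrometres with the calibration scale.
#'
#' @param pairs matrix or data frame with columns x1, y1, x2, y2 in pixel
#'   coordinates, one row per measured fiber.
#' @param scale a \code{calibration_scale}.
#' @return A [fiber_report()].
#' @export
measure_point_pairs <- function(pairs, scale) {
  p <- as.matrix(pairs)
  stopifnot(ncol(p) == 4)
  d_px <- sqrt((p[, 3] - p[, 1])^2 + (p[, 4] - p[, 2])^2)
  fiber_report(d_px * scale$um_per_px)
}

as_gray_matrix <- function(image) {
  if (inherits(image, "Image")) image <- EBImage::imageData(image)
  if (length(dim(image)) == 3) image <- apply(image, c(1, 2), mean)
  storage.mode(image) <- "double"
  image
}

#' Read a grayscale micrograph
#'
#' PNG rasters are read with \pkg{png}; anything else is delegated to
#' [EBImage::readImage()]. Multi-channel images are averaged to gray.
#'
#' @param path image file path.
#' @return Numeric matrix in [0, 1], rows = image rows.
#' @export
read_micrograph <- function(path) {
  img <- if (grepl("\\.png$", path, ignore.case = TRUE))
    png::readPNG(path)
  else
    EBImage::imageData(EBImage::readImage(path))
  if (length(dim(img)) == 3) img <- apply(img, c(1, 2), mean)
  img
}

#' Write a grayscale micrograph as PNG
#'
#' @param image numeric matrix in [0, 1].
#' @param path output path (.png).
#' @return \code{path}, invisibly.
#' @export
write_micrograph <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

odd_brush <- function(r) EBImage::makeBrush(2L * max(1L, r) + 1L, "disc")

inside <- function(m, r, c) r >= 1 && r <= nrow(m) && c >= 1 && c <= ncol(m)

mask_at <- function(mask, r, c) {
  ri <- round(r); ci <- round(c)
  inside(mask, ri, ci) && mask[ri, ci] > 0
}

# Chord length through (r0, c0) along unit direction u = (dr, dc), by
# coarse march + bisection refinement of each boundary crossing.
chord_length <- function(mask, r0, c0, u, t_max) {
  half <- function(sgn) {
    t_lo <- 0; t_hi <- NA_real_
    t <- 0.5
    while (t <= t_max) {
      if (mask_at(mask, r0 + sgn * t * u[1], c0 + sgn * t * u[2])) t_lo <- t
      else { t_hi <- t; break }
      t <- t + 0.5
    }
    if (is.na(t_hi)) return(t_lo + 0.5)   # ran off the mask/image edge
    for (i in 1:25) {
      tm <- (t_lo + t_hi) / 2
      if (mask_at(mask, r0 + sgn * tm * u[1], c0 + sgn * tm * u[2]))
        t_lo <- tm else t_hi <- tm
    }
    (t_lo + t_hi) / 2
  }
  half(1) + half(-1)
}

#' Measure fiber diameters on a calibrated micrograph
#'
#' Automated transect procedure for thin bright structures: the image is
#' thresholded (Otsu by default), cleaned with a small morphological
#' opening, and macro-strands are removed by a width-based morphological
#' separation — an opening with a disc of the fiber/strand cutoff radius
#' keeps only structures wider than the cutoff, and everything within a
#' small dilation of them is discarded. The remaining thin components are
#' measured individually: the component orientation is taken from the
#' principal axis of its pixel coordinates, and fiber width is the chord
#' length perpendicular to that axis, sampled at several transect points
#' along the component (median over transects); sub-pixel edges are
#' located by bisection, so a straight noise-free band of k pixels
#' measures exactly k. Components shorter than twice their width (blobs,
#' junction debris) are discarded.
#'
#' @param image numeric matrix in [0, 1] (bright structures on dark
#'   background), an \code{EBImage::Image}, or a file path.
#' @param scale a \code{calibration_scale} (or a number, micrometres per
#'   pixel).
#' @param cutoff_um structures wider than this are treated as
#'   macro-strands, not fibers (default 150 um: below the 300-700 um
#'   strand scale, above the tens-of-um fiber scale).
#' @param threshold fixed threshold in [0, 1]; default NULL uses Otsu.
#' @param transects number of transect sample points per fiber.
#' @param min_area_px components smaller than this many pixels are noise.
#' @return A [fiber_report()]; the per-fiber table (component id, width in
#'   px and um, length, orientation angle) is attached as attribute
#'   \code{"fibers"}.
#' @examples
#' syn <- synth_micrograph(widths_um = rep(50, 4), um_per_px = 5, seed = 1)
#' measure_fibers(syn$image, fixed_scale(5))
#' @export
measure_fibers <- function(image, scale, cutoff_um = 150, threshold = NULL,
                           transects = 15L, min_area_px = 9L) {
  if (is.character(image)) image <- read_micrograph(image)
  img <- as_gray_matrix(image)
  if (is.numeric(scale) && !inherits(scale, "calibration_scale"))
    scale <- fixed_scale(scale)
  upp <- scale$um_per_px
  if (is.null(threshold))
    threshold <- EBImage::otsu(EBImage::Image(img), range = c(0, 1))
  mask <- (img > threshold) * 1
  empty <- function() {
    rep0 <- fiber_report(numeric(0))
    attr(rep0, "fibers") <- data.frame(id = integer(0),
                                       width_px = numeric(0),
                                       width_um = numeric(0),
                                       length_px = numeric(0),
                                       angle = numeric(0))
    rep0
  }
  if (sum(mask) == 0) return(empty())
  mask <- as_gray_matrix(EBImage::opening(mask, EBImage::makeBrush(3, "disc")))
  cutoff_px <- cutoff_um / upp
  strands <- as_gray_matrix(EBImage::opening(mask, odd_brush(floor(cutoff_px / 2))))
  fiber_mask <- mask * (1 - as_gray_matrix(EBImage::dilate(strands, odd_brush(2L))))
  if (sum(fiber_mask) == 0) return(empty())
  lab <- as_gray_matrix(EBImage::bwlabel(fiber_mask))
  ids <- seq_len(max(lab))
  out <- list()
  for (k in ids) {
    pix <- which(lab == k, arr.ind = TRUE)
    if (nrow(pix) < min_area_px) next
    ctr <- colMeans(pix)
    cv <- stats::cov(pix)
    ev <- eigen(cv, symmetric = TRUE)
    v <- ev$vectors[, 1]          # principal (length) axis, (row, col)
    u <- c(-v[2], v[1])           # perpendicular: transect direction
    proj <- as.numeric((pix[, 1] - ctr[1]) * v[1] + (pix[, 2] - ctr[2]) * v[2])
    length_px <- diff(range(proj)) + 1
    qs <- stats::quantile(proj, probs = seq(0.1, 0.9,
                                            length.out = transects))
    widths <- vapply(qs, function(q) {
      i <- which.min(abs(proj - q))
      chord_length(fiber_mask, pix[i, 1], pix[i, 2], u,
                   t_max = cutoff_px + 2)
    }, numeric(1))
    w_px <- stats::median(widths)
    if (w_px * upp >= cutoff_um) next
    if (length_px < 2 * w_px) next
    out[[length(out) + 1L]] <-
      data.frame(id = k, width_px = w_px, width_um = w_px * upp,
                 length_px = length_px,
                 angle = atan2(v[1], v[2]))
  }
  if (!length(out)) return(empty())
  fibers <- do.call(rbind, out)
  rep <- fiber_report(fibers$width_um)
  attr(rep, "fibers") <- fibers
  rep
}

draw_band <- function(img, rows, cols, value) {
  rows <- rows[rows >= 1 & rows <= nrow(img)]
  cols <- cols[cols >= 1 & cols <= ncol(img)]
  img[rows, cols] <- value
  img
}

#' Generate a synthetic scaffold micrograph with known fiber widths
#'
#' Renders a top-view strand lattice (bright macro-strands of the given
#' width, spaced \code{d1} along X and \code{d2} along Y) with thin
#' fibers of known width spanning the macropores, plus additive Gaussian
#' noise — a stand-in for digital-microscope images of printed scaffolds,
#' with per-fiber ground truth. Fibers are axis-aligned (the regime the
#' measurement stage is specified against), attach to the bounding
#' strands, and are placed on non-overlapping lanes inside the pores.
#' Widths are rendered at integer pixel counts; the ground-truth table
#' records both the requested and the rendered width.
#'
#' @param widths_um explicit fiber widths, micrometres; if NULL,
#'   \code{n_fibers} widths are drawn from Normal(\code{width_mean},
#'   \code{width_sd}) truncated to the renderable range.
#' @param n_fibers number of fibers when sampling widths.
#' @param width_mean,width_sd sampling distribution of fiber widths, um.
#' @param um_per_px image scale, micrometres per pixel.
#' @param d1,d2 strand spacings, mm (defaults match the reference
#'   scaffold's 1.0 mm; d2 default 1.0 mm keeps pores square).
#' @param n_pores pores along X and Y (length-2 integer).
#' @param strand_width_um macro-strand width, um.
#' @param noise additive Gaussian noise SD (image units, [0, 1] scale).
#' @param fg,bg foreground (polymer) and background intensities.
#' @param seed RNG seed (required for reproducibility; the caller's RNG
#'   state is left untouched).
#' @return List with \code{image} (matrix in [0, 1]) and \code{truth}
#'   (data frame: id, orientation, requested \code{width_um}, rendered
#'   \code{width_px} and \code{width_um_rendered}, pore indices).
#' @examples
#' syn <- synth_micrograph(n_fibers = 5, seed = 42)
#' syn$truth$width_um_rendered
#' @export
synth_micrograph <- function(widths_um = NULL, n_fibers = 10,
                             width_mean = 48, width_sd = 12,
                             um_per_px = 5, d1 = 1.0, d2 = 1.0,
                             n_pores = c(3L, 3L), strand_width_um = 300,
                             noise = 0.02, fg = 0.9, bg = 0.1, seed) {
  if (missing(seed)) stop("a seed is required for a reproducible raster")
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(seed)
  s <- max(1L, round(strand_width_um / um_per_px))
  p1 <- round(d1 * 1000 / um_per_px)
  p2 <- round(d2 * 1000 / um_per_px)
  nx <- as.integer(n_pores[1]); ny <- as.integer(n_pores[2])
  stopifnot(p1 > s + 10, p2 > s + 10)
  width_px <- nx * p1 + s
  height_px <- ny * p2 + s
  img <- matrix(bg, nrow = height_px, ncol = width_px)
  for (k in 0:nx) img <- draw_band(img, seq_len(height_px),
                                   k * p1 + seq_len(s), fg)
  for (k in 0:ny) img <- draw_band(img, k * p2 + seq_len(s),
                                   seq_len(width_px), fg)
  if (is.null(widths_um)) {
    widths_um <- numeric(0)
    while (length(widths_um) < n_fibers) {
      w <- stats::rnorm(n_fibers, width_mean, width_sd)
      widths_um <- c(widths_um, w[w / um_per_px >= 0.5])
    }
    widths_um <- widths_um[seq_len(n_fibers)]
  }
  wpx <- round(widths_um / um_per_px)
  if (any(wpx < 1))
    stop("fiber width below 1 pixel at this scale; use a finer um_per_px")
  truth <- NULL
  lanes <- list()        # used center positions per pore
  pore_orient <- list()  # fibers within a pore are parallel (no crossings)
  for (i in seq_along(widths_um)) {
    placed <- FALSE
    for (try in 1:200) {
      px_i <- sample.int(nx, 1); py_i <- sample.int(ny, 1)
      key <- paste(px_i, py_i)
      if (is.null(pore_orient[[key]]))
        pore_orient[[key]] <- sample(c("h", "v"), 1)
      orient <- pore_orient[[key]]
      x0 <- (px_i - 1L) * p1 + s + 1L; x1 <- px_i * p1        # pore cols
      y0 <- (py_i - 1L) * p2 + s + 1L; y1 <- py_i * p2        # pore rows
      wp <- wpx[i]
      if (orient == "h") {
        lo <- y0 + wp; hi <- y1 - wp
      } else {
        lo <- x0 + wp; hi <- x1 - wp
      }
      if (hi <= lo) next
      ctr <- sample(lo:hi, 1)
      used <- lanes[[key]]
      if (!is.null(used) && any(abs(used$ctr - ctr) <
                                (used$w + wp) / 2 + 4)) next
      if (orient == "h") {
        rows <- ctr - (wp - 1L) %/% 2L + 0:(wp - 1L)
        img <- draw_band(img, rows, (x0 - 1L):(x1 + 1L), fg)
      } else {
        cols <- ctr - (wp - 1L) %/% 2L + 0:(wp - 1L)
        img <- draw_band(img, (y0 - 1L):(y1 + 1L), cols, fg)
      }
      lanes[[key]] <- rbind(used, data.frame(ctr = ctr, w = wp))
      truth <- rbind(truth, data.frame(
        id = i, orientation = orient, width_um = widths_um[i],
        width_px = wp, width_um_rendered = wp * um_per_px,
        pore_x = px_i, pore_y = py_i))
      placed <- TRUE
      break
    }
    if (!placed)
      stop("could not place all fibers; reduce n_fibers or enlarge n_pores")
  }
  if (noise > 0)
    img <- img + matrix(stats::rnorm(length(img), 0, noise), nrow(img))
  img <- pmin(pmax(img, 0), 1)
  list(image = img, truth = truth)
}
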