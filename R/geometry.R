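#' Scaffold specification
#'
#' Describes a square lattice scaffold: side length, within-layer strand
#' spacings along X (\code{d1}) and Y (\code{d2}), layer height and layer
#' count. Units are millimetres throughout.
#'
#' @param pattern lay-down pattern, \code{"rectilinear"} (parallel strands,
#'   0/90 degree alternation between layers) or \code{"triangular"}
#'   (triangle-wave strands).
#' @param L scaffold side length, mm.
#' @param d1 strand spacing measured along the X axis, mm.
#' @param d2 strand spacing measured along the Y axis, mm.
#' @param h layer height, mm (first layer sits at z = h).
#' @param n_layers number of layers (positive integer).
#' @param origin XY offset of the scaffold's lower-left corner on the bed, mm.
#'
#' @return An object of class \code{scaffold_spec}.
#' @examples
#' scaffold_spec(L = 20, d1 = 1.0, d2 = 2.5, h = 0.2, n_layers = 4)
#' @export
scaffold_spec <- function(pattern = c("rectilinear", "triangular"),
                          L = 20.0, d1 = 1.0, d2 = 2.5, h = 0.20,
                          n_layers = 4L, origin = c(0, 0)) {
  pattern <- match.arg(pattern)
  stopifnot(L > 0, d1 > 0, d2 > 0, h > 0, n_layers >= 1,
            d1 <= L, d2 <= L, length(origin) == 2)
  structure(list(pattern = pattern, L = L, d1 = d1, d2 = d2, h = h,
                 n_layers = as.integer(n_layers),
                 origin = as.numeric(origin)),
            class = "scaffold_spec")
}

#' @export
print.scaffold_spec <- function(x, ...) {
  cat(sprintf("Scaffold spec: %s, L = %g mm, d1 = %g mm, d2 = %g mm\n",
              x$pattern, x$L, x$d1, x$d2))
  cat(sprintf("  %d layer(s) of height %g mm, origin (%g, %g)\n",
              x$n_layers, x$h, x$origin[1], x$origin[2]))
  invisible(x)
}

new_layer_path <- function(z, vertices, segment_kinds) {
  vertices <- matrix(as.numeric(vertices), ncol = 2,
                     dimnames = list(NULL, c("x", "y")))
  segment_kinds <- as.character(segment_kinds)
  stopifnot(z > 0, nrow(vertices) >= 2,
            length(segment_kinds) == nrow(vertices) - 1L,
            all(segment_kinds %in% c("extrude", "travel")))
  d <- rowSums(abs(diff(vertices)))
  if (any(d == 0))
    stop("consecutive duplicate vertices are not allowed in a layer path")
  structure(list(z = z, vertices = vertices, segment_kinds = segment_kinds),
            class = "layer_path")
}

# Strand positions across [0, L]: round(L/spacing)+1 of them, endpoints pinned
# to 0 and L so the extruded bounding box is exactly L even when L/spacing is
# not an integer.
strand_positions <- function(L, spacing) {
  n <- round(L / spacing)
  seq(0, L, length.out = n + 1L)
}

check_layer_index <- function(spec, layer_index) {
  if (layer_index < 1L || layer_index > spec$n_layers)
    stop(sprintf("layer_index %d out of range [1, %d]",
                 layer_index, spec$n_layers))
}

#' Generate one rectilinear scaffold layer
#'
#' Odd layers contain parallel strands running along Y, spaced \code{d1}
#' apart in X; even layers run along X spaced \code{d2} in Y (0/90 degree
#' alternation). Strands are connected in boustrophedon (serpentine) order;
#' the short links at the layer boundary are extruded by default so the
#' whole layer is one continuous deposited path.
#'
#' @param spec a [scaffold_spec()].
#' @param layer_index 1-based layer number (determines Z and direction).
#' @param direction override the parity-based strand direction: \code{"y"}
#'   (strands along Y) or \code{"x"}.
#' @param links \code{"extrude"} (default) or \code{"travel"} for the
#'   boundary links between consecutive strands.
#' @return A \code{layer_path}: z height, ordered XY vertices and per-segment
#'   kinds.
#' @examples
#' lp <- generate_rectilinear_layer(scaffold_spec(L = 20, d1 = 1), 1)
#' sum(lp$segment_kinds == "extrude")
#' @export
generate_rectilinear_layer <- function(spec, layer_index,
                                       direction = NULL,
                                       links = c("extrude", "travel")) {
  links <- match.arg(links)
  check_layer_index(spec, layer_index)
  if (is.null(direction))
    direction <- if (layer_index %% 2L == 1L) "y" else "x"
  direction <- match.arg(direction, c("x", "y"))
  spacing <- if (direction == "y") spec$d1 else spec$d2
  pos <- strand_positions(spec$L, spacing)
  n <- length(pos)
  ends <- c(0, spec$L)
  verts <- matrix(NA_real_, nrow = 2L * n, ncol = 2)
  for (k in seq_len(n)) {
    e <- if (k %% 2L == 1L) ends else rev(ends)
    if (direction == "y") {
      verts[2L * k - 1L, ] <- c(pos[k], e[1])
      verts[2L * k, ]      <- c(pos[k], e[2])
    } else {
      verts[2L * k - 1L, ] <- c(e[1], pos[k])
      verts[2L * k, ]      <- c(e[2], pos[k])
    }
  }
  verts <- sweep(verts, 2, spec$origin, "+")
  kinds <- rep(c("extrude", links), length.out = 2L * n - 1L)
  new_layer_path(layer_index * spec$h, verts, kinds)
}

#' Generate one triangular (triangle-wave) scaffold layer
#'
#' Each strand is a zigzag running along X with apex spacing \code{d1} (one
#' full period per \code{d1}) and amplitude spanning \code{d2} along Y; rows
#' are stacked \code{d2} apart to tile the L-by-L square and visited in
#' boustrophedon order. Inter-row links are travel moves by default so every
#' extruded segment carries the pattern's characteristic slope
#' \code{2*d2/d1}.
#'
#' @inheritParams generate_rectilinear_layer
#' @param links \code{"travel"} (default) or \code{"extrude"} for the
#'   inter-row links.
#' @return A \code{layer_path}.
#' @export
generate_triangular_layer <- function(spec, layer_index,
                                      links = c("travel", "extrude")) {
  links <- match.arg(links)
  check_layer_index(spec, layer_index)
  n_half <- 2L * max(1L, round(spec$L / spec$d1))  # half-periods per row
  xs <- seq(0, spec$L, length.out = n_half + 1L)
  n_rows <- max(1L, round(spec$L / spec$d2))
  y0s <- (seq_len(n_rows) - 1L) * (spec$L - spec$d2) /
    if (n_rows > 1L) (n_rows - 1L) else 1L
  verts <- NULL
  kinds <- character(0)
  for (r in seq_len(n_rows)) {
    ys <- y0s[r] + spec$d2 * (seq_along(xs) %% 2L)  # valley, peak, valley, ...
    row <- cbind(xs, ys)
    if (r %% 2L == 0L) row <- row[rev(seq_len(nrow(row))), , drop = FALSE]
    if (is.null(verts)) {
      verts <- row
      kinds <- rep("extrude", nrow(row) - 1L)
    } else {
      verts <- rbind(verts, row)
      kinds <- c(kinds, links, rep("extrude", nrow(row) - 1L))
    }
  }
  verts <- sweep(verts, 2, spec$origin, "+")
  new_layer_path(layer_index * spec$h, verts, kinds)
}

#' Generate all layers of a scaffold
#'
#' @param spec a [scaffold_spec()].
#' @return List of \code{layer_path}, one per layer, in print order.
#' @export
generate_layers <- function(spec) {
  gen <- switch(spec$pattern,
                rectilinear = generate_rectilinear_layer,
                triangular = generate_triangular_layer)
  lapply(seq_len(spec$n_layers), function(i) gen(spec, i))
}

#' Stack layer paths into a toolpath
#'
#' Concatenates per-layer paths into one continuous motion sequence. Each
#' layer starts with a travel move to its first vertex at the new Z; Z then
#' stays constant within the layer. The extruder axis E is not assigned here
#' (see [assign_extrusion()]).
#'
#' @param spec a [scaffold_spec()] (supplies the expected layer heights).
#' @param layers list of \code{layer_path}, sorted by layer index.
#' @return A \code{toolpath}: data frame with columns \code{x}, \code{y},
#'   \code{z} (move targets, mm), \code{kind} (\code{"travel"} or
#'   \code{"extrude"}), \code{e} (cumulative extruder position, NA until
#'   assigned) and \code{f} (feed rate, NA until emission). Motion starts
#'   from the machine origin (0, 0, 0).
#' @examples
#' spec <- scaffold_spec(L = 20, d1 = 1, d2 = 2.5, h = 0.2, n_layers = 4)
#' tp <- stack_layers(spec, generate_layers(spec))
#' unique(tp$z)
#' @export
stack_layers <- function(spec, layers) {
  if (length(layers) == 0) stop("empty layer list")
  rows <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    lp <- layers[[i]]
    v <- lp$vertices
    rows[[i]] <- data.frame(
      x = v[, 1], y = v[, 2], z = lp$z,
      kind = c("travel", lp$segment_kinds),
      stringsAsFactors = FALSE)
  }
  tp <- do.call(rbind, rows)
  tp$e <- NA_real_
  tp$f <- NA_real_
  rownames(tp) <- NULL
  class(tp) <- c("toolpath", "data.frame")
  tp
}

#' Build the full toolpath for a scaffold specification
#'
#' Convenience wrapper: generate the layers and stack them.
#'
#' @inheritParams stack_layers
#' @return A \code{toolpath} (E unassigned).
#' @export
build_toolpath <- function(spec) stack_layers(spec, generate_layers(spec))

#' Per-segment Euclidean lengths of a toolpath
#'
#' Segment i is the move into row i, starting from the previous row (the
#' machine origin for row 1).
#'
#' @param toolpath a \code{toolpath}.
#' @return Numeric vector of lengths, mm, one per row.
#' @export
segment_lengths <- function(toolpath) {
  p <- rbind(c(0, 0, 0), as.matrix(toolpath[, c("x", "y", "z")]))
  sqrt(rowSums(diff(p)^2))
}

#' @export
print.toolpath <- function(x, ...) {
  len <- segment_lengths(x)
  ex <- x$kind == "extrude"
  cat(sprintf("Toolpath: %d moves over %d layer(s), z in [%g, %g] mm\n",
              nrow(x), length(unique(x$z)), min(x$z), max(x$z)))
  cat(sprintf("  extruded path %.1f mm, travel %.1f mm, E %s\n",
              sum(len[ex]), sum(len[!ex]),
              if (all(is.na(x$e))) "unassigned"
              else sprintf("final %.5f mm", max(x$e, na.rm = TRUE))))
  invisible(x)
}

#' Plot a toolpath's XY trajectories
#'
#' Draws extruded segments as solid lines (one panel per layer is obtained
#' by subsetting beforehand); travel moves are dashed.
#'
#' @param x a \code{toolpath}.
#' @param layer optional layer Z value to restrict to.
#' @param ... passed to [graphics::plot()].
#' @export
plot.toolpath <- function(x, layer = NULL, ...) {
  if (!is.null(layer)) x <- x[x$z == layer, , drop = FALSE]
  graphics::plot(x$x, x$y, type = "n", asp = 1, xlab = "x (mm)",
                 ylab = "y (mm)", ...)
  p <- cbind(x$x, x$y)
  for (i in 2:nrow(p))
    graphics::segments(p[i - 1, 1], p[i - 1, 2], p[i, 1], p[i, 2],
                       lty = if (x$kind[i] == "extrude") 1 else 2,
                       col = if (x$kind[i] == "extrude") "firebrick" else "grey50")
  invisible(x)
}
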