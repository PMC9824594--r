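#' Load a packaged experiment matrix
#'
#' The sensitivity-analysis experiment matrices are shipped verbatim as
#' plain tabular data: extrusion-multiplier series (F), printing-speed
#' series (V), cooling / fan-PWM series (T), surface-pass series (P, passes
#' on the last layer without raising Z) and the diagonal-pass experiment
#' (D). Rows whose first layer failed to adhere (V8B, T12B, T13B) are
#' flagged \code{failed} and carry a note; internally inconsistent PWM
#' percentage annotations in the T series are preserved verbatim in the
#' notes, with the numeric PWM column authoritative.
#'
#' For the pass series (P, D), the row's \code{f} and \code{speed} are the
#' PASS parameters; the base scaffold is 3 layers at f = 1.00, 600 mm/min,
#' fan PWM 255.
#'
#' @param name matrix name: \code{"F"}, \code{"V"}, \code{"T"}, \code{"P"}
#'   or \code{"D"}.
#' @return Data frame with columns \code{id}, \code{f}, \code{speed}
#'   (mm/min), \code{fan_pwm}, \code{failed}, \code{n_base_layers},
#'   \code{pass_pattern}, \code{pass_f}, \code{pass_speed}, \code{notes}.
#' @examples
#' load_matrix("F")$f  # 1.00 0.60 0.45 0.30
#' @export
load_matrix <- function(name = c("F", "V", "T", "P", "D")) {
  name <- match.arg(name)
  path <- system.file("extdata", sprintf("experiments_%s.tsv", name),
                      package = "microscaff", mustWork = TRUE)
  m <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(id = "character",
                                        notes = "character"))
  m$notes[is.na(m$notes)] <- ""
  stopifnot(!anyDuplicated(m$id))
  m
}

#' Surface-pass specification
#'
#' Describes low-flow filament passes deposited on the last printed layer
#' without raising the Z axis: the nozzle re-traverses the scaffold at the
#' top layer's height with a strongly reduced extrusion multiplier and a
#' high speed, drawing fibers across the macropores.
#'
#' @param n_base_layers number of normally printed layers below the passes.
#' @param pass_f extrusion multiplier of the passes (>= 0).
#' @param pass_speed pass feed rate, mm/min.
#' @param pass_pattern \code{"parallel"} (strands along Y spaced d1) or
#'   \code{"diagonal"} (45-degree strands across the footprint).
#' @return An object of class \code{surface_pass_spec}.
#' @export
surface_pass_spec <- function(n_base_layers = 3L, pass_f = 0.20,
                              pass_speed = 5000,
                              pass_pattern = c("diagonal", "parallel")) {
  pass_pattern <- match.arg(pass_pattern)
  stopifnot(n_base_layers >= 1, pass_f >= 0, pass_speed > 0)
  structure(list(n_base_layers = as.integer(n_base_layers),
                 pass_f = pass_f, pass_speed = pass_speed,
                 pass_pattern = pass_pattern),
            class = "surface_pass_spec")
}

diagonal_pass_vertices <- function(L, spacing, origin) {
  offs <- seq(-L, L, by = spacing * sqrt(2))   # perpendicular spacing = spacing
  offs <- offs[abs(offs) < L - 1e-9]
  segs <- lapply(offs, function(cc) {
    if (cc >= 0) rbind(c(0, cc), c(L - cc, L))
    else rbind(c(-cc, 0), c(L, L + cc))
  })
  verts <- NULL; kinds <- character(0)
  for (i in seq_along(segs)) {
    s <- segs[[i]]
    if (i %% 2L == 0L) s <- s[2:1, , drop = FALSE]
    if (is.null(verts)) { verts <- s; kinds <- "extrude" }
    else { verts <- rbind(verts, s); kinds <- c(kinds, "travel", "extrude") }
  }
  list(vertices = sweep(verts, 2, origin, "+"), kinds = kinds)
}

#' Append no-Z-raise surface passes to a toolpath
#'
#' Appends pass strands at the toolpath's current maximum Z (the defining
#' property: max Z is unchanged), with E advanced using \code{pass_f} and
#' the pass feed rate on every pass move. Parallel passes run along Y
#' spaced \code{d1} in boustrophedon order with extruded links; diagonal
#' passes run at 45 degrees across the footprint with perpendicular
#' spacing \code{d1} and travel links between strokes.
#'
#' @param toolpath a \code{toolpath} with E assigned, at least
#'   \code{pass$n_base_layers} layers.
#' @param pass a [surface_pass_spec()].
#' @param params the base [extrusion_params()]; the pass flow uses
#'   \code{pass$pass_f} in place of \code{params$f}.
#' @param scaffold the [scaffold_spec()] giving the footprint (L, d1,
#'   origin) the passes cover.
#' @return The extended toolpath; pass rows carry \code{f = pass_speed}.
#' @examples
#' spec <- scaffold_spec(n_layers = 3)
#' tp <- assign_extrusion(build_toolpath(spec), extrusion_params())
#' tp2 <- add_surface_passes(tp, surface_pass_spec(), extrusion_params(),
#'                           spec)
#' max(tp2$z) == max(tp$z)
#' @export
add_surface_passes <- function(toolpath, pass, params, scaffold) {
  if (is.null(toolpath) || nrow(toolpath) == 0)
    stop("cannot add surface passes to an empty toolpath")
  if (any(is.na(toolpath$e)))
    stop("toolpath must have E assigned before adding passes")
  n_layers <- length(unique(toolpath$z))
  if (n_layers < pass$n_base_layers)
    stop(sprintf("toolpath has %d layer(s), fewer than n_base_layers = %d",
                 n_layers, pass$n_base_layers))
  z_top <- max(toolpath$z)
  if (pass$pass_pattern == "parallel") {
    lp <- generate_rectilinear_layer(scaffold, 1L, direction = "y")
    verts <- lp$vertices
    kinds <- lp$segment_kinds
  } else {
    dg <- diagonal_pass_vertices(scaffold$L, scaffold$d1, scaffold$origin)
    verts <- dg$vertices
    kinds <- dg$kinds
  }
  pass_params <- params
  pass_params$f <- pass$pass_f
  A <- cross_section_area(params$w, params$h)
  new <- data.frame(x = verts[, 1], y = verts[, 2], z = z_top,
                    kind = c("travel", kinds), e = NA_real_,
                    f = pass$pass_speed, stringsAsFactors = FALSE)
  prev <- as.numeric(toolpath[nrow(toolpath), c("x", "y", "z")])
  p <- rbind(prev, as.matrix(new[, c("x", "y", "z")]))
  len <- sqrt(rowSums(diff(p)^2))
  dE <- ifelse(new$kind == "extrude",
               extrusion_length(A, len, pass_params), 0)
  new$e <- max(toolpath$e) + cumsum(dE)
  out <- rbind(as.data.frame(toolpath), new)
  rownames(out) <- NULL
  class(out) <- c("toolpath", "data.frame")
  attr(out, "extrusion_params") <- attr(toolpath, "extrusion_params")
  out
}

#' Build the toolpath and settings for one experiment row
#'
#' Plain rows print the full scaffold with the row's multiplier, speed and
#' fan; pass rows (P, D series) print \code{n_base_layers} base layers at
#' f = 1.00, 600 mm/min, fan 255, then append the row's surface passes.
#' First-layer speed is 600 mm/min throughout.
#'
#' @param row one row of a matrix from [load_matrix()].
#' @param base_spec the [scaffold_spec()] to print.
#' @param params base [extrusion_params()] (its \code{f} is overridden per
#'   row).
#' @return List with \code{toolpath} and \code{settings}.
#' @export
build_experiment <- function(row, base_spec, params = extrusion_params()) {
  is_pass <- !is.na(row$n_base_layers)
  if (is_pass) {
    spec <- base_spec
    spec$n_layers <- as.integer(row$n_base_layers)
    base_params <- params; base_params$f <- 1.0
    tp <- assign_extrusion(build_toolpath(spec), base_params)
    ps <- surface_pass_spec(row$n_base_layers, row$pass_f, row$pass_speed,
                            row$pass_pattern)
    tp <- add_surface_passes(tp, ps, params, spec)
    settings <- print_settings(speed = 600, first_layer_speed = 600,
                               fan_pwm = row$fan_pwm, f = 1.0)
  } else {
    row_params <- params; row_params$f <- row$f
    tp <- assign_extrusion(build_toolpath(base_spec), row_params)
    settings <- print_settings(speed = row$speed, first_layer_speed = 600,
                               fan_pwm = row$fan_pwm, f = row$f)
  }
  list(toolpath = tp, settings = settings)
}

#' Generate G-code files for experiment matrices
#'
#' Emits one deterministic G-code file per non-failed experiment row,
#' named \code{<id>.gcode}, plus a \code{manifest.tsv} listing the settings
#' and total E per file. Re-running produces byte-identical output.
#'
#' @param matrices matrix names to include (default all five).
#' @param base_spec the [scaffold_spec()] printed in every experiment
#'   (default: the reference 20 mm rectilinear model, d1 = 1.0 mm,
#'   d2 = 2.5 mm, h = 0.2 mm, 4 layers).
#' @param profile a [printer_profile()].
#' @param params base [extrusion_params()].
#' @param outdir output directory (created if missing).
#' @param include_failed also emit the flagged failed rows.
#' @return The manifest data frame, invisibly written to
#'   \code{manifest.tsv}: id, file, f, speed, fan_pwm, pattern, E_total.
#' @export
run_sweep <- function(matrices = c("F", "V", "T", "P", "D"),
                      base_spec = scaffold_spec(),
                      profile = printer_profile(),
                      params = extrusion_params(),
                      outdir = ".", include_failed = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  rows <- do.call(rbind, lapply(matrices, load_matrix))
  if (!include_failed) rows <- rows[!rows$failed, , drop = FALSE]
  manifest <- NULL
  for (i in seq_len(nrow(rows))) {
    row <- rows[i, ]
    ex <- build_experiment(row, base_spec, params)
    doc <- emit_gcode(ex$toolpath, ex$settings, profile)
    file <- file.path(outdir, paste0(row$id, ".gcode"))
    write_gcode(doc, file)
    manifest <- rbind(manifest, data.frame(
      id = row$id, file = basename(file), f = row$f, speed = row$speed,
      fan_pwm = row$fan_pwm,
      pattern = if (!is.na(row$n_base_layers)) row$pass_pattern else
        base_spec$pattern,
      E_total = round(max(ex$toolpath$e), 5),
      stringsAsFactors = FALSE))
  }
  if (is.null(manifest))
    manifest <- data.frame(id = character(0), file = character(0),
                           f = numeric(0), speed = numeric(0),
                           fan_pwm = integer(0), pattern = character(0),
                           E_total = numeric(0))
  utils::write.table(manifest, file.path(outdir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest
}
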