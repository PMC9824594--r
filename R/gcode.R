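#' Print settings
#'
#' Per-print machine settings applied at G-code emission. Speeds are in
#' mm/min (the unit carried by the G-code F word); the part-cooling fan is
#' commanded as a PWM duty value 0-255 (0-100%).
#'
#' @param speed printing speed, mm/min.
#' @param first_layer_speed first-layer printing speed, mm/min (kept low for
#'   bed adhesion).
#' @param extruder_temp nozzle set temperature, degrees C.
#' @param bed_temp heated-bed set temperature, degrees C.
#' @param fan_pwm part-cooling fan PWM duty, integer 0-255.
#' @param fan_from_layer layer index at whose start the fan command is
#'   emitted (default 1: constant fan state for the whole print).
#' @param f extrusion multiplier carried alongside the settings.
#' @return An object of class \code{print_settings}.
#' @examples
#' print_settings()  # reference settings: 600 mm/min, 150/40 degC, fan off
#' @export
print_settings <- function(speed = 600, first_layer_speed = 600,
                           extruder_temp = 150, bed_temp = 40,
                           fan_pwm = 0L, fan_from_layer = 1L, f = 1.0) {
  stopifnot(speed > 0, first_layer_speed > 0, extruder_temp >= 0,
            bed_temp >= 0, fan_pwm >= 0, fan_pwm <= 255,
            fan_from_layer >= 1, f >= 0)
  structure(list(speed = speed, first_layer_speed = first_layer_speed,
                 extruder_temp = extruder_temp, bed_temp = bed_temp,
                 fan_pwm = as.integer(fan_pwm),
                 fan_from_layer = as.integer(fan_from_layer), f = f),
            class = "print_settings")
}

#' @export
print.print_settings <- function(x, ...) {
  cat(sprintf(
    "Print settings: %g mm/min (%s mm/s), first layer %g mm/min, f = %g\n",
    x$speed, speed_display(x$speed), x$first_layer_speed, x$f))
  cat(sprintf("  nozzle %g degC, bed %g degC, fan PWM %d from layer %d\n",
              x$extruder_temp, x$bed_temp, x$fan_pwm, x$fan_from_layer))
  invisible(x)
}

#' Feed rate in mm/s for display
#'
#' Converts an F word (mm/min) to mm/s rounded to one decimal, the dual
#' notation used in reports ("600 mm/min (10.0 mm/s)").
#'
#' @param F feed rate, mm/min.
#' @return Speed in mm/s, rounded to 1 decimal.
#' @examples
#' speed_display(600)   # 10.0
#' speed_display(5000)  # 83.3
#' @export
speed_display <- function(F) {
  stopifnot(all(F >= 0))
  round(F / 60, 1)
}

fmt_xyz <- function(v) sprintf("%.3f", v + 0)   # + 0 avoids "-0.000"
fmt_e <- function(v) sprintf("%.5f", v + 0)

new_gcode_document <- function(preamble, motion, postamble)
  structure(list(preamble = preamble, motion = motion,
                 postamble = postamble),
            class = "gcode_document")

#' Emit a G-code document from a toolpath
#'
#' Produces a RepRap-flavour G-code subset: the preamble sets the bed and
#' nozzle temperatures (set-then-wait), homes the axes (G28) and selects
#' absolute positioning (G90) with absolute E (M82). Motion lines are G1
#' moves with coordinates fixed to 3 decimals, E to 5 decimals and integer
#' F in mm/min; Z and F words appear only when their value changes, E only
#' on extruding moves. The fan command (M106) is emitted at the start of
#' layer \code{fan_from_layer} when \code{fan_pwm > 0}. Layer-1 moves use
#' \code{first_layer_speed}, later layers \code{speed}; a toolpath whose
#' \code{f} column is fully assigned (e.g. one recovered by
#' [parse_gcode()]) keeps its own per-move feed rates instead.
#'
#' @param toolpath a \code{toolpath} with E assigned (may have zero rows).
#' @param settings a [print_settings()].
#' @param profile a [printer_profile()] (carried for auditing; the emitted
#'   dialect does not depend on it).
#' @return A \code{gcode_document} (preamble / motion / postamble lines);
#'   retrieve the text with [gcode_lines()] or write it with
#'   [write_gcode()].
#' @examples
#' spec <- scaffold_spec(n_layers = 2)
#' tp <- assign_extrusion(build_toolpath(spec), extrusion_params())
#' doc <- emit_gcode(tp, print_settings())
#' head(doc$motion)
#' @export
emit_gcode <- function(toolpath, settings, profile = printer_profile()) {
  preamble <- c(sprintf("M140 S%g", settings$bed_temp),
                sprintf("M104 S%g", settings$extruder_temp),
                sprintf("M190 S%g", settings$bed_temp),
                sprintf("M109 S%g", settings$extruder_temp),
                "G28", "G90", "M82")
  postamble <- c("M107", "M104 S0", "M140 S0", "M84")
  if (is.null(toolpath) || nrow(toolpath) == 0)
    return(new_gcode_document(preamble, character(0), postamble))
  if (any(is.na(toolpath$e)))
    stop("toolpath must have E assigned before emission")

  zs <- unique(toolpath$z)
  layer_of <- match(toolpath$z, zs)
  feeds <- toolpath$f
  na_f <- is.na(feeds)
  feeds[na_f] <- ifelse(layer_of[na_f] == 1L, settings$first_layer_speed,
                        settings$speed)
  motion <- character(0)
  prev_z <- NA_real_
  prev_f <- NA_real_
  for (i in seq_len(nrow(toolpath))) {
    if (settings$fan_pwm > 0 && layer_of[i] == settings$fan_from_layer &&
        (i == 1L || layer_of[i - 1L] < settings$fan_from_layer))
      motion <- c(motion, sprintf("M106 S%d", settings$fan_pwm))
    words <- c("G1",
               paste0("X", fmt_xyz(toolpath$x[i])),
               paste0("Y", fmt_xyz(toolpath$y[i])))
    if (is.na(prev_z) || toolpath$z[i] != prev_z)
      words <- c(words, paste0("Z", fmt_xyz(toolpath$z[i])))
    if (toolpath$kind[i] == "extrude")
      words <- c(words, paste0("E", fmt_e(toolpath$e[i])))
    if (is.na(prev_f) || feeds[i] != prev_f)
      words <- c(words, paste0("F", sprintf("%d", round(feeds[i]))))
    motion <- c(motion, paste(words, collapse = " "))
    prev_z <- toolpath$z[i]
    prev_f <- feeds[i]
  }
  new_gcode_document(preamble, motion, postamble)
}

#' Lines of a G-code document
#'
#' @param doc a \code{gcode_document}.
#' @return Character vector of G-code lines.
#' @export
gcode_lines <- function(doc)
  c(doc$preamble, doc$motion, doc$postamble)

#' @export
as.character.gcode_document <- function(x, ...) gcode_lines(x)

#' @export
print.gcode_document <- function(x, ...) {
  cat(sprintf("G-code document: %d preamble, %d motion, %d postamble lines\n",
              length(x$preamble), length(x$motion), length(x$postamble)))
  invisible(x)
}

#' Write a G-code document to a file
#'
#' @param doc a \code{gcode_document}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_gcode <- function(doc, path) {
  writeLines(gcode_lines(doc), path)
  invisible(path)
}

#' Rebuild print settings from a parsed document
#'
#' Fills the fields a G-code document does not determine (or leaves NA)
#' from a base [print_settings()], so a parsed document can be re-emitted.
#'
#' @param parsed result of [parse_gcode()].
#' @param base settings supplying defaults for undetermined fields.
#' @return A [print_settings()].
#' @export
settings_from_parse <- function(parsed, base = print_settings()) {
  s <- parsed$settings
  s$fan_pwm <- if (is.na(s$fan_pwm)) 0L else s$fan_pwm
  s$fan_from_layer <- if (is.na(s$fan_from_layer)) 1L else s$fan_from_layer
  for (k in names(s)) if (is.na(s[[k]])) s[[k]] <- base[[k]]
  print_settings(speed = s$speed, first_layer_speed = s$first_layer_speed,
                 extruder_temp = s$extruder_temp, bed_temp = s$bed_temp,
                 fan_pwm = s$fan_pwm, fan_from_layer = s$fan_from_layer,
                 f = base$f)
}

gcode_words <- function(line, lineno) {
  toks <- strsplit(trimws(line), "[ \t]+")[[1]]
  letters <- substr(toks[-1], 1, 1)
  if (anyDuplicated(letters))
    stop(sprintf("line %d: duplicate %s word: '%s'", lineno,
                 letters[duplicated(letters)][1], line))
  vals <- suppressWarnings(as.numeric(substring(toks[-1], 2)))
  names(vals) <- letters
  list(cmd = toks[1], vals = vals)
}

#' Parse G-code text back into a toolpath
#'
#' Inverse of [emit_gcode()] for the dialect this package emits (a subset
#' of standard RepRap-flavour G-code). Recovers per-move XYZ/E/F with
#' carry-forward of unspecified words, the first nozzle and bed temperature
#' targets, and the fan PWM with the layer at which it was switched on.
#' A move is classified as extruding when it carries an E word. Unknown
#' commands are preserved as opaque lines. \code{parse_gcode(emit_gcode(tp,
#' s))} reproduces \code{tp} vertex-for-vertex, with E within its 5-decimal
#' quantization, and re-emitting the parsed toolpath reproduces the
#' document byte-for-byte.
#'
#' @param text character vector of lines, a single string with newlines, or
#'   a file path ending in \code{.gcode}.
#' @return List with components \code{toolpath} (with \code{e} and \code{f}
#'   filled), \code{settings} (partial [print_settings()] fields; NA where
#'   the document does not determine them), and \code{opaque} (unrecognised
#'   lines, verbatim).
#' @export
parse_gcode <- function(text) {
  if (length(text) == 1 && grepl("\\.gcode$", text) && file.exists(text))
    text <- readLines(text)
  if (length(text) == 1 && grepl("\n", text))
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  ext_temp <- NA_real_; bed_temp <- NA_real_
  fan_pwm <- NA_integer_; fan_from_layer <- NA_integer_
  x <- y <- z <- 0; e <- 0; f <- NA_real_
  rows <- list(); opaque <- character(0)
  zs_seen <- numeric(0)
  for (ln in seq_along(text)) {
    line <- trimws(text[ln])
    if (line == "" || startsWith(line, ";")) { opaque <- c(opaque, text[ln]); next }
    w <- gcode_words(line, ln)
    v <- w$vals
    if (w$cmd == "G1") {
      if ("X" %in% names(v)) x <- v[["X"]]
      if ("Y" %in% names(v)) y <- v[["Y"]]
      if ("Z" %in% names(v)) z <- v[["Z"]]
      if ("F" %in% names(v)) f <- v[["F"]]
      kind <- "travel"
      if ("E" %in% names(v)) { e <- v[["E"]]; kind <- "extrude" }
      rows[[length(rows) + 1L]] <-
        data.frame(x = x, y = y, z = z, kind = kind, e = e, f = f,
                   stringsAsFactors = FALSE)
      if (!(z %in% zs_seen)) zs_seen <- c(zs_seen, z)
    } else if (w$cmd %in% c("M104", "M109")) {
      if (is.na(ext_temp)) ext_temp <- v[["S"]]
    } else if (w$cmd %in% c("M140", "M190")) {
      if (is.na(bed_temp)) bed_temp <- v[["S"]]
    } else if (w$cmd == "M106") {
      if (is.na(fan_pwm)) {
        fan_pwm <- as.integer(v[["S"]])
        fan_from_layer <- length(zs_seen) + 1L
      }
    } else if (w$cmd %in% c("M107", "G28", "G90", "M82", "M84")) {
      # dialect bookkeeping commands; no state to recover
    } else {
      opaque <- c(opaque, text[ln])
    }
  }
  tp <- if (length(rows)) do.call(rbind, rows) else
    data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
               kind = character(0), e = numeric(0), f = numeric(0),
               stringsAsFactors = FALSE)
  rownames(tp) <- NULL
  class(tp) <- c("toolpath", "data.frame")
  if (nrow(tp) > 0 && is.unsorted(tp$e))
    stop("E words are not non-decreasing: not an absolute-E document")
  layer_of <- match(tp$z, unique(tp$z))
  first_speed <- if (any(layer_of == 1L)) tp$f[layer_of == 1L][1] else NA_real_
  later <- tp$f[layer_of > 1L]
  list(toolpath = tp,
       settings = list(extruder_temp = ext_temp, bed_temp = bed_temp,
                       fan_pwm = fan_pwm, fan_from_layer = fan_from_layer,
                       first_layer_speed = first_speed,
                       speed = if (length(later)) later[1] else NA_real_),
       opaque = opaque)
}
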