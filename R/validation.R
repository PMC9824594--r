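#' Printer profile
#'
#' Machine characteristics of the target cartesian FDM printer. Defaults
#' are the Artillery Genius class of machine used as the reference
#' platform: 0.40 mm nozzle, 1.75 mm filament, 150 / 250 mm/s maximum
#' print / travel speeds, 0.05 / 0.05 / 0.10 mm XYZ resolution.
#'
#' @param d_nozzle nozzle diameter, mm.
#' @param d_filament filament diameter, mm.
#' @param max_print_speed maximum printing speed, mm/s.
#' @param max_travel_speed maximum travel speed, mm/s.
#' @param xyz_resolution positioning resolution, mm, length-3 (X, Y, Z).
#' @return An object of class \code{printer_profile}.
#' @export
printer_profile <- function(d_nozzle = 0.40, d_filament = 1.75,
                            max_print_speed = 150, max_travel_speed = 250,
                            xyz_resolution = c(0.05, 0.05, 0.10)) {
  stopifnot(d_nozzle > 0, d_filament > 0, max_print_speed > 0,
            max_travel_speed > 0, all(xyz_resolution > 0),
            length(xyz_resolution) == 3)
  structure(list(d_nozzle = d_nozzle, d_filament = d_filament,
                 max_print_speed = max_print_speed,
                 max_travel_speed = max_travel_speed,
                 xyz_resolution = as.numeric(xyz_resolution)),
            class = "printer_profile")
}

finding <- function(rule, severity, measured, limit, message)
  data.frame(rule = rule, severity = severity, measured = measured,
             limit = limit, message = message, stringsAsFactors = FALSE)

new_validation_report <- function(findings) {
  if (is.null(findings))
    findings <- finding(character(0), character(0), numeric(0),
                        numeric(0), character(0))
  structure(list(findings = findings), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  if (nrow(x$findings) == 0) {
    cat("Validation: all printability rules pass\n")
  } else {
    cat(sprintf("Validation: %d finding(s)\n", nrow(x$findings)))
    for (i in seq_len(nrow(x$findings)))
      with(x$findings[i, ], cat(sprintf(
        "  [%s] %s: %s (measured %.4g, limit %.4g)\n",
        toupper(severity), rule, message, measured, limit)))
  }
  invisible(x)
}

#' Does a validation report pass?
#'
#' @param report a \code{validation_report}.
#' @param errors_only count only error-severity findings.
#' @return TRUE when no (error) findings are present.
#' @export
validation_passed <- function(report, errors_only = FALSE) {
  f <- report$findings
  if (errors_only) f <- f[f$severity == "error", , drop = FALSE]
  nrow(f) == 0
}

#' Validate settings against printability rules
#'
#' Applies the printability rules for PCL scaffold printing on a standard
#' FDM machine:
#' \describe{
#'   \item{R1 (error)}{layer height at most 80\% of the nozzle diameter
#'     (0.32 mm for a 0.40 mm nozzle).}
#'   \item{R2 (warning)}{extrusion width within 1.05-1.7 times the nozzle
#'     diameter.}
#'   \item{R3 (warning)}{printing speed above 100 mm/s risks machine
#'     instability.}
#'   \item{R4 (warning)}{first-layer speed above 25 mm/s risks poor bed
#'     adhesion.}
#'   \item{R5 (error)}{fan PWM within 0-255.}
#'   \item{R6 (warning)}{nozzle temperature within the material window
#'     (130-170 degC for PCL) and bed within 30-45 degC.}
#' }
#' Severities are a package convention: R1/R5 violations produce
#' physically meaningless output, the rest degrade quality.
#'
#' @param profile a [printer_profile()].
#' @param spec a [scaffold_spec()].
#' @param settings a [print_settings()].
#' @param params an [extrusion_params()].
#' @param material_window nozzle temperature window, degC (default PCL).
#' @param bed_window bed temperature window, degC (default PCL).
#' @return A \code{validation_report}; empty findings means every rule
#'   passes.
#' @examples
#' validate_print(printer_profile(), scaffold_spec(), print_settings(),
#'                extrusion_params())
#' @export
validate_print <- function(profile, spec, settings, params,
                           material_window = c(130, 170),
                           bed_window = c(30, 45)) {
  fs <- NULL
  r1_lim <- 0.8 * profile$d_nozzle
  if (spec$h > r1_lim)
    fs <- rbind(fs, finding("R1", "error", spec$h, r1_lim,
                            "layer height exceeds 80% of nozzle diameter"))
  r2 <- c(1.05, 1.7) * profile$d_nozzle
  if (params$w < r2[1] || params$w > r2[2])
    fs <- rbind(fs, finding("R2", "warning", params$w,
                            if (params$w < r2[1]) r2[1] else r2[2],
                            "extrusion width outside 1.05-1.7x nozzle diameter"))
  if (settings$speed / 60 > 100)
    fs <- rbind(fs, finding("R3", "warning", settings$speed / 60, 100,
                            "printing speed above 100 mm/s may cause instability"))
  if (settings$first_layer_speed / 60 > 25)
    fs <- rbind(fs, finding("R4", "warning",
                            settings$first_layer_speed / 60, 25,
                            "first-layer speed above 25 mm/s risks adhesion problems"))
  if (settings$fan_pwm < 0 || settings$fan_pwm > 255)
    fs <- rbind(fs, finding("R5", "error", settings$fan_pwm, 255,
                            "fan PWM outside 0-255"))
  if (settings$extruder_temp < material_window[1] ||
      settings$extruder_temp > material_window[2])
    fs <- rbind(fs, finding("R6", "warning", settings$extruder_temp,
                            if (settings$extruder_temp < material_window[1])
                              material_window[1] else material_window[2],
                            "extruder temperature outside material window"))
  if (settings$bed_temp < bed_window[1] || settings$bed_temp > bed_window[2])
    fs <- rbind(fs, finding("R6", "warning", settings$bed_temp,
                            if (settings$bed_temp < bed_window[1])
                              bed_window[1] else bed_window[2],
                            "bed temperature outside material window"))
  new_validation_report(fs)
}

#' Rule limits implied by a printer profile
#'
#' @param profile a [printer_profile()].
#' @return List with \code{max_layer_height} (mm) and \code{width_window}
#'   (mm, length 2): the R1 and R2 thresholds.
#' @export
rule_limits <- function(profile)
  list(max_layer_height = 0.8 * profile$d_nozzle,
       width_window = c(1.05, 1.7) * profile$d_nozzle)

#' Audit a G-code document's flow
#'
#' Inverse check of the extrusion model: parses the document, reconstructs
#' the per-segment volumetric flow from the E increments, and reports the
#' flow account plus the effective strand width regime of each extruding
#' segment (fiber regime when the flow cannot fill the layer-height
#' stadium; see [effective_strand_width()]). Also re-applies the rule set
#' that is checkable from the document alone (R3/R5; R1 via the Z steps).
#'
#' @param doc a \code{gcode_document}, G-code lines, or a file path.
#' @param profile a [printer_profile()].
#' @param params the nominal [extrusion_params()] the document was
#'   generated with (supplies w, h and the E-denominator convention).
#' @return List with \code{report} (a \code{validation_report}),
#'   \code{account} (a \code{flow_account}) and \code{segments} (data
#'   frame: length, dE, implied multiplier, effective width, regime per
#'   extruding segment).
#' @export
audit_gcode <- function(doc, profile = printer_profile(),
                        params = extrusion_params()) {
  if (inherits(doc, "gcode_document")) doc <- gcode_lines(doc)
  parsed <- parse_gcode(doc)
  tp <- parsed$toolpath
  A <- cross_section_area(params$w, params$h)
  d <- e_diameter(params)
  fs <- NULL
  if (nrow(tp) == 0) {
    account <- structure(list(V_in = 0, V_out = 0, E_total = 0),
                         class = "flow_account")
    segments <- data.frame(length = numeric(0), dE = numeric(0),
                           f_implied = numeric(0), width = numeric(0),
                           regime = character(0))
    return(list(report = new_validation_report(fs), account = account,
                segments = segments))
  }
  len <- segment_lengths(tp)
  dE <- diff(c(0, tp$e))
  ex <- which(tp$kind == "extrude" & len > 0)
  f_implied <- (dE[ex] * pi * d^2 / 4) / (A * len[ex])
  seg_regime <- character(length(ex))
  seg_width <- numeric(length(ex))
  for (j in seq_along(ex)) {
    pj <- params; pj$f <- f_implied[j]
    if (pj$f <= 0) { seg_width[j] <- 0; seg_regime[j] <- "fiber"; next }
    esw <- effective_strand_width(pj)
    seg_width[j] <- esw$width
    seg_regime[j] <- esw$regime
  }
  E_total <- max(tp$e)
  account <- structure(list(V_in = pi * (d / 2)^2 * E_total,
                            V_out = sum(A * len[tp$kind == "extrude"]),
                            E_total = E_total),
                       class = "flow_account")
  speeds <- tp$f / 60
  if (any(speeds > 100, na.rm = TRUE))
    fs <- rbind(fs, finding("R3", "warning", max(speeds, na.rm = TRUE), 100,
                            "printing speed above 100 mm/s may cause instability"))
  if (!is.na(parsed$settings$fan_pwm) &&
      (parsed$settings$fan_pwm < 0 || parsed$settings$fan_pwm > 255))
    fs <- rbind(fs, finding("R5", "error", parsed$settings$fan_pwm, 255,
                            "fan PWM outside 0-255"))
  dz <- diff(sort(unique(tp$z)))
  if (length(dz) && max(dz) > 0.8 * profile$d_nozzle + 1e-9)
    fs <- rbind(fs, finding("R1", "error", max(dz), 0.8 * profile$d_nozzle,
                            "layer step exceeds 80% of nozzle diameter"))
  list(report = new_validation_report(fs), account = account,
       segments = data.frame(length = len[ex], dE = dE[ex],
                             f_implied = f_implied, width = seg_width,
                             regime = seg_regime, stringsAsFactors = FALSE))
}
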