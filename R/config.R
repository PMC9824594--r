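#' Read a scaffold build configuration
#'
#' Reads a flat YAML configuration (units: mm, mm/min, degrees C) and
#' builds the four configuration objects a print run needs. Recognised
#' keys, all optional, are the constructor arguments of [scaffold_spec()]
#' (\code{pattern}, \code{L}, \code{d1}, \code{d2}, \code{h},
#' \code{n_layers}, \code{origin}), [print_settings()] (\code{speed},
#' \code{first_layer_speed}, \code{extruder_temp}, \code{bed_temp},
#' \code{fan_pwm}, \code{fan_from_layer}), [extrusion_params()]
#' (\code{w}, \code{f}, \code{e_denominator}) and [printer_profile()]
#' (\code{d_nozzle}, \code{d_filament}, \code{max_print_speed},
#' \code{max_travel_speed}, \code{xyz_resolution}); unspecified keys take
#' the reference defaults. \code{h} and \code{d_nozzle}/\code{d_filament}
#' are shared between the objects that use them.
#'
#' @param path YAML file path.
#' @return List with \code{spec}, \code{settings}, \code{params},
#'   \code{profile}.
#' @export
read_build_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  pick <- function(fun, extra = list()) {
    keys <- intersect(names(cfg), names(formals(fun)))
    do.call(fun, c(cfg[keys], extra[setdiff(names(extra), keys)]))
  }
  profile <- pick(printer_profile)
  spec <- pick(scaffold_spec)
  params <- pick(extrusion_params,
                 extra = list(h = spec$h, d_nozzle = profile$d_nozzle,
                              d_filament = profile$d_filament))
  settings <- pick(print_settings,
                   extra = list(f = if (!is.null(cfg$f)) cfg$f else 1.0))
  list(spec = spec, settings = settings, params = params,
       profile = profile)
}

#' Build a scaffold G-code file from a configuration
#'
#' End-to-end wrapper: read the configuration, generate the toolpath,
#' assign E, validate, and emit G-code.
#'
#' @param config path to a YAML configuration (see [read_build_config()])
#'   or the list it returns.
#' @param output output \code{.gcode} path, or NULL to return the
#'   document without writing.
#' @return List with \code{doc} (the \code{gcode_document}),
#'   \code{toolpath}, \code{report} (the [validate_print()] report) and
#'   \code{account} (the [flow_account()]).
#' @export
build_scaffold_gcode <- function(config, output = NULL) {
  cfg <- if (is.character(config)) read_build_config(config) else config
  cfg$params$f <- cfg$settings$f
  report <- validate_print(cfg$profile, cfg$spec, cfg$settings, cfg$params)
  tp <- assign_extrusion(build_toolpath(cfg$spec), cfg$params)
  doc <- emit_gcode(tp, cfg$settings, cfg$profile)
  if (!is.null(output)) write_gcode(doc, output)
  list(doc = doc, toolpath = tp, report = report,
       account = flow_account(tp, cfg$params))
}
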