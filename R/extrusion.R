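#' Extrusion model parameters
#'
#' Parameters of the volumetric extrusion model used to compute the G-code
#' E axis. A deposited strand is modelled with a stadium cross-section (a
#' rectangle of width \code{w - h} capped by two semicircles of diameter
#' \code{h}), the shape assumed by the Slic3r flow model.
#'
#' The E value advanced per unit path length equates the deposited volume
#' \code{A * L} with the volume of a cylinder of diameter \code{d}, scaled
#' by the extrusion multiplier \code{f}. The printed model equations use the
#' NOZZLE diameter for \code{d}; the physically meaningful choice for
#' filament advanced by the extruder gear is the FILAMENT diameter. Both are
#' available through \code{e_denominator}; the default follows the model as
#' published (\code{"nozzle"}). E values are therefore comparable within one
#' convention only.
#'
#' @param w extrusion width, mm (default 1.7 x nozzle diameter, the upper
#'   end of the recommended 1.05-1.7x window).
#' @param h layer height, mm; must satisfy \code{h <= w}.
#' @param d_nozzle nozzle diameter, mm.
#' @param d_filament filament diameter, mm.
#' @param f extrusion multiplier (dimensionless, 1 = 100% flow; values < 1
#'   under-extrude).
#' @param e_denominator which diameter enters the E conversion,
#'   \code{"nozzle"} (as published) or \code{"filament"}.
#' @return An object of class \code{extrusion_params}.
#' @examples
#' extrusion_params(h = 0.2, d_nozzle = 0.4, f = 0.45)
#' @export
extrusion_params <- function(w = 1.7 * d_nozzle, h = 0.20, d_nozzle = 0.40,
                             d_filament = 1.75, f = 1.0,
                             e_denominator = c("nozzle", "filament")) {
  e_denominator <- match.arg(e_denominator)
  stopifnot(h > 0, w >= h, d_nozzle > 0, d_filament > 0, f >= 0)
  structure(list(w = w, h = h, d_nozzle = d_nozzle, d_filament = d_filament,
                 f = f, e_denominator = e_denominator),
            class = "extrusion_params")
}

e_diameter <- function(params)
  if (params$e_denominator == "nozzle") params$d_nozzle else params$d_filament

#' Stadium cross-section area of a deposited strand
#'
#' Area of a rectangle with two semicircular caps: \code{(w - h) * h +
#' pi * (h/2)^2}. The two semicircles of diameter \code{h} together
#' contribute one full circle. Degenerates to a circle of diameter \code{h}
#' when \code{w == h}.
#'
#' @param w extrusion width, mm.
#' @param h layer height, mm; requires \code{w >= h} (the caps are
#'   semicircles of diameter h).
#' @return Cross-section area, mm^2.
#' @examples
#' cross_section_area(0.4, 0.2)  # 0.0714159 mm^2
#' @export
cross_section_area <- function(w, h) {
  stopifnot(h > 0)
  if (any(w < h))
    stop("extrusion width w must be >= layer height h (stadium geometry)")
  (w - h) * h + pi * (h / 2)^2
}

#' Extruded filament length for a deposited segment
#'
#' Solves the volume balance \code{pi * (d/2)^2 * E = A * L_seg} for E and
#' applies the extrusion multiplier: \code{E = A * L_seg * 4 / (pi * d^2) *
#' f}, with \code{d} chosen by \code{params$e_denominator}.
#'
#' @param A strand cross-section area, mm^2 (see [cross_section_area()]).
#' @param L_seg deposited segment length, mm (>= 0).
#' @param params an [extrusion_params()].
#' @return Filament length E, mm.
#' @examples
#' p <- extrusion_params(w = 0.4, h = 0.2)
#' extrusion_length(cross_section_area(0.4, 0.2), 20, p)
#' @export
extrusion_length <- function(A, L_seg, params) {
  stopifnot(all(L_seg >= 0))
  d <- e_diameter(params)
  A * L_seg * 4 / (pi * d^2) * params$f
}

#' Assign cumulative E values to a toolpath
#'
#' Each extruding segment increments E by [extrusion_length()] over its
#' Euclidean length; travel moves leave E unchanged, so E is non-decreasing
#' along the whole path. Re-assigning an already-assigned toolpath is an
#' error; call [reset_extrusion()] first.
#'
#' @param toolpath a \code{toolpath} with segment kinds assigned.
#' @param params an [extrusion_params()].
#' @return The toolpath with its \code{e} column filled in; the parameters
#'   used are attached as attribute \code{"extrusion_params"}.
#' @export
assign_extrusion <- function(toolpath, params) {
  if (!all(is.na(toolpath$e)))
    stop("toolpath already has E assigned; use reset_extrusion() first")
  A <- cross_section_area(params$w, params$h)
  len <- segment_lengths(toolpath)
  dE <- ifelse(toolpath$kind == "extrude",
               extrusion_length(A, len, params), 0)
  toolpath$e <- cumsum(dE)
  attr(toolpath, "extrusion_params") <- params
  toolpath
}

#' Clear assigned E values
#'
#' @param toolpath a \code{toolpath}.
#' @return The toolpath with \code{e} set back to NA.
#' @export
reset_extrusion <- function(toolpath) {
  toolpath$e <- NA_real_
  attr(toolpath, "extrusion_params") <- NULL
  toolpath
}

#' Volumetric flow account of a toolpath
#'
#' \code{V_out} is the geometric volume of the deposited strands at nominal
#' width, \code{sum(A * L_seg)} over extruding segments; \code{V_in} is the
#' filament volume implied by the final E, \code{pi * (d/2)^2 * E_total}.
#' With \code{f = 1} the two agree to numerical precision; under-extrusion
#' (\code{f < 1}) makes \code{V_in < V_out}.
#'
#' @param toolpath a \code{toolpath} with E assigned.
#' @param params the [extrusion_params()] used for the assignment.
#' @return An object of class \code{flow_account}: list with \code{V_in},
#'   \code{V_out} (mm^3) and \code{E_total} (mm).
#' @export
flow_account <- function(toolpath, params) {
  if (all(is.na(toolpath$e))) stop("toolpath has no E assigned")
  A <- cross_section_area(params$w, params$h)
  len <- segment_lengths(toolpath)
  E_total <- max(toolpath$e)
  d <- e_diameter(params)
  structure(list(V_in = pi * (d / 2)^2 * E_total,
                 V_out = sum(A * len[toolpath$kind == "extrude"]),
                 E_total = E_total),
            class = "flow_account")
}

#' @export
print.flow_account <- function(x, ...) {
  cat(sprintf("Flow account: V_in = %.6f mm^3, V_out = %.6f mm^3, E = %.5f mm\n",
              x$V_in, x$V_out, x$E_total))
  invisible(x)
}

#' Effective deposited strand width under a flow multiplier
#'
#' Diagnostic for the under-extrusion regime: solves the stadium area
#' equation \code{(w_eff - h) * h + pi * (h/2)^2 = f * A_nominal} for the
#' width the reduced flow can actually fill at the set layer height. When
#' the reduced flow cannot even fill the semicircular caps (no solution
#' with \code{w_eff >= h}), the strand detaches from the layer-height
#' geometry and the equivalent circular diameter \code{2 * sqrt(f * A /
#' pi)} is returned instead, flagged as the fiber regime — the free-hanging
#' filament regime that produces micrometric fibers.
#'
#' @param params an [extrusion_params()] with \code{f > 0}.
#' @return List with \code{width} (mm), \code{fiber_regime} (logical) and
#'   \code{regime} (\code{"strand"} or \code{"fiber"}).
#' @examples
#' effective_strand_width(extrusion_params(w = 0.68, h = 0.2, f = 0.20))
#' @export
effective_strand_width <- function(params) {
  if (params$f <= 0) stop("effective width undefined for f = 0")
  A_target <- params$f * cross_section_area(params$w, params$h)
  cap <- pi * (params$h / 2)^2
  if (A_target >= cap) {
    w_eff <- params$h + (A_target - cap) / params$h
    list(width = w_eff, fiber_regime = FALSE, regime = "strand")
  } else {
    list(width = 2 * sqrt(A_target / pi), fiber_regime = TRUE,
         regime = "fiber")
  }
}
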