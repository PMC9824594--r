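---
title: "Scaffold toolpaths, under-extrusion microfibers and calibrated fiber metrology"
author: "microscaff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scaffold toolpaths, under-extrusion microfibers and calibrated fiber metrology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microscaff)
```

## The problem

Porous polymer scaffolds for tissue engineering are routinely printed on
fused deposition modeling (FDM) machines as orthogonal strand lattices.
Standard FDM resolution bounds the strand width from below at roughly the
nozzle diameter, so lattice macropores come out in the 300--700 µm range
— too large for many cell systems, which prefer topological cues at the
tens-of-micrometres scale. Dedicated techniques (melt electrowriting,
near-field electrospinning) produce 5--30 µm fibers but require special
equipment. An alternative is to drive a *standard* printer outside its
normal operating envelope: at strongly reduced extrusion multipliers and
high traverse speeds the polymer no longer fills the commanded strand
cross-section and instead draws thin free-hanging filaments across the
macropores. `microscaff` implements the full desk-side toolchain for this
strategy: parametric toolpath generation from primitive geometric
patterns, the volumetric extrusion model that computes the G-code E axis,
the experiment matrices of the parameter study, printability validation,
and a calibrated fiber-diameter measurement stage with a synthetic
micrograph generator for closed-loop testing.

## Scaffold geometry

A scaffold is a square lattice of side `L` built from `n_layers` layers of
height `h`. Odd layers carry parallel strands running along Y spaced `d1`
apart in X; even layers run along X spaced `d2` in Y (the conventional
0°/90° lay-down; the per-layer direction can be overridden). Strand
positions span `[0, L]` with `round(L/spacing) + 1` strands; when
`L/spacing` is not an integer the positions are distributed uniformly so
the extruded bounding box is still exactly `L × L`. Strands are visited
in boustrophedon (serpentine) order and the short boundary links between
them are extruded by default, giving one continuous deposited path per
layer (`links = "travel"` switches them to travel moves). The first layer
sits at `z = h` with no squish offset — layer height is the only Z
control — and coordinates are absolute millimetres with a configurable
bed-origin offset.

The triangular pattern is a triangle wave: apex spacing `d1` along X,
amplitude `d2` along Y, rows stacked to tile the square. Every extruded
segment then has slope magnitude `2·d2/d1`; inter-row links default to
travel moves so this slope property holds for the whole extruded set.

```{r}
spec <- scaffold_spec(pattern = "rectilinear", L = 20, d1 = 1.0,
                      d2 = 2.5, h = 0.2, n_layers = 4)
tp <- build_toolpath(spec)
unique(tp$z)
```

## The extrusion model

The G-code E word is the cumulative length of filament the extruder must
advance. A deposited strand is modelled with a *stadium* cross-section —
a rectangle with two semicircular caps of diameter `h`:

$$A = (w - h)\,h + \pi\left(\frac{h}{2}\right)^2$$

Equating the deposited volume $A \cdot L_{seg}$ with the volume of a
filament cylinder of diameter $d$ and scaling by the extrusion
multiplier $f$ gives

$$E = \frac{4\,A\,L_{seg}}{\pi d^2}\, f.$$

Two conventions exist for $d$. The model as published in the workflow
this package implements uses the **nozzle** diameter (0.40 mm); the
physically meaningful quantity — filament advanced by the extruder gear —
uses the **filament** diameter (1.75 mm). Both are supported through
`e_denominator`, defaulting to `"nozzle"` to match the published
equations; E values are only comparable within one convention, and the
choice rescales all E values by a constant, so ratios (the quantity the
parameter study interprets) are unaffected. The default extrusion width
is `w = 1.7 × d_nozzle = 0.68` mm, the upper end of the recommended
1.05--1.7× window, and is configurable.

The diagnostic `effective_strand_width()` inverts the stadium equation
under a multiplier `f`: when the reduced flow cannot fill even the
semicircular caps ($f A < \pi (h/2)^2$) there is no stadium solution and
the strand detaches from the layer-height geometry; the function then
returns the equivalent circular diameter $2\sqrt{fA/\pi}$ flagged as the
*fiber regime*. At the reference settings, `f = 0.20` gives:

```{r}
effective_strand_width(extrusion_params(w = 0.68, h = 0.2, f = 0.20))
```

a ≈180 µm free filament — the regime in which micrometric fibers form
(the deposited fiber is further thinned by stretching at high traverse
speed, which the static volume model does not capture).

## G-code dialect

`emit_gcode()` writes a deliberately small RepRap-flavour subset: M140/
M190 and M104/M109 set-and-wait temperature pairs, G28 homing, G90
absolute coordinates, M82 absolute E, M106/M107 fan, G1 motion, M84 end.
E is absolute (cumulative) and never retracted. Coordinates are fixed to
3 decimals, E to 5, F words are integer mm/min; Z and F appear only when
they change. This canonical formatting makes emission deterministic:
`parse_gcode()` recovers the toolpath with carry-forward semantics, and
re-emitting a parsed document is byte-identical, which the round-trip
property tests exercise on randomized toolpaths. First-layer moves carry
`first_layer_speed` (600 mm/min throughout the packaged experiments);
the fan command is placed at the start of `fan_from_layer` (default 1 —
a single fan state per print, as the experiment tables imply).

## Printability rules

`validate_print()` encodes the printability recommendations as a
structured report: layer height at most 80 % of the nozzle diameter
(0.32 mm at 0.40 mm — severity *error*, the flow model is meaningless
beyond it), extrusion width within 1.05--1.7× the nozzle diameter,
print speed ≤ 100 mm/s (machine instability), first-layer speed ≤ 25
mm/s (bed adhesion), fan PWM within 0--255 (*error*), and the PCL
material windows of 130--170 °C (nozzle) and 30--45 °C (bed),
overridable per material. The severity split is a package convention;
all rules are recommendations in origin. `audit_gcode()` is the inverse
check: it reconstructs per-segment flow from the E increments of any
document in the dialect and flags fiber-regime segments.

## Experiment matrices and surface passes

The five sensitivity-analysis matrices are shipped verbatim as plain TSV
tables: extrusion multiplier (F, 4 rows), printing speed (V, 8), fan PWM
(T, 13), surface passes (P, 9) and the diagonal-pass experiment (D, 1) —
35 rows in all. Three rows (V8B, T12B, T13B) are flagged as first-layer
adhesion failures and excluded from the default sweep, which therefore
emits 32 deterministic G-code files. Internally inconsistent PWM
percentage annotations in the T table are preserved verbatim in the
notes column, with the numeric PWM value authoritative.

The P and D experiments use the *no-Z-raise pass* strategy: 3 base
layers are printed normally (f = 1.00, 600 mm/min, fan 255), then the
nozzle re-traverses the top layer at its unchanged Z with a strongly
reduced multiplier and high speed. `add_surface_passes()` implements
both pass patterns — parallel strands spaced `d1`, and 45° diagonals at
perpendicular spacing `d1` with travel links between strokes — and
advances E with the pass multiplier, so the max-Z invariant and the
exact linearity of the pass E increment in `pass_f` are testable
properties.

```{r}
D <- load_matrix("D")
D[, c("id", "pass_pattern", "pass_f", "pass_speed")]
```

## Calibrated fiber metrology

The physical workflow measures fiber diameters on digital-microscope
images calibrated against a micrometric ruler: the scale is the average
of n = 20 reference measurements (`calibrate_scale()` reports mean and
SD of the per-measurement ratios, flagging single-measurement
calibrations). The reference measurements were taken manually in an
image-analysis program; `measure_fibers()` automates an equivalent
procedure so it can be tested in a closed loop:

1. Otsu threshold (overridable) on the grayscale image, then a small
   (radius 1) morphological opening to suppress speckle — structures
   thinner than ~3 px are therefore not measurable, so the image scale
   must put the thinnest fiber of interest at ≥ 3 px.
2. Width-based strand/fiber separation: an opening with a disc of
   radius `cutoff/2` retains only structures wider than the cutoff
   (macro-strands); everything within a 2 px dilation of them is
   removed, detaching fibers from the strands they span between. The
   default cutoff of 150 µm sits between the 300--700 µm strand scale
   and the tens-of-µm fiber scale.
3. Per remaining component: orientation from the principal axis of the
   pixel coordinates; width as the chord length perpendicular to that
   axis at 15 transect points along the component (median), with the
   chord endpoints located by bisection to sub-pixel precision — a
   straight noise-free band of k pixels measures exactly k. Components
   shorter than twice their width are discarded as junction debris.
4. Conversion to µm through the calibration scale; the report carries
   per-fiber diameters with mean ± sample SD (n − 1; the convention
   when only "± S.D." is stated).

A manual-equivalent point-pair measurement (`measure_point_pairs()`) is
also exposed.

`synth_micrograph()` renders the ground-truth images: a bright strand
lattice at spacings `d1`/`d2` with fibers of known width spanning the
pores, additive Gaussian noise, and a per-fiber truth table (requested
and pixel-rendered width). Fibers are axis-aligned and parallel within
each pore, attach to the bounding strands, and sit on non-overlapping
lanes. What the generator does *not* emulate — curved and sagging
fibers, width variation along a fiber, specular highlights, depth blur,
beads and lumps — bounds what the closed-loop tests show: they validate
the measurement chain (thresholding, separation, transects,
calibration), not its robustness to every artefact of real micrographs.

```{r}
syn <- synth_micrograph(n_fibers = 50, width_mean = 48, width_sd = 12,
                        um_per_px = 5, n_pores = c(4, 4), noise = 0.02,
                        seed = 101)
measure_fibers(syn$image, fixed_scale(5))
```

## Numerical choices and problem sizes

* Strand counts use `round(L/spacing) + 1` with endpoints pinned to 0
  and `L`; exact divisors reproduce the positions `0, d, 2d, …, L`.
* E is accumulated in double precision and quantized to 5 decimals only
  at emission; volume conservation at `f = 1` holds to ≤ 1e−9 relative
  on the unquantized path, and round-trip E agreement is bounded by the
  5-decimal quantization (5e−6 mm).
* `effective_strand_width()` switches to the fiber regime exactly at
  $fA = \pi(h/2)^2$; the width is continuous and strictly increasing in
  `f` across the switch.
* Degenerate inputs: empty layer lists, empty toolpaths, all-travel
  paths, blank and lattice-only images all return well-defined empty
  results or typed errors rather than NaNs.
* Property tests run 100 randomized toolpaths of 25--30 moves for the
  round-trip and volume invariants, and the closed-loop metrology uses
  one 860×860 px synthetic micrograph with 50 fibers at 5 µm/px —
  sizes chosen to exercise every code path while keeping the default
  suite near 15 s.

## Known limitations

The extrusion model is purely volumetric: no melt rheology, die swell,
pressure advance or stretching dynamics, so it predicts *when* the flow
leaves the strand regime, not the final drawn fiber diameter. The
G-code dialect omits arcs, retraction and firmware extensions. Fiber
measurement assumes bright fibers on a darker background and roughly
straight fibers at the transect scale; strongly curved or crossing
fibers are split or discarded rather than traced.
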