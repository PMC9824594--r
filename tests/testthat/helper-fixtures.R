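# Random toolpath generator used by round-trip and volume-conservation
# property tests. Coordinates are drawn on the 3-decimal grid emitted by
# the G-code writer so quantization does not blur vertex comparisons.
random_toolpath <- function(n_moves = 30, n_layers = 2, h = 0.2) {
  zs <- rep(h * seq_len(n_layers), length.out = n_moves)
  zs <- sort(zs)
  tp <- data.frame(
    x = round(stats::runif(n_moves, 0, 50), 3),
    y = round(stats::runif(n_moves, 0, 50), 3),
    z = zs,
    kind = sample(c("extrude", "travel"), n_moves, replace = TRUE,
                  prob = c(0.8, 0.2)),
    e = NA_real_, f = NA_real_,
    stringsAsFactors = FALSE)
  tp$kind[1] <- "travel"
  class(tp) <- c("toolpath", "data.frame")
  tp
}

ref_spec <- function(n_layers = 4)
  scaffold_spec(pattern = "rectilinear", L = 20, d1 = 1.0, d2 = 2.5,
                h = 0.2, n_layers = n_layers)

# Independent oracle for the stadium cross-section: numeric integration of
# the chord height across the shape (semicircular cap, flat middle,
# semicircular cap), never touching the closed-form area expression.
stadium_area_numeric <- function(w, h) {
  chord <- function(x) {
    cap <- function(d) 2 * sqrt(pmax((h / 2)^2 - d^2, 0))
    ifelse(x < h / 2, cap(h / 2 - x),
           ifelse(x > w - h / 2, cap(x - (w - h / 2)), h))
  }
  stats::integrate(chord, 0, w, rel.tol = 1e-10)$value
}

extrude_lengths_of <- function(tp) {
  len <- segment_lengths(tp)
  len[tp$kind == "extrude"]
}
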