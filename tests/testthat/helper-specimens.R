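# Small fixture builders shared across test files.

# Rectangle specimen: constant width and (optionally) constant thickness.
rect_specimen <- function(L = 100, W = 10, t = 0.25,
                          midrib = c(0.4, 0.35, 0.3), id = "rect") {
  leaf_specimen(leaf_shape(L, W, width_exponent = 0,
                           thickness = rep(t, 3), midrib = midrib), id = id)
}

# Default lanceolate leaf used where the exact shape does not matter.
lance_specimen <- function(L = 150, W = 12, id = "lance", ...) {
  leaf_specimen(leaf_shape(L, W, ...), id = id)
}

# Independent water-density oracle: Kell's rational polynomial for air-free
# water (g/cm^3), accurate to ~1e-6 over 0-100 degC.
kell_density <- function(t) {
  (999.83952 + 16.945176 * t - 7.9870401e-3 * t^2 - 46.170461e-6 * t^3 +
     105.56302e-9 * t^4 - 280.54253e-12 * t^5) / (1 + 16.879850e-3 * t) / 1000
}
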