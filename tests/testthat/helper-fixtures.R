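# Desk-scale geometry shared by image-based tests: small fields with
# correspondingly smaller nuclei so a handful of cells fit per field.
small_render <- function(...) {
  render_params(shape_zyx = c(10L, 256L, 256L),
                nucleus_radius_um = c(2.8, 3.5), ...)
}

# Reduced acceptance geometry: full-sized nuclei in a quarter-area field.
reduced_render <- function(...) {
  render_params(shape_zyx = c(12L, 512L, 512L), ...)
}
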