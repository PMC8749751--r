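# shared in-code fixtures for the test suite

# three hand-built specimens on the exact radius-length line
# VR = -0.65 + 0.08 TL, with plausible band stacks
tiny_specimens <- function() {
  specimen_table(
    specimen_id = c("A", "B", "C"),
    sex = c("female", "female", "male"),
    total_length = c(80, 60, 50),
    capture_year = 2014L,
    capture_month = c(4L, 7L, 1L),
    vertebral_radius = -0.65 + 0.08 * c(80, 60, 50),
    band_radii = list(c(0.8, 2.0, 3.5, 5.0),
                      c(0.8, 1.9, 3.1),
                      c(0.8, 1.7)),
    edge_type = c("translucent", "opaque", "unknown"))
}

default_truth <- function() growth_params("VBG3", linf = 81.87, k = 0.168,
                                          t0 = -1.384)

# exact (noise-free) age-length data on a given curve
exact_curve_data <- function(params, ages = seq(0.5, 14, by = 0.5)) {
  data.frame(age = ages, length = predict_length(params, ages))
}
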