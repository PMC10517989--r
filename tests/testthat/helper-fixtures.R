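# Small geometries shared across tests; built in code, no stored fixtures.

tiny_grid <- function(n = c(5, 2), extent = c(0.02, 0.02)) imaging_grid(extent, n)

tiny_op <- function(n = c(5, 2), n_pos = 8, n_freq = 4, radius = 0.06) {
  forward_operator(tiny_grid(n), scan_circular(radius, n_pos),
                   frequency_sweep(70e9, 110e9, n_freq))
}

# A mid-size operator with enough aperture/bandwidth for focusing tests.
focus_op <- function(n = c(30, 30)) {
  forward_operator(imaging_grid(c(0.049, 0.049), n),
                   scan_circular(0.12, 24, "bistatic", rx_offset_deg = 12),
                   frequency_sweep(70e9, 110e9, 16))
}

random_reflectivity <- function(op, seed = 1, scale = 0.5) {
  set.seed(seed)
  reflectivity_map(complex(real = rnorm(op$npix), imaginary = rnorm(op$npix)) * scale,
                   op$grid)
}

random_measurement <- function(op, seed = 1) {
  set.seed(seed)
  measurement_set(complex(real = rnorm(op$rows), imaginary = rnorm(op$rows)), op)
}

# Reduced-size preset for fast end-to-end workbench tests.
small_sim_cfg <- function() {
  preset_config("desk-sim", overrides = list(
    grid = imaging_grid(c(0.049, 0.049), c(12, 12)),
    scan = scan_circular(0.12, 48, "bistatic", rx_offset_deg = 12),
    sweep = frequency_sweep(70e9, 110e9, 8),
    n_train = 12, n_test = 4, epochs = 2))
}

small_phantom_cfg <- function() {
  preset_config("desk-phantom", overrides = list(
    grid = imaging_grid(c(0.024, 0.024), c(10, 10)),
    scan = scan_circular(0.08, 40, "monostatic"),
    sweep = frequency_sweep(75e9, 110e9, 6),
    n_train = 8, n_test = 3, epochs = 2))
}
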