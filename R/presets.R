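#' Named experiment presets
#'
#' Four presets bundle the geometry, sweep, phase-error and training
#' settings of the two studies the package reproduces:
#'
#' * `"paper-sim"` - the literal simulation-study settings: a 2 x 2 m scene
#'   discretized into 30 x 30 pixels, a bistatic circular trajectory, a
#'   40 GHz bandwidth at 90 GHz center frequency, 100 training / 30 test
#'   point-target samples, an 8-shrinkage-layer network trained for
#'   6 epochs, and a uniform trajectory phase error of half-width 3
#'   (in scene length units).
#' * `"desk-sim"` - the same study at desk scale: identical pixel, sample,
#'   layer and epoch counts on a 4.9 x 4.9 cm scene whose circular aperture and
#'   sweep are chosen so the forward matrix has full column rank (see the
#'   methods vignette), with the trajectory error half-width rescaled to
#'   an eighth of the center wavelength.
#' * `"paper-phantom"` - the literal phantom experiment: 75-110 GHz,
#'   monostatic rectangular scan of 2 x 2 positions at 1.5 mm spacing, 3 cm
#'   standoff, 2 mm skin slab, two spherical tumors of 0.1-0.4 mm diameter
#'   at 0.5-1 mm center distance, 50 training arrangements.
#' * `"desk-phantom"` - the phantom analog at desk scale: tumor sizes and
#'   separations scaled by 10 (1-4 mm diameters, 5-10 mm distances) on a
#'   2.4 x 2.4 cm scene with a surrounding circular aperture, keeping the
#'   75-110 GHz band and the Cole-Cole dielectrics literal.
#'
#' @param name preset name.
#' @param overrides named list merged over the preset fields.
#' @return A list with `grid`, `scan`, `sweep`, `phase_error`, dataset
#'   counts, tumor ranges and training hyperparameters.
#' @export
preset_config <- function(name = c("desk-sim", "paper-sim",
                                   "desk-phantom", "paper-phantom"),
                          overrides = list()) {
  name <- match.arg(name)
  cfg <- switch(
    name,
    "paper-sim" = {
      sweep <- frequency_sweep(70e9, 110e9, 16)
      list(kind = "point",
           grid = imaging_grid(c(2, 2), c(30, 30)),
           scan = scan_circular(3, 128, "bistatic", rx_offset_deg = 12),
           sweep = sweep,
           phase_error = phase_error_spec(3),
           n_train = 100, n_test = 30,
           n_layers = 9, lambda = 1e-7, learning_rate = 1e-4, epochs = 6,
           batch_size = 10)
    },
    "desk-sim" = {
      sweep <- frequency_sweep(70e9, 110e9, 16)
      lam_c <- C_LIGHT / 90e9
      list(kind = "point",
           grid = imaging_grid(c(0.049, 0.049), c(30, 30)),
           scan = scan_circular(0.12, 128, "bistatic", rx_offset_deg = 12),
           sweep = sweep,
           phase_error = phase_error_spec(lam_c / 8),
           n_train = 100, n_test = 30,
           n_layers = 9, lambda = 1e-7, learning_rate = 1e-4, epochs = 6,
           batch_size = 10)
    },
    "paper-phantom" = {
      sweep <- frequency_sweep(75e9, 110e9, 12)
      list(kind = "two_tumor",
           grid = imaging_grid(c(3e-3, 3e-3), c(30, 30)),
           scan = scan_planar(1.5e-3, c(2, 2), standoff = 0.03),
           sweep = sweep,
           phase_error = phase_error_spec((C_LIGHT / sweep$center) / 6),
           diameter_range = c(1e-4, 4e-4), distance_range = c(5e-4, 1e-3),
           thickness = 2e-3,
           n_train = 50, n_test = 10,
           n_layers = 9, lambda = 1e-7, learning_rate = 1e-4, epochs = 6,
           batch_size = 10)
    },
    "desk-phantom" = {
      sweep <- frequency_sweep(75e9, 110e9, 12)
      list(kind = "two_tumor",
           grid = imaging_grid(c(0.024, 0.024), c(16, 16)),
           scan = scan_circular(0.08, 96, "monostatic"),
           sweep = sweep,
           phase_error = phase_error_spec((C_LIGHT / sweep$center) / 6),
           diameter_range = c(1e-3, 4e-3), distance_range = c(5e-3, 1e-2),
           thickness = 2e-2,
           n_train = 50, n_test = 10,
           n_layers = 9, lambda = 1e-7, learning_rate = 1e-4, epochs = 6,
           batch_size = 10)
    })
  cfg$preset <- name
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  cfg
}

#' Load an experiment configuration from a YAML file
#'
#' The file names a preset and optionally overrides any of its fields;
#' geometry overrides use plain scalars (`grid_extent`, `grid_n`,
#' `sweep_fmin`, ...) which are translated into the structured objects.
#'
#' @param path YAML file with at least a `preset:` key.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$preset)) stop_validation("config file must name a preset")
  overrides <- raw[setdiff(names(raw), "preset")]
  structured <- list()
  if (!is.null(overrides$grid_extent) || !is.null(overrides$grid_n)) {
    base <- preset_config(raw$preset)
    structured$grid <- imaging_grid(
      overrides$grid_extent %||% base$grid$extent,
      overrides$grid_n %||% base$grid$n)
  }
  if (!is.null(overrides$sweep_fmin)) {
    base <- preset_config(raw$preset)
    structured$sweep <- frequency_sweep(overrides$sweep_fmin,
                                        overrides$sweep_fmax %||% base$sweep$fmax,
                                        overrides$sweep_n %||% base$sweep$n)
  }
  if (!is.null(overrides$phase_error_half_width))
    structured$phase_error <- phase_error_spec(overrides$phase_error_half_width)
  plain <- overrides[setdiff(names(overrides),
                             c("grid_extent", "grid_n", "sweep_fmin",
                               "sweep_fmax", "sweep_n",
                               "phase_error_half_width"))]
  preset_config(raw$preset, overrides = c(plain, structured))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
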