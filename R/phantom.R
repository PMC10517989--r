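#' Single-pole Cole-Cole parameters
#'
#' Empirical dispersive permittivity model for biological tissue:
#' `eps_r(omega) = eps_ro + delta_eps / (1 + (j omega tau)^(1 - alpha))
#'  + sigma_s / (j omega eps_0)`.
#'
#' @param eps_ro relative permittivity at optical frequencies (>= 1).
#' @param delta_eps magnitude of the dielectric dispersion (>= 0).
#' @param tau relaxation time in seconds (> 0).
#' @param sigma_s ionic conductivity in S/m (>= 0).
#' @param alpha broadening of the dispersion, `0 <= alpha < 1`.
#' @export
cole_cole_params <- function(eps_ro, delta_eps, tau, sigma_s, alpha) {
  if (eps_ro < 1) stop_validation("eps_ro must be >= 1")
  if (delta_eps < 0) stop_validation("delta_eps must be >= 0")
  if (tau <= 0) stop_validation("tau must be > 0")
  if (sigma_s < 0) stop_validation("sigma_s must be >= 0")
  if (alpha < 0 || alpha >= 1) stop_validation("alpha must be in [0, 1)")
  structure(list(eps_ro = eps_ro, delta_eps = delta_eps, tau = tau,
                 sigma_s = sigma_s, alpha = alpha),
            class = "cole_cole_params")
}

#' Cole-Cole parameters of skin-mimicking phantom materials
#'
#' Fitted single-pole Cole-Cole parameters of tissue-mimicking phantom
#' mixtures for normal and malignant (SCC-like) skin at millimeter-wave
#' frequencies.
#'
#' @return Named list with `normal` and `tumor` [cole_cole_params()].
#' @export
skin_cole_cole <- function() {
  list(normal = cole_cole_params(4.25, 45.02, 5.96e-12, 0.0005, 0.15),
       tumor = cole_cole_params(10, 34.99, 3.04e-12, 0.0004, 0.05))
}

#' Complex relative permittivity from the Cole-Cole model
#'
#' Uses the principal branch for the complex power
#' `(j omega tau)^(1 - alpha)`, i.e. `j^(1-alpha) = exp(j (1-alpha) pi/2)`.
#' The convention is `eps_r = eps' - j eps''`, so lossy tissue has a
#' negative imaginary part.
#'
#' @param p a [cole_cole_params()].
#' @param f frequency in Hz (> 0); vectorized.
#' @return Complex relative permittivity, same length as `f`.
#' @examples
#' cole_cole_permittivity(skin_cole_cole()$normal, 90e9)
#' @export
cole_cole_permittivity <- function(p, f) {
  stopifnot(inherits(p, "cole_cole_params"))
  if (any(!is.numeric(f)) || any(f <= 0))
    stop_validation("frequency must be > 0")
  w <- 2 * pi * f
  p$eps_ro + p$delta_eps / (1 + (1i * w * p$tau)^(1 - p$alpha)) +
    p$sigma_s / (1i * w * EPS0)
}

#' Digital skin phantom with spherical tumor inclusions
#'
#' Labels each grid pixel tumor / normal / background. A pixel is tumor iff
#' its center lies inside one of the declared (spherical, here circular
#' cross-section) inclusions; otherwise it is normal inside the slab region
#' and background outside.
#'
#' @param grid an [imaging_grid()].
#' @param inclusions list of `list(center = c(x, y), diameter = d)` (meters).
#' @param thickness slab thickness in meters (metadata for the 2-D
#'   cross-section).
#' @param slab_extent length-2 extent of the skin-slab region centered on the
#'   origin; defaults to the full grid.
#' @return A `tissue_map` with fields `labels` (character per pixel),
#'   `inclusions`, `thickness`, `grid`, and logical `tumor_mask`.
#' @export
make_skin_phantom <- function(grid, inclusions = list(), thickness = 2e-3,
                              slab_extent = grid$extent) {
  px <- grid_centers(grid)
  half <- grid$extent / 2
  for (inc in inclusions) {
    if (any(abs(inc$center) > half))
      stop_validation("inclusion center lies outside the grid")
    if (inc$diameter <= 0) stop_validation("inclusion diameter must be > 0")
  }
  in_slab <- abs(px[, 1]) <= slab_extent[1] / 2 & abs(px[, 2]) <= slab_extent[2] / 2
  labels <- ifelse(in_slab, "normal", "background")
  tumor <- rep(FALSE, grid$npix)
  for (inc in inclusions) {
    r2 <- (inc$diameter / 2)^2
    tumor <- tumor | ((px[, 1] - inc$center[1])^2 +
                        (px[, 2] - inc$center[2])^2 <= r2)
  }
  labels[tumor] <- "tumor"
  structure(list(labels = labels, tumor_mask = tumor, inclusions = inclusions,
                 thickness = thickness, slab_extent = slab_extent, grid = grid),
            class = "tissue_map")
}

#' Reflectivity map of a tissue phantom
#'
#' Maps dielectric properties to the scalar per-pixel reflectivity seen by
#' the forward model. The default `"differential"` mapping is the contrast
#' against the intact normal-skin slab (the static background that a
#' calibrated system subtracts before inversion): normal and background
#' pixels are 0, tumor pixels carry the Fresnel half-space contrast between
#' normal skin and tumor tissue,
#' `(sqrt(eps_skin) - sqrt(eps_tumor)) / (sqrt(eps_skin) + sqrt(eps_tumor))`,
#' evaluated at the sweep's center frequency. Tumor pixels therefore always
#' have strictly larger reflectivity magnitude than normal pixels whenever
#' the two tissues differ. The mapping function is pluggable via `contrast_fn`.
#'
#' @param tissue a `tissue_map`.
#' @param sweep a [frequency_sweep()]; the contrast is evaluated at its
#'   center frequency.
#' @param params named list with `normal` and `tumor` [cole_cole_params()].
#' @param contrast_fn optional function `(eps_bg, eps_px) -> complex`
#'   replacing the Fresnel contrast.
#' @return A `reflectivity_map`.
#' @export
reflectivity_from_tissue <- function(tissue, sweep, params = skin_cole_cole(),
                                     contrast_fn = NULL) {
  stopifnot(inherits(tissue, "tissue_map"), inherits(sweep, "frequency_sweep"))
  if (is.null(params$normal) || is.null(params$tumor))
    stop_validation("params must provide both 'normal' and 'tumor' tissue classes")
  fc <- sweep$center
  eps_n <- cole_cole_permittivity(params$normal, fc)
  eps_t <- cole_cole_permittivity(params$tumor, fc)
  if (is.null(contrast_fn))
    contrast_fn <- function(eps_bg, eps_px)
      (sqrt(eps_bg) - sqrt(eps_px)) / (sqrt(eps_bg) + sqrt(eps_px))
  v <- complex(length.out = tissue$grid$npix)
  v[tissue$labels == "tumor"] <- contrast_fn(eps_n, eps_t)
  reflectivity_map(v, tissue$grid)
}

#' Dataset specification
#'
#' Describes a labeled synthetic dataset: scene arrangements, tumor size and
#' separation ranges, acquisition geometry, phase-error corruption and the
#' master seed. Two kinds are supported: `"point"` (a single unit point
#' scatterer at a random pixel, the simulation-study scene) and
#' `"two_tumor"` (two spherical Cole-Cole tumor inclusions in a skin slab,
#' the phantom-study scene).
#'
#' @param kind `"point"` or `"two_tumor"`.
#' @param n_samples number of arrangements (>= 1).
#' @param grid,scan,sweep acquisition geometry.
#' @param phase_error a [phase_error_spec()] applied to every measurement.
#' @param seed master seed; each sample is reproducible from (seed, index).
#' @param diameter_range tumor diameter range in meters (two_tumor).
#' @param distance_range tumor center-distance range in meters (two_tumor).
#' @param params tissue Cole-Cole parameters (two_tumor).
#' @param slab_margin fraction of the half-extent kept free of tumor centers.
#' @param trajectory_seed seed of the shared systematic trajectory draw (for
#'   `per_sample = FALSE` phase error); defaults to a stage seed derived
#'   from `seed`. Pass the same value to train and test specs so both
#'   splits see the same miscalibrated acquisition system.
#' @export
dataset_spec <- function(kind = c("point", "two_tumor"), n_samples,
                         grid, scan, sweep,
                         phase_error = phase_error_spec(0), seed = 1,
                         diameter_range = c(1e-3, 4e-3),
                         distance_range = c(5e-3, 1e-2),
                         params = skin_cole_cole(), slab_margin = 0.25,
                         trajectory_seed = NULL) {
  kind <- match.arg(kind)
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 1) stop_validation("n_samples must be >= 1")
  if (diff(diameter_range) < 0 || diff(distance_range) < 0)
    stop_validation("ranges must satisfy min <= max")
  structure(list(kind = kind, n_samples = n_samples, grid = grid, scan = scan,
                 sweep = sweep, phase_error = phase_error, seed = seed,
                 diameter_range = diameter_range,
                 distance_range = distance_range, params = params,
                 slab_margin = slab_margin,
                 trajectory_seed = trajectory_seed %||% seed_for(seed, "trajectory")),
            class = "dataset_spec")
}

# Draw one two-tumor arrangement; reject infeasible geometry (tumors outside
# the slab, overlapping, or too small to cover any pixel center).
draw_two_tumor <- function(spec, counter) {
  grid <- spec$grid
  lim <- grid$extent / 2 * (1 - spec$slab_margin)
  repeat {
    if (counter$n > 1000)
      stop("more than 1000 rejections while placing tumors; spec geometry infeasible")
    d1 <- stats::runif(1, spec$diameter_range[1], spec$diameter_range[2])
    d2 <- stats::runif(1, spec$diameter_range[1], spec$diameter_range[2])
    sep <- stats::runif(1, spec$distance_range[1], spec$distance_range[2])
    th <- stats::runif(1, 0, 2 * pi)
    mid <- c(stats::runif(1, -lim[1], lim[1]), stats::runif(1, -lim[2], lim[2]))
    u <- c(cos(th), sin(th)) * sep / 2
    c1 <- mid + u; c2 <- mid - u
    counter$n <- counter$n + 1
    if (sep < (d1 + d2) / 2) next                       # overlapping spheres
    if (any(abs(c1) + d1 / 2 > lim) || any(abs(c2) + d2 / 2 > lim)) next
    tm <- make_skin_phantom(grid, list(list(center = c1, diameter = d1),
                                       list(center = c2, diameter = d2)),
                            slab_extent = grid$extent)
    comp <- mask_components(as_image_matrix(tm$tumor_mask, grid))
    if (comp != 2) next                                  # empty or merged
    return(tm)
  }
}

#' Generate a labeled synthetic dataset
#'
#' For each arrangement, draws the scene, synthesizes the measurement set
#' with the forward operator, corrupts it with the phase-error model, and
#' stores the ground-truth reflectivity and tumor mask alongside. A pure
#' function of (spec, seed): the same spec yields bit-identical datasets.
#'
#' @param spec a [dataset_spec()].
#' @param op optionally a prebuilt [forward_operator()] for the spec
#'   geometry (it is built once otherwise).
#' @return List with `samples` (each `list(S, s_true, mask, meta)`), the
#'   `op` used, and the `spec`.
#' @export
generate_dataset <- function(spec, op = NULL) {
  stopifnot(inherits(spec, "dataset_spec"))
  if (is.null(op)) op <- forward_operator(spec$grid, spec$scan, spec$sweep)
  samples <- vector("list", spec$n_samples)
  for (i in seq_len(spec$n_samples)) {
    si <- seed_for(spec$seed, paste0("sample", i))
    samples[[i]] <- with_seed(si, {
      if (spec$kind == "point") {
        pix <- sample.int(spec$grid$npix, 1)
        s <- complex(length.out = spec$grid$npix)
        s[pix] <- 1 + 0i
        truth <- reflectivity_map(s, spec$grid)
        mask <- seq_len(spec$grid$npix) == pix
        meta <- list(pixel = pix)
      } else {
        counter <- new.env(); counter$n <- 0
        tm <- draw_two_tumor(spec, counter)
        truth <- reflectivity_from_tissue(tm, spec$sweep, spec$params)
        mask <- tm$tumor_mask
        meta <- list(inclusions = tm$inclusions, rejections = counter$n - 1)
      }
      S <- apply_forward(op, truth)
      phase_seed <- if (spec$phase_error$per_sample) seed_for(si, "phase")
                    else spec$trajectory_seed
      S <- inject_phase_error(S, op, spec$phase_error, seed = phase_seed)
      list(S = S, s_true = truth, mask = mask, meta = meta)
    })
  }
  list(samples = samples, op = op, spec = spec)
}

#' Save / load a dataset as a JSON container
#'
#' Plain-text serialization with per-sample groups (`S`, `s`, `mask`),
#' the spec's scalar fields, and provenance (seed). Complex arrays are
#' stored as paired re/im vectors.
#'
#' @param ds a dataset from [generate_dataset()].
#' @param path output file path.
#' @export
save_dataset <- function(ds, path) {
  obj <- list(
    provenance = list(seed = ds$spec$seed, version = "deeptmi-0.1.0",
                      kind = ds$spec$kind, n_samples = ds$spec$n_samples),
    grid = list(extent = ds$spec$grid$extent, n = ds$spec$grid$n),
    samples = lapply(ds$samples, function(sm)
      list(S = complex_to_json(sm$S$values),
           s = complex_to_json(sm$s_true$values),
           mask = as.integer(sm$mask))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_dataset
#' @param grid,op geometry objects to rebind the samples to on load.
#' @export
load_dataset <- function(path, grid, op) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  samples <- lapply(obj$samples, function(sm)
    list(S = measurement_set(complex_from_json(sm$S), op),
         s_true = reflectivity_map(complex_from_json(sm$s), grid),
         mask = as.logical(sm$mask)))
  list(samples = samples, op = op, provenance = obj$provenance)
}

#' Export a segmentation mask as a PNG image
#'
#' Writes tumor pixels as white (255) and everything else as black.
#'
#' @param mask logical pixel vector (or `segmentation_mask`).
#' @param grid the [imaging_grid()].
#' @param path output PNG path.
#' @export
write_mask_png <- function(mask, grid, path) {
  if (inherits(mask, "segmentation_mask")) mask <- mask$mask
  img <- as_image_matrix(as.numeric(mask), grid)
  png::writePNG(img, path)
  invisible(path)
}
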