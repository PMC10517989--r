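#' Imaging grid
#'
#' Uniform pixelization of a rectangular investigation domain. The scene is
#' centered on the origin; pixel values represent pixel centers, and the
#' centers are symmetric about the origin. Pixels are ordered row-major
#' (x varies fastest), matching the flattening used by reflectivity maps
#' and the forward operator columns.
#'
#' @param extent numeric length-2, physical extent per axis in meters (> 0).
#' @param n integer length-2, pixel counts per axis (>= 1).
#' @return An `imaging_grid` object.
#' @examples
#' g <- imaging_grid(c(0.04, 0.04), c(30, 30))
#' head(grid_centers(g))
#' @export
imaging_grid <- function(extent, n) {
  extent <- as.numeric(extent)
  n <- as.integer(n)
  if (length(extent) != 2 || any(!is.finite(extent)) || any(extent <= 0))
    stop_validation("grid extents must be two positive finite numbers")
  if (length(n) != 2 || any(is.na(n)) || any(n < 1))
    stop_validation("grid pixel counts must be two integers >= 1")
  structure(
    list(extent = extent, n = n, npix = prod(n),
         pitch = extent / n),
    class = "imaging_grid")
}

#' Pixel-center coordinates of a grid
#'
#' @param grid an [imaging_grid()].
#' @return A `npix x 3` matrix of (x, y, z) pixel centers in meters (z = 0;
#'   the grid lies in the z = 0 plane). Row order is row-major with x fastest.
#' @export
grid_centers <- function(grid) {
  stopifnot(inherits(grid, "imaging_grid"))
  ax <- function(L, m) (seq_len(m) - 1 - (m - 1) / 2) * (L / m)
  xs <- ax(grid$extent[1], grid$n[1])
  ys <- ax(grid$extent[2], grid$n[2])
  cbind(x = rep(xs, times = grid$n[2]),
        y = rep(ys, each = grid$n[1]),
        z = 0)
}

# Reshape a flat pixel vector into an ny x nx matrix ([row, col] = [y, x]).
#' Reshape a flat pixel vector to a y-by-x image matrix
#' @param v vector of length `npix` in grid order.
#' @param grid an [imaging_grid()].
#' @export
as_image_matrix <- function(v, grid) {
  stopifnot(length(v) == grid$npix)
  matrix(v, nrow = grid$n[2], ncol = grid$n[1], byrow = TRUE)
}

#' Scan geometry
#'
#' Ordered antenna scan positions for a monostatic or bistatic acquisition.
#' Use [scan_planar()] or [scan_circular()] to build the standard
#' trajectories.
#'
#' @param positions numeric `P x 3` matrix of scan positions in meters.
#' @param mode `"monostatic"` or `"bistatic"`.
#' @param positions_rx for bistatic mode, `P x 3` receive positions paired
#'   with `positions`.
#' @param standoff recorded standoff distance in meters (metadata).
#' @param trajectory free-form descriptor of the trajectory (metadata).
#' @export
scan_geometry <- function(positions, mode = c("monostatic", "bistatic"),
                          positions_rx = NULL, standoff = NA_real_,
                          trajectory = list()) {
  mode <- match.arg(mode)
  positions <- as.matrix(positions)
  if (nrow(positions) < 1 || ncol(positions) != 3)
    stop_validation("scan positions must be a P x 3 matrix with P >= 1")
  if (anyDuplicated(positions))
    stop_validation("scan positions must be distinct")
  if (mode == "bistatic") {
    positions_rx <- as.matrix(positions_rx)
    if (is.null(positions_rx) || !all(dim(positions_rx) == dim(positions)))
      stop_validation("bistatic mode needs paired receive positions")
  }
  structure(
    list(mode = mode, positions = positions, positions_rx = positions_rx,
         n_positions = nrow(positions), standoff = standoff,
         trajectory = trajectory),
    class = "scan_geometry")
}

#' Rectangular planar aperture
#'
#' Monostatic rectangular raster of scan positions in a plane parallel to the
#' imaging grid at a given standoff.
#'
#' @param spacing scan spacing in meters (> 0).
#' @param n integer length-2 position counts per axis.
#' @param standoff distance between the aperture plane and the scene plane (m).
#' @export
scan_planar <- function(spacing, n, standoff) {
  if (!is.numeric(spacing) || spacing <= 0)
    stop_validation("aperture spacing must be > 0")
  n <- as.integer(n)
  ax <- function(m) (seq_len(m) - 1 - (m - 1) / 2) * spacing
  xs <- ax(n[1]); ys <- ax(n[2])
  pos <- cbind(rep(xs, times = n[2]), rep(ys, each = n[1]), standoff)
  scan_geometry(pos, "monostatic", standoff = standoff,
                trajectory = list(kind = "planar", spacing = spacing, n = n))
}

#' Circular scan trajectory
#'
#' Scan positions on a circle around the scene, in the scene plane. In
#' bistatic mode the receive antenna trails the transmitter by a fixed
#' angular offset on the same circle.
#'
#' @param radius circle radius in meters.
#' @param n_positions number of positions around the circle.
#' @param mode `"monostatic"` or `"bistatic"`.
#' @param rx_offset_deg bistatic angular separation between the two antennas.
#' @export
scan_circular <- function(radius, n_positions,
                          mode = c("monostatic", "bistatic"),
                          rx_offset_deg = 10) {
  mode <- match.arg(mode)
  if (radius <= 0) stop_validation("circle radius must be > 0")
  th <- 2 * pi * (seq_len(n_positions) - 1) / n_positions
  pos <- cbind(radius * cos(th), radius * sin(th), 0)
  rx <- NULL
  if (mode == "bistatic") {
    th2 <- th + rx_offset_deg * pi / 180
    rx <- cbind(radius * cos(th2), radius * sin(th2), 0)
  }
  scan_geometry(pos, mode, positions_rx = rx, standoff = radius,
                trajectory = list(kind = "circular", radius = radius,
                                  n_positions = n_positions,
                                  rx_offset_deg = if (mode == "bistatic") rx_offset_deg))
}

#' Frequency sweep
#'
#' Stepped-frequency sweep; wavenumbers k = omega / c are derived and
#' strictly increasing.
#'
#' @param fmin,fmax band edges in Hz, `0 < fmin < fmax`.
#' @param n number of frequency samples (>= 2).
#' @export
frequency_sweep <- function(fmin, fmax, n) {
  if (!is.numeric(fmin) || !is.numeric(fmax) || fmin <= 0 || fmax <= fmin)
    stop_validation("need 0 < fmin < fmax")
  n <- as.integer(n)
  if (is.na(n) || n < 2) stop_validation("a sweep needs at least 2 samples")
  f <- seq(fmin, fmax, length.out = n)
  structure(
    list(fmin = fmin, fmax = fmax, n = n, frequencies = f,
         k = 2 * pi * f / C_LIGHT,
         center = (fmin + fmax) / 2),
    class = "frequency_sweep")
}

#' Nyquist scan spacing
#'
#' Maximum spacing between consecutive scan positions that avoids aperture
#' aliasing: half the smallest wavelength of the sweep. For a 110 GHz upper
#' band edge (smallest wavelength about 3 mm) this is about 1.5 mm.
#'
#' @param sweep a [frequency_sweep()].
#' @return Spacing in meters.
#' @examples
#' nyquist_spacing(frequency_sweep(75e9, 100e9, 8))  # 1.5 mm
#' @export
nyquist_spacing <- function(sweep) {
  if (!inherits(sweep, "frequency_sweep"))
    stop_validation("nyquist_spacing expects a frequency_sweep")
  (C_LIGHT / sweep$fmax) / 2
}

#' @export
print.imaging_grid <- function(x, ...) {
  cat(sprintf("<imaging_grid> %d x %d pixels over %.4g x %.4g m (pitch %.4g x %.4g m)\n",
              x$n[1], x$n[2], x$extent[1], x$extent[2], x$pitch[1], x$pitch[2]))
  invisible(x)
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat(sprintf("<scan_geometry> %s, %d positions (%s)\n", x$mode, x$n_positions,
              if (length(x$trajectory)) x$trajectory$kind else "custom"))
  invisible(x)
}

#' @export
print.frequency_sweep <- function(x, ...) {
  cat(sprintf("<frequency_sweep> %.4g-%.4g GHz, %d samples\n",
              x$fmin / 1e9, x$fmax / 1e9, x$n))
  invisible(x)
}
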