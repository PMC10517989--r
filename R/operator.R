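#' Discretized scattering forward operator
#'
#' Builds the dense linear map F between a reflectivity map s (one complex
#' value per grid pixel) and the measurement set S (one complex value per
#' scan position and frequency pair):
#' each raw entry is the pure round-trip phase `exp(-2j k R)` between a scan
#' position and a pixel center (monostatic), or `exp(-j k (R_tx + R_rx))`
#' (bistatic). Rows are ordered position-major with frequency varying
#' fastest. With `normalize = TRUE` (default) the matrix is divided by
#' `sqrt(rows)` so every column has unit l2 norm and the operator norm is
#' O(1); the same normalized operator is used both to synthesize
#' measurements and to invert them, so the convention cancels out of every
#' reconstruction metric. The stored `scale` field records the factor.
#'
#' @param grid an [imaging_grid()].
#' @param scan a [scan_geometry()].
#' @param sweep a [frequency_sweep()].
#' @param normalize divide by `sqrt(rows)` (recorded in the operator).
#' @return A `forward_operator` with fields `F` (rows x npix complex matrix),
#'   `row_pos`/`row_k` (per-row scan-position index and wavenumber), `scale`,
#'   and references to its geometry.
#' @export
forward_operator <- function(grid, scan, sweep, normalize = TRUE) {
  stopifnot(inherits(grid, "imaging_grid"), inherits(scan, "scan_geometry"),
            inherits(sweep, "frequency_sweep"))
  px <- grid_centers(grid)
  dist_to <- function(pos) {
    # P x npix pairwise distances
    t(apply(pos, 1, function(p) sqrt(colSums((t(px) - p)^2))))
  }
  Dtx <- dist_to(scan$positions)
  path <- if (scan$mode == "monostatic") 2 * Dtx else Dtx + dist_to(scan$positions_rx)
  degenerate <- any(path == 0)
  if (degenerate)
    warning("scan position coincides with a pixel center (R = 0); entry phase is 1")
  P <- scan$n_positions; nf <- sweep$n
  rows <- P * nf
  row_pos <- rep(seq_len(P), each = nf)
  row_k <- rep(sweep$k, times = P)
  # rows x npix phase matrix; column recycling applies row_k down each column
  Fm <- exp(-1i * row_k * path[row_pos, , drop = FALSE])
  scale <- if (normalize) 1 / sqrt(rows) else 1
  structure(
    list(F = Fm * scale, rows = rows, npix = grid$npix, scale = scale,
         row_pos = row_pos, row_k = row_k, degenerate = degenerate,
         grid = grid, scan = scan, sweep = sweep),
    class = "forward_operator")
}

op_values <- function(x) if (is.list(x) && !is.null(x$values)) x$values else x

#' Apply the forward operator
#'
#' Computes `S = F s`, the measurement set predicted for a reflectivity map.
#'
#' @param op a [forward_operator()].
#' @param s reflectivity map (complex vector of length `npix`, or a
#'   `reflectivity_map`).
#' @return A `measurement_set`.
#' @export
apply_forward <- function(op, s) {
  v <- op_values(s)
  if (length(v) != op$npix)
    stop_validation("reflectivity length does not match the operator grid")
  measurement_set(as.vector(op$F %*% v), op)
}

#' Apply the adjoint (backpropagation / delay-and-sum focusing)
#'
#' Computes the adjoint image `F^H S`. For noise-free data from a point
#' scatterer with sufficient aperture and bandwidth, the magnitude of the
#' result peaks at the true pixel.
#'
#' @param op a [forward_operator()].
#' @param S measurement set (complex vector of length `rows`, or a
#'   `measurement_set`).
#' @return A `reflectivity_map`.
#' @export
apply_adjoint <- function(op, S) {
  v <- op_values(S)
  if (length(v) != op$rows)
    stop_validation("measurement length does not match the operator geometry")
  reflectivity_map(as.vector(Conj(t(op$F)) %*% v), op$grid)
}

#' Reflectivity map container
#' @param values complex vector, one entry per grid pixel; all finite.
#' @param grid the [imaging_grid()] the values live on.
#' @export
reflectivity_map <- function(values, grid) {
  values <- as.complex(values)
  if (length(values) != grid$npix)
    stop_validation("reflectivity length must equal the grid pixel count")
  if (any(!is.finite(values)))
    stop_validation("reflectivity values must be finite")
  structure(list(values = values, grid = grid), class = "reflectivity_map")
}

#' Measurement set container
#' @param values complex vector, one entry per (scan position, frequency).
#' @param op the [forward_operator()] describing the acquisition.
#' @export
measurement_set <- function(values, op) {
  values <- as.complex(values)
  if (any(!is.finite(values)))
    stop_validation("measurement values must be finite")
  structure(list(values = values, scan = op$scan, sweep = op$sweep,
                 rows = op$rows),
            class = "measurement_set")
}

#' Trajectory phase-error specification
#'
#' Uniformly distributed antenna-position perturbation: each scan position
#' receives an independent offset `delta ~ U[-half_width, +half_width]`
#' (meters), and every sample taken at that position and wavenumber k is
#' multiplied by `exp(-2j k delta)`. Pure phase corruption: moduli are
#' untouched, and `half_width = 0` leaves the data bit-identical.
#'
#' In a dataset, the perturbation models the antenna trajectory error of the
#' acquisition system: with `per_sample = FALSE` (default) one trajectory
#' draw is shared by every measurement of the dataset (a systematic
#' miscalibration that the unrolled network can learn to compensate by
#' refining the ideal forward model); with `per_sample = TRUE` each
#' measurement receives an independent draw.
#'
#' @param half_width half-width w of the uniform position perturbation (m).
#' @param per_sample draw an independent trajectory per sample instead of
#'   one systematic trajectory per dataset.
#' @export
phase_error_spec <- function(half_width, per_sample = FALSE) {
  if (!is.numeric(half_width) || length(half_width) != 1 || half_width < 0)
    stop_validation("phase-error half-width must be a number >= 0")
  structure(list(family = "uniform", half_width = half_width,
                 per_sample = isTRUE(per_sample)),
            class = "phase_error_spec")
}

#' Corrupt a measurement set with trajectory phase error
#'
#' @param S a `measurement_set` (or complex vector).
#' @param op the [forward_operator()] that produced it.
#' @param spec a [phase_error_spec()].
#' @param seed integer seed; the corruption is deterministic given the seed.
#' @return A `measurement_set` with per-position phase corruption applied.
#' @export
inject_phase_error <- function(S, op, spec, seed) {
  stopifnot(inherits(spec, "phase_error_spec"))
  v <- op_values(S)
  if (length(v) != op$rows)
    stop_validation("measurement length does not match the operator geometry")
  if (spec$half_width == 0) {
    return(if (inherits(S, "measurement_set")) S else measurement_set(v, op))
  }
  delta <- with_seed(seed,
                     stats::runif(op$scan$n_positions,
                                  -spec$half_width, spec$half_width))
  measurement_set(v * exp(-2i * op$row_k * delta[op$row_pos]), op)
}

#' @export
print.forward_operator <- function(x, ...) {
  cat(sprintf("<forward_operator> %d measurements x %d pixels (%s, %snormalized)\n",
              x$rows, x$npix, x$scan$mode, if (x$scale != 1) "" else "un"))
  invisible(x)
}
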