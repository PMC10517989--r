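#' Level-set segmentation of a reconstructed image
#'
#' Thresholds the image magnitude to split the domain into tumor and normal
#' regions. The default rule labels a pixel tumor iff
#' `|pixel| >= fraction * max|image|` with `fraction = 0.5` (half-maximum,
#' scale invariant). An automatic bimodal rule (`rule = "otsu"`) selects the
#' threshold maximizing between-class variance of the magnitudes. An
#' all-zero image yields an empty mask.
#'
#' @param image a `reflectivity_map` (or complex/numeric vector).
#' @param rule `"fraction"` or `"otsu"`.
#' @param fraction fraction of the peak magnitude for the default rule.
#' @param grid grid reference if `image` is a bare vector.
#' @return A `segmentation_mask` (logical `mask` + grid + rule echo).
#' @export
levelset_segment <- function(image, rule = c("fraction", "otsu"),
                             fraction = 0.5, grid = NULL) {
  rule <- match.arg(rule)
  if (inherits(image, "reflectivity_map")) {
    grid <- image$grid; v <- Mod(image$values)
  } else v <- Mod(op_values(image))
  if (any(!is.finite(v))) stop_validation("image must be finite")
  if (max(v) == 0) {
    mask <- rep(FALSE, length(v))
  } else if (rule == "fraction") {
    mask <- v >= fraction * max(v)
  } else {
    mask <- v >= otsu_threshold(v)
  }
  structure(list(mask = mask, grid = grid,
                 rule = list(rule = rule, fraction = fraction)),
            class = "segmentation_mask")
}

# Otsu's bimodal threshold on a magnitude vector (256-bin histogram).
otsu_threshold <- function(v) {
  breaks <- seq(0, max(v), length.out = 257)
  h <- tabulate(findInterval(v, breaks, all.inside = TRUE), nbins = 256)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- (breaks[-1] + breaks[-257]) / 2
  mu <- cumsum(p * mids)
  mu_t <- mu[256]
  sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- 0
  mids[which.max(sb)]
}

mask_values <- function(x) if (inherits(x, "segmentation_mask")) x$mask else as.logical(x)

#' Intersection over Union of two masks
#'
#' `|a intersect b| / |a union b|`; 1 for perfect shape recovery. Two empty
#' masks agree vacuously and give 1.
#'
#' @param a,b logical masks (or `segmentation_mask`s) on the same grid.
#' @export
iou <- function(a, b) {
  av <- mask_values(a); bv <- mask_values(b)
  if (length(av) != length(bv)) stop_validation("masks live on different grids")
  u <- sum(av | bv)
  if (u == 0) return(1)
  sum(av & bv) / u
}

#' Shape error in percent
#'
#' `100 * (1 - IoU)`: 0 for perfect shape recovery.
#' @inheritParams iou
#' @export
shape_error <- function(a, b) 100 * (1 - iou(a, b))

#' Root-mean-square relative error in percent
#'
#' The global norm ratio `100 * ||est - truth||_2 / ||truth||_2`.
#'
#' @param est,truth reflectivity maps (or complex vectors) on the same grid.
#' @export
rms_relative_error <- function(est, truth) {
  ev <- op_values(est); tv <- op_values(truth)
  if (length(ev) != length(tv)) stop_validation("images have different sizes")
  nt <- l2norm(tv)
  if (nt == 0) stop_validation("truth has zero norm; relative error undefined")
  100 * l2norm(ev - tv) / nt
}

# Local sums over w x w windows via an integral image ("valid" windows only).
local_sums <- function(m, w) {
  ii <- apply(apply(m, 2, cumsum), 1, cumsum)  # transposed integral image
  ii <- t(ii)
  ii <- rbind(0, cbind(0, ii))
  nr <- nrow(m) - w + 1; nc <- ncol(m) - w + 1
  ii[(1 + w):(nr + w), (1 + w):(nc + w), drop = FALSE] -
    ii[1:nr, (1 + w):(nc + w), drop = FALSE] -
    ii[(1 + w):(nr + w), 1:nc, drop = FALSE] +
    ii[1:nr, 1:nc, drop = FALSE]
}

#' Structural similarity index (SSIM)
#'
#' Mean local SSIM over 7x7 sliding windows with stabilizing constants
#' `(0.01 L)^2` and `(0.03 L)^2`, `L = 1`, on images normalized to
#' `[0, 1]`. Covariances use the unbiased (n - 1) estimator. Images smaller
#' than the window fall back to a single global window with a warning.
#'
#' @param a,b real image matrices (or vectors with `grid`) in `[0, 1]`.
#' @param window odd window size (default 7).
#' @param grid optional [imaging_grid()] used to reshape bare vectors.
#' @export
ssim <- function(a, b, window = 7, grid = NULL) {
  to_mat <- function(x) {
    if (inherits(x, "reflectivity_map")) return(as_image_matrix(Mod(x$values), x$grid))
    if (is.matrix(x)) return(x)
    if (!is.null(grid)) return(as_image_matrix(x, grid))
    matrix(x, nrow = 1)
  }
  A <- to_mat(a); B <- to_mat(b)
  if (!all(dim(A) == dim(B))) stop_validation("images have different shapes")
  C1 <- 0.01^2; C2 <- 0.03^2
  if (min(dim(A)) < window) {
    warning("image smaller than the SSIM window; using a single global window")
    n <- length(A)
    mx <- mean(A); my <- mean(B)
    vx <- stats::var(as.vector(A)); vy <- stats::var(as.vector(B))
    if (n < 2) { vx <- 0; vy <- 0; cxy <- 0 } else
      cxy <- stats::cov(as.vector(A), as.vector(B))
    return(((2 * mx * my + C1) * (2 * cxy + C2)) /
             ((mx^2 + my^2 + C1) * (vx + vy + C2)))
  }
  n <- window^2
  sA <- local_sums(A, window); sB <- local_sums(B, window)
  sAA <- local_sums(A^2, window); sBB <- local_sums(B^2, window)
  sAB <- local_sums(A * B, window)
  mx <- sA / n; my <- sB / n
  vx <- (sAA - n * mx^2) / (n - 1)
  vy <- (sBB - n * my^2) / (n - 1)
  cxy <- (sAB - n * mx * my) / (n - 1)
  sm <- ((2 * mx * my + C1) * (2 * cxy + C2)) /
    ((mx^2 + my^2 + C1) * (vx + vy + C2))
  mean(sm)
}

#' Normalized mean-square error
#'
#' Mean over pixels of `(a - b)^2` for images normalized to `[0, 1]`.
#'
#' @inheritParams ssim
#' @export
mse_normalized <- function(a, b) {
  av <- if (inherits(a, "reflectivity_map")) Mod(a$values) else as.numeric(a)
  bv <- if (inherits(b, "reflectivity_map")) Mod(b$values) else as.numeric(b)
  if (length(av) != length(bv)) stop_validation("images have different sizes")
  mean((av - bv)^2)
}

#' Normalize an image's magnitude to `[0, 1]`
#'
#' @param image `reflectivity_map` or complex/numeric vector.
#' @return Numeric vector of magnitudes with maximum 1 (or all zeros).
#' @export
normalize01 <- function(image) {
  v <- Mod(op_values(image))
  m <- max(v)
  if (m > 0) v / m else v
}

# Dilate a logical image matrix by one pixel (8-neighborhood).
dilate1 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    ys <- pmin(pmax(seq_len(nr) + dy, 1), nr)
    xs <- pmin(pmax(seq_len(nc) + dx, 1), nc)
    out <- out | m[ys, xs, drop = FALSE]
  }
  out
}

# Count connected components of a logical matrix (8-connectivity).
mask_components <- function(m) {
  lab <- matrix(0L, nrow(m), ncol(m))
  comp <- 0L
  nr <- nrow(m); nc <- ncol(m)
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!m[i, j] || lab[i, j]) next
    comp <- comp + 1L
    queue <- list(c(i, j)); lab[i, j] <- comp
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dy in -1:1) for (dx in -1:1) {
        y <- p[1] + dy; x <- p[2] + dx
        if (y >= 1 && y <= nr && x >= 1 && x <= nc && m[y, x] && !lab[y, x]) {
          lab[y, x] <- comp
          queue[[length(queue) + 1]] <- c(y, x)
        }
      }
    }
  }
  comp
}

#' Tumor-to-clutter ratio in dB
#'
#' `20 log10` of the peak image magnitude inside the true tumor region over
#' the peak magnitude outside it. The tumor region is the ground-truth mask
#' dilated by one pixel (recorded), tolerating sub-pixel localization
#' error. A clutter-free image is guarded at a clutter floor of 1e-12 times
#' the tumor peak and flagged via the `"clutter_free"` attribute.
#'
#' @param image reconstructed `reflectivity_map` (or complex vector with
#'   `grid`).
#' @param truth_mask ground-truth tumor mask (logical vector or
#'   `segmentation_mask`), nonempty and not all-true.
#' @param grid grid reference if inputs are bare vectors.
#' @export
tumor_to_clutter_db <- function(image, truth_mask, grid = NULL) {
  if (inherits(image, "reflectivity_map")) { grid <- image$grid }
  v <- Mod(op_values(image))
  mk <- mask_values(truth_mask)
  if (length(mk) != length(v)) stop_validation("mask does not match the image")
  if (!any(mk) || all(mk)) stop_validation("truth mask must be nonempty and not all-true")
  dil <- as.vector(t(dilate1(as_image_matrix(mk, grid))))
  # as_image_matrix is byrow; undo with the transposed flatten
  tumor_peak <- max(v[dil])
  clutter_peak <- max(v[!dil])
  clutter_free <- FALSE
  floor_ <- 1e-12 * max(tumor_peak, .Machine$double.xmin)
  if (clutter_peak < floor_) { clutter_peak <- floor_; clutter_free <- TRUE }
  out <- 20 * log10(tumor_peak / clutter_peak)
  attr(out, "clutter_free") <- clutter_free
  attr(out, "dilation") <- 1L
  out
}
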