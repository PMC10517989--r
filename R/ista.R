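#' Regularized least-squares cost
#'
#' The l1-regularized data-fit objective minimized by the sparse solver:
#' `C(s) = 1/2 ||F s - S||_2^2 + lambda ||s||_1`, with complex moduli in
#' both norms.
#'
#' @param s reflectivity (complex vector or `reflectivity_map`).
#' @param S measurements (complex vector or `measurement_set`).
#' @param op a [forward_operator()].
#' @param lambda regularization weight (>= 0).
#' @export
ista_cost <- function(s, S, op, lambda) {
  sv <- op_values(s); Sv <- op_values(S)
  if (length(sv) != op$npix || length(Sv) != op$rows)
    stop_validation("shape mismatch in cost evaluation")
  if (lambda < 0) stop_validation("lambda must be >= 0")
  0.5 * sum(Mod(op$F %*% sv - Sv)^2) + lambda * sum(Mod(sv))
}

#' Complex soft-thresholding (shrinkage) operator
#'
#' Proximity operator of the l1 norm for complex vectors: shrinks each
#' entry's modulus by `t` and preserves its phase,
#' `P_t(x) = x * max(1 - t/|x|, 0)`. `t = 0` is the identity.
#'
#' @param x complex vector/matrix.
#' @param t threshold (>= 0).
#' @export
soft_threshold <- function(x, t) {
  if (!is.numeric(t) || length(t) != 1 || t < 0)
    stop_validation("threshold must be a single number >= 0")
  if (t == 0) return(x)
  m <- Mod(x)
  x * ifelse(m > t, 1 - t / pmax(m, .Machine$double.xmin), 0)
}

#' Largest-eigenvalue step size for ISTA
#'
#' Estimates `L = ||F^H F||` by power iteration (deterministic start,
#' relative tolerance 1e-6) and returns the step size `alpha = 1/L`, which
#' makes the gradient step of the forward-backward iteration non-expansive.
#'
#' @param op a [forward_operator()].
#' @param tol relative tolerance on the eigenvalue estimate.
#' @param max_iter iteration cap for the power method.
#' @return List with `alpha` and the eigenvalue estimate `L`.
#' @export
estimate_step_size <- function(op, tol = 1e-6, max_iter = 1000) {
  G <- Conj(t(op$F)) %*% op$F   # Gram cache: one matvec per power iteration
  x <- complex(real = seq_len(op$npix) %% 7 + 1,
               imaginary = seq_len(op$npix) %% 3)  # fixed, generic start
  nx <- l2norm(x)
  if (nx == 0 || sum(Mod(G)) == 0) stop("cannot estimate a step size for a zero operator")
  x <- x / nx
  L_old <- 0
  for (it in seq_len(max_iter)) {
    y <- as.vector(G %*% x)
    L <- Re(sum(Conj(x) * y))
    ny <- l2norm(y)
    if (ny == 0) stop("cannot estimate a step size for a zero operator")
    x <- y / ny
    if (it > 1 && abs(L - L_old) <= tol * abs(L)) break
    L_old <- L
  }
  list(alpha = 1 / L, L = L)
}

#' One forward-backward (ISTA) iteration
#'
#' `s_next = P_{alpha lambda}(s - alpha F^H (F s - S))`: a gradient step on
#' the quadratic data-fit term followed by soft thresholding with threshold
#' `alpha * lambda`.
#'
#' @inheritParams ista_cost
#' @param alpha step size (> 0).
#' @export
ista_step <- function(s, S, op, alpha, lambda) {
  if (alpha <= 0) stop_validation("alpha must be > 0")
  sv <- op_values(s); Sv <- op_values(S)
  if (length(sv) != op$npix || length(Sv) != op$rows)
    stop_validation("shape mismatch in ista_step")
  grad <- as.vector(Conj(t(op$F)) %*% (op$F %*% sv - Sv))
  soft_threshold(sv - alpha * grad, alpha * lambda)
}

#' ISTA solver configuration
#'
#' @param lambda l1 weight (>= 0).
#' @param alpha step size, or `"auto"` for `1/L` via [estimate_step_size()].
#' @param iterations fixed iteration count (>= 1).
#' @param init `"bp"` (backpropagation image) or `"zero"`.
#' @param tol optional relative-cost-change stopping tolerance (0 disables).
#' @export
ista_config <- function(lambda = 1e-7, alpha = "auto", iterations = 100,
                        init = c("bp", "zero"), tol = 0) {
  init <- match.arg(init)
  if (lambda < 0 || tol < 0 || iterations < 1)
    stop_validation("invalid ista_config (need lambda >= 0, iterations >= 1, tol >= 0)")
  structure(list(lambda = lambda, alpha = alpha,
                 iterations = as.integer(iterations), init = init, tol = tol),
            class = "ista_config")
}

#' Solve the l1-regularized reconstruction by forward-backward splitting
#'
#' Iterates [ista_step()] from the configured initialization, recording the
#' cost `C(s^k)` at every iteration. With `alpha <= 1/L` the cost sequence
#' is non-increasing. The Gram matrix `F^H F` is cached so each iteration is
#' an image-sized matrix-vector product and the cost comes at negligible
#' extra expense.
#'
#' @param S measurements.
#' @param op a [forward_operator()].
#' @param cfg an [ista_config()].
#' @return A `recon_result`: `image` (a `reflectivity_map`), `cost`
#'   (per-iteration), `iterations`, `alpha`, and the config echo.
#' @export
ista_solve <- function(S, op, cfg = ista_config()) {
  stopifnot(inherits(cfg, "ista_config"))
  Sv <- op_values(S)
  if (length(Sv) != op$rows) stop_validation("shape mismatch in ista_solve")
  alpha <- if (identical(cfg$alpha, "auto")) estimate_step_size(op)$alpha else cfg$alpha
  if (alpha <= 0) stop_validation("alpha must be > 0")
  Fh <- Conj(t(op$F))
  G <- Fh %*% op$F                       # npix x npix Gram cache
  b <- as.vector(Fh %*% Sv)              # F^H S
  normS2 <- sum(Mod(Sv)^2)
  s <- if (cfg$init == "bp") b else complex(length.out = op$npix)
  thr <- alpha * cfg$lambda
  cost <- numeric(0)
  for (it in seq_len(cfg$iterations)) {
    Gs <- as.vector(G %*% s)
    # ||F s - S||^2 = s^H G s - 2 Re(s^H b) + ||S||^2 via the cached Gram
    quad <- Re(sum(Conj(s) * Gs)) - 2 * Re(sum(Conj(s) * b)) + normS2
    cost[it] <- 0.5 * max(quad, 0) + cfg$lambda * sum(Mod(s))
    if (it > 1 && cost[it] > 1e6 * max(cost[1], .Machine$double.xmin))
      stop("ISTA diverged (cost grew by > 1e6x); the step size alpha is too large")
    s <- soft_threshold(s - alpha * (Gs - b), thr)
    if (cfg$tol > 0 && it > 1 &&
        abs(cost[it] - cost[it - 1]) <= cfg$tol * max(cost[it - 1], .Machine$double.xmin))
      break
  }
  structure(list(image = reflectivity_map(s, op$grid), cost = cost,
                 iterations = length(cost), alpha = alpha, config = cfg),
            class = "recon_result")
}

#' Backpropagation (delay-and-sum) image
#'
#' The conventional baseline image `F^H S`, i.e. [apply_adjoint()], with
#' optional magnitude normalization to `[0, 1]` (recorded in the result's
#' `normalized` attribute) for metric computation.
#'
#' @param S measurements.
#' @param op a [forward_operator()].
#' @param normalize scale so the maximum magnitude is 1.
#' @export
backprojection_image <- function(S, op, normalize = FALSE) {
  img <- apply_adjoint(op, S)
  if (normalize) {
    m <- max(Mod(img$values))
    if (m > 0) img$values <- img$values / m
  }
  attr(img, "normalized") <- normalize
  img
}
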