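#' Physics-initialized unrolled network
#'
#' Builds the recurrent auto-encoder obtained by unrolling the
#' forward-backward iteration: `N - 1` recurrent shrinkage layers
#' `s^{k+1} = P_{t_k}(W s^k + B S)` followed by a fixed forward-propagation
#' decoder `F`. At initialization the weights are the physics operators,
#' `W = I - alpha F^H F` and `B = alpha F^H`, and every layer threshold is
#' `alpha * lambda`, so the untrained network reproduces `N - 1` ISTA
#' iterations exactly. `W` and `B` are tied across layers (a true recurrent
#' network); only the thresholds may differ per layer. The decoder is
#' frozen: it defines the unsupervised measurement-residual loss, and
#' training it would collapse the objective.
#'
#' @param op a [forward_operator()]; becomes the frozen decoder.
#' @param n_layers total layer count N (>= 2): `N - 1` shrinkage layers plus
#'   the decoder.
#' @param alpha gradient step size (> 0), e.g. from [estimate_step_size()].
#' @param lambda l1 weight used for the threshold initialization.
#' @return An `unrolled_network` with fields `W`, `B`, `thresholds`
#'   (length `N - 1`), `n_layers`, `op` (decoder), `alpha`.
#' @export
init_from_physics <- function(op, n_layers, alpha, lambda = 1e-7) {
  if (!is.numeric(alpha) || alpha < 0) stop_validation("alpha must be >= 0")
  n_layers <- as.integer(n_layers)
  if (is.na(n_layers) || n_layers < 2) stop_validation("need n_layers >= 2")
  Fh <- Conj(t(op$F))
  W <- diag(op$npix) - alpha * (Fh %*% op$F)
  B <- alpha * Fh
  structure(list(W = W, B = B,
                 thresholds = rep(alpha * lambda, n_layers - 1),
                 n_layers = n_layers, alpha = alpha, op = op),
            class = "unrolled_network")
}

#' Run the unrolled network
#'
#' Applies the `N - 1` recurrent shrinkage layers and the fixed decoder.
#' The default initial image is the backpropagation image `F^H S`.
#'
#' @param net an `unrolled_network`.
#' @param S measurement set (complex vector or `measurement_set`).
#' @param s0 optional initial image; defaults to `F^H S`.
#' @param trace keep the per-layer iterates (for diagnostics/tests).
#' @return List with `image` (`reflectivity_map`), `reprojection`
#'   (`measurement_set` `F s`), and optionally `iterates`.
#' @export
forward_pass <- function(net, S, s0 = NULL, trace = FALSE) {
  Sv <- op_values(S)
  if (length(Sv) != net$op$rows) stop_validation("shape mismatch in forward_pass")
  s <- if (is.null(s0)) as.vector(Conj(t(net$op$F)) %*% Sv) else op_values(s0)
  if (length(s) != net$op$npix) stop_validation("initial image has wrong length")
  iterates <- if (trace) vector("list", net$n_layers - 1)
  BS <- as.vector(net$B %*% Sv)   # data injection, constant across layers
  for (k in seq_len(net$n_layers - 1)) {
    s <- soft_threshold(as.vector(net$W %*% s) + BS, net$thresholds[k])
    if (trace) iterates[[k]] <- s
  }
  out <- list(image = reflectivity_map(s, net$op$grid),
              reprojection = measurement_set(as.vector(net$op$F %*% s), net$op))
  if (trace) out$iterates <- iterates
  out
}

#' Normalized measurement-residual loss
#'
#' The unsupervised training objective and reported error metric:
#' `||F s_hat - S||_2 / ||S||_2` where `s_hat` is the network output. Zero
#' iff the reprojection matches the data exactly. If `||S|| = 0` the
#' unnormalized residual is returned with a warning.
#'
#' @inheritParams forward_pass
#' @export
network_loss <- function(net, S, s0 = NULL) {
  Sv <- op_values(S)
  fp <- forward_pass(net, Sv, s0 = s0)
  res <- l2norm(fp$reprojection$values - Sv)
  nS <- l2norm(Sv)
  if (nS == 0) {
    warning("||S|| = 0; returning the unnormalized residual")
    return(res)
  }
  res / nS
}

#' Training configuration
#'
#' @param learning_rate Adam learning rate (> 0).
#' @param epochs number of passes over the training set (>= 1).
#' @param batch_size samples per gradient update (>= 1; 1 gives per-sample
#'   stochastic updates).
#' @param seed master seed controlling shuffling (training is deterministic
#'   given the seed).
#' @param beta1,beta2,adam_eps Adam moment parameters. The default
#'   `adam_eps = 1e-3` is deliberately large: it damps the full-size
#'   normalized steps Adam would otherwise take in the many dense-parameter
#'   coordinates whose gradient is pure minibatch noise.
#' @export
training_config <- function(learning_rate = 1e-4, epochs = 6, batch_size = 10,
                            seed = 1, beta1 = 0.9, beta2 = 0.999,
                            adam_eps = 1e-3) {
  if (learning_rate <= 0) stop_validation("learning rate must be > 0")
  if (epochs < 1) stop_validation("epochs must be >= 1")
  if (batch_size < 1) stop_validation("batch size must be >= 1")
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = seed,
                 beta1 = beta1, beta2 = beta2, adam_eps = adam_eps),
            class = "training_config")
}

# Gradient of the per-sample loss w.r.t. W, B, thresholds and (Wirtinger
# conjugate-cogradient) intermediate images. Complex parameters are treated
# as independent real and imaginary parts; for a real loss L the descent
# gradient of the real part of a parameter is 2*Re(dL/d conj(p)) and of the
# imaginary part 2*Im(dL/d conj(p)). Returns dL/d conj(.) for W and B and
# the exact real gradient for the thresholds.
network_gradients <- function(net, Sv, s0 = NULL) {
  Fm <- net$op$F
  Fh <- Conj(t(Fm))
  Wh <- Conj(t(net$W))
  nL <- net$n_layers - 1
  npix <- net$op$npix
  s <- if (is.null(s0)) as.vector(Fh %*% Sv) else op_values(s0)
  inputs <- matrix(0i, npix, nL)  # layer inputs s^{k-1}
  pre <- matrix(0i, npix, nL)     # pre-activations u^k
  BS <- as.vector(net$B %*% Sv)
  for (k in seq_len(nL)) {
    inputs[, k] <- s
    u <- as.vector(net$W %*% s) + BS
    pre[, k] <- u
    s <- soft_threshold(u, net$thresholds[k])
  }
  nS <- l2norm(Sv)
  r <- as.vector(Fm %*% s) - Sv
  nr <- l2norm(r)
  loss <- if (nS > 0) nr / nS else nr
  # dL/d conj(r) for L = ||r|| / ||S||
  g <- if (nr > 0) r / (2 * nr * if (nS > 0) nS else 1) else r * 0
  gs <- as.vector(Fh %*% g)               # dL/d conj(s^{N-1})
  gus <- matrix(0i, npix, nL)
  gt <- numeric(nL)
  tiny <- .Machine$double.xmin
  for (k in rev(seq_len(nL))) {
    u <- pre[, k]; t_k <- net$thresholds[k]
    m <- pmax(Mod(u), tiny)
    active <- m > max(t_k, 0) & Mod(u) > 0
    phase <- ifelse(active, u / m, 0i)
    gt[k] <- -2 * Re(sum(Conj(gs[active]) * phase[active]))
    if (t_k > 0) {
      # Wirtinger derivatives of the modulus-shrinkage activation
      a <- ifelse(active, 1 - t_k / (2 * m), 0)
      b <- ifelse(active, t_k * u^2 / (2 * m^3), 0i)
      gu <- a * gs + b * Conj(gs)
    } else {
      gu <- gs       # t = 0: identity activation
    }
    gus[, k] <- gu
    gs <- as.vector(Wh %*% gu)
  }
  # one GEMM accumulates all layer outer products; B sees the same S at
  # every layer so its gradient is a single rank-1 term
  gW <- gus %*% Conj(t(inputs))
  gB <- matrix(rowSums(gus), ncol = 1) %*% matrix(Conj(Sv), nrow = 1)
  list(gW = gW, gB = gB, gt = gt, loss = loss)
}

adam_state <- function(dim) {
  list(m = array(0, dim), v = array(0, dim), t = 0L)
}

adam_update <- function(state, grad, cfg) {
  state$t <- state$t + 1L
  state$m <- cfg$beta1 * state$m + (1 - cfg$beta1) * grad
  state$v <- cfg$beta2 * state$v + (1 - cfg$beta2) * grad^2
  mh <- state$m / (1 - cfg$beta1^state$t)
  vh <- state$v / (1 - cfg$beta2^state$t)
  state$step <- cfg$learning_rate * mh / (sqrt(vh) + cfg$adam_eps)
  state
}

#' Train the unrolled network on measurement residuals
#'
#' Unsupervised training: minimizes the mean normalized residual
#' `||F s_hat - S|| / ||S||` over the training measurements by Adam,
#' updating the tied operators `W` and `B` and the per-layer thresholds
#' while the decoder `F` stays frozen. Gradients of the complex operators
#' follow the real-parameterization of their real and imaginary parts.
#' Thresholds are clamped at 0 after every update. Deterministic given the
#' config seed (fixed shuffling).
#'
#' @param net an `unrolled_network` (typically from [init_from_physics()]).
#' @param train_data list of samples, each with a measurement set `$S`.
#' @param cfg a [training_config()].
#' @param test_data optional held-out samples for a per-epoch test loss.
#' @return List with the trained `net` and a `history` data frame (one row
#'   per epoch: mean train loss, mean test loss, wall seconds), plus the
#'   initial (untrained) mean test loss `test_loss0`.
#' @export
train_network <- function(net, train_data, cfg = training_config(),
                          test_data = NULL) {
  stopifnot(inherits(net, "unrolled_network"), inherits(cfg, "training_config"))
  n <- length(train_data)
  if (n == 0) stop_validation("training set is empty")
  mW <- vW <- rep(0i, length(net$W)); tW <- 0L
  mB <- vB <- rep(0i, length(net$B)); tB <- 0L
  stT <- adam_state(length(net$thresholds))
  test_loss0 <- if (!is.null(test_data))
    mean(vapply(test_data, function(sm) network_loss(net, sm$S), 0)) else NA_real_
  hist <- data.frame(epoch = seq_len(cfg$epochs), train_loss = NA_real_,
                     test_loss = NA_real_, seconds = NA_real_)
  for (ep in seq_len(cfg$epochs)) {
    t0 <- proc.time()[["elapsed"]]
    order_ep <- with_seed(seed_for(cfg$seed, paste0("epoch", ep)), sample.int(n))
    batches <- split(order_ep, ceiling(seq_along(order_ep) / cfg$batch_size))
    ep_losses <- numeric(0)
    for (bt in batches) {
      gW <- NULL; gB <- NULL; gt <- 0
      for (idx in bt) {
        gr <- network_gradients(net, op_values(train_data[[idx]]$S))
        if (!is.finite(gr$loss))
          stop("non-finite training loss; reduce the learning rate")
        gW <- if (is.null(gW)) gr$gW else gW + gr$gW
        gB <- if (is.null(gB)) gr$gB else gB + gr$gB
        gt <- gt + gr$gt
        ep_losses <- c(ep_losses, gr$loss)
      }
      nb <- length(bt)
      # fused Adam on the real-parameterized complex operators
      tW <- tW + 1L
      up <- adam_step_complex(net$W, mW, vW, gW, cfg$learning_rate,
                              cfg$beta1, cfg$beta2, cfg$adam_eps, tW, 1 / nb)
      net$W <- matrix(up$param, nrow(net$W)); mW <- up$m; vW <- up$v
      tB <- tB + 1L
      up <- adam_step_complex(net$B, mB, vB, gB, cfg$learning_rate,
                              cfg$beta1, cfg$beta2, cfg$adam_eps, tB, 1 / nb)
      net$B <- matrix(up$param, nrow(net$B)); mB <- up$m; vB <- up$v
      stT <- adam_update(stT, gt / nb, cfg)
      net$thresholds <- pmax(net$thresholds - stT$step, 0)
    }
    hist$train_loss[ep] <- mean(ep_losses)
    if (!is.null(test_data))
      hist$test_loss[ep] <- mean(vapply(test_data, function(sm)
        network_loss(net, sm$S), 0))
    hist$seconds[ep] <- proc.time()[["elapsed"]] - t0
  }
  list(net = net, history = hist, test_loss0 = test_loss0, config = cfg)
}

#' Evaluate a network on a dataset
#'
#' @param net an `unrolled_network`.
#' @param data list of samples with measurement sets `$S`.
#' @return List with per-sample `losses`, `images` (reconstructions) and the
#'   arithmetic `mean_loss`.
#' @export
evaluate_network <- function(net, data) {
  if (length(data) == 0) stop_validation("dataset is empty")
  images <- vector("list", length(data))
  losses <- numeric(length(data))
  for (i in seq_along(data)) {
    fp <- forward_pass(net, data[[i]]$S)
    Sv <- op_values(data[[i]]$S)
    nS <- l2norm(Sv)
    losses[i] <- l2norm(fp$reprojection$values - Sv) / if (nS > 0) nS else 1
    images[[i]] <- fp$image
  }
  list(losses = losses, images = images, mean_loss = mean(losses))
}

#' Save a trained network as a JSON container
#'
#' Stores `W`, `B`, the per-layer thresholds, the decoder geometry echo and
#' the training seed, as paired re/im arrays in plain text.
#'
#' @param net an `unrolled_network`.
#' @param path output path.
#' @param seed optional seed echo.
#' @export
save_network <- function(net, path, seed = NULL) {
  obj <- list(W = complex_to_json(net$W), B = complex_to_json(net$B),
              thresholds = net$thresholds, n_layers = net$n_layers,
              alpha = net$alpha,
              decoder_ref = list(rows = net$op$rows, npix = net$op$npix,
                                 mode = net$op$scan$mode),
              seed = seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_network
#' @param op the [forward_operator()] to rebind as the decoder.
#' @export
load_network <- function(path, op) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  structure(list(W = complex_from_json(obj$W), B = complex_from_json(obj$B),
                 thresholds = unlist(obj$thresholds),
                 n_layers = as.integer(obj$n_layers), alpha = obj$alpha,
                 op = op),
            class = "unrolled_network")
}
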