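test_that("the physics-initialized network reproduces ISTA layer by layer", {
  set.seed(19)
  for (i in 1:20) {
    op <- tiny_op(n = c(4, 2), n_pos = sample(5:9, 1), n_freq = sample(3:5, 1))
    al <- estimate_step_size(op)$alpha
    lam <- runif(1, 1e-4, 0.1)
    nl <- sample(3:6, 1)
    net <- init_from_physics(op, nl, al, lam)
    S <- complex(real = rnorm(op$rows), imaginary = rnorm(op$rows))
    fp <- forward_pass(net, S, trace = TRUE)
    s <- as.vector(Conj(t(op$F)) %*% S)
    worst <- 0
    for (k in seq_len(nl - 1)) {
      s <- ista_step(s, S, op, al, lam)
      worst <- max(worst, max(Mod(fp$iterates[[k]] - s)))
    }
    expect_lt(worst, 1e-10)
    expect_equal(fp$reprojection$values, as.vector(op$F %*% s), tolerance = 1e-12)
  }
})

test_that("degenerate initializations behave as dictated by the layer map", {
  op <- tiny_op()
  # alpha = 0: W = I, B = 0; the output ignores the data entirely
  net0 <- init_from_physics(op, 4, 0, 0.5)
  expect_equal(net0$W, diag(op$npix) + 0i)
  expect_true(all(net0$B == 0))
  s0 <- random_reflectivity(op, 2)$values
  fp <- forward_pass(net0, random_measurement(op, 3), s0 = s0)
  expect_equal(fp$image$values, soft_threshold(s0, 0), tolerance = 1e-12)
  # N = 2: exactly one shrinkage layer before the decoder
  net2 <- init_from_physics(op, 2, 0.1, 0.01)
  expect_length(net2$thresholds, 1)
  expect_error(init_from_physics(op, 1, 0.1), "n_layers")
  # zero data from a zero start stays zero
  netp <- init_from_physics(op, 5, 0.1, 0.01)
  fp0 <- forward_pass(netp, rep(0i, op$rows), s0 = rep(0i, op$npix))
  expect_true(all(fp0$image$values == 0) && all(fp0$reprojection$values == 0))
})

test_that("zero thresholds unroll to the closed-form gradient-descent recursion", {
  op <- tiny_op(n = c(3, 2), n_pos = 6, n_freq = 3)
  al <- estimate_step_size(op)$alpha
  net <- init_from_physics(op, 5, al, 0)   # lambda = 0: thresholds all 0
  S <- random_measurement(op, 21)$values
  K <- diag(op$npix) - al * (Conj(t(op$F)) %*% op$F)
  b <- al * as.vector(Conj(t(op$F)) %*% S)
  s <- as.vector(Conj(t(op$F)) %*% S)
  for (k in 1:4) s <- as.vector(K %*% s) + b
  expect_equal(forward_pass(net, S)$image$values, s, tolerance = 1e-10)
})

test_that("the loss is the normalized measurement residual", {
  op <- tiny_op()
  al <- estimate_step_size(op)$alpha
  net <- init_from_physics(op, 4, al, 1e-6)
  S <- random_measurement(op, 30)
  fp <- forward_pass(net, S)
  oracle <- sqrt(sum(Mod(fp$reprojection$values - S$values)^2)) /
    sqrt(sum(Mod(S$values)^2))
  expect_equal(network_loss(net, S), oracle, tolerance = 1e-12)
  # a network forced to output zero has unit normalized loss
  netz <- net; netz$thresholds[] <- 1e9
  expect_equal(network_loss(netz, S), 1, tolerance = 1e-12)
  expect_warning(l0 <- network_loss(net, rep(0i, op$rows)), "unnormalized")
  expect_equal(l0, 0)
})

test_that("analytic gradients match central finite differences", {
  op <- tiny_op(n = c(5, 1), n_pos = 4, n_freq = 3)  # 5-pixel instance
  al <- estimate_step_size(op)$alpha
  net <- init_from_physics(op, 4, al, 1e-3)
  net$thresholds <- c(0.02, 0.05, 0.03)
  S <- random_measurement(op, 17)
  gr <- deeptmi:::network_gradients(net, S$values)
  h <- 1e-6
  fd <- function(mutate) {
    np <- mutate(net, h); nm <- mutate(net, -h)
    (network_loss(np, S) - network_loss(nm, S)) / (2 * h)
  }
  for (k in seq_along(net$thresholds)) {
    num <- fd(function(n, d) { n$thresholds[k] <- n$thresholds[k] + d; n })
    expect_lt(abs(gr$gt[k] - num) / max(abs(num), 1e-8), 1e-4)
  }
  for (ij in list(c(1, 1), c(3, 4), c(5, 2))) {
    num_re <- fd(function(n, d) { n$W[ij[1], ij[2]] <- n$W[ij[1], ij[2]] + d; n })
    num_im <- fd(function(n, d) { n$W[ij[1], ij[2]] <- n$W[ij[1], ij[2]] + 1i * d; n })
    expect_lt(abs(2 * Re(gr$gW[ij[1], ij[2]]) - num_re) / max(abs(num_re), 1e-8), 1e-4)
    expect_lt(abs(2 * Im(gr$gW[ij[1], ij[2]]) - num_im) / max(abs(num_im), 1e-8), 1e-4)
  }
  ij <- c(2, 7)
  num_re <- fd(function(n, d) { n$B[ij[1], ij[2]] <- n$B[ij[1], ij[2]] + d; n })
  expect_lt(abs(2 * Re(gr$gB[ij[1], ij[2]]) - num_re) / max(abs(num_re), 1e-8), 1e-4)
})

test_that("training is deterministic, keeps thresholds nonnegative, and does not
           degrade the physics initialization on noise-free data", {
  cfg <- small_sim_cfg()
  cfg$phase_error <- phase_error_spec(0)    # noise-free
  op <- forward_operator(cfg$grid, cfg$scan, cfg$sweep)
  ds <- generate_dataset(deeptmi:::spec_from_preset(cfg, 8, "train", 2), op)
  al <- estimate_step_size(op)$alpha
  net <- init_from_physics(op, 5, al, cfg$lambda)
  tc <- training_config(epochs = 2, batch_size = 4, seed = 9)
  tr1 <- train_network(net, ds$samples, tc, test_data = ds$samples[1:2])
  tr2 <- train_network(net, ds$samples, tc, test_data = ds$samples[1:2])
  expect_identical(tr1$net$thresholds, tr2$net$thresholds)
  expect_identical(tr1$net$W, tr2$net$W)
  expect_true(all(tr1$net$thresholds >= 0))
  expect_equal(nrow(tr1$history), 2)
  # training must not make the (already strong) physics solver worse
  before <- mean(vapply(ds$samples, function(sm) network_loss(net, sm$S), 0))
  after <- mean(vapply(ds$samples, function(sm) network_loss(tr1$net, sm$S), 0))
  expect_lte(after, before + 1e-3)
})

test_that("training reduces the residual on systematically corrupted data", {
  cfg <- small_sim_cfg()
  op <- forward_operator(cfg$grid, cfg$scan, cfg$sweep)
  ds <- generate_dataset(deeptmi:::spec_from_preset(cfg, 20, "train", 4), op)
  ts <- generate_dataset(deeptmi:::spec_from_preset(cfg, 6, "test", 4), op)
  al <- estimate_step_size(op)$alpha
  net <- init_from_physics(op, cfg$n_layers, al, cfg$lambda)
  tr <- train_network(net, ds$samples,
                      training_config(epochs = 6, batch_size = 10, seed = 4),
                      test_data = ts$samples)
  expect_lt(tr$history$train_loss[6], tr$history$train_loss[1])
  expect_false(any(is.na(tr$history$test_loss)))
})

test_that("evaluation returns one loss and one image per sample", {
  op <- tiny_op()
  al <- estimate_step_size(op)$alpha
  net <- init_from_physics(op, 4, al, 1e-6)
  sm <- list(S = random_measurement(op, 5))
  ev <- evaluate_network(net, list(sm, sm, sm))
  expect_length(ev$losses, 3)
  expect_length(ev$images, 3)
  expect_equal(ev$mean_loss, ev$losses[1])  # duplicated sample
  expect_equal(ev$losses[1], network_loss(net, sm$S), tolerance = 1e-12)
  expect_error(evaluate_network(net, list()), "empty")
})

test_that("networks round-trip through the JSON container", {
  op <- tiny_op()
  net <- init_from_physics(op, 3, 0.2, 1e-4)
  path <- withr::local_tempfile(fileext = ".json")
  save_network(net, path, seed = 7)
  back <- load_network(path, op)
  expect_equal(back$W, net$W)
  expect_equal(back$B, net$B)
  expect_equal(back$thresholds, net$thresholds)
  expect_equal(back$n_layers, net$n_layers)
})
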