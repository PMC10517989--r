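test_that("the regularized cost matches a direct summation oracle", {
  op <- tiny_op()
  s <- random_reflectivity(op, 1)
  S <- random_measurement(op, 2)
  expect_equal(ista_cost(rep(0i, op$npix), S, op, 0.3),
               0.5 * sum(Mod(S$values)^2), tolerance = 1e-12)
  Sf <- apply_forward(op, s)
  expect_equal(ista_cost(s, Sf, op, 0), 0, tolerance = 1e-12)
  lam <- 0.17
  oracle <- 0.5 * sum(vapply(seq_len(op$rows), function(m)
    Mod(sum(op$F[m, ] * s$values) - S$values[m])^2, 0)) +
    lam * sum(vapply(s$values, Mod, 0))
  got <- ista_cost(s, S, op, lam)
  expect_lt(abs(got - oracle) / oracle, 1e-12)
  expect_error(ista_cost(s, rep(0i, 3), op, 0.1), "mismatch")
  expect_error(ista_cost(s, S, op, -1), "lambda")
})

test_that("soft thresholding is the complex l1 proximity operator", {
  expect_equal(soft_threshold(0.5 + 0i, 1), 0 + 0i)
  expect_equal(soft_threshold(3 + 0i, 1), 2 + 0i)
  phi <- 1.1
  expect_equal(soft_threshold(4 * exp(1i * phi), 1), 3 * exp(1i * phi),
               tolerance = 1e-12)
  # brute-force proximal oracle: argmin over u of 1/2|u - x|^2 + t|u|
  x <- 1.3 - 0.9i; t <- 0.6
  gr <- seq(-2, 2, length.out = 481)
  u <- outer(gr, 1i * gr, `+`)
  objective <- 0.5 * Mod(u - x)^2 + t * Mod(u)
  u_best <- u[which.min(objective)]
  expect_lt(Mod(soft_threshold(x, t) - u_best), 2e-2)  # grid resolution
  # identity at t = 0, zero fixed point, validation
  z <- complex(real = rnorm(5), imaginary = rnorm(5))
  expect_identical(soft_threshold(z, 0), z)
  expect_equal(soft_threshold(0i, 2), 0i)
  expect_error(soft_threshold(z, -0.1), ">= 0")
})

test_that("soft thresholding is non-expansive", {
  set.seed(8)
  for (i in 1:20) {
    x <- complex(real = rnorm(12), imaginary = rnorm(12))
    y <- complex(real = rnorm(12), imaginary = rnorm(12))
    t <- runif(1, 0, 2)
    expect_lte(sqrt(sum(Mod(soft_threshold(x, t) - soft_threshold(y, t))^2)),
               sqrt(sum(Mod(x - y)^2)) + 1e-12)
  }
})

test_that("the power-iteration step size matches dense eigenvalue oracles", {
  g <- imaging_grid(c(1, 1), c(2, 2))
  mk <- function(Fm) {
    op <- tiny_op()
    op$F <- Fm; op$rows <- nrow(Fm); op$npix <- ncol(Fm)
    op
  }
  # orthonormal columns: L = 1
  q <- qr.Q(qr(matrix(rnorm(24), 6, 4)))
  expect_equal(estimate_step_size(mk(q + 0i))$alpha, 1, tolerance = 1e-6)
  # F = 2 I: L = 4, alpha = 1/4
  expect_equal(estimate_step_size(mk(2 * diag(4) + 0i))$alpha, 0.25,
               tolerance = 1e-6)
  # random complex 20 x 12 vs dense eigendecomposition
  set.seed(5)
  Fm <- matrix(complex(real = rnorm(240), imaginary = rnorm(240)), 20, 12)
  L_true <- max(eigen(Conj(t(Fm)) %*% Fm, only.values = TRUE)$values)
  expect_equal(estimate_step_size(mk(Fm))$alpha, 1 / Re(L_true), tolerance = 1e-5)
  expect_error(estimate_step_size(mk(matrix(0i, 4, 4))), "zero operator")
})

test_that("one ISTA step is a gradient step followed by shrinkage", {
  op <- tiny_op()
  s <- random_reflectivity(op, 3)
  S <- apply_forward(op, s)
  al <- estimate_step_size(op)$alpha
  # exact-data fixed point with no regularization
  expect_equal(ista_step(s, S, op, al, 0), s$values, tolerance = 1e-12)
  # lambda = 0 reduces to plain gradient descent
  S2 <- random_measurement(op, 9)
  grad <- as.vector(Conj(t(op$F)) %*% (op$F %*% s$values - S2$values))
  expect_equal(ista_step(s, S2, op, al, 0), s$values - al * grad,
               tolerance = 1e-12)
})

test_that("the iteration and its unrolled layer form are algebraically identical", {
  op <- tiny_op()
  set.seed(31)
  for (i in 1:10) {
    s <- complex(real = rnorm(op$npix), imaginary = rnorm(op$npix))
    S <- complex(real = rnorm(op$rows), imaginary = rnorm(op$rows))
    alpha <- runif(1, 0.05, 1.5)
    lambda <- runif(1, 0, 0.5)
    lhs <- ista_step(s, S, op, alpha, lambda)
    K <- diag(op$npix) - alpha * (Conj(t(op$F)) %*% op$F)
    rhs <- soft_threshold(as.vector(K %*% s) +
                            alpha * as.vector(Conj(t(op$F)) %*% S),
                          alpha * lambda)
    expect_lt(max(Mod(lhs - rhs)), 1e-12)
  }
})

test_that("ISTA cost is monotone with the estimated step size", {
  set.seed(77)
  for (i in 1:50) {
    op <- tiny_op(n = c(4, 2), n_pos = sample(4:10, 1), n_freq = sample(2:5, 1))
    S <- complex(real = rnorm(op$rows), imaginary = rnorm(op$rows))
    res <- ista_solve(S, op, ista_config(lambda = runif(1, 0, 0.3),
                                         iterations = 40))
    expect_true(all(diff(res$cost) <= 1e-10))
  }
})

test_that("ISTA with lambda = 0 reaches the least-squares solution", {
  op <- tiny_op(n = c(3, 2), n_pos = 10, n_freq = 4)  # overdetermined 40 x 6
  S <- random_measurement(op, 4)
  res <- ista_solve(S, op, ista_config(lambda = 0, iterations = 4000, tol = 0))
  normal_eq <- solve(Conj(t(op$F)) %*% op$F,
                     as.vector(Conj(t(op$F)) %*% S$values))
  expect_lt(max(Mod(res$image$values - normal_eq)), 1e-6)
  expect_equal(res$iterations, 4000)
  expect_length(res$cost, 4000)
})

test_that("a sparse target's support is recovered from noise-free data", {
  op <- tiny_op(n = c(4, 3), n_pos = 12, n_freq = 4)   # 48 x 12
  truth <- rep(0i, op$npix); truth[7] <- 2 - 1i
  S <- apply_forward(op, reflectivity_map(truth, op$grid))
  res <- ista_solve(S, op, ista_config(lambda = 1e-4, iterations = 800))
  support <- which(Mod(res$image$values) > 0.5 * max(Mod(res$image$values)))
  expect_equal(support, 7L)
  # zero data gives the zero image
  res0 <- ista_solve(rep(0i, op$rows), op, ista_config(iterations = 5))
  expect_equal(res0$image$values, rep(0i, op$npix))
})

test_that("a fixed point of ista_step minimizes the convex objective", {
  op <- tiny_op(n = c(5, 2), n_pos = 6, n_freq = 3)
  S <- random_measurement(op, 12)
  lam <- 0.05
  res <- ista_solve(S, op, ista_config(lambda = lam, iterations = 3000))
  al <- res$alpha
  s_star <- res$image$values
  moved <- ista_step(s_star, S, op, al, lam)
  expect_lt(max(Mod(moved - s_star)), 1e-6)
  # no feasible perturbation lowers the cost
  c_star <- ista_cost(s_star, S, op, lam)
  set.seed(2)
  for (i in 1:20) {
    pert <- s_star + 1e-3 * complex(real = rnorm(op$npix),
                                    imaginary = rnorm(op$npix))
    expect_gte(ista_cost(pert, S, op, lam), c_star - 1e-12)
  }
})

test_that("divergent step sizes are reported as such", {
  op <- tiny_op()
  S <- random_measurement(op, 1)
  expect_error(ista_solve(S, op, ista_config(lambda = 0, alpha = 50,
                                             iterations = 300)),
               "step size")
})

test_that("the backpropagation image is the adjoint, optionally normalized", {
  op <- tiny_op()
  S <- random_measurement(op, 6)
  bp <- backprojection_image(S, op)
  expect_equal(bp$values, apply_adjoint(op, S)$values)
  bpn <- backprojection_image(S, op, normalize = TRUE)
  expect_equal(max(Mod(bpn$values)), 1)
  expect_true(attr(bpn, "normalized"))
  expect_equal(backprojection_image(rep(0i, op$rows), op)$values,
               rep(0i, op$npix))
})
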