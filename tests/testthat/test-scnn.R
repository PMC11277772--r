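test_that("bicubic upscaling preserves shape, constants and smoothness", {
  img <- matrix(runif(64), 8, 8)
  up <- bicubic_upscale(img, 2)
  expect_identical(dim(up), c(16L, 16L))

  const <- matrix(3.7, 8, 8)
  expect_lt(max(abs(bicubic_upscale(const, 3) - 3.7)), 1e-9)

  # a smooth ramp survives down/up-scaling far better than a shuffled one
  ramp <- outer(seq(0, 1, length.out = 32), seq(0, 1, length.out = 32), `+`)
  set.seed(1)
  shuffled <- matrix(sample(ramp), 32, 32)
  roundtrip <- function(x) {
    mean((bicubic_upscale(degrade_pair(x, 2, 0)$low, 2) - x)^2)
  }
  expect_lt(roundtrip(ramp), roundtrip(shuffled) / 10)
  expect_error(bicubic_upscale(img, 5), "factor")
})

test_that("convolution matches an explicit quadruple-loop oracle", {
  ident <- array(1, c(1, 1, 1, 1))
  x <- matrix(runif(25), 5, 5)
  out <- conv_relu(x, ident, 0, relu = FALSE)
  expect_equal(out[, , 1], x)

  negf <- array(-1, c(1, 1, 1, 1))
  expect_true(all(conv_relu(x, negf, 0, relu = TRUE) == 0))

  set.seed(3)
  xa <- array(runif(5 * 5 * 2), c(5, 5, 2))
  filt <- array(rnorm(3 * 3 * 2 * 4), c(3, 3, 2, 4))
  bias <- rnorm(4)
  got <- conv_relu(xa, filt, bias, relu = FALSE)
  oracle <- array(0, c(3, 3, 4))
  for (oc in 1:4) for (i in 1:3) for (j in 1:3) {
    acc <- bias[oc]
    for (ic in 1:2) for (di in 1:3) for (dj in 1:3) {
      acc <- acc + xa[i + di - 1, j + dj - 1, ic] * filt[di, dj, ic, oc]
    }
    oracle[i, j, oc] <- acc
  }
  expect_equal(got, oracle, tolerance = 1e-10)
  expect_error(conv_relu(x, array(1, c(2, 2, 1, 1))), "odd")
})

test_that("soft thresholding shrinks with the positive-part clamp", {
  expect_equal(soft_threshold(1.2, 0.5), 0.7)
  expect_equal(soft_threshold(-0.3, 0.5), 0)
  expect_equal(soft_threshold(-2.0, 0.5), -1.5)
  expect_equal(soft_threshold(c(1, -1), c(0.25, 0.5)), c(0.75, -0.5))
  expect_error(soft_threshold(1, -0.1), "nonnegative")
})

test_that("one ISTA step on an orthonormal dictionary solves the lasso", {
  code <- ista_sparse_code(c(1.0, 0.2), diag(2), alpha = 0.5, k_iters = 1,
                           L = 1)
  expect_equal(code, c(0.5, 0), tolerance = 1e-10)

  # full shrinkage when alpha dominates the correlations
  set.seed(4)
  D <- matrix(rnorm(12), 4, 3)
  x <- rnorm(4)
  big <- max(abs(crossprod(D, x))) * (1 + 1e-6)
  expect_true(all(ista_sparse_code(x, D, big, 5) == 0))

  # the lasso objective never increases along the iterates
  for (i in 1:20) {
    set.seed(i)
    D <- matrix(rnorm(30), 5, 6)
    x <- rnorm(5)
    L <- lipschitz_bound(D)
    objs <- vapply(1:8, function(k)
      lasso_objective(x, D, ista_sparse_code(x, D, 0.1, k, L), 0.1),
      numeric(1))
    expect_true(all(diff(objs) <= 1e-12))
  }
  expect_error(ista_sparse_code(c(1, 2), matrix(0, 2, 2), 0.1), "zero")
})

test_that("many ISTA iterations reach the proximal-gradient fixed point", {
  # independent reference: plain proximal gradient with its own step size,
  # run to convergence
  ref_solver <- function(x, D, alpha) {
    L <- max(eigen(crossprod(D), symmetric = TRUE)$values)
    c0 <- rep(0, ncol(D))
    for (i in 1:5000) {
      g <- crossprod(D, D %*% c0 - x)
      c1 <- sign(c0 - g / L) * pmax(abs(c0 - g / L) - alpha / L, 0)
      if (max(abs(c1 - c0)) < 1e-12) break
      c0 <- c1
    }
    as.vector(c0)
  }
  for (i in 1:5) {
    set.seed(i)
    D <- matrix(rnorm(24), 6, 4) + 2 * diag(6)[, 1:4] # well-conditioned
    x <- rnorm(6)
    mine <- ista_sparse_code(x, D, 0.2, k_iters = 3000)
    expect_equal(mine, ref_solver(x, D, 0.2), tolerance = 1e-6)
  }
})

test_that("the Lipschitz bound dominates the Gram spectrum", {
  for (i in 1:5) {
    set.seed(i)
    D <- matrix(rnorm(40), 8, 5)
    L <- lipschitz_bound(D)
    lam <- max(eigen(crossprod(D), symmetric = TRUE)$values)
    expect_gte(L, lam - 1e-9)
    expect_lt(L, lam * 1.01)
  }
})

test_that("initialization follows the stated scheme", {
  cf <- scnn_config(f1 = 9, n1 = 128, m = 32, n2 = 16, nh = 16, f4 = 5)
  p <- init_params(cf, seed = 5)
  expect_true(all(p$b1 == 0) && all(p$b3 == 0) && p$b4 == 0)
  w <- c(as.vector(p$F1), as.vector(p$F3), as.vector(p$F4))
  expect_gt(length(w), 1e4)
  expect_gt(stats::sd(w), 0.0005)
  expect_lt(stats::sd(w), 0.0015)
  expect_equal(unname(colSums(p$Dlow^2)), rep(1, 32), tolerance = 1e-12)
  expect_identical(init_params(cf, seed = 5)[1:9], p[1:9])
})

test_that("the forward pass keeps shape, constants and determinism", {
  cf <- tiny_scnn_config()
  p <- init_params(cf, seed = 6)
  low <- matrix(runif(16 * 16, 0, 255), 16, 16)
  out <- scnn_forward(low, p)
  expect_identical(dim(out), c(32L, 32L))
  expect_identical(scnn_forward(low, p), out)

  # if every patch prediction is the constant c, averaging returns c
  pc <- p
  pc$F1 <- pc$F1 * 0; pc$F4 <- pc$F4 * 0
  pc$b4 <- 0.25
  outc <- scnn_forward(low, pc)
  expect_lt(max(abs(outc - 0.25 * cf$peak)), 1e-9)
})

test_that("the analytic gradient matches central finite differences", {
  cf <- tiny_scnn_config()
  params <- init_params(cf, seed = 42)
  set.seed(7)
  blocks <- c("F1", "b1", "Dlow", "F3", "b3", "DHigh", "F4", "b4")
  for (b in blocks) {
    params[[b]] <- params[[b]] + rnorm(length(params[[b]]), 0, 0.5)
  }
  params$alpha <- 0.3
  params$L <- lipschitz_bound(params$Dlow)
  patch <- matrix(runif(64), 8, 8)
  target <- matrix(runif(64), 8, 8)
  g <- pulmotex:::scnn_patch_grad(patch, target, params)
  eps <- 1e-6
  for (b in c(blocks, "alpha")) {
    th <- params[[b]]
    idxs <- sample(length(th), min(length(th), 10))
    for (i in idxs) {
      pp <- params; pp[[b]][i] <- th[i] + eps
      pm <- params; pm[[b]][i] <- th[i] - eps
      fd <- (pulmotex:::scnn_patch_grad(patch, target, pp)$loss -
             pulmotex:::scnn_patch_grad(patch, target, pm)$loss) / (2 * eps)
      an <- g$grads[[b]][i]
      expect_lt(abs(fd - an) / max(1e-8, abs(fd) + abs(an)), 1e-4)
    }
  }
})

test_that("mse loss and training contracts hold", {
  a <- matrix(1, 4, 4)
  expect_equal(mse_loss(a, a), 0)
  expect_equal(mse_loss(a, a + 1), 1)
  half <- a; half[1:8] <- a[1:8] + 2
  expect_equal(mse_loss(half, a), 2)
  expect_error(mse_loss(a, matrix(1, 2, 2)), "shape")

  cf <- tiny_scnn_config()
  set.seed(8)
  imgs <- lapply(1:2, function(i) generate_phantom("benign", 64, i)$image)
  pairs <- make_patch_pairs(imgs, cf, noise_sd = 5, seed = 9,
                            max_pairs = 20)
  # zero learning rate: the loss trace is exactly constant
  tr0 <- train_scnn(pairs, cf, seed = 10, epochs = 3, lr = 0)
  expect_equal(diff(tr0$trace), rep(0, 3))
  # same seed and config: identical trace
  tr1 <- train_scnn(pairs, cf, seed = 11, epochs = 2)
  tr2 <- train_scnn(pairs, cf, seed = 11, epochs = 2)
  expect_identical(tr1$trace, tr2$trace)
  expect_error(train_scnn(structure(list(low = pairs$low[1:4],
                                         high = pairs$high[1:4]),
                                    class = "patch_set"), cf),
               "at least 16")
})
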