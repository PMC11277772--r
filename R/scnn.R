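#' Bicubic image upscaling
#'
#' Separable cubic-convolution interpolation (Keys kernel, a = -0.5) with
#' centre-aligned sampling and edge replication.  Constant images map to
#' the same constant because the kernel weights sum to one at every
#' sampling phase.
#'
#' @param image numeric matrix.
#' @param factor integer upscale factor, 2, 3 or 4.
#' @return matrix of dimensions `factor * dim(image)`.
#' @export
bicubic_upscale <- function(image, factor = 2L) {
  if (!factor %in% 2:4) stop("`factor` must be 2, 3 or 4")
  wr <- bicubic_weights(nrow(image), factor)
  wc <- bicubic_weights(ncol(image), factor)
  out <- wr %*% image %*% t(wc)
  attr(out, "bit_depth") <- attr(image, "bit_depth")
  out
}

bicubic_kernel <- function(s, a = -0.5) {
  s <- abs(s)
  ifelse(s <= 1, (a + 2) * s^3 - (a + 3) * s^2 + 1,
         ifelse(s < 2, a * s^3 - 5 * a * s^2 + 8 * a * s - 4 * a, 0))
}

# dense (n*factor) x n interpolation operator with replicated edges
bicubic_weights <- function(n, factor) {
  m <- n * factor
  W <- matrix(0, m, n)
  for (i in seq_len(m)) {
    src <- (i - 0.5) / factor + 0.5 # centre-aligned source coordinate
    base <- floor(src)
    for (k in (base - 1):(base + 2)) {
      w <- bicubic_kernel(src - k)
      kk <- min(max(k, 1), n) # edge replication
      W[i, kk] <- W[i, kk] + w
    }
  }
  W
}

#' Valid cross-correlation with optional ReLU
#'
#' Multi-channel 2-D cross-correlation (no kernel flip) plus bias,
#' followed by `max(0, .)` when `relu` is set.  Input may be a matrix
#' (single channel) or an `H x W x C` array; filters are
#' `f x f x C_in x C_out`.
#'
#' @param input matrix or 3-D array.
#' @param filters 4-D filter array with odd spatial size.
#' @param biases numeric vector of length `C_out`.
#' @param relu apply the rectifier.
#' @return `H' x W' x C_out` array with `H' = H - f + 1`.
#' @export
conv_relu <- function(input, filters, biases = NULL, relu = TRUE) {
  x <- as_chw(input)
  f <- dim(filters)[1]
  if (f %% 2 == 0) stop("filter spatial size must be odd")
  if (dim(filters)[2] != f) stop("filters must be spatially square")
  if (dim(filters)[3] != dim(x)[3])
    stop("filter input channels must match the input")
  if (f > dim(x)[1] || f > dim(x)[2])
    stop("filter larger than the input")
  cout <- dim(filters)[4]
  if (is.null(biases)) biases <- numeric(cout)
  cols <- im2col(x, f)
  fmat <- matrix(filters, nrow = f * f * dim(x)[3], ncol = cout)
  A <- sweep(cols %*% fmat, 2, biases, `+`)
  if (relu) A <- pmax(A, 0)
  ho <- dim(x)[1] - f + 1
  wo <- dim(x)[2] - f + 1
  array(A, dim = c(ho, wo, cout))
}

as_chw <- function(x) {
  if (is.matrix(x)) array(x, dim = c(dim(x), 1)) else x
}

# patches-as-rows matrix: row = output position (row-major over the valid
# grid), column order = (dr fastest, then dc, then channel)
im2col <- function(x, f) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  ho <- H - f + 1; wo <- W - f + 1
  out <- matrix(0, ho * wo, f * f * C)
  col <- 0L
  for (ch in seq_len(C)) for (dc in seq_len(f)) for (dr in seq_len(f)) {
    col <- col + 1L
    out[, col] <- as.vector(x[dr:(dr + ho - 1), dc:(dc + wo - 1), ch])
  }
  out
}

# adjoint of im2col: scatter column gradients back onto the input grid
col2im <- function(cols, dim_x, f) {
  H <- dim_x[1]; W <- dim_x[2]; C <- dim_x[3]
  ho <- H - f + 1; wo <- W - f + 1
  out <- array(0, dim_x)
  col <- 0L
  for (ch in seq_len(C)) for (dc in seq_len(f)) for (dr in seq_len(f)) {
    col <- col + 1L
    out[dr:(dr + ho - 1), dc:(dc + wo - 1), ch] <-
      out[dr:(dr + ho - 1), dc:(dc + wo - 1), ch] +
      matrix(cols[, col], ho, wo)
  }
  out
}

zeropad <- function(x, p) {
  x <- as_chw(x)
  if (p == 0) return(x)
  out <- array(0, dim(x) + c(2 * p, 2 * p, 0))
  out[p + seq_len(dim(x)[1]), p + seq_len(dim(x)[2]), ] <- x
  out
}

#' Soft-thresholding (shrinkage) operator
#'
#' `sign(v) * max(|v| - theta, 0)` elementwise; the proximal operator of
#' the l1 norm.  The positive-part clamp is essential: without it the
#' operator is not a shrinkage and the iterative scheme that uses it
#' diverges.
#'
#' @param v numeric vector or matrix.
#' @param theta nonnegative threshold (scalar or conformable).
#' @return shrunk values, same shape as `v`.
#' @export
soft_threshold <- function(v, theta) {
  if (any(theta < 0)) stop("`theta` must be nonnegative")
  sign(v) * pmax(abs(v) - theta, 0)
}

#' Lipschitz bound of a dictionary Gram matrix
#'
#' Largest eigenvalue of `t(D) %*% D` by power iteration, inflated by a
#' factor `1 + 1e-6` as a safety margin.
#'
#' @param D dictionary matrix (atoms in columns).
#' @param iters power-iteration count.
#' @return the bound `L`.
#' @export
lipschitz_bound <- function(D, iters = 200L) {
  G <- crossprod(D)
  if (all(G == 0)) stop("zero dictionary")
  v <- rep(1 / sqrt(ncol(G)), ncol(G))
  lam <- 0
  for (i in seq_len(iters)) {
    w <- G %*% v
    lam_new <- sqrt(sum(w^2))
    if (lam_new == 0) break
    v <- as.vector(w / lam_new)
    if (abs(lam_new - lam) < 1e-12 * max(1, lam)) {
      lam <- lam_new
      break
    }
    lam <- lam_new
  }
  lam * (1 + 1e-6)
}

#' ISTA sparse coding
#'
#' Iterative shrinkage-thresholding for the l1-penalized least squares
#' (lasso / sparse coding) problem
#' `argmin_c 0.5 * ||x - D c||^2 + alpha * ||c||_1`.  Starting from zero,
#' `c <- soft_threshold(c + (1/L) t(D) (x - D c), alpha / L)` is applied
#' `k_iters` times, where `L` bounds the largest eigenvalue of
#' `t(D) %*% D`.
#'
#' @param x observation vector (length `n`), or an `n x P` matrix to code
#'   `P` observations at once.
#' @param D `n x m` dictionary.
#' @param alpha sparsity weight (> 0).
#' @param k_iters number of iterations.
#' @param L optional Lipschitz bound; computed by [lipschitz_bound()]
#'   when omitted.
#' @return sparse code vector (length `m`) or `m x P` matrix.
#' @export
ista_sparse_code <- function(x, D, alpha, k_iters = 3L, L = NULL) {
  if (k_iters < 1) stop("`k_iters` must be at least 1")
  if (!all(is.finite(D))) stop("dictionary must be finite")
  if (all(D == 0)) stop("zero dictionary")
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, ncol = 1) else x
  if (nrow(X) != nrow(D)) stop("`x` length must match dictionary rows")
  if (is.null(L)) L <- lipschitz_bound(D)
  theta <- alpha / L
  C <- matrix(0, ncol(D), ncol(X))
  DtX <- crossprod(D, X)
  G <- crossprod(D)
  for (k in seq_len(k_iters)) {
    U <- C + (DtX - G %*% C) / L
    C <- soft_threshold(U, theta)
  }
  if (vec) as.vector(C) else C
}

#' Lasso objective of a sparse code
#'
#' `0.5 * ||x - D c||^2 + alpha * ||c||_1`, the energy the ISTA layer
#' descends.
#'
#' @inheritParams ista_sparse_code
#' @param code candidate sparse code.
#' @return scalar objective value.
#' @export
lasso_objective <- function(x, D, code, alpha) {
  0.5 * sum((x - D %*% code)^2) + alpha * sum(abs(code))
}

#' Sparse-coding network configuration
#'
#' Architecture and optimization hyper-parameters of the enhancement
#' network: first-layer filter size `f1` and count `n1`, dictionary atom
#' count `m`, mapping width `n2`, high-resolution feature width `nh`,
#' output filter size `f4`, unrolled ISTA depth `k_iters`, patch
#' geometry, upscale factor, sparsity weight `alpha0` and intensity peak.
#'
#' @param f1,n1 first convolution: spatial size (odd) and filter count.
#' @param m dictionary atoms of the sparse-coding layer.
#' @param n2 non-linear mapping width (1x1 filters).
#' @param nh high-resolution feature width after the dictionary multiply.
#' @param f4 output convolution spatial size (odd).
#' @param k_iters unrolled ISTA iterations.
#' @param patch,stride patch size and stride for reconstruction.
#' @param factor upscale factor (2, 3 or 4).
#' @param alpha0 initial sparsity weight.
#' @param peak intensity peak used for internal normalization.
#' @return list of class `scnn_config`.
#' @export
scnn_config <- function(f1 = 9L, n1 = 64L, m = 64L, n2 = 32L, nh = 32L,
                        f4 = 5L, k_iters = 3L, patch = 16L, stride = 8L,
                        factor = 2L, alpha0 = 1e-4, peak = 255) {
  structure(list(f1 = f1, n1 = n1, m = m, n2 = n2, nh = nh, f4 = f4,
                 k_iters = k_iters, patch = patch, stride = stride,
                 factor = factor, alpha0 = alpha0, peak = peak),
            class = "scnn_config")
}

#' Initialize network parameters
#'
#' Filters are drawn from a zero-mean Gaussian with standard deviation
#' 0.001, biases start at zero, both dictionaries are Gaussian with
#' unit-normalized columns, and the Lipschitz bound is computed from the
#' initialized low-resolution dictionary.
#'
#' @param config an [scnn_config()].
#' @param seed integer seed.
#' @return list of class `scnn_params` with elements `F1, b1, Dlow,
#'   alpha, F3, b3, DHigh, F4, b4, L` plus the config.
#' @export
init_params <- function(config = scnn_config(), seed = 1L) {
  set.seed(seed)
  gnorm <- function(...) {
    d <- c(...)
    array(rnorm(prod(d), 0, 0.001), dim = d)
  }
  unit_cols <- function(M) sweep(M, 2, sqrt(colSums(M^2)), `/`)
  Dlow <- unit_cols(matrix(rnorm(config$n1 * config$m), config$n1))
  DHigh <- unit_cols(matrix(rnorm(config$n2 * config$nh), config$n2))
  p <- list(
    F1 = gnorm(config$f1, config$f1, 1, config$n1),
    b1 = numeric(config$n1),
    Dlow = Dlow,
    alpha = config$alpha0,
    F3 = matrix(rnorm(config$m * config$n2, 0, 0.001), config$m),
    b3 = numeric(config$n2),
    DHigh = DHigh,
    F4 = gnorm(config$f4, config$f4, config$nh, 1),
    b4 = 0,
    L = lipschitz_bound(Dlow),
    config = config
  )
  class(p) <- "scnn_params"
  p
}

# forward pass on one (already upscaled, normalized) patch; returns the
# output and, optionally, every intermediate needed by the backward pass
scnn_patch_forward <- function(patch, params, keep = FALSE) {
  cf <- params$config
  p1 <- (cf$f1 - 1) / 2
  x1 <- zeropad(patch, p1)
  cols1 <- im2col(x1, cf$f1)
  F1m <- matrix(params$F1, nrow = cf$f1^2, ncol = cf$n1)
  A1 <- sweep(cols1 %*% F1m, 2, params$b1, `+`)
  Z1 <- pmax(A1, 0) # positions x n1

  G <- crossprod(params$Dlow)
  XD <- Z1 %*% params$Dlow # positions x m
  L <- params$L
  theta <- params$alpha / L
  C <- matrix(0, nrow(Z1), ncol(params$Dlow))
  Us <- Cs <- if (keep) vector("list", cf$k_iters) else NULL
  for (k in seq_len(cf$k_iters)) {
    if (keep) Cs[[k]] <- C
    U <- C - (C %*% G) / L + XD / L
    if (keep) Us[[k]] <- U
    C <- soft_threshold(U, theta)
  }

  A3 <- sweep(C %*% params$F3, 2, params$b3, `+`)
  Z3 <- pmax(A3, 0)
  ZH <- Z3 %*% params$DHigh # positions x nh

  p4 <- (cf$f4 - 1) / 2
  np <- nrow(patch)
  zh_arr <- array(ZH, dim = c(np, ncol(patch), cf$nh))
  x4 <- zeropad(zh_arr, p4)
  cols4 <- im2col(x4, cf$f4)
  F4m <- matrix(params$F4, nrow = cf$f4^2 * cf$nh, ncol = 1)
  A4 <- cols4 %*% F4m + params$b4
  out <- matrix(pmax(A4, 0), np, ncol(patch))

  if (!keep) return(out)
  list(out = out, A4 = A4, cols4 = cols4, dimx4 = dim(x4), Z3 = Z3,
       A3 = A3, C = C, Us = Us, Cs = Cs, XD = XD, G = G, Z1 = Z1,
       A1 = A1, cols1 = cols1, theta = theta)
}

# gradient of the mean-squared patch loss w.r.t. every parameter block
scnn_patch_grad <- function(patch, target, params) {
  cf <- params$config
  fw <- scnn_patch_forward(patch, params, keep = TRUE)
  np2 <- length(target)
  loss <- mean((fw$out - target)^2)

  dA4 <- matrix(2 * (fw$out - target) / np2, ncol = 1) * (fw$A4 > 0)
  F4m <- matrix(params$F4, nrow = cf$f4^2 * cf$nh, ncol = 1)
  dF4 <- crossprod(fw$cols4, dA4)
  db4 <- sum(dA4)
  dcols4 <- dA4 %*% t(F4m)
  dx4 <- col2im(dcols4, fw$dimx4, cf$f4)
  p4 <- (cf$f4 - 1) / 2
  np <- nrow(patch)
  dZH_arr <- dx4[p4 + seq_len(np), p4 + seq_len(ncol(patch)), , drop = FALSE]
  dZH <- matrix(dZH_arr, nrow = np2, ncol = cf$nh)

  dDH <- crossprod(fw$Z3, dZH)
  dZ3 <- dZH %*% t(params$DHigh)
  dA3 <- dZ3 * (fw$A3 > 0)
  dF3 <- crossprod(fw$C, dA3)
  db3 <- colSums(dA3)
  dC <- dA3 %*% t(params$F3)

  # unrolled ISTA backward (L treated as a constant)
  L <- params$L
  dXD <- matrix(0, nrow(fw$XD), ncol(fw$XD))
  dG <- matrix(0, ncol(params$Dlow), ncol(params$Dlow))
  dtheta <- 0
  for (k in rev(seq_len(cf$k_iters))) {
    U <- fw$Us[[k]]
    active <- abs(U) > fw$theta
    dU <- dC * active
    dtheta <- dtheta - sum(sign(U) * dU)
    dXD <- dXD + dU / L
    dG <- dG - crossprod(fw$Cs[[k]], dU) / L
    dC <- dU - (dU %*% fw$G) / L
  }
  dalpha <- dtheta / L
  dD <- crossprod(fw$Z1, dXD) + params$Dlow %*% (dG + t(dG))
  dZ1 <- dXD %*% t(params$Dlow)

  dA1 <- dZ1 * (fw$A1 > 0)
  dF1 <- crossprod(fw$cols1, dA1)
  db1 <- colSums(dA1)

  list(loss = loss,
       grads = list(F1 = array(dF1, dim = dim(params$F1)), b1 = db1,
                    Dlow = dD, alpha = dalpha, F3 = dF3, b3 = db3,
                    DHigh = dDH, F4 = array(dF4, dim = dim(params$F4)),
                    b4 = db4))
}

#' Enhance an image with the sparse-coding network
#'
#' Bicubic-upscales the low-resolution input, normalizes by the
#' configured peak, runs every overlapping patch (size/stride from the
#' config, final row/column patches flush with the border) through the
#' network, and rebuilds the image by unweighted averaging of the
#' overlapping predictions.
#'
#' @param low_image low-resolution numeric matrix.
#' @param params an `scnn_params` object.
#' @return enhanced image at `factor` times the input size.
#' @export
scnn_forward <- function(low_image, params) {
  cf <- params$config
  up <- bicubic_upscale(low_image, cf$factor) / cf$peak
  H <- nrow(up); W <- ncol(up)
  if (H < cf$patch || W < cf$patch)
    stop("upscaled image smaller than the patch size")
  rs <- unique(c(seq(1, H - cf$patch + 1, by = cf$stride), H - cf$patch + 1))
  cs <- unique(c(seq(1, W - cf$patch + 1, by = cf$stride), W - cf$patch + 1))
  acc <- matrix(0, H, W)
  cnt <- matrix(0, H, W)
  for (r in rs) {
    for (cc in cs) {
      pr <- r:(r + cf$patch - 1)
      pc <- cc:(cc + cf$patch - 1)
      pred <- scnn_patch_forward(up[pr, pc], params)
      acc[pr, pc] <- acc[pr, pc] + pred
      cnt[pr, pc] <- cnt[pr, pc] + 1
    }
  }
  out <- acc / cnt * cf$peak
  attr(out, "bit_depth") <- attr(low_image, "bit_depth")
  out
}

#' Mean squared error between two images
#'
#' @param pred,target numeric matrices of identical shape.
#' @return nonnegative scalar.
#' @export
mse_loss <- function(pred, target) {
  if (!all(dim(pred) == dim(target))) stop("shape mismatch")
  mean((pred - target)^2)
}

#' Build aligned low/high patch pairs from images
#'
#' Degrades each image with [degrade_pair()], bicubic-upscales the noisy
#' low-resolution member back to the original grid, normalizes both by
#' the peak and extracts aligned patches.
#'
#' @param images list of numeric matrices.
#' @param config an [scnn_config()].
#' @param noise_sd degradation noise (intensity units).
#' @param seed integer seed.
#' @param max_pairs optional cap on the number of pairs.
#' @return list of class `patch_set` with `low` and `high` patch lists.
#' @export
make_patch_pairs <- function(images, config = scnn_config(), noise_sd = 12,
                             seed = 1L, max_pairs = NULL) {
  lows <- highs <- list()
  for (i in seq_along(images)) {
    dp <- degrade_pair(images[[i]], config$factor, noise_sd,
                       seed = derive_seed(seed, i))
    up <- bicubic_upscale(dp$low, config$factor) / config$peak
    hi <- dp$high / config$peak
    H <- nrow(hi); W <- ncol(hi)
    rs <- unique(c(seq(1, H - config$patch + 1, by = config$stride),
                   H - config$patch + 1))
    cs <- unique(c(seq(1, W - config$patch + 1, by = config$stride),
                   W - config$patch + 1))
    for (r in rs) for (cc in cs) {
      pr <- r:(r + config$patch - 1); pc <- cc:(cc + config$patch - 1)
      lows[[length(lows) + 1]] <- up[pr, pc]
      highs[[length(highs) + 1]] <- hi[pr, pc]
    }
  }
  if (!is.null(max_pairs) && length(lows) > max_pairs) {
    set.seed(derive_seed(seed, 999983))
    keep <- sample(length(lows), max_pairs)
    lows <- lows[keep]; highs <- highs[keep]
  }
  structure(list(low = lows, high = highs), class = "patch_set")
}

#' Train the sparse-coding network
#'
#' Full-batch adaptive-moment (Adam) gradient descent on the mean squared
#' reconstruction error over the patch pairs, with the ISTA layer
#' unrolled at fixed depth so the whole network trains by plain
#' backpropagation; the low-resolution dictionary is itself a trained
#' parameter and its Lipschitz bound is refreshed at the start of each
#' epoch.  Training aborts with a diagnostic if the loss exceeds ten
#' times its initial value for three consecutive epochs.
#'
#' @param pairs a `patch_set` (at least 16 pairs); `low` patches must
#'   already be at the target resolution and normalized scale.
#' @param config an [scnn_config()].
#' @param seed integer seed (initialization and batch shuffling).
#' @param epochs training epochs.
#' @param lr Adam learning rate (0 freezes the parameters).
#' @param batch_size mini-batch size; one Adam step per batch.
#' @return list with `params` (trained `scnn_params`) and `trace`
#'   (per-epoch loss, length `epochs + 1` including the initial loss).
#' @export
train_scnn <- function(pairs, config = scnn_config(), seed = 1L,
                       epochs = 200L, lr = 1e-2, batch_size = 16L) {
  n <- length(pairs$low)
  if (n < 16) stop("need at least 16 patch pairs")
  params <- init_params(config, seed)
  blocks <- c("F1", "b1", "Dlow", "alpha", "F3", "b3", "DHigh", "F4", "b4")
  m1 <- m2 <- lapply(params[blocks], function(x) x * 0)
  eps <- 1e-8
  beta1 <- 0.9; beta2 <- 0.999
  trace <- numeric(epochs + 1)
  bad <- 0L
  step <- 0L
  for (ep in seq_len(epochs + 1)) {
    params$L <- lipschitz_bound(params$Dlow)
    ord <- sample.int(n)
    loss <- 0
    nbatch <- ceiling(n / batch_size)
    for (bt in seq_len(nbatch)) {
      rows <- ord[((bt - 1) * batch_size + 1):min(bt * batch_size, n)]
      total <- lapply(params[blocks], function(x) x * 0)
      for (i in rows) {
        g <- scnn_patch_grad(pairs$low[[i]], pairs$high[[i]], params)
        loss <- loss + g$loss
        for (b in blocks) total[[b]] <- total[[b]] + g$grads[[b]]
      }
      if (lr > 0 && ep <= epochs) {
        step <- step + 1L
        for (b in blocks) {
          g <- total[[b]] / length(rows)
          m1[[b]] <- beta1 * m1[[b]] + (1 - beta1) * g
          m2[[b]] <- beta2 * m2[[b]] + (1 - beta2) * g^2
          mhat <- m1[[b]] / (1 - beta1^step)
          vhat <- m2[[b]] / (1 - beta2^step)
          params[[b]] <- params[[b]] - lr * mhat / (sqrt(vhat) + eps)
        }
        params$alpha <- max(params$alpha, 1e-6) # sparsity weight stays > 0
      }
    }
    trace[ep] <- loss / n
    if (ep > 1 && trace[ep] > 10 * trace[1]) {
      bad <- bad + 1L
      if (bad >= 3L)
        stop("training diverged: loss exceeded 10x the initial value ",
             "for 3 consecutive epochs (epoch ", ep - 1, ", loss ",
             signif(trace[ep], 4), ")")
    } else bad <- 0L
  }
  list(params = params, trace = trace)
}
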