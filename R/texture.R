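#' Quantize a grayscale image to discrete levels
#'
#' Uniform min-max binning to levels `0 .. levels_L - 1`; the maximum
#' pixel maps to the top level and a constant image maps to all zeros.
#'
#' @param image numeric matrix.
#' @param levels_L number of gray levels, at least 2.
#' @return integer matrix of levels.
#' @export
quantize_gray <- function(image, levels_L = 8L) {
  if (levels_L < 2) stop("`levels_L` must be at least 2")
  rng <- range(image)
  if (rng[1] == rng[2]) {
    lv <- matrix(0L, nrow(image), ncol(image))
  } else {
    lv <- floor((image - rng[1]) / (rng[2] - rng[1]) * levels_L)
    lv <- matrix(as.integer(pmin(lv, levels_L - 1)), nrow(image))
  }
  lv
}

glcm_offset <- function(angle, d) {
  switch(as.character(angle),
         "0"   = c(0L, d),
         "45"  = c(-d, d),
         "90"  = c(-d, 0L),
         "135" = c(-d, -d),
         stop("`angle` must be one of 0, 45, 90, 135"))
}

#' Grey-level co-occurrence matrix
#'
#' Counts co-occurrences of level pairs at a pixel offset determined by
#' the angle (in image coordinates with rows increasing downward:
#' 0 deg -> (0, +d), 45 deg -> (-d, +d), 90 deg -> (-d, 0),
#' 135 deg -> (-d, -d)).  Out-of-bounds pairs are dropped.  The symmetric
#' variant adds the transposed counts; normalization divides by the total
#' count so the entries form a joint probability mass.
#'
#' @param levels integer matrix of gray levels in `0 .. levels_L - 1`.
#' @param distance offset length in pixels.
#' @param angle one of 0, 45, 90, 135 (degrees).
#' @param levels_L number of levels `L`.
#' @param symmetric add the transposed counts (default `TRUE`).
#' @param normalize divide by the total count (default `TRUE`).
#' @return `L` x `L` matrix with attributes `distance`, `angle`,
#'   `normalized`.
#' @export
compute_glcm <- function(levels, distance = 1L, angle = 0,
                         levels_L = max(levels) + 1L, symmetric = TRUE,
                         normalize = TRUE) {
  if (any(levels >= levels_L)) stop("level values must be below `levels_L`")
  off <- glcm_offset(angle, as.integer(distance))
  h <- nrow(levels); w <- ncol(levels)
  rlo <- max(1L, 1L - off[1]); rhi <- min(h, h - off[1])
  clo <- max(1L, 1L - off[2]); chi <- min(w, w - off[2])
  if (rlo > rhi || clo > chi)
    stop("image too small for the requested offset")
  r0 <- rlo:rhi; c0 <- clo:chi
  a <- levels[r0, c0, drop = FALSE]
  b <- levels[r0 + off[1], c0 + off[2], drop = FALSE]
  counts <- tabulate(a * levels_L + b + 1L, nbins = levels_L^2)
  m <- matrix(as.numeric(counts), levels_L, levels_L, byrow = TRUE)
  if (symmetric) m <- m + t(m)
  if (normalize) m <- m / sum(m)
  attr(m, "distance") <- as.integer(distance)
  attr(m, "angle") <- angle
  attr(m, "normalized") <- normalize
  m
}

#' Haralick-style texture features of a normalized GLCM
#'
#' With `p(j, i)` the normalized co-occurrence probabilities over
#' zero-based levels, computes contrast `sum (j - i)^2 p`, correlation
#' `(sum j*i*p - mu_a mu_b) / (sigma_a sigma_b)`, energy `sum p^2` and
#' homogeneity `sum p / (1 + |j - i|)`.  A GLCM with zero marginal
#' variance (constant texture) has correlation defined as 1 and is
#' flagged degenerate.
#'
#' @param glcm normalized co-occurrence matrix.
#' @return named numeric vector `contrast`, `correlation`, `energy`,
#'   `homogeneity`, with attribute `degenerate`.
#' @export
glcm_features <- function(glcm) {
  if (abs(sum(glcm) - 1) > 1e-8)
    stop("`glcm` must be normalized (entries summing to 1)")
  L <- nrow(glcm)
  lev <- seq_len(L) - 1
  jj <- matrix(lev, L, L)          # row index j (zero-based)
  ii <- t(jj)                      # column index i
  contrast <- sum((jj - ii)^2 * glcm)
  energy <- sum(glcm^2)
  homogeneity <- sum(glcm / (1 + abs(jj - ii)))
  pa <- rowSums(glcm); pb <- colSums(glcm)
  mua <- sum(lev * pa); mub <- sum(lev * pb)
  sda <- sqrt(sum((lev - mua)^2 * pa))
  sdb <- sqrt(sum((lev - mub)^2 * pb))
  degenerate <- sda * sdb == 0
  correlation <- if (degenerate) 1 else
    (sum(jj * ii * glcm) - mua * mub) / (sda * sdb)
  out <- c(contrast = contrast, correlation = correlation, energy = energy,
           homogeneity = homogeneity)
  attr(out, "degenerate") <- degenerate
  out
}

#' Sixteen-element texture vector of an image
#'
#' Quantizes the image and computes the four GLCM features at the four
#' standard angles (0, 45, 90, 135 degrees), angle-major order.
#'
#' @param image numeric matrix.
#' @param distance GLCM offset in pixels.
#' @param levels_L number of gray levels.
#' @return named numeric vector of length 16, e.g. `a000_contrast`,
#'   `a000_correlation`, ..., `a135_homogeneity`.
#' @export
extract_texture_vector <- function(image, distance = 1L, levels_L = 8L) {
  lv <- quantize_gray(image, levels_L)
  out <- numeric(0)
  for (ang in c(0, 45, 90, 135)) {
    g <- compute_glcm(lv, distance, ang, levels_L)
    f <- glcm_features(g)
    names(f) <- sprintf("a%03d_%s", ang, names(f))
    out <- c(out, f)
  }
  out
}

#' Multi-space image reconstruction (MIR) objective
#'
#' Diagnostic objective combining a squared reconstruction residual with
#' an entropy-like sparsity penalty on normalized activation magnitudes:
#' `fit = sum (alpha_out - alpha_in)^2 - phi`,
#' `sparsity = mean(-r * log(max(r, eps_floor)))` and
#' `objective = fit + tau_s * sparsity`.  The natural logarithm is used
#' and `eps_floor` guards the log at zero activations.
#'
#' @param alpha_in,alpha_out numeric vectors of equal length (input and
#'   reconstructed activations).
#' @param r nonnegative activation magnitudes, each in `[0, 1]`.
#' @param tau_s sparsity weight (>= 0).
#' @param phi offset subtracted from the residual term.
#' @param eps_floor small positive floor inside the logarithm.
#' @return list with `objective`, `fit`, `sparsity`.
#' @export
mir_objective <- function(alpha_in, alpha_out, r, tau_s = 1, phi = 0,
                          eps_floor = 1e-12) {
  if (length(alpha_in) != length(alpha_out))
    stop("`alpha_in` and `alpha_out` must have equal length")
  if (any(r < 0)) stop("`r` entries must be nonnegative")
  if (tau_s < 0) stop("`tau_s` must be nonnegative")
  fit <- sum((alpha_out - alpha_in)^2) - phi
  sparsity <- mean(-r * log(pmax(r, eps_floor)))
  list(objective = fit + tau_s * sparsity, fit = fit, sparsity = sparsity)
}
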