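#' Butterworth frequency-domain kernel
#'
#' Builds the transfer function of a Butterworth low- or high-pass filter
#' on a centered 2-D frequency grid.  With `d` the Euclidean distance of a
#' frequency bin from the centered zero-frequency bin, the low-pass kernel
#' is `1 / (1 + (d/di)^(2n))` and the high-pass kernel is
#' `1 / (1 + (di/d)^(2n))`; the high-pass value at `d = 0` is defined as 0
#' (the continuous limit).  Both kernels equal 0.5 exactly at the cutoff
#' `d = di` (half-power point) for any order.
#'
#' @param shape integer vector `c(H, W)`, both at least 2.
#' @param cutoff_di cutoff radius in pixels from the spectrum center (> 0).
#' @param order_n filter order, a positive integer; larger orders sharpen
#'   the pass/stop transition.
#' @param mode `"lowpass"` or `"highpass"`.
#' @return an `H` x `W` matrix with values in `[0, 1]`, zero frequency at
#'   the centered bin `(floor(H/2) + 1, floor(W/2) + 1)`.
#' @export
butterworth_kernel <- function(shape, cutoff_di, order_n = 2L,
                               mode = c("lowpass", "highpass")) {
  mode <- match.arg(mode)
  if (cutoff_di <= 0) stop("`cutoff_di` must be positive")
  if (order_n < 1) stop("`order_n` must be at least 1")
  h <- shape[1]; w <- shape[2]
  if (h < 2 || w < 2) stop("shape must be at least 2 x 2")
  cy <- floor(h / 2) + 1
  cx <- floor(w / 2) + 1
  d <- sqrt(outer((seq_len(h) - cy)^2, (seq_len(w) - cx)^2, `+`))
  if (mode == "lowpass") {
    k <- 1 / (1 + (d / cutoff_di)^(2 * order_n))
  } else {
    k <- matrix(0, h, w)
    nz <- d > 0
    k[nz] <- 1 / (1 + (cutoff_di / d[nz])^(2 * order_n))
  }
  k
}

# centered-spectrum <-> raw-FFT index shuffling
ifftshift2 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  ri <- c((floor(h / 2) + 1):h, seq_len(floor(h / 2)))
  ci <- c((floor(w / 2) + 1):w, seq_len(floor(w / 2)))
  m[ri, ci]
}

#' Apply a frequency-domain kernel to an image
#'
#' Forward FFT, multiplication by the (centered) kernel, inverse FFT, and
#' the modulus of the result.  The modulus step rectifies any negative
#' ringing introduced by sharp filters.
#'
#' @param image numeric matrix.
#' @param kernel matrix from [butterworth_kernel()], same shape as `image`,
#'   zero frequency centered.
#' @param return_complex if `TRUE`, return the complex inverse transform
#'   before the modulus (used for linearity diagnostics).
#' @return filtered image of the same shape.
#' @export
apply_frequency_filter <- function(image, kernel, return_complex = FALSE) {
  if (!all(dim(image) == dim(kernel)))
    stop("kernel shape must equal image shape")
  f <- stats::fft(image)
  filtered <- f * ifftshift2(kernel)
  inv <- stats::fft(filtered, inverse = TRUE) / length(image)
  if (return_complex) return(inv)
  out <- Mod(inv)
  attr(out, "bit_depth") <- attr(image, "bit_depth")
  out
}

#' Butterworth-smooth an image
#'
#' Convenience wrapper: builds the kernel for the image's own shape and
#' applies it.  The default is a gentle low-pass (order 2, cutoff at 35%
#' of the half-minimum-dimension), the denoising configuration.
#'
#' @inheritParams apply_frequency_filter
#' @inheritParams butterworth_kernel
#' @export
butterworth_filter <- function(image, cutoff_di = NULL, order_n = 2L,
                               mode = c("lowpass", "highpass")) {
  mode <- match.arg(mode)
  if (is.null(cutoff_di))
    cutoff_di <- 0.35 * min(dim(image)) / 2
  k <- butterworth_kernel(dim(image), cutoff_di, order_n, mode)
  apply_frequency_filter(image, k)
}

#' Peak signal-to-noise ratio
#'
#' `10 * log10(peak^2 / MSE)` in decibels; identical images (zero MSE)
#' return `Inf`.
#'
#' @param reference,processed numeric matrices of the same shape.
#' @param peak peak intensity value (> 0); defaults to
#'   `2^bit_depth - 1` of the reference when that attribute is present,
#'   otherwise 255.
#' @return PSNR in dB.
#' @export
psnr <- function(reference, processed, peak = NULL) {
  if (!all(dim(reference) == dim(processed)))
    stop("images must share the same shape")
  if (is.null(peak)) {
    bits <- attr(reference, "bit_depth") %||% 8L
    peak <- 2^bits - 1
  }
  if (peak <= 0) stop("`peak` must be positive")
  mse <- mean((reference - processed)^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}
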