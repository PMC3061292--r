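# Internal separable Gaussian convolution helpers shared by the null-field
# generator and image smoothing. Kernels are truncated at `truncate` sigma.

.fwhm_to_sigma <- function(fwhm) fwhm / sqrt(8 * log(2))

.gauss_kernel <- function(sigma, truncate = 4) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(truncate * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# dense banded convolution operator mapping a padded axis (n + 2*pad) onto
# the unpadded axis of length n; kernel must fit inside the padding
.conv_operator <- function(n, pad, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  stopifnot(r <= pad)
  op <- matrix(0, n, n + 2L * pad)
  for (j in seq_along(kernel))
    op[cbind(seq_len(n), seq_len(n) + pad - r + (j - 1L))] <-
      op[cbind(seq_len(n), seq_len(n) + pad - r + (j - 1L))] + kernel[j]
  op
}

# apply a matrix operator along dimension `along` of array x
.apply_along <- function(x, op, along) {
  dm <- dim(x)
  nd <- length(dm)
  perm <- c(along, seq_len(nd)[-along])
  y <- op %*% matrix(aperm(x, perm), nrow = dm[along])
  dm2 <- dm
  dm2[along] <- nrow(op)
  aperm(array(y, c(nrow(op), dm[-along])), order(perm))
}

# separable convolution of an unpadded array with zero padding outside;
# kernels: list of per-dimension kernels (numeric vectors)
.sep_convolve <- function(x, kernels) {
  for (j in seq_along(kernels)) {
    k <- kernels[[j]]
    if (length(k) == 1L) next
    r <- (length(k) - 1L) %/% 2L
    # zero padding: kernel taps falling outside the image are dropped
    n <- dim(x)[j]
    op <- matrix(0, n, n)
    for (t in -r:r) {
      i <- seq_len(n)
      jj <- i + t
      ok <- jj >= 1L & jj <= n
      op[cbind(i[ok], jj[ok])] <- op[cbind(i[ok], jj[ok])] + k[t + r + 1L]
    }
    x <- .apply_along(x, op, j)
  }
  x
}
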