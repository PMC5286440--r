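# Internal numeric helpers shared across detection and evaluation stages.

# odd-sized normalized Gaussian kernel, truncated at 3 sigma
.gauss_kernel <- function(sigma, truncate = 3) {
  h <- max(1L, ceiling(truncate * sigma))
  xs <- -h:h
  k <- exp(-outer(xs^2, xs^2, "+") / (2 * sigma^2))
  k / sum(k)
}

# Gaussian second-derivative kernels at scale sigma (scale-normalized by
# sigma^2) for the Hessian entries
.hessian_kernels <- function(sigma, truncate = 4) {
  h <- max(2L, ceiling(truncate * sigma))
  xs <- -h:h
  g <- exp(-xs^2 / (2 * sigma^2)) / (sqrt(2 * pi) * sigma)
  gxx <- (xs^2 / sigma^4 - 1 / sigma^2) * g
  gx <- -xs / sigma^2 * g
  k <- list(xx = sigma^2 * outer(g, gxx),  # rows = y, cols = x
            yy = sigma^2 * outer(gxx, g),
            xy = sigma^2 * outer(gx, gx))
  # truncation leaves a small DC component; remove it so a constant
  # image has an exactly zero Hessian
  lapply(k, function(m) m - mean(m))
}

.filter2 <- function(m, k) {
  EBImage::filter2(m, k, boundary = "replicate")
}

# central-difference gradients with replicated borders;
# returns gx (d/dx = d/column), gy (d/dy = d/row)
.gradients <- function(m) {
  H <- nrow(m); W <- ncol(m)
  xl <- m[, c(1, seq_len(W - 1)), drop = FALSE]
  xr <- m[, c(seq_len(W - 1) + 1, W), drop = FALSE]
  yu <- m[c(1, seq_len(H - 1)), , drop = FALSE]
  yd <- m[c(seq_len(H - 1) + 1, H), , drop = FALSE]
  list(gx = (xr - xl) / 2, gy = (yd - yu) / 2)
}

# 8-neighborhood local maxima of a response matrix; plateaus are broken
# lexicographically (strict dominance over earlier-scan neighbors,
# non-strict over later ones) so each flat peak yields exactly one pixel
.local_maxima <- function(R) {
  H <- nrow(R); W <- ncol(R)
  pad <- matrix(-Inf, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- R
  out <- matrix(TRUE, H, W)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    nb <- pad[(2 + dy):(H + 1 + dy), (2 + dx):(W + 1 + dx)]
    strict <- dy < 0 || (dy == 0 && dx < 0)
    out <- out & if (strict) R > nb else R >= nb
  }
  out
}

# histogram Otsu threshold on a numeric vector (used on nonzero
# vesselness values, where whole-image Otsu is inappropriate)
.otsu_threshold <- function(v, levels = 256L) {
  v <- v[is.finite(v)]
  if (length(v) == 0L) return(Inf)
  lo <- min(v); hi <- max(v)
  if (hi <= lo) return(lo)
  br <- seq(lo, hi, length.out = levels + 1L)
  h <- tabulate(findInterval(v, br, rightmost.closed = TRUE), levels)
  w <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  muT <- mu[levels]
  sb2 <- (muT * omega - mu)^2 / (omega * (1 - omega))
  sb2[!is.finite(sb2)] <- -Inf
  mids[which.max(sb2)]
}

# intensities of a ThermalImage or a plain matrix
.as_pixels <- function(x) {
  if (is(x, "ThermalImage")) pixels(x) else as.matrix(x)
}

.check_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("images must have identical dimensions")
}
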