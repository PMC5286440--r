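# Shared fixtures and independent oracles, built in code at test time.

# horizontal Gaussian ridge centered at row y0 (0-based), sd sw
ridge_image <- function(H = 64, W = 96, y0 = 31, sw = 1.5, bright = 0.8) {
  ys <- matrix(0:(H - 1), H, W)
  bright * exp(-(ys - y0)^2 / (2 * sw^2))
}

# axis-aligned plus sign mask: two crossing bars
plus_mask <- function(H = 41, W = 41, arm = 15, thick = 5) {
  m <- matrix(FALSE, H, W)
  cy <- (H + 1) %/% 2; cx <- (W + 1) %/% 2
  h <- (thick - 1) %/% 2
  m[(cy - h):(cy + h), (cx - arm):(cx + arm)] <- TRUE
  m[(cy - arm):(cy + arm), (cx - h):(cx + h)] <- TRUE
  m
}

# O(n^2) double-loop ANMS oracle, independent of the package's
# vectorized implementation
anms_oracle <- function(x, y, response, n_target, c_robust) {
  n <- length(x)
  r <- rep(Inf, n)
  for (i in seq_len(n)) {
    best <- Inf
    for (j in seq_len(n)) {
      if (i == j) next
      if (c_robust * response[j] > response[i]) {
        d <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
        if (d < best) best <- d
      }
    }
    r[i] <- best
  }
  ord <- order(-r, -response, seq_len(n))
  keep <- ord[seq_len(min(n_target, n))]
  list(radius = r, keep = keep)
}

# exhaustive minimum-cost assignment over all permutations (n <= 7)
brute_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (k in seq_along(v))
      for (p in perms(v[-k])) out[[length(out) + 1]] <- c(v[k], p)
    out
  }
  best <- Inf
  for (p in perms(seq_len(m))) {
    cols <- p[seq_len(n)]
    tot <- sum(cost[cbind(seq_len(n), cols)])
    if (tot < best) best <- tot
  }
  best
}

# per-pixel loop oracle for the circular SAD of two descriptor windows
sad_oracle <- function(angS, validS, angT, validT) {
  tot <- 0; nval <- 0
  for (i in seq_along(angS)) {
    if (!validS[i] || !validT[i]) next
    d <- abs(angS[i] - angT[i]) %% (2 * pi)
    tot <- tot + min(d, 2 * pi - d)
    nval <- nval + 1
  }
  if (nval == 0) Inf else tot
}

# chi-squared/2 histogram cost oracle
chi2_oracle <- function(g, h) {
  tot <- 0
  for (k in seq_along(g)) {
    den <- g[k] + h[k]
    if (den > 0) tot <- tot + (g[k] - h[k])^2 / den
  }
  tot / 2
}

# plain R joint-histogram MI oracle (nats)
mi_oracle <- function(a, b, bins) {
  bin <- function(v) pmin(floor(pmin(pmax(v, 0), 1) * bins) + 1, bins)
  j <- table(factor(bin(a), 1:bins), factor(bin(b), 1:bins))
  p <- j / sum(j)
  pa <- rowSums(p); pb <- colSums(p)
  s <- 0
  for (i in 1:bins) for (k in 1:bins)
    if (p[i, k] > 0) s <- s + p[i, k] * log(p[i, k] / (pa[i] * pb[k]))
  unname(s)
}

# small default test pair: textured scene with a known smooth warp
test_pair <- function(seed, maxDisplacement = 15, ...) {
  sc <- generateScene(seed, ...)
  warp <- randomSmoothWarp(seed + 100, width = sc@width,
                           height = sc@height,
                           maxDisplacement = maxDisplacement)
  c(renderPair(sc, warp), list(scene = sc, warp = warp))
}
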