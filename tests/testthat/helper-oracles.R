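# Brute-force loop oracles, written independently of the implementations.

oracle_nmi <- function(a, b, bins = 64, range = c(-1000, 1500)) {
  bi <- function(v) pmin(pmax(floor((v - range[1]) / diff(range) * bins) + 1, 1), bins)
  ia <- bi(as.vector(a)); ib <- bi(as.vector(b))
  pj <- matrix(0, bins, bins)
  for (k in seq_along(ia)) pj[ia[k], ib[k]] <- pj[ia[k], ib[k]] + 1
  pj <- pj / length(ia)
  pa <- rowSums(pj); pb <- colSums(pj)
  h <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  mi <- 0
  for (i in 1:bins) for (j in 1:bins)
    if (pj[i, j] > 0) mi <- mi + pj[i, j] * log(pj[i, j] / (pa[i] * pb[j]))
  2 * mi / (h(pa) + h(pb))
}

oracle_ncc <- function(a, b) {
  a <- as.vector(a); b <- as.vector(b)
  n <- length(a)
  ma <- sum(a) / n; mb <- sum(b) / n
  sa <- sqrt(sum((a - ma)^2) / n); sb <- sqrt(sum((b - mb)^2) / n)
  acc <- 0
  for (k in 1:n) acc <- acc + (a[k] - ma) * (b[k] - mb)
  acc / n / (sa * sb)
}

oracle_ssim_global <- function(a, b, k1 = 0.01, k2 = 0.03) {
  L <- max(a) - min(a)
  c1 <- (k1 * L)^2; c2 <- (k2 * L)^2
  m1 <- mean(a); m2 <- mean(b)
  v1 <- mean((a - m1)^2); v2 <- mean((b - m2)^2)
  cv <- mean((a - m1) * (b - m2))
  (2 * m1 * m2 + c1) * (2 * cv + c2) / ((m1^2 + m2^2 + c1) * (v1 + v2 + c2))
}

oracle_ssim_local <- function(a, b, r = 2, k1 = 0.01, k2 = 0.03) {
  L <- max(a) - min(a); c1 <- (k1 * L)^2; c2 <- (k2 * L)^2
  d <- dim(a); acc <- 0; n <- 0
  for (z in 1:d[1]) for (y in 1:d[2]) for (x in 1:d[3]) {
    ys <- max(1, y - r):min(d[2], y + r)
    xs <- max(1, x - r):min(d[3], x + r)
    wa <- a[z, ys, xs]; wb <- b[z, ys, xs]
    m1 <- mean(wa); m2 <- mean(wb)
    v1 <- mean(wa^2) - m1^2; v2 <- mean(wb^2) - m2^2
    cv <- mean(wa * wb) - m1 * m2
    acc <- acc + (2 * m1 * m2 + c1) * (2 * cv + c2) /
      ((m1^2 + m2^2 + c1) * (v1 + v2 + c2))
    n <- n + 1
  }
  acc / n
}

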