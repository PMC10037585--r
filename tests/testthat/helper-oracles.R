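# Independent reference implementations used as oracles: direct-loop 2D
# convolution, bilinear x2 upsampling, an all-pairs Hausdorff distance,
# and small random-mask factories.  These stay deliberately naive.

refConv2d <- function(X, K, b, stride, pad) {
  d <- dim(X); k <- dim(K)[1]; Cin <- dim(K)[3]; Cout <- dim(K)[4]
  Ho <- (d[1] + 2 * pad - k) %/% stride + 1
  Wo <- (d[2] + 2 * pad - k) %/% stride + 1
  out <- array(0, c(Ho, Wo, Cout, d[4]))
  for (n in seq_len(d[4])) for (f in seq_len(Cout))
    for (wo in seq_len(Wo)) for (ho in seq_len(Ho)) {
      s <- b[f]
      for (c in seq_len(Cin)) for (kx in seq_len(k)) for (ky in seq_len(k)) {
        hi <- (ho - 1) * stride - pad + ky
        wi <- (wo - 1) * stride - pad + kx
        if (hi >= 1 && hi <= d[1] && wi >= 1 && wi <= d[2])
          s <- s + X[hi, wi, c, n] * K[ky, kx, c, f]
      }
      out[ho, wo, f, n] <- s
    }
  out
}

refUpsample2 <- function(X) {
  d <- dim(X)
  out <- array(0, c(2 * d[1], 2 * d[2], d[3], d[4]))
  ix <- function(o, H) {    # align_corners = FALSE source coordinate
    s <- (o + 0.5) / 2 - 0.5
    a <- floor(s); t <- s - a
    if (a < 0) { a <- 0; t <- 0 }
    b <- a + 1
    if (b > H - 1) { b <- H - 1; t <- 0 }
    c(a + 1, b + 1, t)
  }
  for (n in seq_len(d[4])) for (c in seq_len(d[3]))
    for (wo in 0:(2 * d[2] - 1)) for (ho in 0:(2 * d[1] - 1)) {
      h <- ix(ho, d[1]); w <- ix(wo, d[2])
      v <- (1 - h[3]) * ((1 - w[3]) * X[h[1], w[1], c, n] + w[3] * X[h[1], w[2], c, n]) +
        h[3] * ((1 - w[3]) * X[h[2], w[1], c, n] + w[3] * X[h[2], w[2], c, n])
      out[ho + 1, wo + 1, c, n] <- v
    }
  out
}

refAttentionGate <- function(x, g, p) {
  xg <- refConv2d(x, p$Wx, p$bx, 2, 0)
  gg <- refConv2d(g, p$Wg, p$bg, 1, 0)
  q <- pmax(xg + gg, 0)
  a <- 1 / (1 + exp(-refConv2d(q, p$Wpsi, p$bpsi, 1, 0)))
  alpha <- refUpsample2(a)
  out <- x
  for (c in seq_len(dim(x)[3])) out[, , c, ] <- x[, , c, ] * alpha[, , 1, ]
  list(output = out, alpha = alpha)
}

refHausdorff <- function(segArr, refArr, sp) {
  a <- sweep(which(segArr == 1, arr.ind = TRUE), 2, sp, `*`)
  b <- sweep(which(refArr == 1, arr.ind = TRUE), 2, sp, `*`)
  dm <- as.matrix(stats::dist(rbind(a, b)))[seq_len(nrow(a)),
                                            nrow(a) + seq_len(nrow(b)), drop = FALSE]
  max(max(apply(dm, 1, min)), max(apply(dm, 2, min)))
}

randomMask <- function(dims, p = 0.3, nonempty = TRUE) {
  repeat {
    m <- array(stats::rbinom(prod(dims), 1, p), dim = dims)
    if (!nonempty || sum(m) > 0) return(m)
  }
}

unitGeom <- function(dims, sp = c(1, 1, 1)) VolumeGeometry(dims, sp)

maskOf <- function(arr, sp = c(1, 1, 1))
  BinaryMask(unitGeom(dim(arr), sp), arr)
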