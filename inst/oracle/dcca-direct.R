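# Direct-summation detrended cross-correlation coefficient: explicit
# normal-equation regressions and loops, independent of the package's
# vectorized implementation. Verification oracle only.

dccaDirectOracle <- function(x, y, s) {
  N <- length(x)
  X <- numeric(N); Y <- numeric(N)
  mx <- sum(x) / N; my <- sum(y) / N
  accx <- 0; accy <- 0
  for (i in 1:N) {
    accx <- accx + x[i] - mx; X[i] <- accx
    accy <- accy + y[i] - my; Y[i] <- accy
  }
  nwin <- N - s
  Fxy <- 0; Fxx <- 0; Fyy <- 0
  for (i in 1:nwin) {
    idx <- i:(i + s)
    t <- seq_along(idx)
    st <- sum(t); stt <- sum(t * t)
    det <- (s + 1) * stt - st * st
    fitres <- function(z) {
      sz <- sum(z); stz <- sum(t * z)
      slope <- ((s + 1) * stz - st * sz) / det
      intercept <- (sz - slope * st) / (s + 1)
      z - intercept - slope * t
    }
    rx <- fitres(X[idx]); ry <- fitres(Y[idx])
    Fxy <- Fxy + sum(rx * ry) / (s + 1)
    Fxx <- Fxx + sum(rx * rx) / (s + 1)
    Fyy <- Fyy + sum(ry * ry) / (s + 1)
  }
  (Fxy / nwin) / sqrt((Fxx / nwin) * (Fyy / nwin))
}
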