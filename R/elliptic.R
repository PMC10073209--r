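# Complete elliptic integrals K(m) and E(m), parameter m = k^2 (MATLAB
# ellipke convention), computed by the arithmetic-geometric mean.
# Vectorised; accurate to ~1e-15 for m in [0, 1).
ellipke <- function(m) {
  if (any(m < 0 | m >= 1)) stop("elliptic parameter m must lie in [0, 1)")
  a <- rep_len(1, length(m))
  b <- sqrt(1 - m)
  c <- sqrt(m)
  csum <- 0.5 * c^2           # accumulates sum 2^(n-1) c_n^2
  pow <- 1
  for (i in 1:60) {
    if (all(c < 1e-16)) break
    an <- (a + b) / 2
    c <- (a - b) / 2
    b <- sqrt(a * b)
    a <- an
    pow <- pow * 2
    csum <- csum + pow / 2 * c^2
  }
  K <- pi / (2 * a)
  E <- K * (1 - csum)
  list(K = K, E = E)
}
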