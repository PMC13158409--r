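# Independent characteristic-matrix (optical transfer matrix) reflectivity,
# used as the oracle for the Parratt recursion. Deliberately written as a
# per-q scalar loop over 2x2 complex matrices, sharing no code with the
# package implementation. Zero roughness only.
tmatrix_reflectivity <- function(incident_sld, layers, backing_sld, q) {
  layers <- as.data.frame(layers)
  n <- nrow(layers)
  rho <- c(incident_sld, layers$sld, backing_sld) * 1e-6
  vapply(q, function(qq) {
    k0 <- qq / 2
    kz <- sqrt(as.complex(k0^2 - 4 * pi * (rho - rho[1])))
    M <- diag(2) + 0i
    for (j in seq_len(n)) {
      kj <- kz[j + 1]
      delta <- kj * layers$thickness[j]
      Mj <- matrix(c(cos(delta), 1i * kj * sin(delta),
                     1i * sin(delta) / kj, cos(delta)), 2, 2)
      M <- M %*% Mj
    }
    p0 <- kz[1]
    ps <- kz[n + 2]
    num <- (M[1, 1] + M[1, 2] * ps) * p0 - (M[2, 1] + M[2, 2] * ps)
    den <- (M[1, 1] + M[1, 2] * ps) * p0 + (M[2, 1] + M[2, 2] * ps)
    Mod(num / den)^2
  }, numeric(1))
}

# random slab stack with up to n_max layers, zero roughness
random_stack <- function(n_max = 6) {
  n <- sample.int(n_max, 1)
  slab_stack(
    incident_sld = runif(1, 0, 4),
    layers = data.frame(thickness = runif(n, 5, 120),
                        sld = runif(n, -0.5, 7),
                        rough = rep(0, n)),
    backing_sld = runif(1, -0.56, 6.36),
    backing_rough = 0
  )
}
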