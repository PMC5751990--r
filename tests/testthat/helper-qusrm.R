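## Shared helpers for the qusrm test suite. Everything here is deliberately
## independent of the package internals so it can serve as an oracle.

## Envelope of an RF line via the analytic signal (frequency-domain Hilbert
## transform), used as an oracle for the periodic-phantom autocovariance test.
envelopeFFT <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

## Analytic sample/reference spectrum pair whose dB difference follows the
## round-trip attenuation model exactly: diff(f, z) =
## const(f) - 2*(alphaS - alphaR)*fMHz*zCm. Used as the noise-free ACE oracle.
attenSpectrumPair <- function(alphaSample, alphaRef, depthsM,
                              freqHz = seq(4e6, 9e6, by = 0.25e6)) {
  fMHz <- freqHz / 1e6
  shape <- -0.3 * (fMHz - 6.5)^2          # arbitrary common spectral shape
  lapply(depthsM, function(z) {
    zCm <- z * 100
    list(sample = PowerSpectrum(freqHz,
           shape - 2 * alphaSample * fMHz * zCm, depth = z),
         reference = PowerSpectrum(freqHz,
           shape - 2 * alphaRef * fMHz * zCm, depth = z))
  })
}

## Independent brute-force GLCM oracle: enumerate every pixel pair at the
## offset implied by (distance, angle), count symmetrically, normalize.
## Convention (documented in computeGLCM): rows axial, columns lateral;
## 0 deg = (0, +d), 45 deg = (-d, +d), 90 deg = (-d, 0), 135 deg = (-d, -d).
bruteGLCM <- function(levels, nLevels, distance, angle) {
  off <- switch(as.character(angle),
                "0" = c(0, distance), "45" = c(-distance, distance),
                "90" = c(-distance, 0), "135" = c(-distance, -distance))
  m <- matrix(0, nLevels, nLevels)
  for (r in seq_len(nrow(levels))) {
    for (cc in seq_len(ncol(levels))) {
      r2 <- r + off[1]; c2 <- cc + off[2]
      if (r2 < 1 || r2 > nrow(levels) || c2 < 1 || c2 > ncol(levels)) next
      a <- levels[r, cc]; b <- levels[r2, c2]
      if (is.na(a) || is.na(b)) next
      m[a + 1, b + 1] <- m[a + 1, b + 1] + 1
      m[b + 1, a + 1] <- m[b + 1, a + 1] + 1
    }
  }
  if (sum(m) > 0) m <- m / sum(m)
  m
}

## Independent Haralick features from a normalized GLCM.
bruteHaralick <- function(p) {
  n <- nrow(p)
  con <- 0; ene <- 0; hom <- 0; cov <- 0
  pi_ <- rowSums(p)
  mu <- sum(seq_len(n) * pi_)
  va <- sum((seq_len(n) - mu)^2 * pi_)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      con <- con + p[i, j] * (i - j)^2
      ene <- ene + p[i, j]^2
      hom <- hom + p[i, j] / (1 + abs(i - j))
      cov <- cov + (i - mu) * (j - mu) * p[i, j]
    }
  }
  c(CON = con, COR = if (va > 0) cov / va else 1, ENE = ene, HOM = hom)
}

## One named vector of the 31 per-scan features with deterministic values.
scanVector <- function(offset = 0) {
  nm <- scanFeatureNames()
  stats::setNames(seq_along(nm) / 10 + offset, nm)
}
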