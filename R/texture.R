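## Gray-level co-occurrence texture features of QUS parametric maps:
## contrast (CON), correlation (COR), energy (ENE) and homogeneity (HOM),
## averaged over 16 symmetric GLCMs (distances 1-4 pixels, angles
## 0/45/90/135 degrees).

#' Quantize a parametric map to discrete gray levels
#'
#' Uniform binning between the unmasked minimum and maximum into `nLevels`
#' levels (the maximum maps to the top level), making the downstream texture
#' features invariant to affine rescaling of the map values.
#'
#' @param map a \linkS4class{ParametricMap} or numeric matrix.
#' @param nLevels number of gray levels (default 16).
#' @return a list of class `QuantizedMap`: `levels` (integer matrix, values in
#'   0..nLevels-1, NA where masked), `nLevels`, `valueRange`, `degenerate`
#'   (TRUE when the map is constant).
#' @export
quantizeMap <- function(map, nLevels = 16L) {
  if (is(map, "ParametricMap")) {
    v <- mapValues(map)
    v[!mapMask(map)] <- NA_real_
  } else v <- as.matrix(map)
  ok <- is.finite(v)
  if (!any(ok)) stopf("map has no valid cells")
  rng <- range(v[ok])
  degenerate <- rng[1] == rng[2]
  lv <- matrix(NA_integer_, nrow(v), ncol(v))
  if (degenerate) {
    lv[ok] <- 0L
  } else {
    q <- floor((v[ok] - rng[1]) / (rng[2] - rng[1]) * nLevels)
    lv[ok] <- as.integer(pmin(q, nLevels - 1L))
  }
  structure(list(levels = lv, nLevels = as.integer(nLevels),
                 valueRange = rng, degenerate = degenerate),
            class = "QuantizedMap")
}

## Pixel offset (drow, dcol) for a GLCM direction. Convention: rows are axial,
## columns are lateral; 0 degrees = lateral neighbor (same row, next column),
## 90 degrees = axial neighbor (previous row, same column), 45/135 diagonals.
#' @noRd
glcmOffset <- function(distance, angle) {
  switch(as.character(angle),
         "0" = c(0L, distance),
         "45" = c(-distance, distance),
         "90" = c(-distance, 0L),
         "135" = c(-distance, -distance),
         stopf("angle must be one of 0, 45, 90, 135"))
}

#' Compute a symmetric gray-level co-occurrence matrix
#'
#' Counts co-occurrences of gray levels at the given pixel offset, in both
#' directions (symmetric GLCM), skipping pairs with a masked member, and
#' normalizes the matrix to sum to 1.
#'
#' @param qmap a `QuantizedMap` from [quantizeMap()].
#' @param distance offset distance in pixels (>= 1).
#' @param angle direction in degrees: 0, 45, 90 or 135 (0 = lateral neighbor,
#'   90 = axial neighbor).
#' @return a list of class `GLCM`: `matrix` (nLevels x nLevels, sums to 1),
#'   `distance`, `angle`, `nPairs`, `empty`.
#' @export
computeGLCM <- function(qmap, distance, angle) {
  stopifnot(inherits(qmap, "QuantizedMap"))
  if (distance < 1) stopf("distance must be >= 1")
  off <- glcmOffset(as.integer(distance), angle)
  lv <- qmap$levels
  nr <- nrow(lv); nc <- ncol(lv)
  n <- qmap$nLevels
  r1lo <- max(1L, 1L - off[1]); r1hi <- min(nr, nr - off[1])
  c1lo <- max(1L, 1L - off[2]); c1hi <- min(nc, nc - off[2])
  m <- matrix(0, n, n)
  nPairs <- 0L
  if (r1lo <= r1hi && c1lo <= c1hi) {
    r1 <- r1lo:r1hi
    c1 <- c1lo:c1hi
    a <- lv[r1, c1, drop = FALSE]
    b <- lv[r1 + off[1], c1 + off[2], drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (any(ok)) {
      ai <- a[ok] + 1L; bi <- b[ok] + 1L
      for (k in seq_along(ai)) {
        m[ai[k], bi[k]] <- m[ai[k], bi[k]] + 1
        m[bi[k], ai[k]] <- m[bi[k], ai[k]] + 1
      }
      nPairs <- sum(ok)
    }
  }
  empty <- nPairs == 0L
  if (!empty) m <- m / sum(m)
  structure(list(matrix = m, distance = as.integer(distance),
                 angle = angle, nPairs = nPairs, empty = empty),
            class = "GLCM")
}

#' Haralick features of one GLCM
#'
#' Contrast `sum p(i,j) (i-j)^2`, correlation
#' `sum (i-mu_i)(j-mu_j) p(i,j) / (sd_i sd_j)`, energy `sum p(i,j)^2` and
#' homogeneity `sum p(i,j) / (1 + |i-j|)`. Correlation of a zero-variance
#' marginal is reported as 1 by convention (with a warning).
#'
#' @param glcm a `GLCM` from [computeGLCM()].
#' @return named numeric vector `c(CON, COR, ENE, HOM)`.
#' @export
haralickFeatures <- function(glcm) {
  stopifnot(inherits(glcm, "GLCM"))
  if (glcm$empty) stopf("empty GLCM: no valid pixel pairs at this offset")
  p <- glcm$matrix
  n <- nrow(p)
  i <- matrix(seq_len(n), n, n)           # row index
  j <- t(i)
  con <- sum(p * (i - j)^2)
  ene <- sum(p^2)
  hom <- sum(p / (1 + abs(i - j)))
  pi_ <- rowSums(p)
  mu <- sum(seq_len(n) * pi_)
  va <- sum((seq_len(n) - mu)^2 * pi_)
  if (va <= .Machine$double.eps) {
    warning("zero-variance marginal; correlation reported as 1 by convention",
            call. = FALSE)
    cor <- 1
  } else {
    cor <- sum((i - mu) * (j - mu) * p) / va  # symmetric: sd_i = sd_j
  }
  c(CON = con, COR = cor, ENE = ene, HOM = hom)
}

#' GLCM distance-angle configurations
#'
#' The 16 symmetric GLCM configurations: distances 1-4 pixels crossed with
#' angles 0, 45, 90 and 135 degrees.
#'
#' @return data frame with columns `distance` and `angle` (16 rows).
#' @export
glcmConfigurations <- function() {
  expand.grid(distance = 1:4, angle = c(0, 45, 90, 135))
}

#' Texture features of a parametric map
#'
#' Quantizes the map, builds the 16 symmetric GLCMs and averages the four
#' Haralick features over the non-empty configurations. A constant map is
#' degenerate: CON = 0, ENE = 1, HOM = 1 and COR = 1 by convention.
#'
#' @param map a \linkS4class{ParametricMap} or numeric matrix.
#' @param nLevels number of gray levels.
#' @return a list of class `TextureSet`: `CON`, `COR`, `ENE`, `HOM`,
#'   `sourceParameter`, `nConfigurations` (non-empty GLCMs averaged).
#' @examples
#' m <- ParametricMap(matrix(rnorm(36), 6, 6), "MBF")
#' textureFeatures(m)
#' @export
textureFeatures <- function(map, nLevels = 16L) {
  param <- if (is(map, "ParametricMap")) parameterName(map) else NA_character_
  q <- quantizeMap(map, nLevels)
  if (q$degenerate) {
    warning("constant map: degenerate texture features", call. = FALSE)
    return(structure(list(CON = 0, COR = 1, ENE = 1, HOM = 1,
                          sourceParameter = param, nConfigurations = 0L),
                     class = "TextureSet"))
  }
  cfg <- glcmConfigurations()
  feats <- matrix(NA_real_, nrow(cfg), 4,
                  dimnames = list(NULL, c("CON", "COR", "ENE", "HOM")))
  for (k in seq_len(nrow(cfg))) {
    g <- computeGLCM(q, cfg$distance[k], cfg$angle[k])
    if (!g$empty) feats[k, ] <- suppressWarnings(haralickFeatures(g))
  }
  ok <- stats::complete.cases(feats)
  if (!any(ok)) stopf("all 16 GLCMs empty: map too small for texture analysis")
  avg <- colMeans(feats[ok, , drop = FALSE])
  structure(list(CON = avg[["CON"]], COR = avg[["COR"]], ENE = avg[["ENE"]],
                 HOM = avg[["HOM"]], sourceParameter = param,
                 nConfigurations = sum(ok)),
            class = "TextureSet")
}

#' @export
print.TextureSet <- function(x, ...) {
  cat(sprintf("TextureSet[%s]: CON = %.3f, COR = %.3f, ENE = %.3f, HOM = %.3f (%d GLCMs)\n",
              if (is.na(x$sourceParameter)) "?" else x$sourceParameter,
              x$CON, x$COR, x$ENE, x$HOM, x$nConfigurations))
  invisible(x)
}
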