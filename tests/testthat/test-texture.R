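test_that("quantization bins the value range uniformly and flags constants", {
  m <- matrix(c(0, 1, 2, 3), 2, 2)
  q <- quantizeMap(m, nLevels = 4)
  expect_equal(sort(as.vector(q$levels)), 0:3)
  expect_false(q$degenerate)
  qc <- suppressWarnings(quantizeMap(matrix(5, 3, 3)))
  expect_true(qc$degenerate)
  expect_true(all(qc$levels == 0))
  ## masked cells stay NA and do not affect the range
  pm <- ParametricMap(matrix(c(1, 2, 3, 100), 2, 2), "MBF",
                      mask = matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2))
  qm <- quantizeMap(pm, nLevels = 4)
  expect_true(is.na(qm$levels[2, 2]))
  expect_equal(qm$valueRange, c(1, 3))
})

test_that("there are 16 GLCM configurations: distances 1-4 x angles 0/45/90/135", {
  cfg <- glcmConfigurations()
  expect_equal(nrow(cfg), 16)
  expect_setequal(unique(cfg$distance), 1:4)
  expect_setequal(unique(cfg$angle), c(0, 45, 90, 135))
  expect_equal(nrow(unique(cfg)), 16)
})

test_that("GLCMs match hand-computed values on a 2x2 two-level map", {
  ## map: top row level 0, bottom row level 1
  q <- quantizeMap(rbind(c(1, 1), c(2, 2)), nLevels = 2)
  lat <- computeGLCM(q, 1, 0)             # lateral pairs: (0,0) and (1,1)
  expect_equal(lat$matrix, matrix(c(0.5, 0, 0, 0.5), 2, 2))
  hLat <- haralickFeatures(lat)
  expect_equal(unname(hLat), c(0, 1, 0.5, 1))
  ax <- computeGLCM(q, 1, 90)             # axial pairs: (1,0) twice
  expect_equal(ax$matrix, matrix(c(0, 0.5, 0.5, 0), 2, 2))
  hAx <- haralickFeatures(ax)
  expect_equal(unname(hAx), c(1, -1, 0.5, 0.5))
})

test_that("GLCMs are symmetric, normalized and skip masked pairs", {
  set.seed(1)
  q <- quantizeMap(matrix(rnorm(64), 8, 8), nLevels = 8)
  for (k in seq_len(nrow(glcmConfigurations()))) {
    cfg <- glcmConfigurations()[k, ]
    g <- computeGLCM(q, cfg$distance, cfg$angle)
    expect_false(g$empty)
    expect_equal(sum(g$matrix), 1, tolerance = 1e-12)
    expect_equal(g$matrix, t(g$matrix))
  }
  ## masking one cell removes its pairs from the counts
  m <- matrix(rnorm(36), 6, 6)
  qFull <- quantizeMap(m, 4)
  mNA <- m; mNA[3, 3] <- NA
  qMasked <- quantizeMap(mNA, 4)
  gF <- computeGLCM(qFull, 1, 0)
  gM <- computeGLCM(qMasked, 1, 0)
  expect_equal(gM$nPairs, gF$nPairs - 2)  # pairs (3,2)-(3,3) and (3,3)-(3,4)
})

test_that("an offset larger than the map yields an empty GLCM that cannot be summarized", {
  q <- quantizeMap(matrix(rnorm(4), 2, 2), 2)
  g <- computeGLCM(q, 4, 0)
  expect_true(g$empty)
  expect_equal(g$nPairs, 0)
  expect_error(haralickFeatures(g), "empty GLCM")
})

test_that("GLCM features equal the brute-force oracle on random maps", {
  set.seed(7)
  for (rep in 1:3) {
    m <- matrix(rnorm(36), 6, 6)
    q <- quantizeMap(m, nLevels = 6)
    cfg <- glcmConfigurations()
    for (k in seq_len(nrow(cfg))) {
      g <- computeGLCM(q, cfg$distance[k], cfg$angle[k])
      oracle <- bruteGLCM(q$levels, q$nLevels, cfg$distance[k], cfg$angle[k])
      expect_equal(g$matrix, oracle, tolerance = 1e-14)
      if (!g$empty)
        expect_equal(unname(suppressWarnings(haralickFeatures(g))),
                     unname(bruteHaralick(oracle)), tolerance = 1e-12)
    }
  }
})

test_that("texture features average the non-empty configurations", {
  set.seed(3)
  m <- matrix(rnorm(15 * 12), 15, 12)
  tx <- textureFeatures(m)
  expect_equal(tx$nConfigurations, 16)
  expect_true(tx$CON >= 0)
  expect_true(tx$ENE > 0 && tx$ENE <= 1)
  expect_true(tx$HOM > 0 && tx$HOM <= 1)
  expect_true(abs(tx$COR) <= 1 + 1e-12)
})

test_that("texture features are invariant to affine rescaling of the map", {
  set.seed(11)
  m <- matrix(rnorm(100), 10, 10)
  a <- textureFeatures(m)
  b <- textureFeatures(3.7 * m + 42)
  expect_equal(a$CON, b$CON)
  expect_equal(a$COR, b$COR)
  expect_equal(a$ENE, b$ENE)
  expect_equal(a$HOM, b$HOM)
})

test_that("a constant map degenerates to CON 0, COR/ENE/HOM 1 with a warning", {
  expect_warning(tx <- textureFeatures(matrix(2, 8, 8)), "constant map")
  expect_equal(c(tx$CON, tx$COR, tx$ENE, tx$HOM), c(0, 1, 1, 1))
  expect_equal(tx$nConfigurations, 0L)
})
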