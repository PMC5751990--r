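## Small, well-separated synthetic data used across classifier tests.
makeSeparable <- function(n = 10, seed = 1) {
  set.seed(seed)
  y <- rep(c("A", "B", "C"), each = n)
  X <- cbind(
    good1 = c(rnorm(n, 0), rnorm(n, 6), rnorm(n, 12)) / 2,
    good2 = c(rnorm(n, 0), rnorm(n, -6), rnorm(n, -12)) / 2,
    noise1 = rnorm(3 * n),
    noise2 = rnorm(3 * n))
  list(X = X, y = y)
}

test_that("balanced subsets contain min(class sizes) samples of every class", {
  labels <- rep(c("CR", "PR", "NR"), c(21, 52, 23))
  plan <- balancedSubsets(labels, nSubsets = 10, seed = 3)
  expect_length(plan$subsets, 10)
  for (s in plan$subsets) {
    expect_length(s, 63)
    expect_equal(as.vector(table(labels[s])), c(21, 21, 21))
    ## the minimum-size class contributes all of its members
    expect_true(all(which(labels == "CR") %in% s))
  }
  expect_identical(plan, balancedSubsets(labels, 10, seed = 3))
  plan2 <- balancedSubsets(labels, 10, seed = 4)
  expect_false(identical(plan, plan2))
  expect_error(balancedSubsets(rep("CR", 5)), "class")
})

test_that("leave-one-out evaluation is perfect on well-separated classes", {
  d <- makeSeparable()
  ev <- looEvaluate(d$X, d$y, selected = c("good1", "good2"),
                    C = 10, gamma = 0.5)
  expect_equal(ev$accuracy, 100)
  expect_equal(unname(ev$sensitivity), c(100, 100, 100))
  expect_equal(unname(ev$specificity), c(100, 100, 100))
  expect_equal(dim(ev$confusion), c(3, 3))
  expect_equal(sum(ev$confusion), length(d$y))
})

test_that("the grid search scans the full grid and breaks ties toward small C", {
  d <- makeSeparable(n = 5)
  cfg <- classifierConfig(CGrid = 2^(0:2), gammaGrid = 2^(-2:0),
                          nSubsets = 2, nSelected = 2)
  gs <- gridSearchSVM(d$X[, 1:2], d$y, cfg)
  expect_equal(nrow(gs$grid), 9)
  expect_true(gs$C %in% cfg$CGrid && gs$gamma %in% cfg$gammaGrid)
  ## the reported pair attains the maximum at the smallest C then gamma
  top <- gs$grid[gs$grid$accuracy == max(gs$grid$accuracy), ]
  expect_equal(gs$C, min(top$C))
  expect_equal(gs$gamma, min(top$gamma[top$C == gs$C]))
  expect_error(gridSearchSVM(d$X, rep("A", nrow(d$X)), cfg), "two classes")
})

test_that("forward selection picks the informative features first", {
  d <- makeSeparable(seed = 5)
  cfg <- classifierConfig(nSelected = 2)
  sel <- sfsSelect(d$X, d$y, cfg, C = 10, gamma = 0.5)
  expect_length(sel$selected, 2)
  expect_setequal(sel$selected, c("good1", "good2"))
  expect_true(all(diff(sel$accuracyPath) >= -1e-9) ||
              sel$accuracyPath[1] <= max(sel$accuracyPath))
  expect_warning(
    sfsSelect(d$X[, 1:2], d$y, classifierConfig(nSelected = 6),
              C = 10, gamma = 0.5),
    "fewer candidate features")
})

test_that("consensus features rank by cross-subset occurrence with stable ties", {
  sel <- list(perSubset = list(c("a", "b"), c("a", "c"), c("a", "b")),
              featureOrder = c("z", "a", "b", "c"))
  top <- consensusFeatures(sel, k = 2)
  expect_identical(as.character(top[1:2]), c("a", "b"))
  expect_equal(attr(top, "counts"), c(3L, 2L))
  ## all counts equal: ties broken by the fixed feature order, with a warning
  tied <- list(perSubset = list(c("c", "b"), c("b", "c"), "a"),
               featureOrder = c("a", "b", "c"))
  expect_warning(t2 <- consensusFeatures(tied, k = 2), NA) # counts differ
  tiedAll <- list(perSubset = list("c", "b", "a"),
                  featureOrder = c("b", "c", "a"))
  expect_warning(t3 <- consensusFeatures(tiedAll, k = 2), "ties broken")
  expect_identical(as.character(t3), c("b", "c"))
  expect_warning(consensusFeatures(tied, k = 10), "fewer distinct")
  expect_error(consensusFeatures(list(perSubset = list())), "empty")
})

test_that("the full protocol reports per-subset metrics and a consensus set", {
  co <- simulateCohort(CohortSpec(groupSizes = c(CR = 7L, PR = 9L, NR = 7L)),
                       seed = 5)
  ft <- cohortFeatureTable(co, "week8")
  cfg <- classifierConfig(CGrid = 2^c(2, 6), gammaGrid = 2^c(-6, -3),
                          nSubsets = 3, nSelected = 2, seed = 1)
  ## restrict to a small candidate set to keep the test fast
  cols <- c("id", "label", "dMBF", "dSI", "dAAC", "dSS", "SS0", "ACE0")
  res <- runResponseClassification(ft[, cols], "combined", cfg)
  expect_s3_class(res, "ResponseClassification")
  expect_length(res$perSubset, 3)
  expect_length(res$selection$perSubset, 3)
  expect_length(res$selection$consensus, 2)
  expect_true(all(res$selection$consensus %in% setdiff(cols, c("id", "label"))))
  expect_true(res$meanAccuracy >= 0 && res$meanAccuracy <= 100)
  expect_equal(sum(res$selection$histogram), 3 * 2)
})

test_that("the binary task merges CR and PR into responders before balancing", {
  co <- simulateCohort(CohortSpec(groupSizes = c(CR = 5L, PR = 6L, NR = 4L)),
                       seed = 9)
  ft <- cohortFeatureTable(co, "week4")
  cfg <- classifierConfig(CGrid = 4, gammaGrid = 0.25, nSubsets = 2,
                          nSelected = 1, seed = 2,
                          task = "responder_vs_nonresponder")
  res <- runResponseClassification(ft[, c("id", "label", "dMBF", "dAAC")],
                                   "combined", cfg)
  expect_identical(sort(res$plan$classes), c("NR", "R"))
  expect_equal(res$plan$perClass, 4)      # min(11 R, 4 NR)
  expect_true(all(lengths(res$plan$subsets) == 8))
})
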