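test_that("featurization entries follow the inverse-distance overlap rule", {
  reps <- featureFrame(c("HBA", "AR"), c(0, 5), 0, 0, memberCount = c(3L, 2L),
                       activities = list(c(6, 7, 8), c(5, 6)))
  sampleAt <- function(x, type = "HBA")
    Pharmacophore(featureFrame(type, x, 0, 0))
  ## overlap at 0.5 A: inverse distance 2
  expect_equal(featurize(sampleAt(0.5), reps, "distance")[1], 2)
  ## no overlap at 2 A: zero
  expect_equal(featurize(sampleAt(2), reps, "distance")[1], 0)
  ## binary weights
  expect_equal(as.numeric(featurize(sampleAt(0.5), reps, "none")), c(1, 0))
  ## member-count weighting
  expect_equal(featurize(sampleAt(0.5), reps, "nrOfFeatures")[1], 6)
  ## near-zero distances are floored at 0.01 A
  expect_equal(featurize(sampleAt(0), reps, "distance")[1], 100)
  ## a sample feature matching no representative is out of domain
  v <- featurize(sampleAt(0.5, "PI"), reps, "distance")
  expect_equal(as.numeric(v), c(0, 0))
  expect_equal(attr(v, "oodFeatures"), 1L)
  ## type must match even within range
  expect_equal(featurize(sampleAt(0.5, "AR"), reps, "distance")[1], 0)
})

test_that("featurize entries stay within [0, 1/eps] and zero iff no overlap", {
  set.seed(41)
  reps <- featureFrame(rep("H", 4), runif(4, 0, 6), runif(4, 0, 6),
                       runif(4, 0, 6), memberCount = 2L,
                       activities = rep(list(c(5, 6)), 4))
  for (i in 1:20) {
    ph <- randomPharmacophore(5)
    v <- featurize(ph, reps, "distance")
    expect_true(all(v >= 0 & v <= 100))
    vb <- featurize(ph, reps, "none")
    expect_true(all(vb %in% c(0, 1)))
    expect_equal(as.numeric(vb), as.numeric(v > 0))
  }
})

test_that("fitting a synthetic series yields a working, deterministic model", {
  gen <- generateSynthData(synthSpecRecovery(seed = 5))
  cfg <- qpharConfig(randomSeed = 5)
  m1 <- fitQphar(gen$dataset, cfg)
  expect_s4_class(m1, "QpharModel")
  expect_gte(nrow(representatives(m1)), 1)
  expect_true(all(representatives(m1)$memberCount >= 2))
  ## determinism: same data, same seed, identical predictions
  m2 <- fitQphar(gen$dataset, cfg)
  for (s in samples(gen$dataset)[1:5])
    expect_identical(predict(m1, s)$estimate, predict(m2, s)$estimate)
})

test_that("datasets whose features all span the activity range are degenerate", {
  ## identical pharmacophores with wildly different activities: every
  ## cluster inherits the full range
  phs <- lapply(1:6, function(i)
    makePh(c("AR", "HBD", "H"), c(0, 0, 0, 4, 0, 0, 0, 4, 0),
           id = sprintf("S%d", i)))
  ds <- ActivityDataset(phs, c(4, 5, 6, 7, 8, 9))
  expect_error(suppressMessages(fitQphar(ds, qpharConfig())), "pruned")
})

test_that("prediction reports the applicability domain", {
  gen <- generateSynthData(synthSpecRecovery(seed = 6))
  m <- fitQphar(gen$dataset, qpharConfig(randomSeed = 6))
  pr <- predict(m, samples(gen$dataset)[[2]])
  expect_true(pr$inDomain)
  expect_true(is.finite(pr$estimate))
  ## a sample sharing no feature types with the template
  alien <- makePh(c("NI", "NI", "NI"), c(0, 0, 0, 3, 0, 0, 0, 3, 0))
  pr2 <- predict(m, alien)
  expect_false(pr2$inDomain)
  expect_true(is.na(pr2$estimate))
  ## the template itself predicts within a sane activity window
  pr3 <- predict(m, modelTemplate(m))
  rng <- globalActivityRange(m)
  span <- diff(rng)
  expect_gte(pr3$estimate, rng[1] - span)
  expect_lte(pr3$estimate, rng[2] + span)
})

test_that("the default grid enumerates the full 90-configuration space", {
  grid <- defaultGrid()
  expect_equal(length(grid), 90)
  tab <- table(vapply(grid, function(g) g@modelType, character(1)))
  expect_equal(as.integer(tab[c("ridge", "pls", "pca_ridge", "pca_linear")]),
               rep(9L, 4))
  expect_equal(as.integer(tab["random_forest"]), 54L)  # 3 wt x 3 cut x 3 trees x 2 depths
  cuts <- unique(vapply(grid, function(g) g@clusterCutoff, numeric(1)))
  expect_equal(sort(cuts), c(1, 1.5, 2))
})

test_that("grid search returns the configuration minimising CV error", {
  gen <- generateSynthData(synthSpecRecovery(seed = 8))
  ds <- qphar:::.subsetDataset(gen$dataset, 1:12)
  small <- list(qpharConfig(modelType = "ridge", randomSeed = 8),
                qpharConfig(modelType = "random_forest", randomSeed = 8),
                qpharConfig(modelType = "pls", weightType = "none",
                            randomSeed = 8))
  gs <- suppressMessages(suppressWarnings(
    gridSearch(ds, folds = 2L, seed = 8, grid = small)))
  expect_s4_class(gs$best, "QpharConfig")
  expect_equal(nrow(gs$table), 3)
  best <- min(gs$table$meanRMSE)
  expect_equal(gs$table$meanRMSE[gs$table$config ==
    which(vapply(small, identical, logical(1), gs$best))], best)
})

test_that("the model report tabulates the interpretability surface", {
  gen <- generateSynthData(synthSpecRecovery(seed = 9))
  m <- fitQphar(gen$dataset, qpharConfig(randomSeed = 9))
  rep <- modelReport(m)
  expect_equal(nrow(rep), nrow(representatives(m)))
  expect_true(all(c("type", "memberCount", "activityMin", "activityMax")
                  %in% names(rep)))
  expect_true(all(rep$activityMax - rep$activityMin <=
                  diff(globalActivityRange(m)) / 2 + 1e-12))
})
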