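test_that("KL heterogeneity matches its closed forms", {
  ## one activity per bin: P = Q, KL = 0
  r0 <- klHeterogeneity(c(4.5, 5.5, 6.5, 7.5))
  expect_equal(r0$kl, 0)
  expect_true(r0$pass)          # range 3 and KL 0
  ## all mass in one bin at N = 4: KL = ln 4
  r1 <- klHeterogeneity(rep(6, 4))
  expect_equal(r1$kl, log(4))
  expect_false(r1$pass)
  ## wide uniform range passes; narrow uniform range fails the 3-log gate
  expect_true(klHeterogeneity(seq(4, 9, length.out = 10) + 0.25)$pass)
  expect_false(klHeterogeneity(seq(5, 6, length.out = 10) + 0.05)$pass)
})

test_that("KL is invariant under affine rescaling of the activity axis", {
  set.seed(51)
  for (i in 1:100) {
    y <- rnorm(sample(5:40, 1), 6, 1.2)
    a <- runif(1, 0.2, 5); b <- runif(1, -10, 10)
    expect_equal(klHeterogeneity(y)$kl, klHeterogeneity(a * y + b)$kl,
                 tolerance = 1e-12)
  }
})

test_that("stratified folds partition the data with balanced classes", {
  folds <- stratifiedKFold(1:10, k = 5, seed = 1)
  tests <- lapply(folds, `[[`, "test")
  expect_equal(sort(unlist(tests)), 1:10)
  expect_true(all(lengths(tests) == 2))
  ## activities 1..10 in 5 equal-width bins: pairs {1,2},{3,4},...;
  ## each fold's two samples come from two distinct bins
  binOf <- qphar:::.binIndices(1:10, 1, 10, 5)
  for (te in tests) expect_equal(length(unique(binOf[te])), 2)
  ## train is the complement
  for (f in folds) expect_equal(sort(c(f$train, f$test)), 1:10)
  ## reproducible, and responsive to the seed
  expect_identical(folds, stratifiedKFold(1:10, k = 5, seed = 1))
})

test_that("fold class proportions track the global proportions within one", {
  set.seed(52)
  y <- rnorm(47, 6, 1)
  folds <- stratifiedKFold(y, k = 5, seed = 3)
  binOf <- qphar:::.binIndices(y, min(y), max(y), 5)
  for (b in unique(binOf)) {
    perFold <- vapply(folds, function(f) sum(binOf[f$test] == b), integer(1))
    expect_lte(diff(range(perFold)), 1)
  }
})

test_that("single stratified splits hit the requested sizes exactly", {
  set.seed(53)
  y <- rnorm(50, 6, 1.5)
  s20 <- makeSplit(y, 0.2, seed = 2)
  expect_equal(length(s20$train), 10)
  expect_equal(length(s20$test), 40)
  s80 <- makeSplit(y, 0.8, seed = 2)
  expect_equal(length(s80$train), 40)
  expect_equal(length(s80$test), 10)
  expect_equal(sort(c(s80$train, s80$test)), 1:50)
})

test_that("baseline domains are the training min/max bounds", {
  bm <- fitBaseline("feature_counts", rbind(c(1, 2), c(3, 4)), c(5, 6))
  expect_equal(unname(bm$domainMin), c(1, 2))
  expect_equal(unname(bm$domainMax), c(3, 4))
  expect_true(baselineInDomain(bm, c(2, 3)))
  expect_false(baselineInDomain(bm, c(0, 3)))
  expect_true(baselineInDomain(bm, c(1, 2)))   # training vectors in-domain
  expect_true(baselineInDomain(bm, c(3, 4)))
  expect_error(baselineInDomain(bm, c(1, 2, 3)), "dimension")
})

test_that("baseline models train and predict reproducibly on synthetic data", {
  gen <- generateSynthData(synthSpec(seed = 4))
  X <- buildBaselineVectors(gen$dataset, "feature_counts")
  expect_equal(dim(X), c(30, 6))
  y <- activities(gen$dataset)
  cfg <- qpharConfig(randomSeed = 4)
  b1 <- fitBaseline("feature_counts", X, y, cfg)
  b2 <- fitBaseline("feature_counts", X, y, cfg)
  p1 <- predictBaseline(b1, X); p2 <- predictBaseline(b2, X)
  expect_identical(p1, p2)
  expect_true(all(is.finite(p1)))
  ## all training vectors are inside their own domain
  expect_true(all(vapply(seq_len(nrow(X)), function(i)
    baselineInDomain(b1, X[i, ]), logical(1))))
})

test_that("evaluation metrics match hand arithmetic", {
  ev <- evaluatePredictions(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ev$rmse, 0); expect_equal(ev$r2, 1)
  ev2 <- evaluatePredictions(c(1, 1), c(0, 2))
  expect_equal(ev2$rmse, 1); expect_equal(ev2$r2, 0)
  truths <- c(4, 6, 8)
  ev3 <- evaluatePredictions(rep(mean(truths), 3), truths)
  expect_equal(ev3$r2, 0)
  expect_true(is.na(evaluatePredictions(c(1, 2), c(3, 3))$r2))
})

test_that("cross-validation aggregates are consistent and reproducible", {
  gen <- generateSynthData(synthSpecPositional(seed = 2))
  rep1 <- suppressMessages(runCV(gen$dataset, c("qphar", "feature_baseline"),
                                 k = 3, seed = 2))
  ## means and SDs recompute from the per-fold table
  for (m in unique(rep1$perFold$method)) {
    r <- rep1$perFold$rmse[rep1$perFold$method == m]
    s <- rep1$summary[rep1$summary$method == m, ]
    expect_equal(s$meanRMSE, mean(r))
    expect_equal(s$sdRMSE, sd(r))
  }
  rep2 <- suppressMessages(runCV(gen$dataset, c("qphar", "feature_baseline"),
                                 k = 3, seed = 2))
  expect_identical(rep1$perFold, rep2$perFold)
  expect_identical(rep1$summary, rep2$summary)
})

test_that("activity-record curation applies the standard predicates", {
  rec <- data.frame(
    molecule_id = paste0("m", 1:8),
    standard_type = c("IC50", "Ki", "EC50", "IC50", "IC50", "Ki", "IC50", "IC50"),
    standard_value = c(10, 100, 10, -5, 1000, 20, 50, 10),
    standard_units = c("nM", "nM", "nM", "nM", "uM", "nM", "nM", "nM"),
    standard_relation = c("=", "=", "=", "=", "=", ">", "=", "="),
    assay_type = c("B", "B", "B", "B", "B", "B", "F", "B"),
    assay_id = c("a1", "a1", "a1", "a1", "a1", "a1", "a1", "a2"),
    target_organism = c(rep("Homo sapiens", 7), "Mus musculus"))
  cur <- curateActivityRecords(rec)
  ## survivors: m1 (all predicates), m2; the rest each violate one filter
  expect_equal(cur$records$molecule_id, c("m1", "m2"))
  expect_equal(cur$records$pActivity, c(8, 7))
  expect_true(all(c("assay_id", "kl", "pass") %in% names(cur$assays)))
})
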