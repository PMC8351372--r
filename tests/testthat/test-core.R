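test_that("activity values convert to pActivity on the molar log scale", {
  expect_equal(toLogActivity(1, "nM"), 9)
  expect_equal(toLogActivity(1, "uM"), 6)
  expect_equal(toLogActivity(1, "µM"), 6)
  expect_equal(toLogActivity(1, "M"), 0)
  expect_equal(toLogActivity(7.3, "logunits"), 7.3)
  expect_error(toLogActivity(0, "nM"), "positive")
  expect_error(toLogActivity(-1, "uM"), "positive")
  expect_error(toLogActivity(1, "parsecs"), "unknown")
})

test_that("log transform is strictly decreasing and unit-invariant in differences", {
  v <- sort(10^runif(20, -2, 4))
  p <- toLogActivity(v, "nM")
  expect_true(all(diff(p) < 0))
  ## the same ratio of raw values gives the same log difference in any unit
  d_nM <- toLogActivity(50, "nM") - toLogActivity(500, "nM")
  d_uM <- toLogActivity(0.05, "uM") - toLogActivity(0.5, "uM")
  expect_equal(d_nM, d_uM)
})

test_that("feature tables enforce the six-type vocabulary and geometry", {
  expect_error(featureFrame("XX", 0, 0, 0), "XX")
  expect_error(featureFrame("AR", NaN, 0, 0), "finite")
  expect_error(featureFrame("AR", 0, 0, 0, radius = 0), "positive")
  df <- featureFrame(c("H", "AR"), 1:2, 0, 0)
  expect_equal(df$radius, c(1.5, 1.5))
  expect_equal(df$memberCount, c(1L, 1L))
})

test_that("pharmacophore JSON round-trips features exactly", {
  ph <- makePh(c("H", "AR", "PI", "HBD", "HBA"),
               rnorm(15), id = "mol-7", activity = 6.25)
  path <- tempfile(fileext = ".json")
  writePharmacophoreJSON(ph, path)
  back <- readPharmacophoreJSON(path)
  expect_equal(sampleId(back), "mol-7")
  expect_equal(activity(back), 6.25)
  expect_equal(features(back)$type, features(ph)$type)
  for (col in c("x", "y", "z", "radius"))
    expect_lt(max(abs(features(back)[[col]] - features(ph)[[col]])), 1e-9)
})

test_that("merged-model JSON keeps member counts and inherited activities", {
  df <- featureFrame(c("AR", "HBA"), c(0, 3), 0, 0, memberCount = c(4L, 2L),
                     activities = list(c(5, 6, 7, 8), c(6.5, 7.5)))
  path <- tempfile(fileext = ".json")
  writePharmacophoreJSON(Pharmacophore(df, sampleId = "merged"), path,
                         merged = TRUE)
  back <- features(readPharmacophoreJSON(path))
  expect_equal(back$memberCount, c(4L, 2L))
  expect_equal(back$activities, list(c(5, 6, 7, 8), c(6.5, 7.5)))
})

test_that("unknown feature type codes in JSON are rejected by name", {
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(list(id = "x", activity = NULL, features = list(
    list(type = "XX", x = 0, y = 0, z = 0, radius = 1.5))),
    path, auto_unbox = TRUE, null = "null")
  expect_error(readPharmacophoreJSON(path), "XX")
})

test_that("directed features are reduced to spherical base points", {
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(list(id = "x", activity = NULL, features = list(
    list(type = "HBD", x = 1, y = 2, z = 3, radius = 1.5,
         nx = 0, ny = 0, nz = 1),
    list(type = "AR", x = 0, y = 0, z = 0, radius = 1.5),
    list(type = "H", x = 4, y = 0, z = 0, radius = 1.5))),
    path, auto_unbox = TRUE, null = "null")
  back <- features(readPharmacophoreJSON(path))
  expect_equal(nrow(back), 3)
  expect_false(any(c("nx", "ny", "nz") %in% names(back)))
  expect_equal(as.numeric(back[1, c("x", "y", "z")]), c(1, 2, 3))
})

test_that("SDF loading counts samples, skips missing activities, groups conformers", {
  path <- tempfile(fileext = ".sdf")
  writeLines(c(benzeneRecord("mol1", tags = c(IC50_nM = "100")),
               benzeneRecord("mol2", tags = c(IC50_nM = "10")),
               benzeneRecord("mol3", tags = c(IC50_nM = "1000"))), path)
  ds <- loadMolecules(path, "IC50_nM")
  expect_equal(length(samples(ds)), 3)
  expect_equal(attr(ds, "skipped"), 0L)
  ## activities arrive on the log scale
  expect_equal(sort(activities(ds)), c(6, 7, 8))

  ## a record without the tag is skipped and counted
  writeLines(c(benzeneRecord("mol1", tags = c(IC50_nM = "100")),
               benzeneRecord("mol2", tags = c(OTHER = "1"))), path)
  expect_warning(ds2 <- loadMolecules(path, "IC50_nM"), "skipped")
  expect_equal(length(samples(ds2)), 1)
  expect_equal(attr(ds2, "skipped"), 1L)

  ## two records sharing a title become one 2-conformer sample
  rot <- benzeneRecord("mol1", coords = .hexagon(cx = 2),
                       tags = c(IC50_nM = "100"))
  writeLines(c(benzeneRecord("mol1", tags = c(IC50_nM = "100")), rot), path)
  ds3 <- loadMolecules(path, "IC50_nM")
  expect_equal(length(samples(ds3)), 1)
  expect_equal(length(conformers(samples(ds3)[[1]])), 2)
})

test_that("model archives round-trip to identical predictions", {
  gen <- generateSynthData(synthSpecRecovery(seed = 3))
  model <- fitQphar(gen$dataset, qpharConfig(randomSeed = 3))
  dir <- tempfile()
  saveQpharModel(model, dir)
  expect_true(file.exists(file.path(dir, "merged_pharmacophore.json")))
  back <- loadQpharModel(dir)
  expect_equal(nrow(representatives(back)), nrow(representatives(model)))
  expect_equal(globalActivityRange(back), globalActivityRange(model))
  for (s in samples(gen$dataset)[1:5]) {
    p1 <- predict(model, s); p2 <- predict(back, s)
    expect_identical(p1$estimate, p2$estimate)
    expect_identical(p1$inDomain, p2$inDomain)
  }
})
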