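test_that("superposition recovers closed-form rigid transforms", {
  set.seed(21)
  P <- matrix(rnorm(15), 5, 3)
  s <- superpose(P, P)
  expect_equal(s$rotation, diag(3), tolerance = 1e-9)
  expect_equal(s$translation, rep(0, 3), tolerance = 1e-9)
  expect_equal(s$rmsd, 0, tolerance = 1e-9)

  s2 <- superpose(P, sweep(P, 2, c(1, 2, 3)))   # query = P - (1,2,3)
  expect_equal(s2$translation, c(1, 2, 3), tolerance = 1e-9)
  expect_equal(s2$rmsd, 0, tolerance = 1e-9)

  Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3)  # 90 deg about z
  Q <- P %*% t(Rz)
  s3 <- superpose(P, Q)
  expect_equal(s3$rmsd, 0, tolerance = 1e-9)
  expect_equal(Q %*% t(s3$rotation) +
                 matrix(s3$translation, 5, 3, byrow = TRUE), P,
               tolerance = 1e-9)
  expect_equal(det(s3$rotation), 1, tolerance = 1e-9)
  expect_error(superpose(P[1:2, ], P[1:2, ]), "3 points")
})

test_that("superposition never returns a reflection", {
  set.seed(22)
  for (i in 1:20) {
    P <- matrix(rnorm(12), 4, 3)
    Q <- P; Q[, 1] <- -Q[, 1]          # mirrored query
    s <- superpose(P, Q)
    expect_equal(det(s$rotation), 1, tolerance = 1e-9)
  }
})

test_that("self-alignment is perfect and disjoint types align nowhere", {
  ph <- makePh(c("AR", "HBD", "H", "HBA"),
               c(0, 0, 0, 4, 0, 0, 0, 4, 0, 2, 2, 2))
  res <- alignPharmacophores(ph, ph)
  expect_equal(res$score, 4)
  expect_lt(res$rmsd, 1e-9)
  other <- makePh(c("PI", "PI", "NI"), c(0, 0, 0, 3, 0, 0, 0, 3, 0))
  expect_null(alignPharmacophores(other, ph))
})

test_that("a rigidly transformed copy aligns back onto the template", {
  set.seed(23)
  ph <- randomPharmacophore(6)
  R <- randomRotation(); tr <- runif(3, -8, 8)
  moved <- transformPharmacophore(ph, R, tr)
  res <- alignPharmacophores(moved, ph)
  expect_equal(res$score, 6)
  expect_lt(res$rmsd, 1e-6)
  back <- features(res$alignedQuery)
  expect_lt(max(abs(as.matrix(back[, c("x", "y", "z")]) -
                    as.matrix(features(ph)[, c("x", "y", "z")]))), 1e-6)
})

test_that("alignment score and rmsd are invariant under rigid motion of the query", {
  set.seed(24)
  for (i in 1:10) {
    template <- randomPharmacophore(sample(4:7, 1))
    query <- transformPharmacophore(template, randomRotation(), runif(3, -5, 5))
    base <- alignPharmacophores(query, template)
    again <- alignPharmacophores(
      transformPharmacophore(query, randomRotation(), runif(3, -5, 5)),
      template)
    expect_equal(again$score, base$score)
    expect_lt(abs(again$rmsd - base$rmsd), 1e-6)
  }
})

test_that("seeded search matches the exhaustive mapping oracle on small cases", {
  set.seed(25)
  for (i in 1:15) {
    template <- randomPharmacophore(sample(4:5, 1))
    ## query: transformed template subset plus unrelated extra features,
    ## lightly jittered, so real correspondences exist to be found
    keep <- sort(sample(nFeatures(template), sample(3:4, 1)))
    qf <- features(template)[keep, , drop = FALSE]
    qf[, c("x", "y", "z")] <- qf[, c("x", "y", "z")] +
      matrix(rnorm(3 * nrow(qf), 0, 0.2), ncol = 3)
    extra <- features(randomPharmacophore(2))
    query <- transformPharmacophore(
      Pharmacophore(rbind(qf, extra), sampleId = "q"),
      randomRotation(), runif(3, -5, 5))
    res <- alignPharmacophores(query, template)
    oracle <- alignmentOracleScore(query, template)
    got <- if (is.null(res)) 0L else res$score
    expect_gte(got, oracle)
    expect_lte(got, min(nFeatures(template), nFeatures(query)))
  }
})

test_that("the best-fitting conformer wins sample alignment", {
  tpath <- tempfile(fileext = ".sdf")
  writeLines(aminophenolRecord(), tpath)
  template <- perceivePharmacophore(samples(loadMolecules(tpath, "ACT"))[[1]])
  expect_gte(nFeatures(template), 5)
  path <- tempfile(fileext = ".sdf")
  writeLines(c(aminophenolRecord("m", transform = function(x)
                 sweep(x, 2, c(3, -1, 2), "+")),      # rigid copy
               aminophenolRecord("m", transform = function(x) x * 2.2)),
             path)                                    # blown-up geometry
  mol <- samples(loadMolecules(path, "ACT"))[[1]]
  res <- alignSample(mol, template)
  expect_equal(res$conformerIndex, 1L)
  expect_equal(res$score, nFeatures(template))

  ## no shared feature types: out of domain
  ionic <- makePh(c("PI", "NI", "PI"), c(0, 0, 0, 3, 0, 0, 0, 3, 0))
  expect_null(alignSample(ionic, template))
})
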