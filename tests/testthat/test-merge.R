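featRow <- function(x, y = 0, z = 0, radius = 1.5, type = "H",
                    activity = 5, mc = 1L)
  featureFrame(type, x, y, z, radius = radius, memberCount = mc,
               activities = as.list(rep_len(activity, length(x))))

test_that("clustering merges exactly the sub-cutoff links", {
  f <- featRow(c(0, 1, 2.6))
  cl <- clusterFeatures(f, cutoff = 1.5)
  expect_equal(lapply(cl, `[[`, "indices"), list(c(1L, 2L), 3L))
  ## all pairwise below the cutoff: one cluster
  f2 <- featRow(c(0, 1.4, 0.7), y = c(0, 0, 1.2))
  expect_equal(length(clusterFeatures(f2, cutoff = 1.5)), 1)
  ## singleton
  expect_equal(length(clusterFeatures(featRow(0), 1.5)), 1)
  ## empty input, empty output
  expect_equal(clusterFeatures(featureFrame(), 1.5), list())
  expect_error(clusterFeatures(featureFrame(c("H", "AR"), 1:2, 0, 0), 1.5),
               "single type")
})

test_that("clustering equals the brute-force single-linkage oracle", {
  set.seed(31)
  for (i in 1:100) {
    n <- sample(1:8, 1)
    pos <- matrix(runif(3 * n, 0, 6), n, 3)
    cutoff <- runif(1, 0.5, 3)
    f <- featureFrame(rep("AR", n), pos[, 1], pos[, 2], pos[, 3])
    got <- canonicalPartition(
      lapply(clusterFeatures(f, cutoff), `[[`, "indices"))
    expect_equal(got, singleLinkageOracle(pos, cutoff))
  }
})

test_that("each representative-selection branch behaves as specified", {
  ## (1) singleton: the feature itself
  r1 <- selectRepresentatives(featRow(2, activity = 6))
  expect_equal(attr(r1, "strategy"), "singleton")
  expect_equal(r1$memberCount, 1L)
  expect_equal(r1$x, 2)

  ## (2) middle member overlaps both ends
  r2 <- selectRepresentatives(featRow(c(0, 1.4, 2.8), activity = c(5, 6, 7)))
  expect_equal(attr(r2, "strategy"), "member")
  expect_equal(nrow(r2), 1)
  expect_equal(r2$x, 1.4)
  expect_equal(r2$memberCount, 3L)
  expect_equal(sort(r2$activities[[1]]), c(5, 6, 7))

  ## (3) no member covers all, the centroid does (equilateral, side 1.6)
  tri <- featRow(c(0, 1.6, 0.8), y = c(0, 0, 1.6 * sqrt(3) / 2))
  r3 <- selectRepresentatives(tri)
  expect_equal(attr(r3, "strategy"), "centroid")
  expect_equal(nrow(r3), 1)
  expect_equal(r3$memberCount, 3L)

  ## (4) centroid pulled away by a lopsided cluster, bounding-box centre works
  lop <- featRow(c(0, 0.1, 0.2, 2.9))
  r4 <- selectRepresentatives(lop)
  expect_equal(attr(r4, "strategy"), "centre")
  expect_equal(r4$x, 1.45)
  expect_equal(r4$memberCount, 4L)

  ## (5) nothing covers all: greedy multi-representative cover
  far <- featRow(c(0, 1.4, 2.8), radius = 1.4)
  r5 <- selectRepresentatives(far)
  expect_equal(attr(r5, "strategy"), "greedy")
  expect_gte(nrow(r5), 2)
  expect_equal(sum(r5$memberCount), 3L)
})

test_that("representative cover is a partition conserving counts and activities", {
  set.seed(32)
  for (i in 1:50) {
    n <- sample(2:8, 1)
    f <- featureFrame(rep("HBA", n), runif(n, 0, 4), runif(n, 0, 4),
                      runif(n, 0, 4), radius = 1.5,
                      activities = as.list(runif(n, 4, 9)))
    reps <- selectRepresentatives(f)
    assignment <- attr(reps, "assignment")
    expect_equal(length(assignment), n)
    expect_true(all(assignment >= 1 & assignment <= nrow(reps)))
    expect_equal(sum(reps$memberCount), n)
    expect_equal(sort(unlist(reps$activities)), sort(unlist(f$activities)))
    ## every member overlaps the representative it was assigned to
    for (j in seq_len(n)) {
      r <- assignment[j]
      d <- sqrt(sum((as.numeric(reps[r, c("x", "y", "z")]) -
                     as.numeric(f[j, c("x", "y", "z")]))^2))
      expect_lt(d, min(reps$radius[r], f$radius[j]))
    }
  }
})

test_that("ambiguity pruning applies the span and singleton rules", {
  mk <- function(acts, mc) featureFrame("AR", 0, 0, 0, memberCount = mc,
                                        activities = list(acts))
  ## span 4 over a [4, 9] range: more than half, removed
  wide <- mk(c(5, 9), 2L)
  ok <- mk(c(6, 7), 3L)
  once <- mk(6.5, 1L)
  kept <- pruneAmbiguous(rbind(wide, ok, once), 4, 9)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$memberCount, 3L)
  ## boundary: span exactly half is kept
  half <- mk(c(5, 7.5), 2L)
  expect_equal(nrow(pruneAmbiguous(rbind(half, ok), 4, 9)), 2)
  ## everything pruned is a degenerate-model error
  expect_error(pruneAmbiguous(rbind(wide, once), 4, 9), "pruned")
})
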