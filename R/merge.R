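#' Single-linkage feature clustering at a distance cutoff
#'
#' Minimum-distance (single-linkage) agglomerative clustering of same-type
#' features from a Euclidean distance matrix: two clusters merge exactly
#' when their minimum inter-feature distance is below `cutoff`. At a fixed
#' cutoff this partition equals the connected components of the graph with
#' an edge wherever two features are closer than `cutoff`, which is how it
#' is computed. The caller is expected to loop over the six per-type
#' feature containers; mixing types is an error.
#'
#' @param features feature table ([featureFrame()]), all of one type.
#' @param cutoff clustering cutoff in Angstrom (default 1.5, the feature
#'   radius).
#' @return list of clusters, each a list with `indices` (row indices into
#'   `features`) and `members` (the sub-table); ordered by smallest member
#'   index. Empty input gives an empty list.
#' @export
clusterFeatures <- function(features, cutoff = 1.5) {
  n <- nrow(features)
  if (n == 0) return(list())
  if (length(unique(features$type)) > 1)
    stop("clusterFeatures expects features of a single type")
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  d <- .featDist(features, features)
  for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
    if (d[i, j] < cutoff) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  lapply(sort(unique(roots)), function(r) {
    idx <- which(roots == r)
    list(indices = idx, members = features[idx, , drop = FALSE],
         type = features$type[idx[1]])
  })
}

.overlapMatrix <- function(members) {
  d <- .featDist(members, members)
  rmin <- outer(members$radius, members$radius, pmin)
  o <- d < rmin
  diag(o) <- TRUE
  o
}

.mergeInto <- function(position, type, radius, members, assigned) {
  sub <- members[assigned, , drop = FALSE]
  featureFrame(type = type, x = position[1], y = position[2], z = position[3],
               radius = radius, memberCount = sum(sub$memberCount),
               sourceId = "",
               activities = list(unlist(sub$activities)))
}

#' Select representative features for a cluster
#'
#' Reduces one cluster to as few representative features as possible. A
#' feature represents another when they overlap (distance below both
#' radii). Strategies are tried in order: (1) a singleton cluster is its
#' own representative; (2) an existing member that overlaps all other
#' members; (3) a new feature at the cluster centroid (mean position), if
#' it overlaps every member; (4) a new feature at the cluster centre
#' (bounding-box centre), likewise; (5) otherwise a greedy loop repeatedly
#' promotes the member overlapping the most remaining members and removes
#' the members it covers, until none remain. Every representative inherits
#' the activity values and the summed merged-feature count of everything it
#' represents.
#'
#' @param cluster a cluster as returned by [clusterFeatures()] (or a bare
#'   feature table).
#' @return feature table of representatives; attribute `"assignment"` maps
#'   each cluster member to the representative (row) covering it, and
#'   attribute `"strategy"` names the branch that produced the result.
#' @export
selectRepresentatives <- function(cluster) {
  members <- if (is.data.frame(cluster)) cluster else cluster$members
  n <- nrow(members)
  stopifnot(n >= 1)
  type <- members$type[1]
  done <- function(reps, assignment, strategy) {
    attr(reps, "assignment") <- assignment
    attr(reps, "strategy") <- strategy
    reps
  }
  if (n == 1)
    return(done(members, 1L, "singleton"))

  ov <- .overlapMatrix(members)
  coversAll <- which(rowSums(ov) == n)
  if (length(coversAll) > 0) {
    i <- coversAll[1]
    rep1 <- .mergeInto(as.numeric(members[i, c("x", "y", "z")]), type,
                       members$radius[i], members, seq_len(n))
    return(done(rep1, rep(1L, n), "member"))
  }

  pos <- as.matrix(members[, c("x", "y", "z")])
  newRadius <- min(members$radius)
  probeNew <- function(p) {
    d <- sqrt(colSums((t(pos) - p)^2))
    all(d < pmin(newRadius, members$radius))
  }
  centroid <- colMeans(pos)
  if (probeNew(centroid))
    return(done(.mergeInto(centroid, type, newRadius, members, seq_len(n)),
                rep(1L, n), "centroid"))
  centre <- (apply(pos, 2, min) + apply(pos, 2, max)) / 2
  if (probeNew(centre))
    return(done(.mergeInto(centre, type, newRadius, members, seq_len(n)),
                rep(1L, n), "centre"))

  ## greedy cover: most overlaps first, ties to the lowest member index
  remaining <- seq_len(n)
  reps <- NULL
  assignment <- integer(n)
  repIdx <- 0L
  while (length(remaining) > 0) {
    sub <- ov[remaining, remaining, drop = FALSE]
    counts <- rowSums(sub)
    pick <- remaining[which.max(counts)]
    covered <- remaining[sub[match(pick, remaining), ]]
    repIdx <- repIdx + 1L
    assignment[covered] <- repIdx
    reps <- rbind(reps, .mergeInto(as.numeric(members[pick, c("x", "y", "z")]),
                                   type, members$radius[pick],
                                   members, covered))
    remaining <- setdiff(remaining, covered)
  }
  done(reps, assignment, "greedy")
}

#' Remove ambiguous representative features
#'
#' A representative is kept only if its inherited activity values span at
#' most half the global activity range and it merges at least two source
#' features; wide-span features are non-conclusive (the shared-scaffold
#' case) and features encountered only once are unvalidated outliers.
#'
#' @param representatives feature table of representatives with inherited
#'   activities and merged counts.
#' @param globalMin,globalMax minimum and maximum training-set activity
#'   (log units).
#' @return the retained feature table.
#' @export
pruneAmbiguous <- function(representatives, globalMin, globalMax) {
  stopifnot(globalMax > globalMin)
  if (nrow(representatives) == 0) return(representatives)
  span <- vapply(representatives$activities,
                 function(a) if (length(a) == 0) Inf else diff(range(a)),
                 numeric(1))
  keep <- span <= (globalMax - globalMin) / 2 &
    representatives$memberCount >= 2L
  out <- representatives[keep, , drop = FALSE]
  if (nrow(out) == 0)
    stop("all representative features were pruned as ambiguous; ",
         "consider a different template or clustering cutoff",
         call. = FALSE)
  rownames(out) <- NULL
  out
}
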