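#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rigid transform (rotation `R`, translation `t`)
#' minimising the RMSD between paired point sets, i.e. mapping
#' `query %*% t(R) + t` onto `template`. Reflections are never returned.
#'
#' @param template,query n x 3 coordinate matrices, n >= 3, rows paired.
#' @return list with `rotation` (3 x 3, det +1), `translation` (length 3)
#'   and `rmsd`.
#' @export
#' @examples
#' p <- matrix(rnorm(12), 4, 3)
#' s <- superpose(p, p)
#' s$rmsd  # 0
superpose <- function(template, query) {
  template <- as.matrix(template); query <- as.matrix(query)
  if (nrow(template) != nrow(query))
    stop("point sets must have equal length")
  if (nrow(template) < 3)
    stop("superposition needs at least 3 points")
  tc <- colMeans(template); qc <- colMeans(query)
  P <- sweep(template, 2, tc); Q <- sweep(query, 2, qc)
  H <- crossprod(Q, P)                # 3x3
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  trans <- tc - as.numeric(R %*% qc)
  moved <- query %*% t(R) + matrix(trans, nrow(query), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((moved - template)^2)))
  list(rotation = R, translation = trans, rmsd = rmsd)
}

.applyTransform <- function(coords, rotation, translation) {
  as.matrix(coords) %*% t(rotation) +
    matrix(translation, nrow(coords), 3, byrow = TRUE)
}

#' Rigidly transform a pharmacophore
#'
#' @param pharmacophore a [Pharmacophore].
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 translation vector.
#' @return the transformed [Pharmacophore].
#' @export
transformPharmacophore <- function(pharmacophore, rotation,
                                   translation = c(0, 0, 0)) {
  df <- features(pharmacophore)
  if (nrow(df) > 0) {
    moved <- .applyTransform(df[, c("x", "y", "z")], rotation, translation)
    df$x <- moved[, 1]; df$y <- moved[, 2]; df$z <- moved[, 3]
  }
  initialize(pharmacophore, features = df)
}

.featDist <- function(a, b) {
  ## cross-distance matrix between two feature tables
  ax <- as.matrix(a[, c("x", "y", "z")])
  bx <- as.matrix(b[, c("x", "y", "z")])
  outer(rowSums(ax^2), rep(1, nrow(bx))) +
    outer(rep(1, nrow(ax)), rowSums(bx^2)) - 2 * ax %*% t(bx) ->
    d2
  sqrt(pmax(d2, 0))
}

## greedy injective matching of type-compatible overlapping pairs, nearest
## pairs first; returns 2-column index matrix (template, query)
.greedyPairs <- function(tf, qfMoved) {
  d <- .featDist(tf, qfMoved)
  rmin <- outer(tf$radius, qfMoved$radius, pmin)
  ok <- which(d < rmin & outer(tf$type, qfMoved$type, "=="), arr.ind = TRUE)
  if (nrow(ok) == 0) return(matrix(integer(), 0, 2))
  ord <- order(d[ok], ok[, 1], ok[, 2])
  ok <- ok[ord, , drop = FALSE]
  usedT <- logical(nrow(tf)); usedQ <- logical(nrow(qfMoved))
  keep <- logical(nrow(ok))
  for (i in seq_len(nrow(ok))) {
    a <- ok[i, 1]; b <- ok[i, 2]
    if (!usedT[a] && !usedQ[b]) { keep[i] <- TRUE; usedT[a] <- TRUE; usedQ[b] <- TRUE }
  }
  ok[keep, , drop = FALSE]
}

.isCollinear <- function(p, tol = 1e-6) {
  v1 <- p[2, ] - p[1, ]; v2 <- p[3, ] - p[1, ]
  cr <- c(v1[2] * v2[3] - v1[3] * v2[2],
          v1[3] * v2[1] - v1[1] * v2[3],
          v1[1] * v2[2] - v1[2] * v2[1])
  sqrt(sum(cr^2)) < tol
}

#' Align one pharmacophore onto another
#'
#' Enumerates correspondence seeds from feature triplets whose pairwise
#' distance triangles approximately match (tolerance = `cutoff`), superposes
#' each seed, greedily extends the correspondence with every additional
#' type-compatible pair whose post-transform distance is below both feature
#' radii, re-superposes on the full correspondence, and keeps the result
#' with the most matched pairs (ties broken by lower RMSD). The score is
#' the number of overlapping feature pairs; a correspondence needs at
#' least 3 pairs, otherwise no alignment exists and `NULL` is returned
#' (which marks the query out-of-domain downstream).
#'
#' @param query,template [Pharmacophore] objects.
#' @param cutoff distance tolerance in Angstrom for seed triangles
#'   (default: the clustering cutoff, 1.5 A).
#' @return list of class `"AlignmentResult"` with elements `rotation`,
#'   `translation`, `pairs` (2-column index matrix template/query),
#'   `score`, `rmsd`, `alignedQuery`, `conformerIndex`; or `NULL`.
#' @export
alignPharmacophores <- function(query, template, cutoff = 1.5) {
  tf <- features(template); qf <- features(query)
  if (nrow(tf) < 3 || nrow(qf) < 3) return(NULL)
  tpos <- as.matrix(tf[, c("x", "y", "z")])
  qpos <- as.matrix(qf[, c("x", "y", "z")])
  ## candidate query features per template feature, by type
  cand <- lapply(tf$type, function(t) which(qf$type == t))
  if (sum(lengths(cand) > 0) < 3) return(NULL)

  best <- NULL
  tdist <- .featDist(tf, tf)
  qdist <- .featDist(qf, qf)
  trip <- utils::combn(nrow(tf), 3)
  for (ci in seq_len(ncol(trip))) {
    i <- trip[1, ci]; j <- trip[2, ci]; k <- trip[3, ci]
    if (.isCollinear(tpos[c(i, j, k), ])) next
    for (a in cand[[i]]) for (b in cand[[j]]) {
      if (b == a) next
      if (abs(tdist[i, j] - qdist[a, b]) >= cutoff) next
      for (cc in cand[[k]]) {
        if (cc == a || cc == b) next
        if (abs(tdist[i, k] - qdist[a, cc]) >= cutoff) next
        if (abs(tdist[j, k] - qdist[b, cc]) >= cutoff) next
        if (.isCollinear(qpos[c(a, b, cc), ])) next
        sp <- superpose(tpos[c(i, j, k), ], qpos[c(a, b, cc), ])
        moved <- qf
        mv <- .applyTransform(qpos, sp$rotation, sp$translation)
        moved$x <- mv[, 1]; moved$y <- mv[, 2]; moved$z <- mv[, 3]
        pairs <- .greedyPairs(tf, moved)
        if (nrow(pairs) < 3) next
        ## refine on the full correspondence
        sp2 <- superpose(tpos[pairs[, 1], , drop = FALSE],
                         qpos[pairs[, 2], , drop = FALSE])
        mv2 <- .applyTransform(qpos, sp2$rotation, sp2$translation)
        moved$x <- mv2[, 1]; moved$y <- mv2[, 2]; moved$z <- mv2[, 3]
        pairs2 <- .greedyPairs(tf, moved)
        if (nrow(pairs2) < 3) { pairs2 <- pairs; sp2 <- sp
                                mv2 <- mv; moved$x <- mv[, 1]
                                moved$y <- mv[, 2]; moved$z <- mv[, 3] }
        rmsd <- sqrt(mean(rowSums(
          (mv2[pairs2[, 2], , drop = FALSE] -
           tpos[pairs2[, 1], , drop = FALSE])^2)))
        score <- nrow(pairs2)
        if (is.null(best) || score > best$score ||
            (score == best$score && rmsd < best$rmsd - 1e-12)) {
          best <- list(rotation = sp2$rotation, translation = sp2$translation,
                       pairs = pairs2, score = score, rmsd = rmsd,
                       alignedQuery = initialize(query, features = moved),
                       conformerIndex = query@conformerIndex)
          class(best) <- "AlignmentResult"
        }
      }
    }
  }
  best
}

#' @export
print.AlignmentResult <- function(x, ...) {
  cat(sprintf("AlignmentResult: score %d, rmsd %.4f A, %d matched pairs\n",
              x$score, x$rmsd, nrow(x$pairs)))
  invisible(x)
}

#' Align a sample (all conformers) to a template
#'
#' Molecules are perceived per conformer and every conformer is aligned to
#' the template; the best-fitting conformer wins (highest score, then
#' lowest RMSD, then lowest conformer index). Pharmacophore samples are
#' aligned directly. A `NULL` result marks the sample out-of-domain.
#'
#' @param sample a [Molecule] or [Pharmacophore].
#' @param template the template [Pharmacophore].
#' @param cutoff seed distance tolerance in Angstrom.
#' @return An `AlignmentResult` (with `conformerIndex` set for molecules)
#'   or `NULL`.
#' @export
alignSample <- function(sample, template, cutoff = 1.5) {
  if (is(sample, "Pharmacophore"))
    return(alignPharmacophores(sample, template, cutoff))
  stopifnot(is(sample, "Molecule"))
  best <- NULL
  for (ci in seq_along(conformers(sample))) {
    ph <- tryCatch(perceivePharmacophore(sample, ci), error = function(e) NULL)
    if (is.null(ph)) next
    res <- alignPharmacophores(ph, template, cutoff)
    if (is.null(res)) next
    res$conformerIndex <- ci
    if (is.null(best) || res$score > best$score ||
        (res$score == best$score && res$rmsd < best$rmsd - 1e-12))
      best <- res
  }
  best
}
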