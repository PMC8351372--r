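#' Select the alignment template
#'
#' An explicitly supplied pharmacophore is used verbatim. Otherwise, for
#' molecule datasets with `mostRigidTemplate`, the most rigid molecule
#' (fewest rotatable bonds; ties broken by fewer heavy atoms, then by id)
#' is aligned against the second-most-rigid over all conformer pairs, and
#' the pharmacophore perceived from its best-aligned conformer becomes the
#' template. A dataset of bare pharmacophores without an explicit template
#' falls back to the first pharmacophore in id order (with a message).
#'
#' @param dataset an [ActivityDataset].
#' @param config a [QpharConfig].
#' @param template optional explicit template [Pharmacophore].
#' @return the template [Pharmacophore].
#' @export
selectTemplate <- function(dataset, config = qpharConfig(), template = NULL) {
  if (!is.null(template)) {
    stopifnot(is(template, "Pharmacophore"))
    return(template)
  }
  smps <- samples(dataset)
  if (length(smps) == 0) stop("empty dataset")
  isMol <- vapply(smps, function(s) is(s, "Molecule"), logical(1))
  if (!any(isMol)) {
    ids <- vapply(smps, sampleId, character(1))
    first <- order(ids)[1]
    message("pharmacophore-only dataset: using ", sQuote(ids[first]),
            " as template")
    return(smps[[first]])
  }
  mols <- smps[isMol]
  rot <- vapply(mols, countRotatableBonds, integer(1))
  heavies <- vapply(mols, function(m)
    sum(conformers(m)[[1]]$atoms$elem != "H"), integer(1))
  ids <- vapply(mols, sampleId, character(1))
  ord <- order(rot, heavies, ids)
  firstMol <- mols[[ord[1]]]
  if (length(mols) == 1 || !config@mostRigidTemplate)
    return(perceivePharmacophore(firstMol, 1L))
  secondMol <- mols[[ord[2]]]
  ## best conformer pair between the two most rigid molecules
  best <- NULL; bestCi <- 1L
  for (ci in seq_along(conformers(firstMol))) {
    phi <- perceivePharmacophore(firstMol, ci)
    for (cj in seq_along(conformers(secondMol))) {
      phj <- perceivePharmacophore(secondMol, cj)
      res <- alignPharmacophores(phj, phi, cutoff = config@clusterCutoff)
      if (!is.null(res) && (is.null(best) || res$score > best$score ||
          (res$score == best$score && res$rmsd < best$rmsd - 1e-12))) {
        best <- res; bestCi <- ci
      }
    }
  }
  perceivePharmacophore(firstMol, bestCi)
}

#' Featurize an aligned sample against a model
#'
#' Builds the regression input vector: one entry per representative
#' feature of the merged pharmacophore. Each entry is the inverse
#' Euclidean distance `1/max(d, 0.01)` to the nearest same-type sample
#' feature that overlaps the representative (distance below both radii),
#' and 0 when none overlaps. `weightType = "none"` binarizes the entries
#' to 0/1; `weightType = "nrOfFeatures"` multiplies each entry by the
#' representative's merged-feature count. Sample features overlapping no
#' representative contribute nothing; their number is returned in the
#' `"oodFeatures"` attribute (the feature-level applicability domain).
#'
#' @param alignment an `AlignmentResult` against the model's template frame,
#'   or an aligned [Pharmacophore].
#' @param model a [QpharModel] (or bare representative feature table plus
#'   `weightType`).
#' @param weightType overrides the model configuration when given.
#' @return numeric vector of length `nrow(representatives)` with attribute
#'   `"oodFeatures"`.
#' @export
featurize <- function(alignment, model, weightType = NULL) {
  reps <- if (is.data.frame(model)) model else representatives(model)
  if (is.null(weightType))
    weightType <- if (is.data.frame(model)) "distance"
                  else modelConfig(model)@weightType
  ph <- if (is(alignment, "Pharmacophore")) alignment else alignment$alignedQuery
  sf <- features(ph)
  v <- numeric(nrow(reps))
  matched <- logical(nrow(sf))
  if (nrow(sf) > 0 && nrow(reps) > 0) {
    d <- .featDist(reps, sf)
    rmin <- outer(reps$radius, sf$radius, pmin)
    ok <- d < rmin & outer(reps$type, sf$type, "==")
    for (i in seq_len(nrow(reps))) {
      cand <- which(ok[i, ])
      if (length(cand) == 0) next
      dmin <- min(d[i, cand])
      v[i] <- 1 / max(dmin, 0.01)
    }
    matched <- apply(ok, 2, any)
  }
  if (weightType == "none") {
    v <- as.numeric(v > 0)
  } else if (weightType == "nrOfFeatures") {
    v <- v * reps$memberCount
  }
  attr(v, "oodFeatures") <- sum(!matched)
  v
}

#' Fit a quantitative pharmacophore model
#'
#' Runs the full pipeline: template selection, alignment of every training
#' sample to the template, per-type single-linkage clustering of the pooled
#' aligned features, representative selection, removal of ambiguous
#' features, featurization of all alignable samples and fitting of the
#' configured regressor. Unalignable samples are dropped with a warning;
#' fewer than three alignable samples is an error.
#'
#' @param dataset an [ActivityDataset] (>= 5 samples recommended).
#' @param config a [QpharConfig].
#' @param template optional explicit template [Pharmacophore].
#' @return a fitted [QpharModel].
#' @export
fitQphar <- function(dataset, config = qpharConfig(), template = NULL) {
  y <- activities(dataset)
  smps <- samples(dataset)
  ids <- sampleIds(dataset)
  template <- selectTemplate(dataset, config, template)

  alignments <- vector("list", length(smps))
  for (i in seq_along(smps))
    alignments[[i]] <- alignSample(smps[[i]], template,
                                   cutoff = config@clusterCutoff)
  alignable <- !vapply(alignments, is.null, logical(1))
  dropped <- ids[!alignable]
  if (length(dropped) > 0)
    warning("dropping unalignable training sample(s): ",
            paste(dropped, collapse = ", "))
  if (sum(alignable) < 3)
    stop("fewer than 3 training samples could be aligned to the template")

  ## pool aligned features, each carrying its parent's activity
  pooled <- do.call(rbind, lapply(which(alignable), function(i) {
    df <- features(alignments[[i]]$alignedQuery)
    df$sourceId <- ids[i]
    df$activities <- rep(list(y[i]), nrow(df))
    df$memberCount <- 1L
    df
  }))

  reps <- do.call(rbind, lapply(featureTypes(), function(t) {
    sub <- pooled[pooled$type == t, , drop = FALSE]
    if (nrow(sub) == 0) return(NULL)
    clusters <- clusterFeatures(sub, cutoff = config@clusterCutoff)
    do.call(rbind, lapply(clusters, function(cl) {
      r <- selectRepresentatives(cl)
      attr(r, "assignment") <- NULL
      attr(r, "strategy") <- NULL
      r
    }))
  }))
  gmin <- min(y[alignable]); gmax <- max(y[alignable])
  reps <- pruneAmbiguous(reps, gmin, gmax)
  rownames(reps) <- NULL

  X <- do.call(rbind, lapply(which(alignable), function(i)
    featurize(alignments[[i]], reps, weightType = config@weightType)))
  regressor <- .fitRegressor(X, y[alignable], config)

  new("QpharModel", template = template, representatives = reps,
      globalMin = gmin, globalMax = gmax, regressor = regressor,
      config = config, droppedSamples = dropped)
}

#' Predict the activity of a new sample
#'
#' Aligns the sample to the model template; failure to align puts the
#' whole sample out of the applicability domain (no estimate). Otherwise
#' the sample is featurized against the representatives and passed to the
#' regressor; the number of sample features matching no representative is
#' reported (feature-level out-of-domain count).
#'
#' @param object a fitted [QpharModel].
#' @param sample a [Pharmacophore] or [Molecule].
#' @return list with `estimate` (log units, `NA` when out of domain),
#'   `inDomain` and `oodFeatures`.
#' @aliases predict,QpharModel-method
#' @export
setMethod("predict", "QpharModel", function(object, sample) {
  res <- alignSample(sample, modelTemplate(object),
                     cutoff = modelConfig(object)@clusterCutoff)
  if (is.null(res))
    return(list(estimate = NA_real_, inDomain = FALSE,
                oodFeatures = NA_integer_))
  v <- featurize(res, object)
  est <- .predictRegressor(object@regressor, matrix(v, 1))
  list(estimate = est, inDomain = TRUE,
       oodFeatures = attr(v, "oodFeatures"))
})

#' The default hyperparameter grid
#'
#' Exhaustive grid over featurization weight (`distance`, `nrOfFeatures`,
#' `none`), model family (four non-forest models plus six restricted
#' forests crossing 10/15/20 trees with depth 2/3) and clustering cutoff
#' (1, 1.5, 2 A): 90 configurations in a fixed, documented order.
#'
#' @param seed seed copied into every configuration.
#' @return list of [QpharConfig] objects.
#' @export
defaultGrid <- function(seed = 42L) {
  grid <- list()
  for (cutoff in c(1, 1.5, 2))
    for (wt in c("distance", "nrOfFeatures", "none")) {
      for (mt in c("ridge", "pls", "pca_ridge", "pca_linear"))
        grid[[length(grid) + 1L]] <-
          qpharConfig(weightType = wt, clusterCutoff = cutoff,
                      modelType = mt, randomSeed = seed)
      for (nt in c(10L, 15L, 20L)) for (md in c(2L, 3L))
        grid[[length(grid) + 1L]] <-
          qpharConfig(weightType = wt, clusterCutoff = cutoff,
                      modelType = "random_forest", rfNEstimators = nt,
                      rfMaxDepth = md, randomSeed = seed)
    }
  grid
}

#' Cross-validated hyperparameter search
#'
#' Evaluates every configuration of the grid with the same stratified
#' K-fold partition and returns the configuration with the lowest mean CV
#' RMSE; ties are broken by the smaller mean number of representatives,
#' then by grid order.
#'
#' @param dataset an [ActivityDataset].
#' @param folds number of CV folds.
#' @param seed seed for the fold partition and the forests.
#' @param grid list of [QpharConfig]; defaults to [defaultGrid()].
#' @return list with `best` (a [QpharConfig]) and `table` (one row per
#'   configuration: parameters, mean/sd CV RMSE, mean representative count,
#'   failed folds).
#' @export
gridSearch <- function(dataset, folds = 5L, seed = 42L, grid = NULL) {
  if (is.null(grid)) grid <- defaultGrid(seed)
  parts <- stratifiedKFold(activities(dataset), k = folds, seed = seed)
  rows <- lapply(seq_along(grid), function(g) {
    cfg <- grid[[g]]
    rmses <- numeric(); nreps <- numeric(); failed <- 0L
    for (fold in parts) {
      res <- tryCatch({
        m <- fitQphar(.subsetDataset(dataset, fold$train), cfg)
        preds <- vapply(samples(.subsetDataset(dataset, fold$test)),
                        function(s) predict(m, s)$estimate, numeric(1))
        truth <- activities(dataset)[fold$test]
        okp <- is.finite(preds)
        list(rmse = evaluatePredictions(preds[okp], truth[okp])$rmse,
             nrep = nrow(representatives(m)))
      }, error = function(e) NULL)
      if (is.null(res)) failed <- failed + 1L
      else { rmses <- c(rmses, res$rmse); nreps <- c(nreps, res$nrep) }
    }
    data.frame(config = g, weightType = cfg@weightType,
               modelType = cfg@modelType, clusterCutoff = cfg@clusterCutoff,
               rfNEstimators = cfg@rfNEstimators, rfMaxDepth = cfg@rfMaxDepth,
               meanRMSE = if (length(rmses)) mean(rmses) else Inf,
               sdRMSE = if (length(rmses) > 1) stats::sd(rmses) else NA_real_,
               meanNReps = if (length(nreps)) mean(nreps) else NA_real_,
               failedFolds = failed)
  })
  tab <- do.call(rbind, rows)
  ord <- order(tab$meanRMSE, tab$meanNReps, tab$config)
  list(best = grid[[tab$config[ord[1]]]], table = tab)
}

.subsetDataset <- function(dataset, idx) {
  ActivityDataset(samples(dataset)[idx], activities(dataset)[idx],
                  unitOfOrigin = unitOfOrigin(dataset))
}

#' Human-readable model report
#'
#' Lists every representative feature with its type, position, merged
#' count and inherited activity range -- the favourable/unfavourable
#' region interpretation surface of the merged pharmacophore.
#'
#' @param model a fitted [QpharModel].
#' @return data.frame, one row per representative.
#' @export
modelReport <- function(model) {
  reps <- representatives(model)
  data.frame(
    type = reps$type, x = reps$x, y = reps$y, z = reps$z,
    radius = reps$radius, memberCount = reps$memberCount,
    activityMin = vapply(reps$activities, min, numeric(1)),
    activityMax = vapply(reps$activities, max, numeric(1)),
    activityMean = vapply(reps$activities, mean, numeric(1))
  )
}
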