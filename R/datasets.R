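#' Activity heterogeneity by KL divergence against uniform
#'
#' Dataset-curation gate: the activity values are binned into N equal-width
#' bins over their range (N = sample size, last bin right-closed), the
#' empirical bin distribution P is compared against the uniform reference
#' Q = 1/N by the Kullback-Leibler divergence `sum P(x) log(P(x)/Q(x))`
#' (natural log; empty bins contribute zero). KL is 0 exactly when every
#' bin holds one value and reaches log(N) when all values share a bin. A
#' dataset passes when KL <= 0.75 and the activity range spans at least 3
#' log units. The log base of the divergence is a convention; the 0.75
#' cutoff is calibrated for the natural log and must be recalibrated if a
#' different base is used.
#'
#' @param activities numeric log-unit activities, length >= 2.
#' @return list of class `"HeterogeneityReport"`: `kl`, `nBins`, `range`,
#'   `pass`. Identical activities give `kl = Inf` and `pass = FALSE`.
#' @export
#' @examples
#' klHeterogeneity(c(4.5, 5.5, 6.5, 7.5))$kl  # 0
klHeterogeneity <- function(activities) {
  stopifnot(length(activities) >= 2, all(is.finite(activities)))
  n <- length(activities)
  a <- min(activities); b <- max(activities)
  if (a == b) {
    ## all mass in a single bin: P(x) = 1 for one bin, the closed-form
    ## maximum log(N); degenerate range always fails the gate
    rep <- list(kl = log(n), nBins = n, range = c(a, b), pass = FALSE)
    class(rep) <- "HeterogeneityReport"
    return(rep)
  }
  bins <- .binIndices(activities, a, b, n)
  p <- tabulate(bins, nbins = n) / n
  nz <- p > 0
  kl <- sum(p[nz] * log(p[nz] * n))
  rep <- list(kl = kl, nBins = n, range = c(a, b),
              pass = kl <= 0.75 && (b - a) >= 3)
  class(rep) <- "HeterogeneityReport"
  rep
}

#' @export
print.HeterogeneityReport <- function(x, ...) {
  cat(sprintf(
    "HeterogeneityReport: KL = %.4f over %d bins, range %.2f - %.2f (%s)\n",
    x$kl, x$nBins, x$range[1], x$range[2], if (x$pass) "pass" else "fail"))
  invisible(x)
}

## equal-width bin index on [a, b]; values at b fall in the last bin
.binIndices <- function(x, a, b, k) {
  idx <- floor((x - a) / (b - a) * k) + 1L
  pmin(pmax(idx, 1L), k)
}

#' Stratified K-fold partition for a regression endpoint
#'
#' Bins the activities into `k` equal-width classes over their range and
#' deals each class's (seeded, shuffled) members round-robin across folds,
#' rotating the starting fold so fold sizes stay balanced. Folds are
#' disjoint and exhaustive; each fold's class proportions match the
#' dataset's within one sample per class. Classes with fewer members than
#' folds are simply spread over as many folds as they have members.
#'
#' @param activities numeric log-unit activities.
#' @param k number of folds (default 5).
#' @param seed integer seed for the within-class shuffles.
#' @param nBins number of stratification classes (default `k`).
#' @return list of `k` lists with `train` and `test` index vectors.
#' @export
stratifiedKFold <- function(activities, k = 5L, seed = 42L, nBins = k) {
  n <- length(activities)
  stopifnot(n >= k)
  a <- min(activities); b <- max(activities)
  cls <- if (a == b) rep(1L, n) else .binIndices(activities, a, b, nBins)
  foldOf <- integer(n)
  offset <- 0L
  rng <- .seededRNG(seed)
  for (c in sort(unique(cls))) {
    idx <- which(cls == c)
    idx <- idx[rng$sample(length(idx))]
    foldOf[idx] <- ((offset + seq_along(idx) - 1L) %% k) + 1L
    offset <- offset + length(idx)
  }
  lapply(seq_len(k), function(f)
    list(train = which(foldOf != f), test = which(foldOf == f)))
}

## isolated, stateful RNG stream so library code never disturbs (nor is
## disturbed by) the caller's global RNG state
.seededRNG <- function(seed) {
  env <- new.env()
  env$state <- NULL
  withState <- function(f) function(...) {
    g <- globalenv()
    old <- if (exists(".Random.seed", g, inherits = FALSE))
      get(".Random.seed", g) else NULL
    if (is.null(env$state)) set.seed(seed)
    else assign(".Random.seed", env$state, envir = g)
    res <- f(...)
    env$state <- get(".Random.seed", g)
    if (is.null(old)) rm(".Random.seed", envir = g)
    else assign(".Random.seed", old, envir = g)
    res
  }
  list(sample = withState(function(n, size = n) sample.int(n, size)),
       rnorm = withState(stats::rnorm),
       runif = withState(stats::runif),
       rbinom = withState(stats::rbinom))
}

#' Stratified single split
#'
#' One stratified train/test split at the requested training fraction,
#' using the same equal-width activity binning as [stratifiedKFold()]
#' (5 classes). Class quotas are apportioned by largest remainder so the
#' train size is exactly `round(n * trainFraction)`.
#'
#' @param activities numeric log-unit activities.
#' @param trainFraction fraction of samples for training (0.8 for the
#'   standard split, 0.2 for the data-poor medicinal-chemistry setting).
#' @param seed integer seed.
#' @param nBins number of stratification classes.
#' @return list with `train` and `test` index vectors.
#' @export
makeSplit <- function(activities, trainFraction = 0.8, seed = 42L, nBins = 5L) {
  n <- length(activities)
  a <- min(activities); b <- max(activities)
  cls <- if (a == b) rep(1L, n) else .binIndices(activities, a, b, nBins)
  target <- round(n * trainFraction)
  classes <- sort(unique(cls))
  sizes <- vapply(classes, function(c) sum(cls == c), integer(1))
  quota <- floor(sizes * trainFraction)
  rem <- target - sum(quota)
  if (rem > 0) {
    frac <- sizes * trainFraction - quota
    extra <- order(-frac, classes)[seq_len(rem)]
    quota[extra] <- quota[extra] + 1L
  } else if (rem < 0) {
    cut <- order(sizes * trainFraction - quota, classes)[seq_len(-rem)]
    quota[cut] <- pmax(0L, quota[cut] - 1L)
  }
  rng <- .seededRNG(seed)
  train <- integer()
  for (ci in seq_along(classes)) {
    idx <- which(cls == classes[ci])
    idx <- idx[rng$sample(length(idx))]
    train <- c(train, idx[seq_len(quota[ci])])
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_len(n), train))
}

#' Build baseline input vectors
#'
#' Feature-count baseline: the 6-vector of pharmacophore feature counts
#' per sample (molecules are perceived on their first conformer).
#' Physico-chemical baseline: the 7 descriptors of [computeDescriptors()]
#' (molecule samples only).
#'
#' @param dataset an [ActivityDataset].
#' @param kind `"feature_counts"` or `"physchem"`.
#' @return numeric matrix, one row per sample.
#' @export
buildBaselineVectors <- function(dataset, kind = c("feature_counts", "physchem")) {
  kind <- match.arg(kind)
  rows <- lapply(samples(dataset), function(s) {
    if (kind == "feature_counts") {
      ph <- if (is(s, "Pharmacophore")) s else perceivePharmacophore(s, 1L)
      countFeaturesByType(ph)
    } else {
      if (!is(s, "Molecule"))
        stop("the physico-chemical baseline needs molecule samples")
      computeDescriptors(s)
    }
  })
  do.call(rbind, rows)
}

#' Fit a baseline model
#'
#' Trains the same restricted regressor family as the quantitative
#' pharmacophore default (random forest, parameters and seed from
#' `config`) on baseline input vectors, and records the per-dimension
#' min/max of the training vectors as the model's applicability domain.
#'
#' @param kind `"feature_counts"` or `"physchem"`.
#' @param X numeric training matrix (rows = samples), e.g. from
#'   [buildBaselineVectors()].
#' @param y numeric log-unit activities.
#' @param config a [QpharConfig] supplying the regressor parameters.
#' @return list of class `"BaselineModel"`: `kind`, `regressor`,
#'   `domainMin`, `domainMax`.
#' @export
fitBaseline <- function(kind, X, y, config = qpharConfig()) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y))
  reg <- .fitRegressor(X, y, config)
  out <- list(kind = kind, regressor = reg,
              domainMin = apply(X, 2, min), domainMax = apply(X, 2, max))
  class(out) <- "BaselineModel"
  out
}

#' @export
print.BaselineModel <- function(x, ...) {
  cat("BaselineModel (", x$kind, "), ", length(x$domainMin),
      "-dim input, regressor ", x$regressor$kind, "\n", sep = "")
  invisible(x)
}

#' Baseline applicability domain check
#'
#' A test vector is in-domain exactly when every component lies within the
#' min/max bounds recorded on the training fold.
#'
#' @param model a `"BaselineModel"`.
#' @param vector numeric input vector.
#' @return logical flag.
#' @export
baselineInDomain <- function(model, vector) {
  if (length(vector) != length(model$domainMin))
    stop("input dimension ", length(vector),
         " does not match baseline dimension ", length(model$domainMin))
  all(vector >= model$domainMin & vector <= model$domainMax)
}

#' @rdname fitBaseline
#' @param newX matrix of vectors to predict.
#' @export
predictBaseline <- function(model, newX) {
  .predictRegressor(model$regressor, as.matrix(newX))
}

#' Regression metrics
#'
#' Root-mean-square error and coefficient of determination
#' `R2 = 1 - SS_res/SS_tot`. With zero-variance truths R2 is undefined and
#' returned as `NA`.
#'
#' @param predictions,truths equal-length numeric vectors.
#' @return list with `rmse` and `r2`.
#' @export
evaluatePredictions <- function(predictions, truths) {
  stopifnot(length(predictions) == length(truths), length(truths) > 0)
  rmse <- sqrt(mean((predictions - truths)^2))
  sstot <- sum((truths - mean(truths))^2)
  r2 <- if (sstot == 0) NA_real_ else 1 - sum((predictions - truths)^2) / sstot
  list(rmse = rmse, r2 = r2)
}

#' Cross-validate the model and its baselines
#'
#' Runs stratified K-fold cross-validation, training each requested method
#' on every training fold and evaluating on the held-out fold. For the
#' baselines, test samples outside the min/max applicability domain are
#' counted, and on exactly those samples the quantitative model's absolute
#' error is compared head-to-head with the baseline's. Folds where the
#' quantitative model cannot be fitted are marked failed and excluded from
#' the aggregate means.
#'
#' @param dataset an [ActivityDataset] (should pass [klHeterogeneity()]).
#' @param methods subset of
#'   `c("qphar", "feature_baseline", "physchem_baseline")`.
#' @param k number of folds.
#' @param seed integer seed (folds and forests).
#' @param config a [QpharConfig].
#' @return list of class `"CVReport"`: `perFold` (fold x method table with
#'   RMSE, R2, test size, out-of-domain count), `summary` (per-method mean
#'   and SD of fold RMSEs), `improvement` (per baseline, fraction of its
#'   out-of-domain samples where the quantitative model had the smaller
#'   absolute error), `failedFolds`.
#' @export
runCV <- function(dataset,
                  methods = c("qphar", "feature_baseline", "physchem_baseline"),
                  k = 5L, seed = 42L, config = qpharConfig(randomSeed = seed)) {
  methods <- match.arg(methods, several.ok = TRUE)
  y <- activities(dataset)
  parts <- stratifiedKFold(y, k = k, seed = seed)
  perFold <- NULL
  failed <- integer()
  better <- list(feature_baseline = logical(),
                 physchem_baseline = logical())
  baseKinds <- c(feature_baseline = "feature_counts",
                 physchem_baseline = "physchem")

  for (f in seq_along(parts)) {
    tr <- parts[[f]]$train; te <- parts[[f]]$test
    trainDs <- .subsetDataset(dataset, tr)
    qpharPred <- rep(NA_real_, length(te))
    qm <- NULL
    if ("qphar" %in% methods) {
      qm <- tryCatch(fitQphar(trainDs, config), error = function(e) NULL)
      if (is.null(qm)) { failed <- c(failed, f) }
      else {
        qpharPred <- vapply(samples(dataset)[te], function(s)
          predict(qm, s)$estimate, numeric(1))
        okp <- is.finite(qpharPred)
        ev <- evaluatePredictions(qpharPred[okp], y[te][okp])
        perFold <- rbind(perFold, data.frame(
          fold = f, method = "qphar", rmse = ev$rmse, r2 = ev$r2,
          nTest = length(te), nOutOfDomain = sum(!okp)))
      }
    }
    for (mth in intersect(methods, names(baseKinds))) {
      kind <- baseKinds[[mth]]
      Xtr <- buildBaselineVectors(trainDs, kind)
      Xte <- buildBaselineVectors(.subsetDataset(dataset, te), kind)
      bm <- fitBaseline(kind, Xtr, y[tr], config)
      pred <- predictBaseline(bm, Xte)
      ood <- !vapply(seq_len(nrow(Xte)), function(i)
        baselineInDomain(bm, Xte[i, ]), logical(1))
      ev <- evaluatePredictions(pred, y[te])
      perFold <- rbind(perFold, data.frame(
        fold = f, method = mth, rmse = ev$rmse, r2 = ev$r2,
        nTest = length(te), nOutOfDomain = sum(ood)))
      if (!is.null(qm) && any(ood)) {
        cmp <- is.finite(qpharPred[ood])
        better[[mth]] <- c(better[[mth]],
          (abs(qpharPred[ood] - y[te][ood]) <
           abs(pred[ood] - y[te][ood]))[cmp])
      }
    }
  }
  summary <- do.call(rbind, lapply(unique(perFold$method), function(m) {
    r <- perFold$rmse[perFold$method == m]
    data.frame(method = m, meanRMSE = mean(r),
               sdRMSE = if (length(r) > 1) stats::sd(r) else NA_real_,
               nFolds = length(r))
  }))
  out <- list(
    perFold = perFold, summary = summary,
    improvement = lapply(better, function(b)
      if (length(b) == 0) NA_real_ else mean(b)),
    failedFolds = failed, seed = seed, k = k)
  class(out) <- "CVReport"
  out
}

#' @export
print.CVReport <- function(x, ...) {
  cat("Cross-validation report (", x$k, "folds, seed", x$seed, ")\n")
  print(x$summary, row.names = FALSE)
  if (length(x$failedFolds) > 0)
    cat("failed folds:", paste(x$failedFolds, collapse = ", "), "\n")
  invisible(x)
}

#' Curate an activity-record table
#'
#' Applies the standard quality predicates to a table of assay activity
#' records (columns `molecule_id, standard_type, standard_value,
#' standard_units, standard_relation, assay_type, assay_id,
#' target_organism`): keeps IC50/Ki measurements in nM with an exact
#' relation, from binding assays on Homo sapiens; groups records per assay
#' id; converts values to log units; and gates each assay dataset on
#' activity range (>= 3 log units) and heterogeneity (KL <= 0.75). No
#' network access: the table is provided by the caller.
#'
#' @param records data.frame of activity records.
#' @return list with `records` (filtered rows plus a `pActivity` column)
#'   and `assays` (per-assay summary: n, range, kl, pass).
#' @export
curateActivityRecords <- function(records) {
  req <- c("molecule_id", "standard_type", "standard_value", "standard_units",
           "standard_relation", "assay_type", "assay_id", "target_organism")
  missing <- setdiff(req, names(records))
  if (length(missing) > 0)
    stop("records lack column(s): ", paste(missing, collapse = ", "))
  keep <- records$standard_type %in% c("IC50", "Ki") &
    records$standard_units == "nM" &
    records$standard_relation == "=" &
    records$assay_type == "B" &
    tolower(records$target_organism) == "homo sapiens" &
    is.finite(suppressWarnings(as.numeric(records$standard_value))) &
    suppressWarnings(as.numeric(records$standard_value)) > 0
  rec <- records[keep, , drop = FALSE]
  rec$pActivity <- toLogActivity(as.numeric(rec$standard_value), "nM")
  assays <- do.call(rbind, lapply(unique(rec$assay_id), function(aid) {
    act <- rec$pActivity[rec$assay_id == aid]
    if (length(act) < 2)
      return(data.frame(assay_id = aid, n = length(act), rangeLog = 0,
                        kl = Inf, pass = FALSE))
    rep <- klHeterogeneity(act)
    data.frame(assay_id = aid, n = length(act),
               rangeLog = diff(rep$range), kl = rep$kl, pass = rep$pass)
  }))
  list(records = rec, assays = assays)
}
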