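#' @import methods
NULL

#' Pharmacophore feature types
#'
#' The six interaction feature types recognised throughout the package, in
#' their canonical order: hydrophobic (`H`), aromatic (`AR`), positive and
#' negative ionisable (`PI`, `NI`), hydrogen-bond donor and acceptor
#' (`HBD`, `HBA`). All feature containers, count vectors and perception
#' output use this order.
#'
#' @return Character vector of the six type codes.
#' @export
#' @examples
#' featureTypes()
featureTypes <- function() c("H", "AR", "PI", "NI", "HBD", "HBA")

.FEATURE_COLS <- c("type", "x", "y", "z", "radius", "memberCount",
                   "sourceId", "activities")

#' Construct a feature table
#'
#' Features are stored as rows of a data.frame with one row per spherical
#' feature: a type code, Cartesian coordinates in Angstrom, a tolerance
#' radius (default 1.5 A), the number of source features merged into it,
#' the id of the sample it came from, and a list-column of inherited
#' activity values (log units; empty for features that are not part of a
#' merged model).
#'
#' @param type character vector of type codes (see [featureTypes()]).
#' @param x,y,z numeric coordinates in Angstrom.
#' @param radius feature tolerance radius in Angstrom, recycled.
#' @param memberCount number of merged source features, recycled.
#' @param sourceId originating sample id, recycled.
#' @param activities list of numeric vectors (one per feature) of inherited
#'   activity values, or `NULL` for none.
#' @return data.frame with columns `type, x, y, z, radius, memberCount,
#'   sourceId, activities`.
#' @export
#' @examples
#' featureFrame(c("AR", "HBD"), x = c(0, 3), y = 0, z = 0)
featureFrame <- function(type = character(), x = numeric(), y = numeric(),
                         z = numeric(), radius = 1.5, memberCount = 1L,
                         sourceId = "", activities = NULL) {
  n <- max(length(type), length(x), length(y), length(z))
  if (length(type) == 0) n <- 0L
  bad <- setdiff(unique(type), featureTypes())
  if (length(bad) > 0)
    stop("unknown feature type code(s): ", paste(bad, collapse = ", "))
  df <- data.frame(
    type = rep_len(as.character(type), n),
    x = rep_len(as.numeric(x), n),
    y = rep_len(as.numeric(y), n),
    z = rep_len(as.numeric(z), n),
    radius = rep_len(as.numeric(radius), n),
    memberCount = rep_len(as.integer(memberCount), n),
    sourceId = rep_len(as.character(sourceId), n),
    stringsAsFactors = FALSE
  )
  if (is.null(activities)) activities <- rep(list(numeric()), n)
  stopifnot(length(activities) == n)
  df$activities <- lapply(activities, as.numeric)
  if (n > 0) {
    if (any(!is.finite(as.matrix(df[, c("x", "y", "z")]))))
      stop("feature positions must be finite")
    if (any(df$radius <= 0)) stop("feature radius must be positive")
    if (any(df$memberCount < 1L)) stop("memberCount must be >= 1")
  }
  df
}

.emptyFeatures <- function() featureFrame()

.checkFeatureFrame <- function(df) {
  if (!is.data.frame(df)) return("features must be a data.frame")
  missing <- setdiff(.FEATURE_COLS, names(df))
  if (length(missing) > 0)
    return(paste("features lack column(s):", paste(missing, collapse = ", ")))
  if (nrow(df) > 0) {
    if (!all(df$type %in% featureTypes())) return("unknown feature type code")
    if (!all(is.finite(as.matrix(df[, c("x", "y", "z")]))))
      return("non-finite feature position")
    if (!all(df$radius > 0)) return("non-positive feature radius")
    if (!all(df$memberCount >= 1L)) return("memberCount < 1")
  }
  TRUE
}

#' @rdname Pharmacophore
#' @export
setClass("Pharmacophore",
  representation(
    sampleId = "character",
    features = "data.frame",
    activity = "numeric",
    conformerIndex = "integer"
  ),
  prototype(
    sampleId = "",
    features = featureFrame(),
    activity = NA_real_,
    conformerIndex = NA_integer_
  ),
  validity = function(object) {
    msg <- .checkFeatureFrame(object@features)
    if (!isTRUE(msg)) return(msg)
    if (length(object@sampleId) != 1L) return("sampleId must be length 1")
    if (length(object@activity) != 1L) return("activity must be length 1")
    TRUE
  }
)

#' Pharmacophore objects
#'
#' A pharmacophore is a set of typed spherical features in 3D, optionally
#' annotated with the sample it came from, its log-unit activity, and the
#' conformer it was perceived from. Directed donor/acceptor features are
#' reduced to their base point on input, so every stored feature is
#' spherical and undirected.
#'
#' @param features a feature table, see [featureFrame()].
#' @param sampleId sample identifier.
#' @param activity log-unit activity (pActivity) or `NA`.
#' @param conformerIndex index of the originating conformer or `NA`.
#' @return A `Pharmacophore` object.
#' @aliases Pharmacophore-class
#' @export
#' @examples
#' p <- Pharmacophore(featureFrame(c("AR", "HBD", "H"),
#'                    x = c(0, 3, 0), y = c(0, 0, 4), z = 0), sampleId = "mol1")
#' nFeatures(p)
Pharmacophore <- function(features, sampleId = "", activity = NA_real_,
                          conformerIndex = NA_integer_) {
  new("Pharmacophore", sampleId = as.character(sampleId), features = features,
      activity = as.numeric(activity),
      conformerIndex = as.integer(conformerIndex))
}

#' @rdname ActivityDataset
#' @export
setClass("ActivityDataset",
  representation(
    samples = "list",
    activities = "numeric",
    unitOfOrigin = "character"
  ),
  prototype(samples = list(), activities = numeric(), unitOfOrigin = "logunits"),
  validity = function(object) {
    if (length(object@samples) != length(object@activities))
      return("one activity per sample required")
    ids <- vapply(object@samples, sampleId, character(1))
    if (anyDuplicated(ids)) return("sample ids must be unique")
    if (length(object@activities) > 0 && any(!is.finite(object@activities)))
      return("every sample needs a finite activity")
    TRUE
  }
)

#' Activity-annotated sample collections
#'
#' An `ActivityDataset` couples samples (pharmacophores or multi-conformer
#' molecules) with finite activities on the internal log scale
#' (pActivity = -log10 molar). The unit the activities were originally
#' reported in is retained for provenance.
#'
#' @param samples list of [Pharmacophore] or [Molecule] objects with unique ids.
#' @param activities numeric vector of log-unit activities, one per sample.
#' @param unitOfOrigin unit the raw activities were reported in.
#' @return An `ActivityDataset`.
#' @aliases ActivityDataset-class
#' @export
ActivityDataset <- function(samples, activities, unitOfOrigin = "logunits") {
  new("ActivityDataset", samples = samples, activities = as.numeric(activities),
      unitOfOrigin = as.character(unitOfOrigin))
}

#' @rdname Molecule
#' @export
setClass("Molecule",
  representation(
    sampleId = "character",
    conformers = "list"
  ),
  validity = function(object) {
    if (length(object@conformers) < 1L) return("at least one conformer required")
    ok <- vapply(object@conformers, function(cf) {
      is.list(cf) && all(c("atoms", "bonds") %in% names(cf))
    }, logical(1))
    if (!all(ok)) return("each conformer needs $atoms and $bonds tables")
    TRUE
  }
)

#' Multi-conformer molecules
#'
#' Light-weight container for a molecule with one or more pre-generated 3D
#' conformers. Each conformer holds an atom table (element, coordinates,
#' formal charge, implicit hydrogen count) and a bond table (atom indices,
#' bond order, ring membership) as parsed from SDF input. Conformer
#' generation itself is out of scope; conformers are consumed as given.
#'
#' @param sampleId molecule identifier (conformers sharing an id are grouped).
#' @param conformers list of conformer structures (`$atoms`, `$bonds`).
#' @return A `Molecule` object.
#' @aliases Molecule-class
#' @export
Molecule <- function(sampleId, conformers) {
  new("Molecule", sampleId = as.character(sampleId), conformers = conformers)
}

#' @rdname QpharConfig
#' @export
setClass("QpharConfig",
  representation(
    fuzzy = "logical",
    weightType = "character",
    mostRigidTemplate = "logical",
    clusterCutoff = "numeric",
    modelType = "character",
    rfNEstimators = "integer",
    rfMaxDepth = "integer",
    randomSeed = "integer"
  ),
  validity = function(object) {
    if (!object@weightType %in% c("distance", "nrOfFeatures", "none"))
      return("weightType must be distance, nrOfFeatures or none")
    if (!object@modelType %in%
        c("random_forest", "ridge", "pls", "pca_ridge", "pca_linear"))
      return("unknown modelType")
    if (object@clusterCutoff <= 0) return("clusterCutoff must be positive")
    if (object@rfNEstimators < 1L || object@rfMaxDepth < 1L)
      return("random forest size parameters must be positive")
    TRUE
  }
)

#' Model configuration
#'
#' Bundles the tunable parameters of the quantitative pharmacophore
#' pipeline. Defaults mirror the out-of-the-box settings used for
#' cross-validation: fuzzy (spherical) features, inverse-distance
#' featurization weights, most-rigid template selection, a 1.5 A
#' clustering cutoff (the feature radius), and a deliberately restricted
#' random forest (10 trees, maximum depth 3).
#'
#' @param fuzzy treat directed features as spherical (only fuzzy behaviour is
#'   implemented; the flag is recorded).
#' @param weightType featurization weighting: `"distance"` (inverse distance),
#'   `"nrOfFeatures"` (inverse distance scaled by the representative's merged
#'   feature count) or `"none"` (binary overlap).
#' @param mostRigidTemplate pick the template from the most rigid molecule.
#' @param clusterCutoff single-linkage clustering cutoff in Angstrom; also the
#'   distance tolerance for alignment correspondence seeding.
#' @param modelType regressor: `"random_forest"`, `"ridge"`, `"pls"`,
#'   `"pca_ridge"` or `"pca_linear"`.
#' @param rfNEstimators number of random-forest trees.
#' @param rfMaxDepth maximum random-forest tree depth.
#' @param randomSeed seed controlling every stochastic step.
#' @return A `QpharConfig`.
#' @aliases QpharConfig-class
#' @export
#' @examples
#' qpharConfig(clusterCutoff = 2, modelType = "ridge")
qpharConfig <- function(fuzzy = TRUE, weightType = "distance",
                        mostRigidTemplate = TRUE, clusterCutoff = 1.5,
                        modelType = "random_forest", rfNEstimators = 10L,
                        rfMaxDepth = 3L, randomSeed = 42L) {
  new("QpharConfig", fuzzy = fuzzy, weightType = weightType,
      mostRigidTemplate = mostRigidTemplate,
      clusterCutoff = as.numeric(clusterCutoff), modelType = modelType,
      rfNEstimators = as.integer(rfNEstimators),
      rfMaxDepth = as.integer(rfMaxDepth), randomSeed = as.integer(randomSeed))
}

#' @rdname QpharModel
#' @export
setClass("QpharModel",
  representation(
    template = "Pharmacophore",
    representatives = "data.frame",
    globalMin = "numeric",
    globalMax = "numeric",
    regressor = "list",
    config = "QpharConfig",
    droppedSamples = "character"
  ),
  validity = function(object) {
    msg <- .checkFeatureFrame(object@representatives)
    if (!isTRUE(msg)) return(msg)
    reps <- object@representatives
    if (nrow(reps) > 0) {
      if (any(reps$memberCount < 2L))
        return("every representative must merge >= 2 source features")
      span <- vapply(reps$activities,
                     function(a) diff(range(a)), numeric(1))
      if (any(span > (object@globalMax - object@globalMin) / 2 + 1e-12))
        return("representative activity span exceeds half the global range")
    }
    if (!is.null(object@regressor$p) &&
        object@regressor$p != nrow(reps))
      return("regressor input dimension must equal number of representatives")
    TRUE
  }
)

#' Fitted quantitative pharmacophore models
#'
#' The result of [fitQphar()]: the alignment template, the cleaned merged
#' pharmacophore (representative features carrying inherited activities and
#' merged-feature counts), the training activity range defining the
#' ambiguity threshold, a fitted regressor in portable numeric form, and
#' the configuration used. Access with [modelTemplate()],
#' [representatives()], [globalActivityRange()] and [modelConfig()];
#' predict with [predict()][predict,QpharModel-method].
#'
#' @name QpharModel
#' @aliases QpharModel-class
NULL
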