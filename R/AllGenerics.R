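#' @rdname accessors
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))

#' @rdname accessors
#' @export
setGeneric("features", function(object) standardGeneric("features"))

#' @rdname accessors
#' @export
setGeneric("activity", function(object) standardGeneric("activity"))

#' @rdname accessors
#' @export
setGeneric("nFeatures", function(object) standardGeneric("nFeatures"))

#' @rdname accessors
#' @export
setGeneric("samples", function(object) standardGeneric("samples"))

#' @rdname accessors
#' @export
setGeneric("activities", function(object) standardGeneric("activities"))

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(object) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setGeneric("unitOfOrigin", function(object) standardGeneric("unitOfOrigin"))

#' @rdname accessors
#' @export
setGeneric("conformers", function(object) standardGeneric("conformers"))

#' @rdname accessors
#' @export
setGeneric("modelTemplate", function(object) standardGeneric("modelTemplate"))

#' @rdname accessors
#' @export
setGeneric("representatives", function(object) standardGeneric("representatives"))

#' @rdname accessors
#' @export
setGeneric("globalActivityRange",
           function(object) standardGeneric("globalActivityRange"))

#' @rdname accessors
#' @export
setGeneric("modelConfig", function(object) standardGeneric("modelConfig"))

#' Accessors for qphar classes
#'
#' Slot access for the package's S4 classes: `sampleId`, `features`,
#' `activity`, `nFeatures` and `conformers` for samples; `samples`,
#' `activities`, `sampleIds` and `unitOfOrigin` for datasets;
#' `modelTemplate`, `representatives`, `globalActivityRange` and
#' `modelConfig` for fitted models.
#'
#' @param object the object to access.
#' @name accessors
NULL

setMethod("sampleId", "Pharmacophore", function(object) object@sampleId)
setMethod("sampleId", "Molecule", function(object) object@sampleId)
setMethod("features", "Pharmacophore", function(object) object@features)
setMethod("activity", "Pharmacophore", function(object) object@activity)
setMethod("nFeatures", "Pharmacophore", function(object) nrow(object@features))
setMethod("conformers", "Molecule", function(object) object@conformers)

setMethod("samples", "ActivityDataset", function(object) object@samples)
setMethod("activities", "ActivityDataset", function(object) object@activities)
setMethod("sampleIds", "ActivityDataset", function(object)
  vapply(object@samples, sampleId, character(1)))
setMethod("unitOfOrigin", "ActivityDataset", function(object) object@unitOfOrigin)

setMethod("modelTemplate", "QpharModel", function(object) object@template)
setMethod("representatives", "QpharModel", function(object) object@representatives)
setMethod("globalActivityRange", "QpharModel",
          function(object) c(object@globalMin, object@globalMax))
setMethod("modelConfig", "QpharModel", function(object) object@config)

setMethod("show", "Pharmacophore", function(object) {
  cat("Pharmacophore", if (nzchar(object@sampleId)) object@sampleId else "<unnamed>",
      "with", nrow(object@features), "features\n")
  if (nrow(object@features) > 0) {
    tab <- table(factor(object@features$type, levels = featureTypes()))
    cat(" ", paste(names(tab), tab, sep = ":", collapse = " "), "\n")
  }
  if (!is.na(object@activity))
    cat("  activity:", format(object@activity, digits = 4), "log units\n")
})

setMethod("show", "Molecule", function(object) {
  cat("Molecule", object@sampleId, "with", length(object@conformers),
      "conformer(s),", nrow(object@conformers[[1]]$atoms), "atoms\n")
})

setMethod("show", "ActivityDataset", function(object) {
  cat("ActivityDataset with", length(object@samples), "samples",
      sprintf("(unit of origin: %s)\n", object@unitOfOrigin))
  if (length(object@activities) > 0)
    cat("  activity range:",
        paste(format(range(object@activities), digits = 4), collapse = " - "),
        "log units\n")
})

setMethod("show", "QpharConfig", function(object) {
  cat("QpharConfig:",
      sprintf("fuzzy=%s weightType=%s mostRigidTemplate=%s cutoff=%g model=%s",
              object@fuzzy, object@weightType, object@mostRigidTemplate,
              object@clusterCutoff, object@modelType))
  if (object@modelType == "random_forest")
    cat(sprintf(" (trees=%d depth=%d)", object@rfNEstimators, object@rfMaxDepth))
  cat(" seed=", object@randomSeed, "\n", sep = "")
})

setMethod("show", "QpharModel", function(object) {
  cat("QpharModel:", nrow(object@representatives), "representative features,",
      "template", sQuote(sampleId(object@template)), "\n")
  cat("  training activity range:",
      paste(format(c(object@globalMin, object@globalMax), digits = 4),
            collapse = " - "), "log units\n")
  cat("  regressor:", object@regressor$kind, "\n")
  if (length(object@droppedSamples) > 0)
    cat("  unalignable training samples dropped:",
        paste(object@droppedSamples, collapse = ", "), "\n")
})
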