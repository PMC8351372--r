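#' Convert a raw activity to the internal log scale
#'
#' All activities are handled internally as pActivity = -log10 of the molar
#' concentration, so that differences are "log units". Values already on the
#' log scale pass through unchanged.
#'
#' @param value positive numeric activity value(s).
#' @param unit one of `"nM"`, `"uM"` (accepted spellings `"µM"`, `"um"`),
#'   `"M"` or `"logunits"`.
#' @return numeric pActivity in log units.
#' @export
#' @examples
#' toLogActivity(1, "nM")   # 9
#' toLogActivity(1, "uM")   # 6
toLogActivity <- function(value, unit) {
  unit <- tolower(gsub("µ", "u", unit))
  if (unit == "logunits") return(as.numeric(value))
  scale <- switch(unit, nm = 1e-9, um = 1e-6, m = 1, NULL)
  if (is.null(scale))
    stop("unknown activity unit: ", unit,
         " (expected nM, uM, M or logunits)")
  value <- as.numeric(value)
  if (any(!is.finite(value) | value <= 0))
    stop("activity values must be positive to be log-transformed")
  -log10(value * scale)
}

.featuresToJSONList <- function(df, merged = FALSE) {
  lapply(seq_len(nrow(df)), function(i) {
    f <- list(type = df$type[i], x = df$x[i], y = df$y[i], z = df$z[i],
              radius = df$radius[i])
    if (merged) {
      f$memberCount <- df$memberCount[i]
      f$activities <- df$activities[[i]]
    }
    f
  })
}

#' Read and write pharmacophores as JSON
#'
#' The on-disk schema is
#' `{"id": str, "activity": float|null, "features": [{"type", "x", "y", "z",
#' "radius"}]}` with coordinates in Angstrom in a right-handed frame.
#' Directed features may additionally carry a direction vector
#' (`"nx","ny","nz"`); they are reduced to undirected spherical features at
#' their base point on reading (fuzzy feature handling). Features of merged
#' models may carry `memberCount` and `activities` fields, which are
#' preserved. Writing then reading a pharmacophore reproduces it up to
#' floating-point round-trip.
#'
#' @param path file path.
#' @param pharmacophore a [Pharmacophore].
#' @param merged write `memberCount`/`activities` fields as well.
#' @return `readPharmacophoreJSON` returns a [Pharmacophore];
#'   `writePharmacophoreJSON` returns `path` invisibly.
#' @export
readPharmacophoreJSON <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  feats <- obj$features
  if (is.null(feats)) stop("pharmacophore JSON lacks a 'features' array")
  types <- vapply(feats, function(f) as.character(f$type), character(1))
  bad <- setdiff(unique(types), featureTypes())
  if (length(bad) > 0)
    stop("unknown feature type code(s) in ", path, ": ",
         paste(bad, collapse = ", "))
  num <- function(field, default = NULL) vapply(feats, function(f) {
    v <- f[[field]]
    if (is.null(v)) {
      if (is.null(default)) stop("feature lacks field '", field, "'")
      default
    } else as.numeric(v)
  }, numeric(1))
  df <- featureFrame(
    type = types, x = num("x"), y = num("y"), z = num("z"),
    radius = num("radius", 1.5),
    memberCount = as.integer(num("memberCount", 1)),
    sourceId = if (is.null(obj$id)) "" else as.character(obj$id),
    activities = lapply(feats, function(f)
      if (is.null(f$activities)) numeric() else as.numeric(unlist(f$activities)))
  )
  Pharmacophore(df, sampleId = if (is.null(obj$id)) "" else obj$id,
                activity = if (is.null(obj$activity)) NA_real_
                           else as.numeric(obj$activity))
}

#' @rdname readPharmacophoreJSON
#' @export
writePharmacophoreJSON <- function(pharmacophore, path, merged = FALSE) {
  stopifnot(is(pharmacophore, "Pharmacophore"))
  obj <- list(
    id = sampleId(pharmacophore),
    activity = if (is.na(activity(pharmacophore))) NULL
               else activity(pharmacophore),
    features = .featuresToJSONList(features(pharmacophore), merged = merged)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

.CHARGE_CODES <- c(`0` = 0, `1` = 3, `2` = 2, `3` = 1, `4` = 0,
                   `5` = -1, `6` = -2, `7` = -3)
.DEFAULT_VALENCE <- c(C = 4, N = 3, O = 2, S = 2, P = 3, F = 1,
                      Cl = 1, Br = 1, I = 1, B = 3, H = 1, Si = 4)

## Atom and bond blocks are taken from the raw V2000 text (fixed-width
## fields; old-style charge codes and M CHG lines both honoured): this
## also covers single-atom and bondless records. Ring perception is
## delegated to ChemmineR on the parsed record where bonds exist.
.parseConformer <- function(recLines, sdf = NULL) {
  ci <- grep("V2000", recLines)[1]
  if (is.na(ci)) ci <- 4L
  counts <- recLines[ci]
  n <- as.integer(substr(counts, 1, 3))
  nb <- as.integer(substr(counts, 4, 6))
  if (is.na(n) || n < 1) stop("malformed V2000 counts line")
  atomLines <- recLines[(ci + 1):(ci + n)]
  num <- function(l, a, b) as.numeric(substr(l, a, b))
  elem <- trimws(substr(atomLines, 32, 34))
  code <- trimws(substr(atomLines, 37, 39))
  charge <- rep(0, n)
  known <- code %in% names(.CHARGE_CODES)
  charge[known] <- .CHARGE_CODES[code[known]]
  xyz <- cbind(num(atomLines, 1, 10), num(atomLines, 11, 20),
               num(atomLines, 21, 30))
  bonds <- if (nb > 0) {
    bondLines <- recLines[(ci + n + 1):(ci + n + nb)]
    data.frame(a1 = as.integer(substr(bondLines, 1, 3)),
               a2 = as.integer(substr(bondLines, 4, 6)),
               order = as.numeric(substr(bondLines, 7, 9)))
  } else {
    data.frame(a1 = integer(), a2 = integer(), order = numeric())
  }
  for (l in grep("^M  CHG", recLines, value = TRUE)) {
    f <- as.integer(strsplit(trimws(substr(l, 7, nchar(l))), "\\s+")[[1]])
    npairs <- f[1]
    for (k in seq_len(npairs))
      charge[f[2 * k]] <- f[2 * k + 1]
  }
  ordSum <- rep(0, n)
  effOrder <- ifelse(bonds$order == 4, 1.5, bonds$order)
  for (i in seq_len(nrow(bonds))) {
    ordSum[bonds$a1[i]] <- ordSum[bonds$a1[i]] + effOrder[i]
    ordSum[bonds$a2[i]] <- ordSum[bonds$a2[i]] + effOrder[i]
  }
  val <- .DEFAULT_VALENCE[elem]
  val[is.na(val)] <- 0
  eff <- ifelse(elem == "C", val - abs(charge), val + charge)
  nImplicitH <- pmax(0, round(eff - ordSum))
  nImplicitH[elem == "H"] <- 0
  rings <- if (is.null(sdf) || nrow(bonds) < 3) {
    list(RINGS = list(), AROMATIC = logical())
  } else {
    tryCatch(ChemmineR::rings(sdf, upper = 8, type = "all", arom = TRUE),
             error = function(e) list(RINGS = list(), AROMATIC = logical()))
  }
  ringList <- lapply(rings$RINGS, function(r)
    as.integer(sub("^.*_", "", r)))
  aromatic <- as.logical(rings$AROMATIC)
  ringBondKey <- unique(unlist(lapply(ringList, function(idx) {
    k <- length(idx)
    pairs <- cbind(idx, idx[c(2:k, 1)])
    paste(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
  })))
  bonds$inRing <- paste(pmin(bonds$a1, bonds$a2),
                        pmax(bonds$a1, bonds$a2)) %in% ringBondKey
  list(
    atoms = data.frame(elem = elem, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                       charge = charge, nImplicitH = nImplicitH,
                       stringsAsFactors = FALSE),
    bonds = bonds,
    aromaticRings = if (length(ringList) > 0) ringList[aromatic] else list()
  )
}

#' Load multi-conformer molecules from an SDF file
#'
#' Reads a V2000/V3000 SDF, groups records that share an id (by default the
#' title line) into one multi-conformer sample, parses the activity from an
#' SD tag and converts it to the internal log scale. Records missing the
#' activity tag are skipped with a warning and counted in the
#' `"skipped"` attribute of the result.
#'
#' @param path SDF file path.
#' @param activityField name of the SD tag carrying the activity value.
#' @param unit unit of the raw activity values (see [toLogActivity()]).
#' @param idField `"title"` (SDF title line) or the name of an SD tag used to
#'   group conformers into samples.
#' @return An [ActivityDataset] of [Molecule] samples; attribute `"skipped"`
#'   holds the number of records dropped for lack of an activity value.
#' @export
loadMolecules <- function(path, activityField, unit = "nM", idField = "title") {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  ends <- which(trimws(lines) == "$$$$")
  if (length(ends) == 0) stop("no SDF records in ", path)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  sdfs <- suppressWarnings(ChemmineR::read.SDFset(path))
  n <- length(ends)
  ids <- character(n); act <- rep(NA_real_, n)
  confs <- vector("list", n)
  for (i in seq_len(n)) {
    rec <- lines[starts[i]:ends[i]]
    sdf <- if (i <= length(sdfs)) sdfs[[i]] else NULL
    db <- if (!is.null(sdf)) ChemmineR::datablock(sdf) else character()
    ids[i] <- if (idField == "title") rec[1] else as.character(db[idField])
    v <- suppressWarnings(as.numeric(db[activityField]))
    act[i] <- if (length(v) == 1) v else NA_real_
    confs[[i]] <- .parseConformer(rec, sdf)
    coords <- as.matrix(confs[[i]]$atoms[, c("x", "y", "z")])
    if (nrow(coords) == 0 || (nrow(coords) > 1 && all(coords == 0)))
      stop("record ", i, " (", ids[i], ") has no 3D coordinates")
  }
  skipped <- 0L
  samples <- list(); activities <- numeric()
  for (id in unique(ids)) {
    idx <- which(ids == id)
    a <- act[idx]
    if (all(is.na(a))) {
      warning("sample ", id, " lacks activity field '", activityField,
              "'; skipped")
      skipped <- skipped + 1L
      next
    }
    samples[[length(samples) + 1L]] <- Molecule(id, confs[idx])
    activities <- c(activities, toLogActivity(a[!is.na(a)][1], unit))
  }
  ds <- ActivityDataset(samples, activities, unitOfOrigin = unit)
  attr(ds, "skipped") <- skipped
  ds
}

#' Read an activity table
#'
#' CSV with columns `id`, `activity` and optionally `unit` (default
#' `"logunits"`); activities are converted to the internal log scale.
#'
#' @param path CSV file path.
#' @return data.frame with columns `id` and `activity` (log units).
#' @export
readActivityTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("id", "activity") %in% names(df)))
    stop("activity table needs 'id' and 'activity' columns")
  unit <- if ("unit" %in% names(df)) df$unit else rep("logunits", nrow(df))
  data.frame(id = as.character(df$id),
             activity = mapply(toLogActivity, df$activity, unit),
             stringsAsFactors = FALSE)
}

#' Save and load fitted models
#'
#' A model archive is a directory of plain-text files: the cleaned merged
#' pharmacophore (`merged_pharmacophore.json`, features with inherited
#' activities and merged counts), the alignment template (`template.json`),
#' the configuration (`config.yaml`), the regressor parameters in portable
#' numeric form (`regressor.json`) and training metadata (`meta.json`).
#' Reloading reproduces predictions bitwise.
#'
#' @param model a fitted [QpharModel].
#' @param path directory to create or read.
#' @return `loadQpharModel` returns the [QpharModel]; `saveQpharModel`
#'   returns `path` invisibly.
#' @export
saveQpharModel <- function(model, path) {
  stopifnot(is(model, "QpharModel"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  writePharmacophoreJSON(
    Pharmacophore(representatives(model), sampleId = "merged"),
    file.path(path, "merged_pharmacophore.json"), merged = TRUE)
  writePharmacophoreJSON(modelTemplate(model), file.path(path, "template.json"))
  cfg <- modelConfig(model)
  yaml::write_yaml(list(
    fuzzy = cfg@fuzzy, weightType = cfg@weightType,
    mostRigidTemplate = cfg@mostRigidTemplate,
    clusterCutoff = cfg@clusterCutoff, modelType = cfg@modelType,
    rfNEstimators = cfg@rfNEstimators, rfMaxDepth = cfg@rfMaxDepth,
    randomSeed = cfg@randomSeed), file.path(path, "config.yaml"))
  jsonlite::write_json(.serializeRegressor(model@regressor),
                       file.path(path, "regressor.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(list(globalMin = model@globalMin,
                            globalMax = model@globalMax,
                            droppedSamples = as.list(model@droppedSamples)),
                       file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveQpharModel
#' @export
loadQpharModel <- function(path) {
  merged <- readPharmacophoreJSON(file.path(path, "merged_pharmacophore.json"))
  template <- readPharmacophoreJSON(file.path(path, "template.json"))
  cfg <- yaml::read_yaml(file.path(path, "config.yaml"))
  config <- qpharConfig(fuzzy = cfg$fuzzy, weightType = cfg$weightType,
                        mostRigidTemplate = cfg$mostRigidTemplate,
                        clusterCutoff = cfg$clusterCutoff,
                        modelType = cfg$modelType,
                        rfNEstimators = cfg$rfNEstimators,
                        rfMaxDepth = cfg$rfMaxDepth,
                        randomSeed = cfg$randomSeed)
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  reg <- .deserializeRegressor(
    jsonlite::read_json(file.path(path, "regressor.json"),
                        simplifyVector = TRUE))
  new("QpharModel", template = template, representatives = features(merged),
      globalMin = as.numeric(meta$globalMin),
      globalMax = as.numeric(meta$globalMax),
      regressor = reg, config = config,
      droppedSamples = as.character(unlist(meta$droppedSamples)))
}
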