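## Shared fixtures: tiny molecules built in code, pharmacophore builders,
## random generators and brute-force oracles.

makePh <- function(types, pos, radius = 1.5, id = "ph", activity = NA_real_) {
  pos <- matrix(pos, ncol = 3, byrow = TRUE)
  Pharmacophore(featureFrame(types, pos[, 1], pos[, 2], pos[, 3],
                             radius = radius),
                sampleId = id, activity = activity)
}

## --- toy molecules as V2000 SDF text -------------------------------------

.hexagon <- function(cx = 0, cy = 0, r = 1.395) {
  ang <- seq(0, by = pi / 3, length.out = 6)
  cbind(cx + r * cos(ang), cy + r * sin(ang), 0)
}

.sdfRecord <- function(title, elem, coords, bonds, charges = NULL,
                       tags = c(ACT = "100")) {
  n <- length(elem)
  chargeCode <- rep(0L, n)
  if (!is.null(charges)) {
    map <- c(`1` = 3L, `2` = 2L, `3` = 1L, `-1` = 5L, `-2` = 6L, `-3` = 7L)
    nz <- as.character(charges)
    chargeCode[nz %in% names(map)] <- map[nz[nz %in% names(map)]]
  }
  atomLines <- sprintf(
    "%10.4f%10.4f%10.4f %-3s 0%3d  0  0  0  0  0  0  0  0  0  0",
    coords[, 1], coords[, 2], coords[, 3], elem, chargeCode)
  bondLines <- if (is.null(bonds) || nrow(bonds) == 0) character() else
    sprintf("%3d%3d%3d  0  0  0  0", bonds[, 1], bonds[, 2], bonds[, 3])
  tagLines <- unlist(lapply(names(tags), function(k)
    c(sprintf("> <%s>", k), tags[[k]], "")))
  c(title, "  test", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
            n, if (is.null(bonds)) 0L else nrow(bonds)),
    atomLines, bondLines, "M  END", tagLines, "$$$$")
}

benzeneRecord <- function(title = "benzene", coords = .hexagon(),
                          tags = c(ACT = "100")) {
  bonds <- cbind(1:6, c(2:6, 1), rep(c(2, 1), 3))
  .sdfRecord(title, rep("C", 6), coords, bonds, tags = tags)
}

## meta-aminophenol: aromatic ring + OH + NH2 -> 7 well-spread features
## (AR, 2 H, HBD/HBA at O, HBD/HBA at N); transform remaps the coordinates
aminophenolRecord <- function(title = "aminophenol",
                              transform = function(xyz) xyz,
                              tags = c(ACT = "100")) {
  ring <- .hexagon()
  o <- c(2.76, 0, 0); n <- c(-1.38, 2.39, 0)
  coords <- transform(rbind(ring, o, n))
  bonds <- rbind(cbind(1:6, c(2:6, 1), rep(c(2, 1), 3)),
                 c(1, 7, 1), c(3, 8, 1))
  .sdfRecord(title, c(rep("C", 6), "O", "N"), coords, bonds, tags = tags)
}

toySDFText <- function(name) {
  switch(name,
    benzene = benzeneRecord(),
    methanol = .sdfRecord("methanol", c("C", "O"),
                          rbind(c(0, 0, 0), c(1.43, 0, 0)),
                          cbind(1, 2, 1)),
    methane = .sdfRecord("methane", "C", matrix(c(0.5, 0.5, 0.5), 1), NULL),
    water = .sdfRecord("water", "O", matrix(c(0, 0, 0), 1), NULL),
    ethane = .sdfRecord("ethane", c("C", "C"),
                        rbind(c(0, 0, 0), c(1.54, 0, 0)), cbind(1, 2, 1)),
    propane = .sdfRecord("propane", c("C", "C", "C"),
                         rbind(c(0, 0, 0), c(1.54, 0, 0), c(2.3, 1.3, 0)),
                         rbind(c(1, 2, 1), c(2, 3, 1))),
    butane = .sdfRecord("butane", rep("C", 4),
                        rbind(c(0, 0, 0), c(1.54, 0, 0), c(2.3, 1.3, 0),
                              c(3.84, 1.3, 0)),
                        rbind(c(1, 2, 1), c(2, 3, 1), c(3, 4, 1))),
    biphenyl = {
      a <- .hexagon(); b <- .hexagon(cx = 4.28)
      bonds <- rbind(cbind(1:6, c(2:6, 1), rep(c(2, 1), 3)),
                     cbind(7:12, c(8:12, 7), rep(c(2, 1), 3)),
                     c(1, 10, 1))
      .sdfRecord("biphenyl", rep("C", 12), rbind(a, b), bonds)
    },
    hexane = .sdfRecord("hexane", rep("C", 6),
                        cbind(seq(0, by = 1.3, length.out = 6),
                              rep(c(0, 0.8), 3), 0),
                        cbind(1:5, 2:6, 1)),
    methylammonium = .sdfRecord("methylammonium", c("C", "N"),
                                rbind(c(0, 0, 0), c(1.48, 0, 0)),
                                cbind(1, 2, 1), charges = c(0, 1)),
    acetate = .sdfRecord("acetate", c("C", "C", "O", "O"),
                         rbind(c(0, 0, 0), c(1.5, 0, 0), c(2.2, 1.1, 0),
                               c(2.2, -1.1, 0)),
                         rbind(c(1, 2, 1), c(2, 3, 2), c(2, 4, 1)),
                         charges = c(0, 0, 0, -1)),
    stop("unknown toy molecule: ", name)
  )
}

toyMolecule <- function(name) {
  path <- tempfile(fileext = ".sdf")
  writeLines(toySDFText(name), path)
  ds <- suppressWarnings(loadMolecules(path, "ACT", unit = "nM"))
  samples(ds)[[1]]
}

## --- random generators ----------------------------------------------------

randomRotation <- function() {
  M <- matrix(rnorm(9), 3, 3)
  qrd <- qr(M)
  Q <- qr.Q(qrd) %*% diag(sign(diag(qr.R(qrd))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

randomPharmacophore <- function(n = sample(3:8, 1), box = 8, id = "rand") {
  types <- sample(featureTypes(), n, replace = TRUE)
  makePh(types, t(replicate(n, runif(3, -box, box))), id = id)
}

## --- brute-force oracles --------------------------------------------------

## single-linkage agglomerative clustering, literal algorithm: repeatedly
## merge the two clusters at minimum inter-member distance while < cutoff
singleLinkageOracle <- function(pos, cutoff) {
  n <- nrow(pos)
  clusters <- as.list(seq_len(n))
  d <- as.matrix(dist(pos))
  repeat {
    if (length(clusters) == 1) break
    bestD <- Inf; bestPair <- NULL
    for (i in seq_len(length(clusters) - 1))
      for (j in seq((i + 1), length(clusters))) {
        dij <- min(d[clusters[[i]], clusters[[j]]])
        if (dij < bestD) { bestD <- dij; bestPair <- c(i, j) }
      }
    if (bestD >= cutoff) break
    clusters[[bestPair[1]]] <- sort(c(clusters[[bestPair[1]]],
                                      clusters[[bestPair[2]]]))
    clusters[[bestPair[2]]] <- NULL
  }
  canonicalPartition(clusters)
}

canonicalPartition <- function(parts) {
  parts <- lapply(parts, sort)
  parts[order(vapply(parts, min, numeric(1)))]
}

## exhaustive alignment oracle: every injective type-compatible mapping of
## size >= 3 is superposed and scored by the overlap rule
alignmentOracleScore <- function(query, template) {
  tf <- features(template); qf <- features(query)
  tpos <- as.matrix(tf[, c("x", "y", "z")])
  qpos <- as.matrix(qf[, c("x", "y", "z")])
  nT <- nrow(tf)
  best <- 0L
  countOverlapPairs <- function(moved) {
    ## independent greedy overlap count (nearest pairs first, injective)
    d <- matrix(Inf, nT, nrow(qf))
    for (i in seq_len(nT)) for (j in seq_len(nrow(qf)))
      if (tf$type[i] == qf$type[j]) {
        dij <- sqrt(sum((tpos[i, ] - moved[j, ])^2))
        if (dij < min(tf$radius[i], qf$radius[j])) d[i, j] <- dij
      }
    cnt <- 0L
    while (any(is.finite(d))) {
      ix <- which(d == min(d), arr.ind = TRUE)[1, ]
      cnt <- cnt + 1L
      d[ix[1], ] <- Inf; d[, ix[2]] <- Inf
    }
    cnt
  }
  subsets <- utils::combn(nT, 3, simplify = FALSE)
  for (ss in subsets) {
    candLists <- lapply(ss, function(i) which(qf$type == tf$type[i]))
    if (any(lengths(candLists) == 0)) next
    for (a in candLists[[1]]) for (b in candLists[[2]]) for (cc in candLists[[3]]) {
      if (length(unique(c(a, b, cc))) < 3) next
      sp <- tryCatch(superpose(tpos[ss, ], qpos[c(a, b, cc), ]),
                     error = function(e) NULL)
      if (is.null(sp)) next
      moved <- qpos %*% t(sp$rotation) +
        matrix(sp$translation, nrow(qpos), 3, byrow = TRUE)
      sc <- countOverlapPairs(moved)
      if (sc > best) best <- sc
    }
  }
  best
}

## --- CLI helpers ---------------------------------------------------------

cliPath <- function() {
  p <- system.file("exec", "qphar", package = "qphar")
  if (!nzchar(p)) p <- file.path(system.file(package = "qphar"), "exec", "qphar")
  p
}

runCli <- function(...) {
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- suppressWarnings(
    system2(rscript, c(cliPath(), ...), stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  list(status = if (is.null(status)) 0L else status, output = out)
}
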