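## Rule-based pharmacophore perception from a 3D conformer.
##
## The rule set is deliberately small and auditable; perception toolkits
## differ in their definitions, so these rules are pinned and versioned here
## rather than matched to any particular program:
##   AR  - centroid of each aromatic ring (flat 5/6-ring of C/N/O/S in which
##         every ring atom takes part in a double or aromatic ring bond)
##   HBD - N or O carrying at least one hydrogen, one feature per donor
##         heavy atom (not per hydrogen)
##   HBA - N or O with no positive formal charge and fewer than four heavy
##         neighbours
##   PI  - atom with positive formal charge
##   NI  - atom with negative formal charge
##   H   - apolar carbons (no heteroatom neighbour, uncharged); maximal
##         bonded groups of >= 3 collapse to their centroid, smaller groups
##         yield one feature per atom
## All features are spherical with the default 1.5 A tolerance radius.

PERCEPTION_RULES_VERSION <- "1.0"

.heavyNeighbours <- function(conf) {
  n <- nrow(conf$atoms)
  nb <- vector("list", n)
  for (i in seq_len(nrow(conf$bonds))) {
    a <- conf$bonds$a1[i]; b <- conf$bonds$a2[i]
    nb[[a]] <- c(nb[[a]], b)
    nb[[b]] <- c(nb[[b]], a)
  }
  nb
}

.explicitH <- function(conf, nb) {
  vapply(seq_along(nb), function(i)
    sum(conf$atoms$elem[nb[[i]]] == "H"), integer(1))
}

#' Perceive a pharmacophore from a 3D conformer
#'
#' Applies the package's rule set (see source header of `perception.R`) to
#' one conformer of a [Molecule], producing spherical features of the six
#' types at ring centroids, donor/acceptor heavy atoms, charged atoms and
#' hydrophobic group centroids. Perception is deterministic and
#' equivariant: rigidly moving the conformer moves every feature
#' identically.
#'
#' @param molecule a [Molecule].
#' @param conformerIndex which conformer to perceive (default 1).
#' @param radius feature tolerance radius in Angstrom.
#' @return A [Pharmacophore] with `conformerIndex` recorded.
#' @export
perceivePharmacophore <- function(molecule, conformerIndex = 1L, radius = 1.5) {
  stopifnot(is(molecule, "Molecule"))
  conf <- conformers(molecule)[[conformerIndex]]
  atoms <- conf$atoms
  nb <- .heavyNeighbours(conf)
  nH <- atoms$nImplicitH + .explicitH(conf, nb)
  heavy <- atoms$elem != "H"
  nHeavyNb <- vapply(nb, function(ix) sum(atoms$elem[ix] != "H"), integer(1))

  type <- character(); px <- numeric(); py <- numeric(); pz <- numeric()
  addFeat <- function(t, pos) {
    type <<- c(type, t); px <<- c(px, pos[1])
    py <<- c(py, pos[2]); pz <<- c(pz, pos[3])
  }

  ## AR: aromatic ring centroids
  for (ring in conf$aromaticRings)
    addFeat("AR", colMeans(atoms[ring, c("x", "y", "z")]))

  ## HBD / HBA on N and O heavy atoms
  for (i in which(atoms$elem %in% c("N", "O"))) {
    pos <- as.numeric(atoms[i, c("x", "y", "z")])
    if (nH[i] >= 1) addFeat("HBD", pos)
    if (atoms$charge[i] <= 0 && nHeavyNb[i] < 4) addFeat("HBA", pos)
  }

  ## PI / NI on formally charged atoms
  for (i in which(heavy & atoms$charge > 0))
    addFeat("PI", as.numeric(atoms[i, c("x", "y", "z")]))
  for (i in which(heavy & atoms$charge < 0))
    addFeat("NI", as.numeric(atoms[i, c("x", "y", "z")]))

  ## H: hydrophobic groups of apolar carbons
  polarNb <- vapply(nb, function(ix)
    any(atoms$elem[ix] %in% c("N", "O", "S", "P")), logical(1))
  apolar <- which(atoms$elem == "C" & atoms$charge == 0 & !polarNb)
  if (length(apolar) > 0) {
    comp <- .connectedComponents(apolar, conf$bonds)
    for (grp in comp) {
      if (length(grp) >= 3) {
        addFeat("H", colMeans(atoms[grp, c("x", "y", "z")]))
      } else {
        for (i in grp) addFeat("H", as.numeric(atoms[i, c("x", "y", "z")]))
      }
    }
  }

  if (length(type) == 0)
    stop("no perceivable pharmacophore feature in sample ",
         sampleId(molecule), "; it cannot take part in alignment")
  Pharmacophore(featureFrame(type, px, py, pz, radius = radius,
                             sourceId = sampleId(molecule)),
                sampleId = sampleId(molecule),
                conformerIndex = as.integer(conformerIndex))
}

## connected components of the subgraph induced by `nodes` under the bond list
.connectedComponents <- function(nodes, bonds) {
  inSet <- logical(max(c(nodes, bonds$a1, bonds$a2, 1)))
  inSet[nodes] <- TRUE
  adj <- list()
  for (i in seq_len(nrow(bonds))) {
    a <- bonds$a1[i]; b <- bonds$a2[i]
    if (a <= length(inSet) && b <= length(inSet) && inSet[a] && inSet[b]) {
      adj[[as.character(a)]] <- c(adj[[as.character(a)]], b)
      adj[[as.character(b)]] <- c(adj[[as.character(b)]], a)
    }
  }
  seen <- logical(length(inSet))
  comps <- list()
  for (s in nodes) {
    if (seen[s]) next
    queue <- s; seen[s] <- TRUE; comp <- integer()
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      comp <- c(comp, v)
      for (w in adj[[as.character(v)]])
        if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

#' Count features by type
#'
#' Tallies a pharmacophore's features in the fixed container order
#' `(H, AR, PI, NI, HBD, HBA)`; the entries sum to the feature count. This
#' 6-vector is the input of the feature-count baseline model.
#'
#' @param pharmacophore a [Pharmacophore].
#' @return named integer 6-vector.
#' @export
countFeaturesByType <- function(pharmacophore) {
  stopifnot(is(pharmacophore, "Pharmacophore"))
  tab <- table(factor(features(pharmacophore)$type, levels = featureTypes()))
  stats::setNames(as.integer(tab), featureTypes())
}

#' Count rotatable bonds
#'
#' Standard definition: single, non-ring bonds between two non-terminal
#' heavy atoms. Used as the rigidity criterion for template selection
#' (fewest rotatable bonds = most rigid).
#'
#' @param molecule a [Molecule] (topology of conformer 1 is used).
#' @return integer count.
#' @export
countRotatableBonds <- function(molecule) {
  conf <- conformers(molecule)[[1]]
  atoms <- conf$atoms; bonds <- conf$bonds
  if (nrow(bonds) == 0) return(0L)
  nb <- .heavyNeighbours(conf)
  heavyDeg <- vapply(nb, function(ix) sum(atoms$elem[ix] != "H"), integer(1))
  rot <- bonds$order == 1 & !bonds$inRing &
    atoms$elem[bonds$a1] != "H" & atoms$elem[bonds$a2] != "H" &
    heavyDeg[bonds$a1] >= 2 & heavyDeg[bonds$a2] >= 2
  sum(rot)
}

#' Physico-chemical descriptors
#'
#' The 7-vector used by the descriptor baseline, in fixed order:
#' H-bond donors, H-bond acceptors, rotatable bonds, molecular weight,
#' heavy atoms, cLogP and TPSA. Donor/acceptor counts follow the same
#' per-heavy-atom rules as feature perception so that baseline vectors are
#' reproducible from documented rules; cLogP and TPSA are computed with
#' Open Babel.
#'
#' @param molecule a [Molecule].
#' @return named numeric 7-vector
#'   `(HBD, HBA, nRot, MW, nHeavy, cLogP, TPSA)`.
#' @export
computeDescriptors <- function(molecule) {
  conf <- conformers(molecule)[[1]]
  atoms <- conf$atoms
  nb <- .heavyNeighbours(conf)
  nH <- atoms$nImplicitH + .explicitH(conf, nb)
  nHeavyNb <- vapply(nb, function(ix) sum(atoms$elem[ix] != "H"), integer(1))
  isNO <- atoms$elem %in% c("N", "O")
  hbd <- sum(isNO & nH >= 1)
  hba <- sum(isNO & atoms$charge <= 0 & nHeavyNb < 4)
  heavy <- atoms$elem != "H"
  masses <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
              F = 18.998, Cl = 35.45, Br = 79.904, I = 126.904, B = 10.81,
              H = 1.008, Si = 28.085)
  mw <- sum(masses[atoms$elem], na.rm = TRUE) + sum(atoms$nImplicitH) * 1.008
  ob <- .obProperties(molecule)
  c(HBD = hbd, HBA = hba, nRot = as.numeric(countRotatableBonds(molecule)),
    MW = mw, nHeavy = sum(heavy), cLogP = ob$logP, TPSA = ob$TPSA)
}

## cLogP / TPSA through Open Babel; the conformer is rendered back to a
## minimal V2000 block for the call.
.obProperties <- function(molecule) {
  conf <- conformers(molecule)[[1]]
  txt <- paste(c(.conformerToSDFText(conf, sampleId(molecule)), ""),
               collapse = "\n")
  p <- NULL
  ChemmineOB::forEachMol("SDF", txt, function(mol) {
    p <<- ChemmineOB::prop_OB(mol)
  })
  if (is.null(p)) stop("Open Babel could not read the conformer")
  list(logP = as.numeric(p$logP[1]), TPSA = as.numeric(p$TPSA[1]))
}

.REV_CHARGE_CODES <- c(`3` = 1, `2` = 2, `1` = 3, `-1` = 5, `-2` = 6, `-3` = 7)

.conformerToSDFText <- function(conf, id = "mol") {
  atoms <- conf$atoms; bonds <- conf$bonds
  chargeCode <- rep(0L, nrow(atoms))
  nz <- as.character(atoms$charge)
  known <- nz %in% names(.REV_CHARGE_CODES)
  chargeCode[known] <- .REV_CHARGE_CODES[nz[known]]
  atomLines <- sprintf("%10.4f%10.4f%10.4f %-3s 0%3d  0  0  0  0  0  0  0  0  0  0",
                       atoms$x, atoms$y, atoms$z, atoms$elem, chargeCode)
  bondLines <- sprintf("%3d%3d%3d  0  0  0  0", bonds$a1, bonds$a2,
                       as.integer(bonds$order))
  c(id, "  qphar", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
            nrow(atoms), nrow(bonds)),
    atomLines, bondLines, "M  END", "$$$$")
}
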