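# Geometric pocket detection: alpha spheres and their clustering.

#' Compute alpha spheres of a structure
#'
#' An alpha sphere is the circumsphere of four heavy atoms that contains no
#' other heavy atom; spheres with radii inside \code{[rMin, rMax]} probe
#' clefts and cavities (smaller radii sit inside the protein, larger ones
#' in bulk solvent). Candidates are enumerated over locally close atom
#' quadruples with an empty-circumsphere test, which in general position
#' yields the Delaunay-tetrahedron circumspheres in the radius window.
#'
#' @param structure a \code{\linkS4class{StructureModel}}.
#' @param rMin,rMax radius window in Angstrom; defaults 3.0 and 6.0.
#' @param apolarElements elements counted as apolar for sphere polarity;
#'   default carbon and sulfur.
#' @param tol emptiness tolerance: an atom is inside a sphere iff its
#'   distance to the center is < radius - tol (default 1e-6), which keeps
#'   degenerate co-spherical atoms from rejecting valid spheres.
#' @return An \code{\linkS4class{AlphaSphereSet}}.
#' @export
computeAlphaSpheres <- function(structure, rMin = 3, rMax = 6,
                                apolarElements = c("C", "S"),
                                tol = 1e-6) {
  a <- atoms(structure)
  polyIdx <- which(!a$hetero)  # ligands must not fill their own cavity
  xyz <- as.matrix(a[polyIdx, c("x", "y", "z")])
  if (nrow(xyz) < 4)
    stop("tessellation error: need >= 4 heavy atoms, got ", nrow(xyz))
  ctr <- sweep(xyz, 2, colMeans(xyz))
  if (qr(ctr)$rank < 3)
    stop("tessellation error: atoms are degenerate (coplanar or collinear)")
  res <- cpp_alpha_spheres(xyz, rMin, rMax, tol)
  s <- data.frame(x = res$x, y = res$y, z = res$z, radius = res$radius,
                  a1 = polyIdx[res$a1], a2 = polyIdx[res$a2],
                  a3 = polyIdx[res$a3], a4 = polyIdx[res$a4])
  if (nrow(s)) {
    ord <- order(s$a1, s$a2, s$a3, s$a4)
    s <- s[ord, , drop = FALSE]
    rownames(s) <- NULL
    s$apolar <- classifySpherePolarity(s, structure, apolarElements)
  } else {
    s$apolar <- logical(0)
  }
  new("AlphaSphereSet", spheres = s, structureId = sourceId(structure),
      radiusWindow = c(rMin, rMax))
}

#' Classify alpha-sphere polarity
#'
#' A sphere is apolar iff at least 3 of its 4 defining atoms are apolar;
#' by default an atom is apolar iff its element is carbon or sulfur.
#'
#' @param spheres sphere data.frame with columns a1..a4 (atom row indices),
#'   or an \code{\linkS4class{AlphaSphereSet}}.
#' @param structure the source \code{\linkS4class{StructureModel}}.
#' @param apolarElements apolar element table (config-overridable).
#' @return Logical vector, one flag per sphere.
#' @export
classifySpherePolarity <- function(spheres, structure,
                                   apolarElements = c("C", "S")) {
  if (is(spheres, "AlphaSphereSet")) spheres <- spheres@spheres
  ele <- atoms(structure)$element
  ap <- ele %in% toupper(apolarElements)
  nApolar <- ap[spheres$a1] + ap[spheres$a2] + ap[spheres$a3] + ap[spheres$a4]
  nApolar >= 3
}

#' Cluster alpha spheres into pockets
#'
#' Single-linkage clustering of sphere centers at \code{linkageDist},
#' followed by a coarse pass that merges clusters whose centroids lie
#' within \code{mergeDist}. Clusters with fewer than \code{minSpheres}
#' spheres are discarded; surviving pockets are ranked by sphere count
#' (descending), ties broken by centroid x, y, z so that the ranking is
#' reproducible. \code{pocket_id} is the rank.
#'
#' @param sphereSet an \code{\linkS4class{AlphaSphereSet}} (non-empty).
#' @param structure the source \code{\linkS4class{StructureModel}}.
#' @param linkageDist single-linkage threshold in Angstrom, default 1.73.
#' @param mergeDist centroid-merge threshold of the second pass, default
#'   4.5 Angstrom.
#' @param minSpheres minimum spheres per retained pocket, default 30
#'   (engineered small-cavity fixtures use lower values explicitly).
#' @return A \code{\linkS4class{PocketSet}} (possibly with zero pockets).
#' @export
clusterPockets <- function(sphereSet, structure, linkageDist = 1.73,
                           mergeDist = 4.5, minSpheres = 30) {
  s <- spheres(sphereSet)
  if (!nrow(s)) stop("no alpha spheres to cluster")
  ctr <- as.matrix(s[, c("x", "y", "z")])
  cl <- if (nrow(s) == 1) 1L else
    cutree(hclust(dist(ctr), method = "single"), h = linkageDist)
  # coarse pass: merge clusters whose centroids are close
  cents <- do.call(rbind, lapply(split(seq_len(nrow(s)), cl), function(i)
    colMeans(ctr[i, , drop = FALSE])))
  if (nrow(cents) > 1) {
    merge <- cutree(hclust(dist(cents), method = "single"), h = mergeDist)
    cl <- merge[as.character(cl)]
  }
  groups <- split(seq_len(nrow(s)), cl)
  groups <- groups[vapply(groups, length, 1L) >= minSpheres]
  if (!length(groups)) {
    s$pocket_id <- NA_integer_
    return(new("PocketSet", spheres = s,
               summary = data.frame(pocket_id = integer(),
                                    n_spheres = integer(), cx = numeric(),
                                    cy = numeric(), cz = numeric()),
               contactAtomList = list(), contactResidueList = list(),
               structureId = sphereSet@structureId))
  }
  sizes <- vapply(groups, length, 1L)
  gc <- t(vapply(groups, function(i) colMeans(ctr[i, , drop = FALSE]),
                 numeric(3)))
  ord <- order(-sizes, gc[, 1], gc[, 2], gc[, 3])
  groups <- groups[ord]; sizes <- sizes[ord]; gc <- gc[ord, , drop = FALSE]

  a <- atoms(structure)
  s$pocket_id <- NA_integer_
  contactsA <- contactsR <- vector("list", length(groups))
  for (p in seq_along(groups)) {
    idx <- groups[[p]]
    s$pocket_id[idx] <- p
    ca <- sort(unique(c(s$a1[idx], s$a2[idx], s$a3[idx], s$a4[idx])))
    contactsA[[p]] <- ca
    contactsR[[p]] <- unique(residueKey(a$chain[ca], a$resno[ca]))
  }
  new("PocketSet", spheres = s,
      summary = data.frame(pocket_id = seq_along(groups),
                           n_spheres = as.integer(sizes),
                           cx = gc[, 1], cy = gc[, 2], cz = gc[, 3]),
      contactAtomList = contactsA, contactResidueList = contactsR,
      structureId = sphereSet@structureId)
}

#' Detect pockets of a structure in one call
#'
#' Convenience wrapper: \code{\link{computeAlphaSpheres}} then
#' \code{\link{clusterPockets}}.
#'
#' @param structure a \code{\linkS4class{StructureModel}}.
#' @param config a \code{\link{detectionConfig}} list.
#' @return A \code{\linkS4class{PocketSet}}.
#' @export
detectPockets <- function(structure, config = detectionConfig()) {
  ss <- computeAlphaSpheres(structure, rMin = config$rMin,
                            rMax = config$rMax,
                            apolarElements = config$apolarElements)
  clusterPockets(ss, structure, linkageDist = config$linkageDist,
                 mergeDist = config$mergeDist,
                 minSpheres = config$minSpheres)
}

#' Pocket detection and descriptor configuration
#'
#' Collects the tunable geometry parameters in one list.
#'
#' @param rMin,rMax alpha-sphere radius window (Angstrom).
#' @param linkageDist,mergeDist,minSpheres clustering parameters, see
#'   \code{\link{clusterPockets}}.
#' @param apolarElements apolar element table.
#' @param mcSamples Monte-Carlo samples for pocket volume.
#' @param surfPoints sample points per atom for surface areas.
#' @param seed RNG seed for the stochastic descriptor estimates.
#' @return Named list of parameters.
#' @export
detectionConfig <- function(rMin = 3, rMax = 6, linkageDist = 1.73,
                            mergeDist = 4.5, minSpheres = 30,
                            apolarElements = c("C", "S"),
                            mcSamples = 20000, surfPoints = 500,
                            seed = 1L) {
  list(rMin = rMin, rMax = rMax, linkageDist = linkageDist,
       mergeDist = mergeDist, minSpheres = minSpheres,
       apolarElements = apolarElements, mcSamples = mcSamples,
       surfPoints = surfPoints, seed = seed)
}

#' Export pocket spheres for visual inspection
#'
#' Writes the member spheres of each pocket as HETATM pseudo-atoms
#' (residue \code{STP}, residue number = pocket id) with the sphere radius
#' in the occupancy column, a PQR-like convention viewers accept.
#'
#' @param pocketSet a \code{\linkS4class{PocketSet}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePocketPDB <- function(pocketSet, path) {
  s <- spheres(pocketSet)
  s <- s[!is.na(s$pocket_id), , drop = FALSE]
  rec <- sprintf(
    "HETATM%5d  O   STP P%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           O",
    seq_len(nrow(s)), s$pocket_id, s$x, s$y, s$z, s$radius, 0)
  writeLines(c(rec, "END"), path)
  invisible(path)
}
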