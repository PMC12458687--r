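# The 17 per-pocket physicochemical descriptors.

#' Descriptor names in canonical order
#'
#' @param extra include the 17th slot (count of apolar alpha spheres,
#'   \code{n_apol_as}); \code{FALSE} gives the 16-feature mode.
#' @return Character vector of descriptor column names.
#' @export
descriptorNames <- function(extra = TRUE) {
  base <- c("pock_vol", "nb_AS", "surf_vdw", "surf_pol_vdw",
            "surf_apol_vdw", "hydrophobicity_score", "mean_loc_hyd_dens",
            "apol_as_prop", "prop_polar_atm", "mean_as_solv_acc",
            "as_dens", "as_max_dst", "volume_score", "polarity_score",
            "charge_score", "flex")
  if (extra) c(base, "n_apol_as") else base
}

#' Compute pocket descriptors
#'
#' Computes the physicochemical descriptor vector for every pocket of a
#' \code{\linkS4class{PocketSet}}: Monte-Carlo pocket volume, sphere count,
#' sampled van der Waals surface areas (total / polar / apolar),
#' residue-scale scores over the contact residues, sphere density and
#' extent, local hydrophobic density, sphere solvent accessibility, and
#' flexibility (contact-residue B normalized by the structure mean B).
#' Stochastic estimates are seeded and bit-reproducible.
#'
#' @param pocketSet a \code{\linkS4class{PocketSet}} with >= 1 pocket.
#' @param structure the source \code{\linkS4class{StructureModel}}.
#' @param scales a \code{\link{defaultResidueScales}} list.
#' @param config a \code{\link{detectionConfig}} list (Monte-Carlo sample
#'   counts, polarity tables, seed).
#' @param extra include the 17th descriptor (\code{n_apol_as}).
#' @return A \code{\linkS4class{DescriptorTable}} (unlabeled), one row per
#'   pocket.
#' @export
computeDescriptors <- function(pocketSet, structure,
                               scales = defaultResidueScales(),
                               config = detectionConfig(),
                               extra = TRUE) {
  if (nPockets(pocketSet) < 1)
    stop("invalid pocket set: no pockets to describe")
  a <- atoms(structure)
  s <- spheres(pocketSet)
  polyB <- a$b[!a$hetero]
  meanB <- if (length(polyB) && mean(polyB) > 0) mean(polyB) else NA_real_
  rows <- lapply(pocketIds(pocketSet), function(p) {
    idx <- which(s$pocket_id == p)
    sp <- s[idx, , drop = FALSE]
    seedP <- childSeed(config$seed, p)
    ctr <- as.matrix(sp[, c("x", "y", "z")])

    nbAS <- nrow(sp)
    apolProp <- mean(sp$apolar)
    pockVol <- pocketVolumeMC(ctr, sp$radius, mcSamples = config$mcSamples,
                              seed = seedP)
    ca <- contactAtoms(pocketSet, p)
    surf <- vdwSurfaceAreas(structure, ca, nPoints = config$surfPoints,
                            seed = childSeed(seedP, 1))
    # pairwise sphere-center geometry
    if (nbAS > 1) {
      pd <- dist(ctr)
      asDens <- mean(pd)
      asMax <- max(pd)
    } else {
      asDens <- 0
      asMax <- 0
    }
    # local hydrophobic density: mean over apolar spheres of the number of
    # apolar spheres within the overlap neighbourhood (center distance
    # < sum of radii); the sphere itself counts
    apIdx <- which(sp$apolar)
    mlhd <- if (length(apIdx)) {
      apc <- ctr[apIdx, , drop = FALSE]
      dm <- crossDist(apc, apc)
      rs <- outer(sp$radius[apIdx], sp$radius[apIdx], "+")
      mean(rowSums(dm < rs))
    } else 0
    # contact-atom polarity
    ele <- a$element[ca]
    propPolar <- mean(ele %in% c("N", "O"))
    # sphere solvent accessibility: fraction of sphere-surface sample
    # points not covered by any atom vdW sphere
    solvAcc <- meanSphereSolvAcc(ctr, sp$radius, a,
                                 seed = childSeed(seedP, 2))
    # residue-scale scores over contact residues
    resKeys <- contactResidues(pocketSet, p)
    keyAll <- residueKey(a$chain, a$resno)
    resNames <- vapply(resKeys, function(k) a$resid[match(k, keyAll)], "")
    scoreOf <- function(map) {
      v <- map[resNames]
      if (all(is.na(v))) 0 else mean(v, na.rm = TRUE)
    }
    # flexibility: contact-residue mean B over structure mean B
    flex <- if (is.na(meanB)) 0 else {
      cb <- a$b[!a$hetero & keyAll %in% resKeys]
      mean(cb) / meanB
    }
    out <- c(pock_vol = pockVol, nb_AS = nbAS, surf_vdw = surf[["total"]],
             surf_pol_vdw = surf[["polar"]],
             surf_apol_vdw = surf[["apolar"]],
             hydrophobicity_score = scoreOf(scales$hydrophobicity),
             mean_loc_hyd_dens = mlhd, apol_as_prop = apolProp,
             prop_polar_atm = propPolar, mean_as_solv_acc = solvAcc,
             as_dens = asDens, as_max_dst = asMax,
             volume_score = scoreOf(scales$volume),
             polarity_score = scoreOf(scales$polarity),
             charge_score = scoreOf(scales$charge), flex = flex)
    if (extra) out <- c(out, n_apol_as = sum(sp$apolar))
    out
  })
  mat <- do.call(rbind, rows)
  df <- data.frame(structure_id = pocketSet@structureId,
                   pocket_id = pocketIds(pocketSet), mat,
                   stringsAsFactors = FALSE)
  DescriptorTable(df)
}

#' Monte-Carlo volume of a union of spheres
#'
#' Samples uniformly in the axis-aligned bounding box of the spheres and
#' returns hit fraction times box volume. Deterministic for a fixed seed.
#'
#' @param centers n x 3 matrix of sphere centers.
#' @param radii sphere radii.
#' @param mcSamples number of samples (>= 1e4).
#' @param seed RNG seed.
#' @return Volume in cubic Angstrom.
#' @export
pocketVolumeMC <- function(centers, radii, mcSamples = 1e5, seed = 1L) {
  centers <- matrix(as.numeric(centers), ncol = 3)
  stopifnot(nrow(centers) == length(radii), mcSamples >= 1e4)
  lo <- apply(centers - radii, 2, min)
  hi <- apply(centers + radii, 2, max)
  boxVol <- prod(hi - lo)
  withSeed(seed, {
    pts <- cbind(runif(mcSamples, lo[1], hi[1]),
                 runif(mcSamples, lo[2], hi[2]),
                 runif(mcSamples, lo[3], hi[3]))
    hit <- rep(FALSE, mcSamples)
    for (i in seq_along(radii)) {
      d2 <- (pts[, 1] - centers[i, 1])^2 + (pts[, 2] - centers[i, 2])^2 +
            (pts[, 3] - centers[i, 3])^2
      hit <- hit | (d2 <= radii[i]^2)
    }
    mean(hit) * boxVol
  })
}

#' Exposed van der Waals surface areas of pocket contact atoms
#'
#' Estimates the exposed vdW area of each contact atom by sampling points
#' on its vdW sphere and discarding points inside any \emph{other} contact
#' atom's vdW sphere. Totals are split by atom polarity (polar = N, O);
#' polar + apolar = total exactly because the same atom partition is used.
#'
#' @param structure a \code{\linkS4class{StructureModel}}.
#' @param contactIdx atom row indices of the pocket's contact atoms.
#' @param nPoints sample points per atom.
#' @param seed RNG seed.
#' @param polarElements elements counted polar; default N and O.
#' @return Named numeric: total, polar, apolar (square Angstrom).
#' @export
vdwSurfaceAreas <- function(structure, contactIdx, nPoints = 500,
                            seed = 1L, polarElements = c("N", "O")) {
  a <- atoms(structure)[contactIdx, , drop = FALSE]
  r <- vdwRadius(a$element)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  n <- nrow(a)
  polar <- a$element %in% toupper(polarElements)
  areas <- withSeed(seed, {
    vapply(seq_len(n), function(i) {
      pts <- sphereSurfacePoints(nPoints) * r[i]
      pts <- sweep(pts, 2, xyz[i, ], "+")
      exposed <- rep(TRUE, nPoints)
      for (j in seq_len(n)[-i]) {
        d2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
              (pts[, 3] - xyz[j, 3])^2
        exposed <- exposed & (d2 > r[j]^2)
        if (!any(exposed)) break
      }
      mean(exposed) * 4 * pi * r[i]^2
    }, numeric(1))
  })
  c(total = sum(areas), polar = sum(areas[polar]),
    apolar = sum(areas[!polar]))
}

# Uniform random points on the unit sphere.
sphereSurfacePoints <- function(n) {
  z <- runif(n, -1, 1)
  phi <- runif(n, 0, 2 * pi)
  rxy <- sqrt(pmax(0, 1 - z^2))
  cbind(rxy * cos(phi), rxy * sin(phi), z)
}

# Mean fraction of each sphere's surface sample points not covered by any
# atom vdW sphere (100 points per sphere).
meanSphereSolvAcc <- function(centers, radii, atomTable, seed = 1L,
                              pointsPerSphere = 100) {
  xyz <- as.matrix(atomTable[, c("x", "y", "z")])
  rv <- vdwRadius(atomTable$element)
  withSeed(seed, {
    fr <- vapply(seq_along(radii), function(i) {
      pts <- sphereSurfacePoints(pointsPerSphere) * radii[i]
      pts <- sweep(pts, 2, centers[i, ], "+")
      d <- crossDist(pts, xyz)
      cov <- rowSums(d < matrix(rv, nrow(pts), length(rv),
                                byrow = TRUE)) > 0
      mean(!cov)
    }, numeric(1))
    mean(fr)
  })
}

#' Write a descriptor table as TSV
#'
#' Header is exactly structure_id, pocket_id, the descriptor names, and
#' (when present) label and matched_ligand.
#'
#' @param table a \code{\linkS4class{DescriptorTable}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeDescriptorTable <- function(table, path) {
  write.table(descriptorRows(table), path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  invisible(path)
}

#' Read a descriptor table TSV
#'
#' @param path file path.
#' @return A \code{\linkS4class{DescriptorTable}}.
#' @export
readDescriptorTable <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, na.strings = "")
  DescriptorTable(df)
}
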