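# Synthetic fixtures: engineered cavity structures and class-conditional
# descriptor tables. These exercise the pipeline's contracts offline; they
# make no attempt at physical realism (no backbone geometry, no rotamers).

# element assigned to the single pseudo-atom of each residue type
RESIDUE_ELEMENT <- c(ALA = "C", VAL = "C", LEU = "C", ILE = "C",
                     PHE = "C", PRO = "C", GLY = "C", TRP = "C",
                     MET = "S", CYS = "S",
                     SER = "O", THR = "O", ASN = "O", GLN = "O",
                     ASP = "O", GLU = "O", TYR = "O",
                     LYS = "N", ARG = "N", HIS = "N")

#' Specification of an engineered cavity structure
#'
#' @param shellRadius radius of the atom shell, Angstrom (default 12).
#' @param nShellAtoms atoms on the shell (>= 20, default 60).
#' @param cavityRadius nominal interior cavity radius (< shellRadius).
#' @param lining named residue-frequency map for the lining composition.
#' @param plantedLigand optional component code placed at the cavity
#'   center (e.g. "CLR").
#' @param plddt B-factor / pLDDT value written to all atoms (default 90);
#'   may be a per-residue vector.
#' @param jitter initial positional jitter amplitude, Angstrom.
#' @param seed RNG seed; generation is bit-reproducible.
#' @return A cavity-spec list.
#' @export
cavitySpec <- function(shellRadius = 12, nShellAtoms = 60,
                       cavityRadius = 5,
                       lining = c(ILE = 1, LEU = 1, PHE = 1, SER = 1,
                                  ASP = 1, LYS = 1),
                       plantedLigand = NULL, plddt = 90, jitter = 0.6,
                       seed = 1L) {
  stopifnot(cavityRadius < shellRadius, nShellAtoms >= 20)
  list(shellRadius = shellRadius, nShellAtoms = nShellAtoms,
       cavityRadius = cavityRadius, lining = lining,
       plantedLigand = plantedLigand, plddt = plddt, jitter = jitter,
       seed = seed)
}

# deterministic Fibonacci lattice on the unit sphere
fibonacciSphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Generate an engineered cavity structure
#'
#' Places single-atom pseudo-residues on a jittered sphere shell, leaving
#' an empty interior cavity; residue identities are drawn from the lining
#' composition and each residue's atom element follows its polarity class
#' (hydrophobic residues carry C, polar O/N, Cys/Met S). An optional
#' ligand is planted at the cavity center. If jittered atoms collide
#' (closer than 1.5 Angstrom) the layout is regenerated with reduced
#' jitter, failing after 10 attempts.
#'
#' @param spec a \code{\link{cavitySpec}}.
#' @param path optional output PDB path.
#' @param modelKind "predicted" (default; pLDDT in B-factor) or
#'   "experimental".
#' @param sourceId structure id, default "cavity".
#' @return A \code{\linkS4class{StructureModel}}.
#' @export
makeCavityStructure <- function(spec, path = NULL,
                                modelKind = c("predicted", "experimental"),
                                sourceId = "cavity") {
  modelKind <- match.arg(modelKind)
  n <- spec$nShellAtoms
  base <- fibonacciSphere(n) * spec$shellRadius
  xyz <- NULL
  jit <- spec$jitter
  withSeed(spec$seed, {
    for (attempt in 1:10) {
      cand <- base + matrix(runif(3 * n, -jit, jit), ncol = 3)
      if (min(dist(cand)) >= 1.5) { xyz <- cand; break }
      jit <- jit * 0.7
    }
    if (is.null(xyz))
      stop("geometric infeasibility: atoms collide after 10 attempts")
    resNames <- sample(names(spec$lining), n, replace = TRUE,
                       prob = spec$lining)
    b <- rep_len(spec$plddt, n)
    atomsDf <- data.frame(
      serial = seq_len(n),
      name = c(C = "CA", N = "N", O = "O", S = "SG")[
        RESIDUE_ELEMENT[resNames]],
      element = unname(RESIDUE_ELEMENT[resNames]),
      resid = resNames, chain = "A", resno = seq_len(n),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], b = b,
      hetero = FALSE, stringsAsFactors = FALSE)
    if (!is.null(spec$plantedLigand)) {
      # small tetrahedral heavy-atom cluster + one oxygen at the center
      lig <- rbind(c(0, 0, 0),
                   rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1),
                         c(-1, -1, 1)) * 0.75)
      ligDf <- data.frame(
        serial = n + seq_len(nrow(lig)),
        name = c("O1", "C1", "C2", "C3", "C4"),
        element = c("O", "C", "C", "C", "C"),
        resid = toupper(spec$plantedLigand), chain = "A",
        resno = n + 1L,
        x = lig[, 1], y = lig[, 2], z = lig[, 3],
        b = mean(b), hetero = TRUE, stringsAsFactors = FALSE)
      atomsDf <- rbind(atomsDf, ligDf)
    }
  })
  m <- StructureModel(atomsDf, sourceId = sourceId, modelKind = modelKind)
  if (!is.null(path)) writeStructurePDB(m, path)
  m
}

#' Detection configuration matched to the cavity fixtures
#'
#' Shell fixtures carry their alpha spheres near the shell circumsphere
#' (every quadruple of shell atoms is nearly co-spherical with the shell),
#' so the radius window brackets the shell radius and the sphere minimum
#' is small.
#'
#' @param spec a \code{\link{cavitySpec}}.
#' @param seed RNG seed for the descriptor estimates.
#' @return A \code{\link{detectionConfig}}.
#' @export
cavityDetectionConfig <- function(spec, seed = 1L) {
  detectionConfig(rMin = spec$shellRadius - 3.5,
                  rMax = spec$shellRadius + 2.5,
                  linkageDist = 3, mergeDist = 6, minSpheres = 5,
                  mcSamples = 20000, surfPoints = 300, seed = seed)
}

#' Specification of a synthetic descriptor corpus
#'
#' Class-conditional multivariate normals (diagonal covariance) over the
#' 17 descriptors. LBP rows are shifted upward on hydrophobicity_score by
#' \code{separation} standard deviations and on mean_loc_hyd_dens by half
#' that, making hydrophobicity the dominant discriminating feature.
#' Default corpus: 200 LBP / 300 nLBP / 4000 PP (a 20:1 PP:LBP imbalance).
#'
#' @param nPerClass named counts per label.
#' @param separation standardized hydrophobicity shift of the LBP class,
#'   default 3.
#' @param seed RNG seed.
#' @return A table-spec list.
#' @export
tableSpec <- function(nPerClass = c(LBP = 200, nLBP = 300, PP = 4000),
                      separation = 3, seed = 1L) {
  stopifnot(all(nPerClass >= 0))
  list(nPerClass = nPerClass, separation = separation, seed = seed)
}

# per-descriptor generative baseline (mean, sd) shared by all classes
DESCRIPTOR_BASELINE <- data.frame(
  name = c("pock_vol", "nb_AS", "surf_vdw", "hydrophobicity_score",
           "mean_loc_hyd_dens", "apol_as_prop", "prop_polar_atm",
           "mean_as_solv_acc", "as_dens", "as_max_dst", "volume_score",
           "polarity_score", "charge_score", "flex", "n_apol_as"),
  mean = c(600, 50, 250, 5, 8, 0.5, 0.45, 0.45, 6, 15, 140, 8.5, 0, 1,
           25),
  sd = c(250, 18, 90, 18, 4, 0.15, 0.12, 0.15, 1.5, 4, 25, 1.6, 0.3,
         0.2, 12),
  stringsAsFactors = FALSE)

#' Generate a class-conditional synthetic descriptor table
#'
#' Draws descriptor rows per class from diagonal-covariance normals,
#' truncating to respect the descriptor invariants (fractions clipped to
#' [0, 1], volumes and counts positive, surf_pol + surf_apol = surf_vdw,
#' as_max_dst >= as_dens). LBP rows get the hydrophobicity shift of the
#' spec.
#'
#' @param spec a \code{\link{tableSpec}}.
#' @return A labeled \code{\linkS4class{DescriptorTable}}.
#' @export
makeDescriptorTable <- function(spec) {
  bl <- DESCRIPTOR_BASELINE
  mu <- setNames(bl$mean, bl$name)
  sdv <- setNames(bl$sd, bl$name)
  classes <- names(spec$nPerClass)
  withSeed(spec$seed, {
    parts <- lapply(classes, function(cls) {
      n <- spec$nPerClass[[cls]]
      if (n == 0) return(NULL)
      draw <- function(nm) rnorm(n, mu[nm], sdv[nm])
      shift <- if (cls == "LBP") spec$separation else 0
      hydro <- rnorm(n, mu["hydrophobicity_score"] +
                       shift * sdv["hydrophobicity_score"],
                     sdv["hydrophobicity_score"])
      mlhd <- pmax(0, rnorm(n, mu["mean_loc_hyd_dens"] +
                              0.5 * shift * sdv["mean_loc_hyd_dens"],
                            sdv["mean_loc_hyd_dens"]))
      surf <- pmax(10, draw("surf_vdw"))
      apolFrac <- pmin(1, pmax(0, rnorm(n, 0.55, 0.12)))
      asDens <- pmax(0.5, draw("as_dens"))
      asMax <- asDens * pmax(1, rnorm(n, 2.5, 0.4))
      nApol <- round(pmax(0, draw("n_apol_as")))
      df <- data.frame(
        structure_id = sprintf("syn_%s_%04d", cls, seq_len(n)),
        pocket_id = 1L,
        pock_vol = pmax(20, draw("pock_vol")),
        nb_AS = pmax(1, round(draw("nb_AS"))),
        surf_vdw = surf,
        surf_pol_vdw = surf * (1 - apolFrac),
        surf_apol_vdw = surf * apolFrac,
        hydrophobicity_score = hydro,
        mean_loc_hyd_dens = mlhd,
        apol_as_prop = pmin(1, pmax(0, draw("apol_as_prop"))),
        prop_polar_atm = pmin(1, pmax(0, draw("prop_polar_atm"))),
        mean_as_solv_acc = pmin(1, pmax(0, draw("mean_as_solv_acc"))),
        as_dens = asDens,
        as_max_dst = asMax,
        volume_score = pmax(60, draw("volume_score")),
        polarity_score = pmax(0, draw("polarity_score")),
        charge_score = draw("charge_score"),
        flex = pmax(0, draw("flex")),
        n_apol_as = nApol,
        label = cls,
        stringsAsFactors = FALSE)
      df$matched_ligand <- switch(cls,
        LBP = rep_len(lipidLigandCodes(), n),
        nLBP = rep_len(nonLipidLigandCodes(), n),
        HEME = "HEM",
        NA_character_)
      df
    })
    DescriptorTable(do.call(rbind, parts))
  })
}
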