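# Structure and ligand I/O.
#
# Parsing is delegated to bio3d (PDB and mmCIF); this layer resolves
# alternate locations by occupancy, drops hydrogens and waters, and
# normalizes the atom table to the package contract. All geometry in the
# package is heavy-atom only.

WATER_CODES <- c("HOH", "WAT", "DOD", "H2O")

#' Ligand chemical-component code sets used for corpus curation
#'
#' The lipid set (positive class), the non-lipid set and heme.
#'
#' @return Character vector of component codes.
#' @export
lipidLigandCodes <- function() c("CLR", "MYR", "PLM", "STE", "OLA")

#' @rdname lipidLigandCodes
#' @export
nonLipidLigandCodes <- function() c("ADN", "B12", "BGC", "COA")

#' @rdname lipidLigandCodes
#' @export
hemeLigandCodes <- function() "HEM"

#' Parse a protein structure file
#'
#' Reads a PDB or mmCIF file into a \code{\linkS4class{StructureModel}}.
#' Hydrogens are dropped, alternate locations are resolved to the highest
#' occupancy (ties by altloc letter), waters are excluded from the polymer,
#' and only the first model of multi-model files is kept.
#'
#' @param path file path.
#' @param format "auto" (by extension), "pdb" or "cif".
#' @param modelKind "experimental" or "predicted" (predicted models carry
#'   pLDDT in the B-factor column).
#' @param sourceId structure id; default is the file base name.
#' @return A \code{StructureModel}.
#' @export
parseStructure <- function(path, format = c("auto", "pdb", "cif"),
                           modelKind = c("experimental", "predicted"),
                           sourceId = NULL) {
  format <- match.arg(format)
  modelKind <- match.arg(modelKind)
  if (!file.exists(path)) stop("structure file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  parsed <- tryCatch(
    if (format == "cif") suppressWarnings(bio3d::read.cif(path,
                                                          verbose = FALSE))
    else suppressWarnings(bio3d::read.pdb(path, multi = FALSE,
                                          rm.alt = FALSE, verbose = FALSE)),
    error = function(e) stop("failed to parse ", format, " file '", path,
                             "': ", conditionMessage(e), call. = FALSE))
  a <- parsed$atom
  if (is.null(a) || nrow(a) == 0)
    stop("empty structure: no ATOM/HETATM records in ", path)
  atoms <- normalizeAtomTable(a)
  if (nrow(atoms) == 0)
    stop("empty structure after hydrogen/water filtering: ", path)
  StructureModel(atoms, sourceId = sourceId %||%
                   sub("\\.(pdb|cif|mmcif|ent)$", "", basename(path),
                       ignore.case = TRUE),
                 modelKind = modelKind)
}

# bio3d atom table -> package atom contract.
normalizeAtomTable <- function(a) {
  ele <- a$elesy
  ele[is.na(ele) | !nzchar(ele)] <- guessElement(a$elety[is.na(ele) | !nzchar(ele)])
  ele <- toupper(trimws(ele))
  keep <- !(ele %in% c("H", "D"))
  a <- a[keep, , drop = FALSE]; ele <- ele[keep]
  # altloc: highest occupancy per (chain, resno, insert, resid, name),
  # ties by altloc letter order
  alt <- a$alt; alt[is.na(alt)] <- ""
  occ <- a$o; occ[is.na(occ)] <- 1
  key <- paste(a$chain, a$resno, ifelse(is.na(a$insert), "", a$insert),
               a$resid, a$elety, sep = "|")
  ord <- order(key, -occ, alt)
  a <- a[ord, , drop = FALSE]; ele <- ele[ord]; key <- key[ord]
  first <- !duplicated(key)
  a <- a[first, , drop = FALSE]; ele <- ele[first]
  # restore file order
  ord2 <- order(a$eleno)
  a <- a[ord2, , drop = FALSE]; ele <- ele[ord2]
  hetero <- a$type == "HETATM" | a$resid %in% WATER_CODES
  b <- a$b; b[is.na(b)] <- 0
  out <- data.frame(
    serial = as.integer(a$eleno),
    name = as.character(a$elety),
    element = ele,
    resid = as.character(a$resid),
    chain = as.character(ifelse(is.na(a$chain), "A", a$chain)),
    resno = as.integer(a$resno),
    x = a$x, y = a$y, z = a$z,
    b = b,
    hetero = hetero,
    stringsAsFactors = FALSE)
  # waters never enter the polymer nor the ligand pool
  out[!(out$resid %in% WATER_CODES), , drop = FALSE]
}

guessElement <- function(name) {
  name <- gsub("[0-9']", "", toupper(trimws(name)))
  two <- substr(name, 1, 2)
  one <- substr(name, 1, 1)
  ifelse(two %in% c("FE", "ZN", "MG", "MN", "CU", "NA", "CL", "BR", "SE"),
         two, one)
}

#' Write a structure as PDB
#'
#' @param structure a \code{StructureModel}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeStructurePDB <- function(structure, path) {
  a <- atoms(structure)
  rec <- sprintf(
    "%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    ifelse(a$hetero, "HETATM", "ATOM"),
    a$serial %% 100000L,
    formatAtomName(a$name, a$element),
    substr(a$resid, 1, 3), substr(a$chain, 1, 1), a$resno %% 10000L,
    a$x, a$y, a$z, 1, a$b, a$element)
  writeLines(c(rec, "END"), path)
  invisible(path)
}

formatAtomName <- function(name, element) {
  # PDB columns 13-16: element right-justified in 13-14 for 1-char elements
  ifelse(nchar(element) == 1 & nchar(name) < 4,
         sprintf(" %-3s", name), sprintf("%-4s", name))
}

#' Extract standalone (non-covalent) ligands
#'
#' Returns every hetero residue whose component code is in \code{compIds}
#' and which forms no covalent link to the polymer: its minimum heavy-atom
#' distance to any polymer atom must exceed \code{covalentCutoff}.
#'
#' @param structure a \code{StructureModel}.
#' @param compIds chemical component codes to extract (non-empty).
#' @param covalentCutoff Angstrom; an inter-residue contact at or below this
#'   distance marks the ligand as covalently attached. Default 1.9.
#' @param massWeighted use atomic-mass weighting for the center of mass
#'   instead of the unweighted heavy-atom centroid.
#' @return List of \code{\linkS4class{LigandInstance}} (possibly empty).
#' @export
extractStandaloneLigands <- function(structure, compIds,
                                     covalentCutoff = 1.9,
                                     massWeighted = FALSE) {
  stopifnot(length(compIds) >= 1)
  a <- structure@atoms
  het <- a[a$hetero & a$resid %in% toupper(compIds), , drop = FALSE]
  if (!nrow(het)) return(list())
  poly <- a[!a$hetero, c("x", "y", "z"), drop = FALSE]
  out <- list()
  for (key in unique(residueKey(het$chain, het$resno))) {
    la <- het[residueKey(het$chain, het$resno) == key, , drop = FALSE]
    if (nrow(poly)) {
      dmin <- min(crossDist(la[, c("x", "y", "z")], poly))
      if (dmin <= covalentCutoff) next
    }
    xyz <- as.matrix(la[, c("x", "y", "z")])
    w <- if (massWeighted) atomicMass(la$element) else rep(1, nrow(la))
    ctr <- as.numeric(colSums(xyz * w) / sum(w))
    out[[length(out) + 1L]] <- new("LigandInstance",
                                   compId = la$resid[1], atoms = la,
                                   center = ctr)
  }
  out
}

atomicMass <- function(element) {
  m <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
         FE = 55.845, ZN = 65.38, MG = 24.305, SE = 78.971, CL = 35.45,
         BR = 79.904, F = 18.998, I = 126.904, CO = 58.933)
  out <- m[toupper(element)]
  out[is.na(out)] <- 12.011
  unname(out)
}

#' Is a ligand buried in the protein?
#'
#' A ligand is buried when at least \code{minResidues} distinct polymer
#' residues have an atom within \code{radius} of the ligand center of mass.
#' Used at curation time to drop surface-bound lipids.
#'
#' @param structure a \code{StructureModel}.
#' @param ligand a \code{\linkS4class{LigandInstance}}.
#' @param radius Angstrom, default 8.
#' @param minResidues count, default 10.
#' @return Logical flag.
#' @export
isBuriedLigand <- function(structure, ligand, radius = 8, minResidues = 10) {
  a <- atoms(structure, polymerOnly = TRUE)
  if (!nrow(a)) return(FALSE)
  d <- crossDist(matrix(centerOfMass(ligand), nrow = 1),
                 a[, c("x", "y", "z")])
  near <- as.vector(d) <= radius
  length(unique(residueKey(a$chain[near], a$resno[near]))) >= minResidues
}

#' Trim N-terminal residues (signal peptide removal)
#'
#' Removes the first \code{cutSite} polymer residues (in chain order) and
#' their atoms; \code{cutSite = 0} returns the structure unchanged.
#'
#' @param structure a \code{StructureModel}.
#' @param cutSite index of the last residue to remove (0-based count).
#' @return A trimmed \code{StructureModel}.
#' @export
trimNTerminal <- function(structure, cutSite) {
  res <- polymerResidues(structure)
  if (cutSite < 0 || cutSite >= nrow(res))
    stop("invalid cut site ", cutSite, ": structure has ", nrow(res),
         " residues")
  if (cutSite == 0) return(structure)
  drop <- residueKey(res$chain[seq_len(cutSite)], res$resno[seq_len(cutSite)])
  a <- structure@atoms
  keep <- a$hetero | !(residueKey(a$chain, a$resno) %in% drop)
  StructureModel(a[keep, , drop = FALSE], sourceId = structure@sourceId,
                 modelKind = structure@modelKind)
}

#' Mean per-residue pLDDT of a predicted model
#'
#' The per-residue confidence is read from the B-factor of the residue's
#' CA atom (first atom as fallback); predicted models write identical
#' pLDDT to every atom of a residue, so the representative choice is safe.
#'
#' @param structure a predicted \code{StructureModel}.
#' @return Mean pLDDT (0-100).
#' @export
meanPlddt <- function(structure) {
  if (modelKind(structure) != "predicted")
    stop("meanPlddt is defined for predicted models only")
  a <- atoms(structure, polymerOnly = TRUE)
  if (!nrow(a)) stop("no polymer residues")
  key <- residueKey(a$chain, a$resno)
  per <- vapply(split(seq_len(nrow(a)), key)[unique(key)], function(idx) {
    ca <- idx[a$name[idx] == "CA"]
    a$b[if (length(ca)) ca[1] else idx[1]]
  }, numeric(1))
  mean(per)
}

#' Read a signal-peptide annotation table
#'
#' TSV with header \code{protein_id<TAB>cut_site}; cut sites are the index
#' of the last signal residue.
#'
#' @param path file path.
#' @return Named integer vector of cut sites.
#' @export
readSignalPeptides <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  if (!all(c("protein_id", "cut_site") %in% names(tab)))
    stop("signal-peptide table must have columns protein_id and cut_site")
  setNames(as.integer(tab$cut_site), tab$protein_id)
}
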