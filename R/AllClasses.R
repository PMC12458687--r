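# Central S4 containers.
#
# Atom tables are plain data.frames with a fixed column contract
# (serial, name, element, resid, chain, resno, x, y, z, b, hetero);
# the classes wrap them with validity checks and accessors.

ATOM_COLS <- c("serial", "name", "element", "resid", "chain", "resno",
               "x", "y", "z", "b", "hetero")

#' StructureModel: parsed protein structure
#'
#' Holds the heavy atoms of one structure model. The B-factor column doubles
#' as per-residue pLDDT (0-100) for predicted models.
#'
#' @slot atoms data.frame with columns serial, name, element, resid, chain,
#'   resno, x, y, z, b, hetero.
#' @slot sourceId character scalar identifying the structure.
#' @slot modelKind "experimental" or "predicted".
#' @export
setClass("StructureModel",
  representation(atoms = "data.frame", sourceId = "character",
                 modelKind = "character"))

setValidity("StructureModel", function(object) {
  a <- object@atoms
  msg <- character()
  if (!all(ATOM_COLS %in% names(a)))
    msg <- c(msg, paste("atoms must have columns:",
                        paste(setdiff(ATOM_COLS, names(a)), collapse = ", ")))
  else {
    if (nrow(a) > 0) {
      if (!all(is.finite(as.matrix(a[, c("x", "y", "z")]))))
        msg <- c(msg, "atom coordinates must be finite")
      if (any(is.na(a$element) | !nzchar(a$element)))
        msg <- c(msg, "atom element symbols must be non-empty")
      if (any(!is.finite(a$b)) || any(a$b < 0))
        msg <- c(msg, "B-factor / pLDDT values must be finite and >= 0")
    }
  }
  if (length(object@modelKind) != 1L ||
      !object@modelKind %in% c("experimental", "predicted"))
    msg <- c(msg, "modelKind must be 'experimental' or 'predicted'")
  if (length(msg)) msg else TRUE
})

#' Construct a StructureModel from an atom table
#'
#' @param atoms atom data.frame (see \code{\linkS4class{StructureModel}}).
#' @param sourceId structure identifier.
#' @param modelKind "experimental" or "predicted".
#' @return A \code{StructureModel}.
#' @export
StructureModel <- function(atoms, sourceId = "structure",
                           modelKind = c("experimental", "predicted")) {
  modelKind <- match.arg(modelKind)
  rownames(atoms) <- NULL
  new("StructureModel", atoms = atoms, sourceId = sourceId,
      modelKind = modelKind)
}

#' LigandInstance: one standalone hetero ligand
#'
#' @slot compId chemical component code (uppercase).
#' @slot atoms heavy-atom table for the ligand.
#' @slot center unweighted (or mass-weighted) heavy-atom centroid, Angstrom.
#' @export
setClass("LigandInstance",
  representation(compId = "character", atoms = "data.frame",
                 center = "numeric"))

setValidity("LigandInstance", function(object) {
  msg <- character()
  if (nrow(object@atoms) < 1) msg <- c(msg, "ligand needs >= 1 heavy atom")
  if (object@compId != toupper(object@compId))
    msg <- c(msg, "compId must be uppercase")
  if (length(object@center) != 3) msg <- c(msg, "center must be length 3")
  if (length(msg)) msg else TRUE
})

#' AlphaSphereSet: candidate cavity probes of one structure
#'
#' Each alpha sphere is the circumsphere of four heavy atoms that contains
#' no other heavy atom; the radius window keeps spheres that fit clefts and
#' cavities rather than bulk solvent or buried voids.
#'
#' @slot spheres data.frame with columns x, y, z (center), radius,
#'   a1..a4 (row indices of the defining atoms in the structure's atom
#'   table) and apolar (logical).
#' @slot structureId id of the source structure.
#' @slot radiusWindow numeric(2), the [r_min, r_max] used.
#' @export
setClass("AlphaSphereSet",
  representation(spheres = "data.frame", structureId = "character",
                 radiusWindow = "numeric"))

setValidity("AlphaSphereSet", function(object) {
  s <- object@spheres
  need <- c("x", "y", "z", "radius", "a1", "a2", "a3", "a4", "apolar")
  if (!all(need %in% names(s)))
    return(paste("spheres must have columns:", paste(need, collapse = ", ")))
  if (nrow(s) && any(s$radius < object@radiusWindow[1] - 1e-9 |
                     s$radius > object@radiusWindow[2] + 1e-9))
    return("sphere radii outside the configured window")
  TRUE
})

#' PocketSet: clustered alpha spheres of one structure
#'
#' @slot spheres sphere table as in \code{\linkS4class{AlphaSphereSet}} plus
#'   a pocket_id column (NA for spheres dropped by the min-sphere filter).
#' @slot summary data.frame: pocket_id, n_spheres, cx, cy, cz (centroid).
#' @slot contactAtomList per-pocket integer vectors of atom row indices.
#' @slot contactResidueList per-pocket character vectors of "chain:resno"
#'   residue keys.
#' @slot structureId id of the source structure.
#' @export
setClass("PocketSet",
  representation(spheres = "data.frame", summary = "data.frame",
                 contactAtomList = "list", contactResidueList = "list",
                 structureId = "character"))

setValidity("PocketSet", function(object) {
  s <- object@summary
  msg <- character()
  if (nrow(s)) {
    if (!identical(s$pocket_id, seq_len(nrow(s))))
      msg <- c(msg, "pocket_id must be the rank 1..n")
    if (any(s$n_spheres < 1)) msg <- c(msg, "pockets must be non-empty")
    if (length(object@contactAtomList) != nrow(s) ||
        length(object@contactResidueList) != nrow(s))
      msg <- c(msg, "contact lists must have one entry per pocket")
  }
  if (length(msg)) msg else TRUE
})

#' DescriptorTable: labeled pocket descriptor rows
#'
#' On-disk form is a TSV whose header is structure_id, pocket_id, the
#' descriptor names (see \code{\link{descriptorNames}}), label and
#' matched_ligand.
#'
#' @slot rows data.frame; one row per (structure_id, pocket_id).
#' @export
setClass("DescriptorTable", representation(rows = "data.frame"))

setValidity("DescriptorTable", function(object) {
  r <- object@rows
  msg <- character()
  if (!all(c("structure_id", "pocket_id") %in% names(r)))
    return("rows must have structure_id and pocket_id columns")
  if (nrow(r)) {
    key <- paste(r$structure_id, r$pocket_id)
    if (anyDuplicated(key))
      msg <- c(msg, "duplicate (structure_id, pocket_id) pairs")
    if ("label" %in% names(r) && "matched_ligand" %in% names(r)) {
      lab <- r$label
      ml <- r$matched_ligand
      bad <- !is.na(lab) &
        ((lab == "PP" & !is.na(ml)) | (lab != "PP" & is.na(ml)))
      if (any(bad))
        msg <- c(msg, "label is PP iff matched_ligand is absent")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a DescriptorTable
#'
#' @param rows data.frame with structure_id, pocket_id, descriptor columns
#'   and optionally label / matched_ligand.
#' @return A \code{DescriptorTable}.
#' @export
DescriptorTable <- function(rows) {
  rownames(rows) <- NULL
  new("DescriptorTable", rows = rows)
}

#' PocketClassifier: a trained pocket-level model
#'
#' Binary task: lipid-binding pocket (LBP) versus everything else.
#'
#' @slot fit the fitted engine object (e.g. a ranger forest).
#' @slot algorithm one of svm, logistic, knn, naive_bayes, decision_tree,
#'   random_forest.
#' @slot hyperparameters named list as supplied at training.
#' @slot featureOrder descriptor names, in training order.
#' @slot threshold decision threshold on the positive-class probability
#'   (inclusive: score >= threshold is called positive).
#' @slot manifest training provenance: seed, class counts, engine versions.
#' @slot scaling optional centering/scaling used by distance-based engines.
#' @export
setClass("PocketClassifier",
  representation(fit = "ANY", algorithm = "character",
                 hyperparameters = "list", featureOrder = "character",
                 threshold = "numeric", manifest = "list", scaling = "list"))

setValidity("PocketClassifier", function(object) {
  msg <- character()
  if (!(object@threshold > 0 && object@threshold < 1))
    msg <- c(msg, "threshold must be in (0, 1)")
  if (!length(object@featureOrder))
    msg <- c(msg, "featureOrder must be non-empty")
  if (length(msg)) msg else TRUE
})
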