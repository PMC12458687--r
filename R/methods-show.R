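# Accessors and show methods.

#' @describeIn StructureModel atom table accessor
#' @param x,object a \code{StructureModel}.
#' @param polymerOnly drop hetero atoms.
#' @param ... unused.
#' @export
setMethod("atoms", "StructureModel", function(x, polymerOnly = FALSE, ...) {
  a <- x@atoms
  if (polymerOnly) a <- a[!a$hetero, , drop = FALSE]
  a
})

#' @describeIn StructureModel number of heavy atoms
#' @export
setMethod("nAtoms", "StructureModel", function(x) nrow(x@atoms))

#' @describeIn StructureModel ordered polymer residue table
#'   (chain, resno, resid), chain order then residue number
#' @export
setMethod("polymerResidues", "StructureModel", function(x) {
  a <- x@atoms[!x@atoms$hetero, , drop = FALSE]
  if (!nrow(a))
    return(data.frame(chain = character(), resno = integer(),
                      resid = character()))
  key <- residueKey(a$chain, a$resno)
  first <- !duplicated(key)
  r <- data.frame(chain = a$chain[first], resno = a$resno[first],
                  resid = a$resid[first], stringsAsFactors = FALSE)
  r[order(r$chain, r$resno), , drop = FALSE]
})

#' @describeIn StructureModel number of polymer residues
#' @export
setMethod("nResidues", "StructureModel",
          function(x) nrow(polymerResidues(x)))

#' @describeIn StructureModel structure identifier
#' @export
setMethod("sourceId", "StructureModel", function(x) x@sourceId)

#' @describeIn StructureModel "experimental" or "predicted"
#' @export
setMethod("modelKind", "StructureModel", function(x) x@modelKind)

setMethod("show", "StructureModel", function(object) {
  cat(sprintf("StructureModel '%s' (%s)\n", object@sourceId,
              object@modelKind))
  cat(sprintf("  %d heavy atoms, %d polymer residues, %d hetero atoms\n",
              nAtoms(object), nResidues(object), sum(object@atoms$hetero)))
})

#' @describeIn LigandInstance chemical component code
#' @param x,object a \code{LigandInstance}.
#' @export
setMethod("compId", "LigandInstance", function(x) x@compId)

#' @describeIn LigandInstance heavy-atom centroid
#' @export
setMethod("centerOfMass", "LigandInstance", function(x) x@center)

#' @describeIn LigandInstance ligand atom table
#' @param ... unused.
#' @export
setMethod("atoms", "LigandInstance", function(x, ...) x@atoms)

setMethod("show", "LigandInstance", function(object) {
  cat(sprintf("LigandInstance %s: %d heavy atoms, center (%.2f, %.2f, %.2f)\n",
              object@compId, nrow(object@atoms), object@center[1],
              object@center[2], object@center[3]))
})

#' @describeIn AlphaSphereSet sphere table accessor
#' @param x,object an \code{AlphaSphereSet}.
#' @export
setMethod("spheres", "AlphaSphereSet", function(x) x@spheres)

setMethod("length", "AlphaSphereSet", function(x) nrow(x@spheres))

setMethod("show", "AlphaSphereSet", function(object) {
  cat(sprintf("AlphaSphereSet of '%s': %d spheres, radius window [%.2f, %.2f]\n",
              object@structureId, nrow(object@spheres),
              object@radiusWindow[1], object@radiusWindow[2]))
  if (nrow(object@spheres))
    cat(sprintf("  %d apolar (%.1f%%)\n", sum(object@spheres$apolar),
                100 * mean(object@spheres$apolar)))
})

#' @describeIn PocketSet sphere table (with pocket_id assignment)
#' @param x,object a \code{PocketSet}.
#' @export
setMethod("spheres", "PocketSet", function(x) x@spheres)

#' @describeIn PocketSet number of retained pockets
#' @export
setMethod("nPockets", "PocketSet", function(x) nrow(x@summary))

#' @describeIn PocketSet pocket ids (rank order)
#' @export
setMethod("pocketIds", "PocketSet", function(x) x@summary$pocket_id)

#' @describeIn PocketSet atom row indices contacted by one pocket
#' @param pocket pocket id.
#' @export
setMethod("contactAtoms", "PocketSet", function(x, pocket) {
  x@contactAtomList[[pocket]]
})

#' @describeIn PocketSet residue keys ("chain:resno") contacted by one pocket
#' @export
setMethod("contactResidues", "PocketSet", function(x, pocket) {
  x@contactResidueList[[pocket]]
})

setMethod("show", "PocketSet", function(object) {
  cat(sprintf("PocketSet of '%s': %d pockets from %d spheres\n",
              object@structureId, nrow(object@summary),
              sum(!is.na(object@spheres$pocket_id))))
  if (nrow(object@summary))
    print(head(object@summary, 5))
})

#' @describeIn DescriptorTable row accessor
#' @param x,object a \code{DescriptorTable}.
#' @export
setMethod("descriptorRows", "DescriptorTable", function(x) x@rows)

#' @describeIn DescriptorTable per-label row counts (named integer vector)
#' @export
setMethod("classCounts", "DescriptorTable", function(x) {
  if (!"label" %in% names(x@rows) || !nrow(x@rows))
    return(integer())
  tab <- table(x@rows$label)
  setNames(as.integer(tab), names(tab))
})

setMethod("nrow", "DescriptorTable", function(x) nrow(x@rows))

setMethod("show", "DescriptorTable", function(object) {
  cc <- classCounts(object)
  cat(sprintf("DescriptorTable: %d pockets\n", nrow(object@rows)))
  if (length(cc))
    cat("  ", paste(sprintf("%s=%d", names(cc), cc), collapse = ", "), "\n")
})

#' @describeIn PocketClassifier descriptor names in training order
#' @param x,object a \code{PocketClassifier}.
#' @export
setMethod("featureOrder", "PocketClassifier", function(x) x@featureOrder)

#' @describeIn PocketClassifier decision threshold (inclusive)
#' @export
setMethod("scoreThreshold", "PocketClassifier", function(x) x@threshold)

setMethod("show", "PocketClassifier", function(object) {
  cat(sprintf("PocketClassifier (%s), %d features, threshold %.2f\n",
              object@algorithm, length(object@featureOrder),
              object@threshold))
  m <- object@manifest
  if (length(m$class_counts))
    cat("  trained on:",
        paste(sprintf("%s=%d", names(m$class_counts),
                      unlist(m$class_counts)), collapse = ", "), "\n")
})
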