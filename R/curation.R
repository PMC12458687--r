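# Corpus curation: pocket labeling, assembly, balancing, splitting.

POCKET_LABELS <- c("LBP", "nLBP", "PP", "HEME")

ligandClassOf <- function(compId) {
  ifelse(compId %in% lipidLigandCodes(), "LBP",
         ifelse(compId %in% nonLipidLigandCodes(), "nLBP",
                ifelse(compId %in% hemeLigandCodes(), "HEME",
                       NA_character_)))
}

#' Label pockets against bound ligands
#'
#' A pocket matches a ligand iff at least one alpha-sphere center lies
#' within \code{contactCutoff} of any ligand heavy atom. Matched pockets
#' take the ligand-class label (LBP for the lipid codes, nLBP for the
#' non-lipid codes, HEME for HEM); unmatched pockets are pseudo-pockets
#' (PP). A pocket matching several ligands takes the nearest (ties broken
#' by component code, lexicographically).
#'
#' @param pocketSet a \code{\linkS4class{PocketSet}}.
#' @param ligands list of \code{\linkS4class{LigandInstance}} from the
#'   same structure.
#' @param contactCutoff Angstrom, default 3.0.
#' @return data.frame: pocket_id, label, matched_ligand (NA for PP),
#'   min_dist.
#' @export
labelPockets <- function(pocketSet, ligands, contactCutoff = 3) {
  s <- spheres(pocketSet)
  ids <- pocketIds(pocketSet)
  out <- data.frame(pocket_id = ids, label = "PP",
                    matched_ligand = NA_character_,
                    min_dist = NA_real_, stringsAsFactors = FALSE)
  if (!length(ligands)) return(out)
  ligDist <- function(idx, lig) {
    min(crossDist(s[idx, c("x", "y", "z")],
                  atoms(lig)[, c("x", "y", "z")]))
  }
  for (i in seq_along(ids)) {
    idx <- which(s$pocket_id == ids[i])
    d <- vapply(ligands, function(l) ligDist(idx, l), numeric(1))
    comp <- vapply(ligands, compId, "")
    hit <- d <= contactCutoff
    if (!any(hit)) next
    ord <- order(d, comp)
    best <- ord[hit[ord]][1]
    out$label[i] <- ligandClassOf(comp[best])
    out$matched_ligand[i] <- comp[best]
    out$min_dist[i] <- d[best]
  }
  out
}

#' Label a descriptor table in place
#'
#' Joins \code{\link{labelPockets}} output onto the descriptor rows of the
#' same structure.
#'
#' @param table unlabeled \code{\linkS4class{DescriptorTable}} of one
#'   structure.
#' @param pocketSet,ligands,contactCutoff as in \code{\link{labelPockets}}.
#' @return Labeled \code{\linkS4class{DescriptorTable}}.
#' @export
labelDescriptorTable <- function(table, pocketSet, ligands,
                                 contactCutoff = 3) {
  lab <- labelPockets(pocketSet, ligands, contactCutoff)
  r <- descriptorRows(table)
  m <- match(r$pocket_id, lab$pocket_id)
  r$label <- lab$label[m]
  r$matched_ligand <- lab$matched_ligand[m]
  DescriptorTable(r)
}

#' Assemble a descriptor corpus from per-structure tables
#'
#' Concatenates labeled tables, drops duplicate (structure_id, pocket_id)
#' rows, and recomputes class counts. Duplicates carrying conflicting
#' labels raise a consistency error.
#'
#' @param tables list of \code{\linkS4class{DescriptorTable}}.
#' @return Combined \code{\linkS4class{DescriptorTable}}.
#' @export
assembleDataset <- function(tables) {
  rows <- do.call(rbind, lapply(tables, descriptorRows))
  if (is.null(rows) || !nrow(rows))
    return(DescriptorTable(data.frame(structure_id = character(),
                                      pocket_id = integer())))
  key <- paste(rows$structure_id, rows$pocket_id)
  if ("label" %in% names(rows)) {
    conflict <- vapply(split(rows$label, key),
                       function(l) length(unique(l)) > 1, TRUE)
    if (any(conflict))
      stop("conflicting labels for pocket(s): ",
           paste(names(conflict)[conflict], collapse = ", "))
  }
  DescriptorTable(rows[!duplicated(key), , drop = FALSE])
}

#' Curation report
#'
#' Class counts, total size, and per-ligand structure tallies; warns when
#' a ligand class is backed by fewer than \code{minStructures} distinct
#' structures.
#'
#' @param table a labeled \code{\linkS4class{DescriptorTable}}.
#' @param minStructures warning threshold, default 20.
#' @return List: class_counts, total, ligand_structures.
#' @export
curationReport <- function(table, minStructures = 20) {
  r <- descriptorRows(table)
  cc <- classCounts(table)
  ligTab <- if ("matched_ligand" %in% names(r)) {
    lr <- r[!is.na(r$matched_ligand), , drop = FALSE]
    tapply(lr$structure_id, lr$matched_ligand,
           function(s) length(unique(s)))
  } else NULL
  if (!is.null(ligTab)) {
    low <- names(ligTab)[ligTab < minStructures]
    if (length(low))
      warning("ligand(s) backed by fewer than ", minStructures,
              " structures: ", paste(low, collapse = ", "))
  }
  list(class_counts = cc, total = nrow(r),
       ligand_structures = ligTab)
}

#' Downsample pseudo-pockets
#'
#' Downsamples the PP rows without replacement to
#' \code{round(ratio * nLBP)} (capped at the available PPs); LBP and nLBP
#' rows are untouched. \code{ratio = "full"} is the identity.
#'
#' @param table a labeled \code{\linkS4class{DescriptorTable}} with >= 1
#'   LBP row.
#' @param ratio positive real (PP per LBP) or "full".
#' @param seed RNG seed; the subsample is bit-reproducible.
#' @return A \code{\linkS4class{DescriptorTable}}.
#' @export
subsamplePseudo <- function(table, ratio, seed = 1L) {
  if (identical(ratio, "full")) return(table)
  if (!is.numeric(ratio) || ratio <= 0)
    stop("invalid ratio: must be a positive number or \"full\"")
  r <- descriptorRows(table)
  nLbp <- sum(r$label == "LBP")
  if (nLbp < 1) stop("table contains no LBP rows")
  ppIdx <- which(r$label == "PP")
  target <- min(length(ppIdx), round(ratio * nLbp))
  keepPP <- withSeed(seed, sort(sample(ppIdx, target)))
  keep <- sort(c(which(r$label != "PP"), keepPP))
  DescriptorTable(r[keep, , drop = FALSE])
}

#' Stratified train/test split
#'
#' Splits each class at \code{testFraction} (rounded per class); the two
#' parts are disjoint and reassemble to the input.
#'
#' @param table a labeled \code{\linkS4class{DescriptorTable}}.
#' @param testFraction fraction in [0, 1).
#' @param seed RNG seed.
#' @return List with elements train and test
#'   (\code{\linkS4class{DescriptorTable}}).
#' @export
stratifiedSplit <- function(table, testFraction, seed = 1L) {
  stopifnot(testFraction >= 0, testFraction < 1)
  r <- descriptorRows(table)
  if (testFraction == 0)
    return(list(train = table,
                test = DescriptorTable(r[integer(), , drop = FALSE])))
  sizes <- base::table(r$label)  # `table` argument shadows base::table
  if (any(sizes < 2))
    stop("stratification error: class(es) with a single row: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  testIdx <- withSeed(seed, {
    unlist(lapply(split(seq_len(nrow(r)), r$label), function(idx) {
      nTest <- round(testFraction * length(idx))
      if (nTest == 0) integer() else sample(idx, nTest)
    }), use.names = FALSE)
  })
  testIdx <- sort(testIdx)
  list(train = DescriptorTable(r[-testIdx, , drop = FALSE]),
       test = DescriptorTable(r[testIdx, , drop = FALSE]))
}
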