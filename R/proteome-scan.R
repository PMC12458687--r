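# Proteome-wide screening of predicted structure models.

SCAN_STATUSES <- c("scored", "filtered_length", "filtered_plddt",
                   "no_pockets", "detection_error")

#' Filter predicted models before scanning
#'
#' Removes models with fewer than \code{minLen} residues, then models with
#' mean pLDDT below \code{minPlddt}; both bounds are strict "less than"
#' removals (a 100-residue, pLDDT-70.0 model is kept).
#'
#' @param models list of predicted \code{\linkS4class{StructureModel}}.
#' @param minLen minimum residue count, default 100.
#' @param minPlddt minimum mean pLDDT, default 70.
#' @return List: kept (models), report (data.frame protein_id,
#'   n_residues, mean_plddt, status), counts (removal tallies).
#' @export
filterProteome <- function(models, minLen = 100, minPlddt = 70) {
  report <- do.call(rbind, lapply(models, function(m) {
    nres <- nResidues(m)
    if (nres < minLen)
      return(data.frame(protein_id = sourceId(m), n_residues = nres,
                        mean_plddt = NA_real_,
                        status = "filtered_length",
                        stringsAsFactors = FALSE))
    pl <- meanPlddt(m)
    data.frame(protein_id = sourceId(m), n_residues = nres,
               mean_plddt = pl,
               status = if (pl < minPlddt) "filtered_plddt" else "scored",
               stringsAsFactors = FALSE)
  }))
  kept <- models[report$status == "scored"]
  counts <- c(input = length(models),
              filtered_length = sum(report$status == "filtered_length"),
              filtered_plddt = sum(report$status == "filtered_plddt"),
              kept = length(kept))
  list(kept = kept, report = report, counts = counts)
}

#' Score one protein
#'
#' Detects pockets, computes descriptors, scores every pocket with the
#' classifier; the protein score is the maximum pocket probability and the
#' best pocket is the one attaining it.
#'
#' @param structure a filtered, signal-trimmed predicted
#'   \code{\linkS4class{StructureModel}}.
#' @param model a \code{\linkS4class{PocketClassifier}}.
#' @param config a \code{\link{detectionConfig}}.
#' @param keepPockets also return the per-pocket descriptor table.
#' @return One-row data.frame: protein_id, n_residues, mean_plddt,
#'   n_pockets, best_pocket_id, score, status (plus attribute "pockets"
#'   when \code{keepPockets}).
#' @export
scoreProtein <- function(structure, model, config = detectionConfig(),
                         keepPockets = FALSE) {
  base <- data.frame(protein_id = sourceId(structure),
                     n_residues = nResidues(structure),
                     mean_plddt = if (modelKind(structure) == "predicted")
                       meanPlddt(structure) else NA_real_,
                     n_pockets = 0L, best_pocket_id = NA_integer_,
                     score = NA_real_, status = "scored",
                     stringsAsFactors = FALSE)
  res <- tryCatch({
    pockets <- detectPockets(structure, config)
    if (nPockets(pockets) == 0) {
      base$status <- "no_pockets"
      base
    } else {
      desc <- computeDescriptors(pockets, structure, config = config)
      p <- predictPocket(model, desc)
      best <- which.max(p)
      base$n_pockets <- nPockets(pockets)
      base$best_pocket_id <- descriptorRows(desc)$pocket_id[best]
      base$score <- p[best]
      if (keepPockets) {
        r <- descriptorRows(desc); r$score <- p
        attr(base, "pockets") <- r
      }
      base
    }
  }, error = function(e) {
    base$status <- "detection_error"
    attr(base, "error") <- conditionMessage(e)
    base
  })
  res
}

#' Rank scored proteins and report hits
#'
#' Scored proteins are sorted by score (descending); a protein is a hit
#' when its score is at or above the threshold (inclusive, "0.5 or
#' higher"). The hit percentage is n_hits / n_scored, rounded to one
#' decimal (round-half-even).
#'
#' @param predictions data.frame of \code{\link{scoreProtein}} rows.
#' @param threshold hit threshold, default 0.5.
#' @return List: ranked (data.frame with hit flag), summary (n_hits,
#'   n_scored, hit_pct).
#' @export
rankHits <- function(predictions, threshold = 0.5) {
  if (is.null(predictions) || !nrow(predictions))
    return(list(ranked = data.frame(),
                summary = list(n_hits = 0L, n_scored = 0L,
                               hit_pct = NA_real_)))
  scored <- predictions[predictions$status == "scored" &
                          !is.na(predictions$score), , drop = FALSE]
  scored <- scored[order(-scored$score, scored$protein_id), , drop = FALSE]
  scored$hit <- scored$score >= threshold
  rownames(scored) <- NULL
  list(ranked = scored,
       summary = list(n_hits = sum(scored$hit),
                      n_scored = nrow(scored),
                      hit_pct = hitRate(sum(scored$hit), nrow(scored))))
}

#' Hit percentage, one decimal
#'
#' 100 * nHits / nScored rounded to one decimal with round-half-even (the
#' reporting convention of the summary line).
#'
#' @param nHits,nScored counts.
#' @return Percentage rounded to one decimal.
#' @export
hitRate <- function(nHits, nScored) {
  if (nScored == 0) return(NA_real_)
  round(100 * nHits / nScored, 1)
}

#' Scan a proteome of predicted models
#'
#' The complete screening workflow: signal-peptide trimming (before the
#' length filter), length and pLDDT filters, per-protein pocket detection,
#' description and scoring, and hit ranking. Proteins are independent:
#' scanning any subset in any order gives identical per-protein rows.
#'
#' @param models list of predicted \code{\linkS4class{StructureModel}}, or
#'   a directory of PDB/mmCIF files.
#' @param model a \code{\linkS4class{PocketClassifier}}.
#' @param signalPeptides optional named cut-site vector (see
#'   \code{\link{readSignalPeptides}}); names are protein ids.
#' @param minLen,minPlddt filter thresholds (defaults 100 and 70).
#' @param threshold hit threshold (inclusive), default 0.5.
#' @param config a \code{\link{detectionConfig}}.
#' @param keepPockets keep per-pocket descriptor rows.
#' @return List: predictions (all rows incl. filtered), ranked, summary,
#'   filter_counts, and pockets when \code{keepPockets}.
#' @export
scanProteome <- function(models, model, signalPeptides = NULL,
                         minLen = 100, minPlddt = 70, threshold = 0.5,
                         config = detectionConfig(),
                         keepPockets = FALSE) {
  if (is.character(models) && length(models) == 1 && dir.exists(models)) {
    paths <- list.files(models, pattern = "\\.(pdb|cif|mmcif|ent)$",
                        full.names = TRUE)
    models <- lapply(paths, parseStructure, modelKind = "predicted")
  }
  # signal peptides first: trimming changes the residue count the length
  # filter sees
  if (!is.null(signalPeptides)) {
    models <- lapply(models, function(m) {
      cut <- signalPeptides[sourceId(m)]
      if (!is.na(cut) && cut > 0) trimNTerminal(m, cut) else m
    })
  }
  flt <- filterProteome(models, minLen = minLen, minPlddt = minPlddt)
  scoredRows <- lapply(flt$kept, scoreProtein, model = model,
                       config = config, keepPockets = keepPockets)
  pocketRows <- if (keepPockets)
    do.call(rbind, lapply(scoredRows, attr, "pockets")) else NULL
  filteredRows <- flt$report[flt$report$status != "scored",
                             c("protein_id", "n_residues", "mean_plddt",
                               "status"), drop = FALSE]
  nf <- nrow(filteredRows)
  filteredRows[c("n_pockets", "best_pocket_id", "score")] <-
    list(rep(NA_integer_, nf), rep(NA_integer_, nf), rep(NA_real_, nf))
  predictions <- rbind(
    filteredRows,
    do.call(rbind, lapply(scoredRows, function(r)
      r[, c("protein_id", "n_residues", "mean_plddt", "status",
            "n_pockets", "best_pocket_id", "score")])))
  rownames(predictions) <- NULL
  rk <- rankHits(predictions, threshold)
  out <- list(predictions = predictions, ranked = rk$ranked,
              summary = rk$summary, filter_counts = flt$counts)
  if (keepPockets) out$pockets <- pocketRows
  out
}

#' Write scan outputs
#'
#' Ranked TSV (protein_id, score, best_pocket_id, n_pockets, status) and
#' a summary JSON.
#'
#' @param scan result of \code{\link{scanProteome}}.
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
writeScanReport <- function(scan, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(scan$ranked[, c("protein_id", "score", "best_pocket_id",
                              "n_pockets", "status")],
              file.path(dir, "ranked.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(
    c(scan$summary, as.list(scan$filter_counts)),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(scan$pockets))
    write.table(scan$pockets, file.path(dir, "pockets.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  invisible(dir)
}
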