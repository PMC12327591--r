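# Structure cleaning: heteroatoms out, non-protein chains out, incomplete
# residues rejected, everything accounted for in a ValidationReport.

#' Validate and clean one raw PDB model
#'
#' Applies the cleaning rules used before any trajectory analysis:
#' \itemize{
#'   \item HETATM records (ligands, ions, waters) are removed and counted by
#'     category; waters are counted separately from ligands.
#'   \item Chains containing no standard amino-acid ATOM residue are removed
#'     whole and listed as non-protein chains.
#'   \item Alternate-location groups are collapsed to the conformer with the
#'     highest total occupancy (ties: first occurrence).
#'   \item A residue missing any heavy atom of its standard chemical
#'     composition (hydrogens are never required), or carrying a duplicate
#'     residue identifier or a nonstandard residue name (e.g. MSE), is
#'     rejected and listed with its reason.
#'   \item Format anomalies (non-monotonic serials, collapsed alt-locs,
#'     unparseable records reported by [parsePDB()]) are recorded.
#' }
#' Coordinates are never modified; retained residues are a subset of the
#' input, in file order.
#'
#' @param raw one element of the list returned by [parsePDB()] (or the whole
#'   list, in which case the first model is used and a note is added).
#' @param sourceLabel provenance string stored on the model.
#' @return a list with elements `model` ([StructureModel-class]) and
#'   `report` ([ValidationReport-class]).
#' @examples
#' pdb <- makeStructure(synthSpec(nResidues = 3))
#' tf <- tempfile(fileext = ".pdb")
#' writePDB(pdb, tf)
#' v <- validateStructure(parsePDB(tf))
#' report(v$report)
#' @export
validateStructure <- function(raw, sourceLabel = "pdb") {
  anomalies <- character(0)
  if (inherits(raw, "rawPDBModels")) {
    if (length(raw) > 1L)
      anomalies <- c(anomalies, sprintf(
        "multi-model input (%d models): first model used as the structure",
        length(raw)))
    raw <- raw[[1L]]
  }
  anomalies <- c(attr(raw, "anomalies"), anomalies)
  if (!nrow(raw)) stopSM("no valid protein residues")
  m <- raw
  m$name <- trimws(m$name)
  m$element <- inferElement(m$name, m$element)

  het <- m[m$recordType == "HETATM", , drop = FALSE]
  atm <- m[m$recordType == "ATOM", , drop = FALSE]

  # --- heteroatom groups, counted by category ------------------------------
  hetCounts <- c(ligand = 0L, ion = 0L, water = 0L)
  if (nrow(het)) {
    key <- paste(het$chainId, het$seqNum, het$insCode, het$resName, sep = "|")
    groups <- split(seq_len(nrow(het)), factor(key, levels = unique(key)))
    for (g in groups) {
      rn <- het$resName[g[1L]]
      heavy <- sum(!isHydrogen(het$element[g]))
      cat. <- if (rn %in% .WATER_NAMES) "water"
              else if (rn %in% .ION_NAMES || heavy == 1L) "ion"
              else "ligand"
      hetCounts[cat.] <- hetCounts[cat.] + 1L
    }
  }

  # --- chain classification ------------------------------------------------
  proteinChains <- unique(atm$chainId[isStandardAA(atm$resName)])
  allChains <- unique(c(atm$chainId, het$chainId))
  removedChains <- setdiff(allChains, proteinChains)
  removedChainResidues <- .emptyResidueList()
  if (nrow(atm)) {
    inRemoved <- !(atm$chainId %in% proteinChains)
    if (any(inRemoved)) {
      rc <- atm[inRemoved, , drop = FALSE]
      key <- paste(rc$chainId, rc$seqNum, rc$insCode, rc$resName, sep = "|")
      first <- rc[!duplicated(key), c("chainId", "seqNum", "insCode", "resName")]
      rownames(first) <- NULL
      removedChainResidues <- first
      atm <- atm[!inRemoved, , drop = FALSE]
    }
  }

  if (nrow(atm) && is.unsorted(atm$serial))
    anomalies <- c(anomalies, "non-monotonic atom serial numbers")

  # --- per-residue screening in file order ---------------------------------
  rejected <- .emptyRejectedList()
  keptAtoms <- list()
  keptResidues <- list()
  seenIds <- character(0)
  if (nrow(atm)) {
    key <- paste(atm$chainId, atm$seqNum, atm$insCode, atm$resName, sep = "|")
    groups <- split(seq_len(nrow(atm)), factor(key, levels = unique(key)))
    for (g in groups) {
      r <- atm[g, , drop = FALSE]
      id <- c(r$chainId[1L], r$seqNum[1L], r$insCode[1L], r$resName[1L])
      idKey <- paste(id[1L], id[2L], id[3L], sep = "|")
      reject <- function(reason) {
        rejected[[length(rejected) + 1L]] <<- data.frame(
          chainId = id[1L], seqNum = as.integer(id[2L]), insCode = id[3L],
          resName = id[4L], reason = reason, stringsAsFactors = FALSE)
      }
      if (idKey %in% seenIds) {
        reject("duplicate residue id")
        anomalies <- c(anomalies, sprintf(
          "duplicate residue id %s", formatResidueId(id[1L], id[2L], id[3L], id[4L])))
        next
      }
      if (!isStandardAA(id[4L])) {
        reject("nonstandard residue name")
        anomalies <- c(anomalies, sprintf(
          "nonstandard residue %s treated as non-protein and removed",
          formatResidueId(id[1L], id[2L], id[3L], id[4L])))
        seenIds <- c(seenIds, idKey)
        next
      }
      seenIds <- c(seenIds, idKey)
      if (any(g != seq(g[1L], length.out = length(g))))
        anomalies <- c(anomalies, sprintf(
          "atoms of residue %s are not contiguous in the file",
          formatResidueId(id[1L], id[2L], id[3L], id[4L])))
      # alt-loc collapse: keep the conformer label with the highest total
      # occupancy, ties broken by first occurrence; blank-label atoms kept
      labels <- unique(r$altLoc[r$altLoc != " " & nzchar(trimws(r$altLoc))])
      if (length(labels) > 1L) {
        occ <- vapply(labels,
                      function(l) sum(r$occupancy[r$altLoc == l]), 0)
        keep <- labels[which.max(occ)]   # which.max: first maximum
        r <- r[r$altLoc == " " | !nzchar(trimws(r$altLoc)) | r$altLoc == keep,
               , drop = FALSE]
        anomalies <- c(anomalies, sprintf(
          "residue %s: alternate locations collapsed to conformer %s",
          formatResidueId(id[1L], id[2L], id[3L], id[4L]), keep))
      }
      if (anyDuplicated(r$name)) {
        anomalies <- c(anomalies, sprintf(
          "residue %s: duplicate atom name(s), first occurrence kept",
          formatResidueId(id[1L], id[2L], id[3L], id[4L])))
        r <- r[!duplicated(r$name), , drop = FALSE]
      }
      required <- .STANDARD_AA[[id[4L]]]
      missing <- setdiff(required, r$name)
      if (length(missing)) {
        reject(paste("missing atoms:", paste(missing, collapse = ", ")))
        next
      }
      keptAtoms[[length(keptAtoms) + 1L]] <- r
      keptResidues[[length(keptResidues) + 1L]] <- data.frame(
        chainId = id[1L], seqNum = as.integer(id[2L]), insCode = id[3L],
        resName = id[4L], caAtom = NA_integer_, stringsAsFactors = FALSE)
    }
  }

  if (!length(keptAtoms)) stopSM("no valid protein residues")

  nAt <- vapply(keptAtoms, nrow, 1L)
  atoms <- do.call(rbind, keptAtoms)
  atoms$residue <- rep(seq_along(keptAtoms), nAt)
  atoms <- atoms[, .ATOM_COLS]
  rownames(atoms) <- NULL
  residues <- do.call(rbind, keptResidues)
  offsets <- cumsum(c(0L, nAt[-length(nAt)]))
  residues$caAtom <- offsets + vapply(keptAtoms,
                                      function(r) match("CA", r$name), 1L)
  rownames(residues) <- NULL

  model <- new("StructureModel", atoms = atoms, residues = residues,
               sourceLabel = sourceLabel)
  rejectedDf <- if (length(rejected)) do.call(rbind, rejected)
                else .emptyRejectedList2()
  report <- new("ValidationReport",
                removedNonproteinChains = as.character(removedChains),
                removedHetero = hetCounts,
                rejectedResidues = rejectedDf,
                removedChainResidues = removedChainResidues,
                formatAnomalies = as.character(anomalies),
                retainedResidueCount = nrow(residues))
  list(model = model, report = report)
}

.emptyResidueList <- function()
  data.frame(chainId = character(0), seqNum = integer(0),
             insCode = character(0), resName = character(0),
             stringsAsFactors = FALSE)

.emptyRejectedList <- function() list()

.emptyRejectedList2 <- function()
  cbind(.emptyResidueList(), data.frame(reason = character(0)))

#' Read and validate a single-structure PDB file
#'
#' Convenience wrapper: parses the file with [parsePDB()], takes the first
#' model (noting a format anomaly if the file holds several, as NMR entries
#' do), and cleans it with [validateStructure()].
#'
#' @param path PDB file path.
#' @return list with `model` and `report`, as [validateStructure()].
#' @export
readStructure <- function(path) {
  validateStructure(parsePDB(path), sourceLabel = as.character(path)[1L])
}

#' Write the validation log
#'
#' Renders a [ValidationReport-class] as the human-readable plain-text log
#' that accompanies every cleaned structure: every removed chain, every
#' removed heteroatom category count, every rejected residue with its
#' reason, every format anomaly verbatim, and the retained residue count.
#'
#' @param report a [ValidationReport-class].
#' @param path output file path or connection.
#' @return invisibly, the log lines.
#' @export
writeValidationLog <- function(report, path) {
  stopifnot(is(report, "ValidationReport"))
  lines <- c("Structure validation log",
             "========================")
  issues <- FALSE
  if (length(report@removedNonproteinChains)) {
    issues <- TRUE
    lines <- c(lines, paste("Removed non-protein chains:",
                            paste(report@removedNonproteinChains,
                                  collapse = ", ")))
  }
  hc <- report@removedHetero
  if (sum(hc) > 0L) {
    issues <- TRUE
    parts <- sprintf("%d %s", hc[hc > 0L], names(hc)[hc > 0L])
    lines <- c(lines, paste("Removed heteroatom groups:",
                            paste(parts, collapse = ", ")))
  }
  rr <- report@rejectedResidues
  if (nrow(rr)) {
    issues <- TRUE
    lines <- c(lines, "Rejected residues:",
               sprintf("  %s  %s",
                       formatResidueId(rr$chainId, rr$seqNum, rr$insCode,
                                       rr$resName),
                       rr$reason))
  }
  if (length(report@formatAnomalies)) {
    issues <- TRUE
    lines <- c(lines, "Format anomalies:",
               paste0("  ", report@formatAnomalies))
  }
  if (!issues) lines <- c(lines, "No issues found.")
  lines <- c(lines, sprintf("Retained residues: %d",
                            report@retainedResidueCount))
  sink <- openTextSink(path)
  on.exit(if (sink$close) close(sink$con))
  writeLines(lines, sink$con)
  invisible(lines)
}

#' Validation report as text
#'
#' Returns the same content as the validation log file, as a character
#' vector (one element per line).
#'
#' @param x a [ValidationReport-class]
#' @return character vector
#' @export
report <- function(x) {
  con <- textConnection(NULL, "w")
  on.exit(close(con))
  writeValidationLog(x, con)
  textConnectionValue(con)
}
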