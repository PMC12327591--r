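# Fixed-column PDB reading and writing (ATOM/HETATM/MODEL/ENDMDL/TER).
# Parsing is line-tolerant: a record whose coordinate fields fail numeric
# parsing is skipped and noted as a format anomaly rather than aborting.

.num <- function(s) suppressWarnings(as.numeric(s))
.int <- function(s) suppressWarnings(as.integer(s))

.emptyRawModel <- function() {
  data.frame(recordType = character(0), serial = integer(0),
             name = character(0), altLoc = character(0),
             resName = character(0), chainId = character(0),
             seqNum = integer(0), insCode = character(0),
             x = numeric(0), y = numeric(0), z = numeric(0),
             occupancy = numeric(0), bFactor = numeric(0),
             element = character(0), line = integer(0),
             stringsAsFactors = FALSE)
}

#' Parse a PDB file into raw models
#'
#' Reads a (possibly multi-model) PDB file and returns one raw model per
#' MODEL/ENDMDL block; a file without MODEL records yields exactly one
#' model. ATOM and HETATM records are retained with their record type as a
#' category tag and file order is preserved. A record whose coordinate (or
#' residue-number) field fails numeric parsing is skipped and recorded as a
#' format anomaly on that model; it is not fatal.
#'
#' @param input a file path, a connection, or a character vector of PDB
#'   lines.
#' @return a list of data.frames (class `rawPDBModels`), one per model, each
#'   with columns recordType, serial, name, altLoc, resName, chainId,
#'   seqNum, insCode, x, y, z, occupancy, bFactor, element, line, an
#'   `anomalies` character attribute, and a `modelLabel` attribute holding
#'   the MODEL serial.
#' @seealso [validateStructure()], [readTrajectory()]
#' @export
parsePDB <- function(input) {
  looksLikeRecord <- function(s)
    grepl("^(ATOM|HETATM|MODEL|ENDMDL|TER|END|HEADER|REMARK|CRYST)", s)
  lines <- if (is.character(input) &&
               (length(input) > 1L || grepl("\n", input, fixed = TRUE) ||
                looksLikeRecord(input))) {
    unlist(strsplit(input, "\n", fixed = TRUE), use.names = FALSE)
  } else {
    if (is.character(input) && !file.exists(input))
      stopSM("cannot read PDB input: file not found: ", input)
    tryCatch(readLines(input, warn = FALSE),
             error = function(e) stopSM("cannot read PDB input: ",
                                        conditionMessage(e)))
  }

  isAtom <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  isModel <- startsWith(lines, "MODEL")
  isEnd <- startsWith(lines, "ENDMDL")
  if (!any(isAtom)) stopSM("no atom records found")

  hasModels <- any(isModel)
  # model index per line: 0 until the first MODEL, then the running count
  modelIdx <- cumsum(isModel)

  strayMsg <- NULL
  if (!hasModels) {
    groups <- list(`1` = which(isAtom))
    labels <- "1"
  } else {
    atomLines <- which(isAtom)
    grp <- modelIdx[atomLines]
    stray <- atomLines[grp == 0L]
    if (length(stray))
      strayMsg <- sprintf(
        "%d atom record(s) before the first MODEL record ignored",
        length(stray))
    keep <- atomLines[grp > 0L]
    groups <- split(keep, modelIdx[keep])
    mserial <- trimws(substr(lines[isModel], 7L, 14L))
    labels <- ifelse(nzchar(mserial), mserial,
                     as.character(seq_len(sum(isModel))))
  }

  out <- vector("list", length(groups))
  for (k in seq_along(groups)) {
    idx <- groups[[k]]
    ln <- lines[idx]
    anomalies <- character(0)
    m <- data.frame(
      recordType = ifelse(startsWith(ln, "ATOM"), "ATOM", "HETATM"),
      serial = .int(substr(ln, 7L, 11L)),
      name = trimws(substr(ln, 13L, 16L)),
      altLoc = substr(ln, 17L, 17L),
      resName = trimws(substr(ln, 18L, 20L)),
      chainId = substr(ln, 22L, 22L),
      seqNum = .int(substr(ln, 23L, 26L)),
      insCode = substr(ln, 27L, 27L),
      x = .num(substr(ln, 31L, 38L)),
      y = .num(substr(ln, 39L, 46L)),
      z = .num(substr(ln, 47L, 54L)),
      occupancy = .num(substr(ln, 55L, 60L)),
      bFactor = .num(substr(ln, 61L, 66L)),
      element = toupper(trimws(substr(ln, 77L, 78L))),
      line = idx,
      stringsAsFactors = FALSE)
    bad <- !is.finite(m$x) | !is.finite(m$y) | !is.finite(m$z) |
      is.na(m$seqNum)
    if (any(bad)) {
      anomalies <- c(anomalies, sprintf(
        "line %d: unparseable coordinate/residue-number field, record skipped",
        m$line[bad]))
      m <- m[!bad, , drop = FALSE]
    }
    if (anyNA(m$occupancy)) {
      m$occupancy[is.na(m$occupancy)] <- 1
    }
    if (anyNA(m$bFactor)) m$bFactor[is.na(m$bFactor)] <- 0
    if (anyNA(m$serial)) {
      anomalies <- c(anomalies, "missing atom serial number(s) replaced by 0")
      m$serial[is.na(m$serial)] <- 0L
    }
    rownames(m) <- NULL
    if (k == 1L && !is.null(strayMsg))
      anomalies <- c(anomalies, strayMsg)
    attr(m, "anomalies") <- anomalies
    attr(m, "modelLabel") <- if (hasModels) labels[as.integer(names(groups)[k])]
                             else labels[k]
    out[[k]] <- m
  }
  if (!length(out) || all(vapply(out, nrow, 1L) == 0L))
    stopSM("no atom records found")
  class(out) <- "rawPDBModels"
  out
}

# One formatted PDB atom line. Atom names shorter than four characters get
# the conventional leading space so the element lands in columns 13-14.
.fmtAtomLines <- function(serial, name, altLoc, resName, chainId, seqNum,
                          insCode, x, y, z, occupancy, bFactor, element,
                          recordType = "ATOM") {
  nm <- ifelse(nchar(name) >= 4L, substr(name, 1L, 4L),
               sprintf(" %-3s", name))
  sprintf("%-6s%5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          recordType, serial %% 100000L, nm,
          substr(paste0(altLoc, " "), 1L, 1L), resName,
          substr(paste0(chainId, " "), 1L, 1L), seqNum,
          substr(paste0(insCode, " "), 1L, 1L),
          x, y, z, occupancy, bFactor, element)
}

.modelBodyLines <- function(atoms, xyz = NULL, bFactor = NULL) {
  if (is.null(xyz)) xyz <- cbind(atoms$x, atoms$y, atoms$z)
  if (is.null(bFactor)) bFactor <- atoms$bFactor
  lines <- .fmtAtomLines(atoms$serial, atoms$name, atoms$altLoc,
                         atoms$resName, atoms$chainId, atoms$seqNum,
                         atoms$insCode, xyz[, 1], xyz[, 2], xyz[, 3],
                         atoms$occupancy, bFactor, atoms$element)
  # TER after the last atom of each chain
  lastOfChain <- which(atoms$chainId != c(atoms$chainId[-1L], NA))
  lastOfChain <- c(lastOfChain, nrow(atoms))
  lastOfChain <- sort(unique(lastOfChain))
  pieces <- character(0)
  prev <- 0L
  for (e in lastOfChain) {
    pieces <- c(pieces, lines[(prev + 1L):e],
                sprintf("TER   %5d      %3s %1s%4d%1s",
                        (atoms$serial[e] + 1L) %% 100000L, atoms$resName[e],
                        atoms$chainId[e], atoms$seqNum[e],
                        substr(paste0(atoms$insCode[e], " "), 1L, 1L)))
    prev <- e
  }
  pieces
}

#' @describeIn writePDB Write a cleaned structure as single-model PDB.
#' @export
setMethod("writePDB", "StructureModel", function(x, path, ...) {
  if (!nrow(x@atoms)) stopSM("cannot write an empty structure")
  sink <- openTextSink(path)
  on.exit(if (sink$close) close(sink$con))
  writeLines(c(.modelBodyLines(x@atoms), "END"), sink$con)
  invisible(path)
})
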