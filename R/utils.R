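# Shared helpers: condition constructors, the amino-acid chemistry tables,
# residue labelling, element inference.

stopConfig <- function(...) {
  stop(errorCondition(paste0(...), class = c("sphereMotif_config_error",
                                             "sphereMotif_error")))
}

stopSM <- function(...) {
  stop(errorCondition(paste0(...), class = "sphereMotif_error"))
}

# Heavy-atom composition of the 20 standard amino acids (PDB v3 atom names).
# Hydrogens are never required; OXT and terminal variants are tolerated as
# extras. A residue missing any atom listed here is rejected by validation.
.STANDARD_AA <- list(
  ALA = c("N", "CA", "C", "O", "CB"),
  ARG = c("N", "CA", "C", "O", "CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  ASN = c("N", "CA", "C", "O", "CB", "CG", "OD1", "ND2"),
  ASP = c("N", "CA", "C", "O", "CB", "CG", "OD1", "OD2"),
  CYS = c("N", "CA", "C", "O", "CB", "SG"),
  GLN = c("N", "CA", "C", "O", "CB", "CG", "CD", "OE1", "NE2"),
  GLU = c("N", "CA", "C", "O", "CB", "CG", "CD", "OE1", "OE2"),
  GLY = c("N", "CA", "C", "O"),
  HIS = c("N", "CA", "C", "O", "CB", "CG", "ND1", "CD2", "CE1", "NE2"),
  ILE = c("N", "CA", "C", "O", "CB", "CG1", "CG2", "CD1"),
  LEU = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2"),
  LYS = c("N", "CA", "C", "O", "CB", "CG", "CD", "CE", "NZ"),
  MET = c("N", "CA", "C", "O", "CB", "CG", "SD", "CE"),
  PHE = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  PRO = c("N", "CA", "C", "O", "CB", "CG", "CD"),
  SER = c("N", "CA", "C", "O", "CB", "OG"),
  THR = c("N", "CA", "C", "O", "CB", "OG1", "CG2"),
  TRP = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "NE1", "CE2",
          "CE3", "CZ2", "CZ3", "CH2"),
  TYR = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "CE1", "CE2",
          "CZ", "OH"),
  VAL = c("N", "CA", "C", "O", "CB", "CG1", "CG2"))

.WATER_NAMES <- c("HOH", "WAT", "H2O", "DOD", "DIS", "SOL")

# Common monatomic ion residue names; any single-atom HETATM group is also
# classified as an ion.
.ION_NAMES <- c("NA", "K", "CL", "MG", "CA", "ZN", "MN", "FE", "FE2", "CU",
                "CU1", "NI", "CO", "CD", "HG", "BR", "IOD", "F", "LI", "SR",
                "CS", "BA", "RB", "AL", "PB", "PT", "AU", "AG", "SM", "YB")

isStandardAA <- function(resName) resName %in% names(.STANDARD_AA)

# "chain:seqnum:icode:resname", e.g. "A:12::ALA" or "A:12:B:SER"
formatResidueId <- function(chainId, seqNum, insCode, resName) {
  ic <- trimws(insCode)
  paste(chainId, seqNum, ic, resName, sep = ":")
}

residueIdsOf <- function(residues) {
  if (!nrow(residues)) return(character(0))
  formatResidueId(residues$chainId, residues$seqNum, residues$insCode,
                  residues$resName)
}

# Element from the PDB element column when present, else inferred from the
# atom name (leading digits stripped; "1HB", "HG1" -> H inside amino acids).
inferElement <- function(name, element = "") {
  el <- toupper(trimws(element))
  need <- !nzchar(el)
  if (any(need)) {
    nm <- toupper(trimws(name[need]))
    nm <- sub("^[0-9]+", "", nm)
    first <- substr(nm, 1L, 1L)
    guess <- first
    guess[first == "H"] <- "H"
    guess[first == "D" & nchar(nm) > 1L] <- "D"
    el[need] <- guess
  }
  el
}

isHydrogen <- function(element) element %in% c("H", "D")

# RFC 4180: quote a field only when it contains a comma, quote or newline.
csvField <- function(x) {
  x <- as.character(x)
  need <- grepl('[",\n\r]', x)
  x[need] <- paste0('"', gsub('"', '""', x[need]), '"')
  x
}

# Compress a sorted integer set into a "4-6+9+12-14" range expression.
compressRanges <- function(v) {
  v <- sort(unique(as.integer(v)))
  if (!length(v)) return("")
  breaks <- c(0L, which(diff(v) != 1L), length(v))
  parts <- vapply(seq_len(length(breaks) - 1L), function(k) {
    a <- v[breaks[k] + 1L]; b <- v[breaks[k + 1L]]
    if (a == b) as.character(a) else paste0(a, "-", b)
  }, character(1))
  paste(parts, collapse = "+")
}

openTextSink <- function(path) {
  if (inherits(path, "connection")) return(list(con = path, close = FALSE))
  con <- file(path, open = "wt")
  list(con = con, close = TRUE)
}
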