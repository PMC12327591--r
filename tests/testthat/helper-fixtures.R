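# Hand-built PDB fixtures, constructed in code so every byte is controlled.

pdbAtomLine <- function(record = "ATOM", serial = 1L, name = "CA",
                        altLoc = " ", resName = "ALA", chain = "A",
                        seq = 1L, icode = " ", x = 0, y = 0, z = 0,
                        occ = 1, b = 0, element = "C") {
  nm <- if (nchar(name) >= 4L) substr(name, 1L, 4L) else sprintf(" %-3s", name)
  sprintf("%-6s%5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, nm, altLoc, resName, chain, seq, icode,
          x, y, z, occ, b, element)
}

# Heavy atoms of one residue, offset from a C-alpha origin. Supports the
# residue types the fixtures need.
.fixtureAtoms <- list(
  ALA = list(N = c(-1.2, 0.8, 0), CA = c(0, 0, 0), C = c(1.2, 0.8, 0),
             O = c(1.4, 1.9, 0.3), CB = c(0, -1, 1.05)),
  GLY = list(N = c(-1.2, 0.8, 0), CA = c(0, 0, 0), C = c(1.2, 0.8, 0),
             O = c(1.4, 1.9, 0.3)),
  SER = list(N = c(-1.2, 0.8, 0), CA = c(0, 0, 0), C = c(1.2, 0.8, 0),
             O = c(1.4, 1.9, 0.3), CB = c(0, -1, 1.05),
             OG = c(0, -2.2, 1.6)))

elementOf <- function(name) substr(sub("^[0-9]+", "", name), 1L, 1L)

# Lines for one residue; `drop` removes named atoms, `extraAlt` appends an
# alternate-location CA copy.
residueLines <- function(seq, resName = "ALA", chain = "A",
                         origin = c((seq - 1) * 3.5, 0, 0),
                         serialStart = (seq - 1L) * 10L + 1L,
                         drop = character(0), record = "ATOM") {
  at <- .fixtureAtoms[[resName]]
  at <- at[setdiff(names(at), drop)]
  vapply(seq_along(at), function(k) {
    p <- origin + at[[k]]
    pdbAtomLine(record, serialStart + k - 1L, names(at)[k], " ", resName,
                chain, seq, " ", p[1], p[2], p[3],
                element = elementOf(names(at)[k]))
  }, character(1))
}

chainLines <- function(nres, chain = "A", resName = "ALA", spacing = 3.5) {
  unlist(lapply(seq_len(nres), function(i)
    residueLines(i, resName, chain, origin = c((i - 1) * spacing, 0, 0),
                 serialStart = (i - 1L) * 10L + 1L)))
}

waterLines <- function(n, chain = "W", seqStart = 101L, serialStart = 9000L) {
  vapply(seq_len(n), function(k)
    pdbAtomLine("HETATM", serialStart + k, "O", " ", "HOH", chain,
                seqStart + k - 1L, " ", 50 + k, 50, 50, element = "O"),
    character(1))
}

writeLinesTmp <- function(lines) {
  tf <- tempfile(fileext = ".pdb")
  writeLines(lines, tf)
  tf
}

modelBlock <- function(lines, k) c(sprintf("MODEL     %4d", k), lines, "ENDMDL")
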