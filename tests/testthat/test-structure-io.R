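# PDB parsing, validation rules, round-trip writing, validation log.

test_that("parsePDB groups records by MODEL block and preserves counts", {
  one <- parsePDB(pdbAtomLine(serial = 1, name = "CA", x = 1.5))
  expect_length(one, 1L)
  expect_equal(nrow(one[[1]]), 1L)

  block1 <- vapply(1:5, function(k) pdbAtomLine(serial = k, name = "CA",
                                                seq = k, x = k), character(1))
  block2 <- vapply(1:5, function(k) pdbAtomLine(serial = k, name = "CA",
                                                seq = k, x = k + 0.5),
                   character(1))
  two <- parsePDB(c(modelBlock(block1, 1), modelBlock(block2, 2)))
  expect_length(two, 2L)
  expect_equal(vapply(two, nrow, 1L), c(5L, 5L))
  expect_equal(two[[2]]$x, 1:5 + 0.5)
  expect_equal(attr(two[[1]], "modelLabel"), "1")
})

test_that("parsePDB rejects empty input and missing files", {
  tf <- writeLinesTmp(c("HEADER    NOTHING", "END"))
  expect_error(parsePDB(tf), "no atom records found")
  expect_error(parsePDB(file.path(tempdir(), "does-not-exist.pdb")),
               "not found")
})

test_that("an unparseable coordinate field skips the line, not the file", {
  bad <- pdbAtomLine(serial = 2, name = "CB", x = 1)
  substr(bad, 31, 38) <- "  xx.yyy"
  m <- parsePDB(c(pdbAtomLine(serial = 1, name = "CA"), bad))[[1]]
  expect_equal(nrow(m), 1L)
  expect_match(attr(m, "anomalies"), "skipped", all = FALSE)
})

test_that("validation removes hetero groups by category and counts them", {
  lines <- c(chainLines(3), waterLines(10))
  v <- validateStructure(parsePDB(lines))
  expect_equal(nResidues(v$model), 3L)
  expect_equal(unname(v$report@removedHetero["water"]), 10L)
  expect_equal(v$report@retainedResidueCount, 3L)
  # ions: single-atom non-water HETATM group
  lines2 <- c(chainLines(3),
              pdbAtomLine("HETATM", 900, "ZN", " ", "ZN", "A", 200,
                          x = 30, element = "ZN"),
              pdbAtomLine("HETATM", 901, "C1", " ", "LIG", "A", 201, x = 40),
              pdbAtomLine("HETATM", 902, "C2", " ", "LIG", "A", 201, x = 41))
  v2 <- validateStructure(parsePDB(lines2))
  expect_equal(unname(v2$report@removedHetero[c("ion", "ligand", "water")]),
               c(1L, 1L, 0L))
})

test_that("residues with missing heavy atoms are rejected with a reason", {
  lines <- c(residueLines(1), residueLines(2, drop = "CA"), residueLines(3))
  v <- validateStructure(parsePDB(lines))
  expect_equal(v$report@retainedResidueCount, 2L)
  rej <- v$report@rejectedResidues
  expect_equal(rej$seqNum, 2L)
  expect_match(rej$reason, "missing atoms")
  expect_match(rej$reason, "CA")
  # missing a side-chain heavy atom is just as fatal
  v2 <- validateStructure(parsePDB(c(residueLines(1),
                                     residueLines(2, drop = "CB"))))
  expect_equal(v2$report@rejectedResidues$seqNum, 2L)
})

test_that("chains without any standard amino acid are removed whole", {
  lines <- c(chainLines(3, chain = "A"),
             pdbAtomLine("HETATM", 900, "C1", " ", "LIG", "B", 1, x = 60),
             pdbAtomLine("HETATM", 901, "C2", " ", "LIG", "B", 1, x = 61))
  v <- validateStructure(parsePDB(lines))
  expect_true("B" %in% v$report@removedNonproteinChains)
  expect_false("A" %in% v$report@removedNonproteinChains)
  expect_equal(sort(unique(atomTable(v$model)$chainId)), "A")
})

test_that("nonstandard residue names are rejected with an anomaly note", {
  mse <- residueLines(2, "ALA")
  mse <- sub("ALA", "MSE", mse)
  v <- validateStructure(parsePDB(c(residueLines(1), mse, residueLines(3))))
  expect_equal(v$report@retainedResidueCount, 2L)
  expect_match(v$report@rejectedResidues$reason, "nonstandard")
  expect_match(v$report@formatAnomalies, "MSE", all = FALSE)
})

test_that("alt-loc groups collapse to the highest-occupancy conformer", {
  base <- residueLines(1, drop = "CA")
  caA <- pdbAtomLine("ATOM", 8, "CA", "A", "ALA", "A", 1, x = 0.1, occ = 0.4)
  caB <- pdbAtomLine("ATOM", 9, "CA", "B", "ALA", "A", 1, x = 0.2, occ = 0.6)
  v <- validateStructure(parsePDB(c(base, caA, caB)))
  a <- atomTable(v$model)
  expect_equal(sum(a$name == "CA"), 1L)
  expect_equal(a$x[a$name == "CA"], 0.2)   # conformer B wins on occupancy
  # tie: first occurrence wins
  caB2 <- pdbAtomLine("ATOM", 9, "CA", "B", "ALA", "A", 1, x = 0.2, occ = 0.4)
  v2 <- validateStructure(parsePDB(c(base, caA, caB2)))
  a2 <- atomTable(v2$model)
  expect_equal(a2$x[a2$name == "CA"], 0.1)
})

test_that("no valid residues is an error, and coordinates are never altered", {
  expect_error(validateStructure(parsePDB(waterLines(3))),
               "no valid protein residues")
  lines <- c(chainLines(4), waterLines(2))
  raw <- parsePDB(lines)[[1]]
  v <- validateStructure(parsePDB(lines))
  kept <- atomTable(v$model)
  src <- raw[raw$recordType == "ATOM", ]
  expect_equal(kept[, c("x", "y", "z")], src[, c("x", "y", "z")],
               ignore_attr = TRUE)
})

test_that("removal categories partition the input residues", {
  lines <- c(chainLines(3, chain = "A"),            # 3 retained
             residueLines(4, drop = "O"),           # rejected
             pdbAtomLine("ATOM", 800, "C1", " ", "UNK", "B", 1, x = 70),
             waterLines(5))
  v <- validateStructure(parsePDB(lines))
  r <- v$report
  raw <- parsePDB(lines)[[1]]
  key <- unique(paste(raw$chainId, raw$seqNum, raw$insCode, raw$resName))
  total <- length(key)
  accounted <- r@retainedResidueCount + nrow(r@rejectedResidues) +
    nrow(r@removedChainResidues) + sum(r@removedHetero)
  expect_equal(accounted, total)
})

test_that("multi-model single-structure input uses model 1 with a note", {
  lines <- c(modelBlock(chainLines(2), 1), modelBlock(chainLines(2), 2))
  v <- validateStructure(parsePDB(lines))
  expect_equal(nResidues(v$model), 2L)
  expect_match(v$report@formatAnomalies, "first model used", all = FALSE)
})

test_that("writePDB round-trips a clean model and keeps 3-decimal precision", {
  v <- validateStructure(parsePDB(chainLines(2)))
  tf <- tempfile(fileext = ".pdb")
  writePDB(v$model, tf)
  v2 <- validateStructure(parsePDB(tf))
  expect_equal(atomTable(v2$model)[, c("name", "resName", "seqNum")],
               atomTable(v$model)[, c("name", "resName", "seqNum")])
  expect_equal(atomTable(v2$model)$x, atomTable(v$model)$x, tolerance = 1e-9)

  m <- v$model
  m@atoms$x[1] <- 1.23456
  writePDB(m, tf)
  expect_match(readLines(tf)[1], "1.235", fixed = TRUE)
  expect_error(writePDB(new("StructureModel",
                            atoms = atomTable(m)[0, ],
                            residues = residueTable(m)[0, ],
                            sourceLabel = "empty"), tf), "empty")
})

test_that("parsed coordinates agree with an independent PDB reader", {
  skip_if_not_installed("bio3d")
  tf <- writeLinesTmp(c(chainLines(5), "END"))
  ours <- parsePDB(tf)[[1]]
  ref <- bio3d::read.pdb(tf)$atom
  expect_equal(ours$x, ref$x)
  expect_equal(ours$y, ref$y)
  expect_equal(ours$z, ref$z)
  expect_equal(trimws(ours$name), ref$elety)
})

test_that("the validation log lists every issue and the retained count", {
  lines <- c(chainLines(2), residueLines(3, drop = "CB"), waterLines(4))
  v <- validateStructure(parsePDB(lines))
  log <- report(v$report)
  expect_match(log, "A:3::ALA", all = FALSE, fixed = TRUE)
  expect_match(log, "missing atoms", all = FALSE)
  expect_match(log, "4 water", all = FALSE)
  expect_match(log, "Retained residues: 2", all = FALSE)

  clean <- validateStructure(parsePDB(chainLines(3)))
  expect_match(report(clean$report), "No issues found", all = FALSE)
  # anomalies appear verbatim
  vr <- clean$report
  vr@formatAnomalies <- c("first odd thing", "second odd thing")
  expect_match(report(vr), "first odd thing", all = FALSE)
  expect_match(report(vr), "second odd thing", all = FALSE)
})

test_that("validation is deterministic on identical input bytes", {
  lines <- c(chainLines(4), waterLines(3))
  v1 <- validateStructure(parsePDB(lines))
  v2 <- validateStructure(parsePDB(lines))
  expect_identical(atomTable(v1$model), atomTable(v2$model))
  expect_identical(report(v1$report), report(v2$report))
})
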