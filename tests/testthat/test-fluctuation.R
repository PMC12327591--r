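# Score matrix over consecutive frame pairs, motif selection, RMSF baseline.

test_that("a static trajectory scores zero everywhere", {
  traj <- makeTrajectory(synthSpec(nResidues = 6, nFrames = 4))
  ss <- buildSpheres(traj, 4)
  for (mode in c("raw", "superposed")) {
    s <- scores(scoreTransitions(traj, ss, mode))
    expect_equal(dim(s), c(6L, 3L))
    expect_equal(max(abs(s)), 0, tolerance = 1e-9)
  }
})

test_that("global translation gives raw = |t| and superposed = 0", {
  traj <- makeTrajectory(synthSpec(nResidues = 10, nFrames = 4,
                                   translation = c(1, 0, 0)))
  ss <- buildSpheres(traj, 4)
  raw <- scores(scoreTransitions(traj, ss, "raw"))
  sup <- scores(scoreTransitions(traj, ss, "superposed"))
  expect_true(all(abs(raw - 1.0) <= 1e-6))
  expect_true(all(abs(sup) <= 1e-8))
  # general rigid motion (rotation + translation) also invisible superposed
  traj2 <- makeTrajectory(synthSpec(nResidues = 10, nFrames = 3,
                                    translation = c(0.5, -1, 2),
                                    rotationAngle = 0.4))
  sup2 <- scores(scoreTransitions(traj2, buildSpheres(traj2, 4), "superposed"))
  expect_true(all(abs(sup2) <= 1e-8))
})

test_that("a localized perturbation surfaces in the right rows and columns", {
  # noise only between specific residues; spheres holding perturbed
  # residues must carry the largest scores
  traj <- makeTrajectory(synthSpec(nResidues = 20, nFrames = 4,
                                   perturbedWindow = c(8, 10),
                                   perturbationSigma = 1.5, seed = 21))
  ss <- buildSpheres(traj, 4)
  sm <- scoreTransitions(traj, ss, "superposed")
  s <- scores(sm)
  touching <- vapply(seq_len(20), function(i)
    any(memberResidues(ss, i) %in% 8:10), TRUE)
  for (t in 1:3) {
    top <- order(s[, t], decreasing = TRUE)[1:3]
    expect_true(all(touching[top]))
  }
  # matrix equals a per-sphere direct recomputation (independent loop)
  for (mode in c("raw", "superposed")) {
    s2 <- scores(scoreTransitions(traj, ss, mode))
    for (i in c(1, 8, 15)) for (t in 1:3) {
      ix <- memberAtoms(ss, i)
      A <- frameCoords(traj, t, ix)
      B <- frameCoords(traj, t + 1, ix)
      ref <- if (mode == "raw") directRawRMSD(A, B) else gridSearchRMSD(A, B)
      expect_equal(s2[i, t], ref, tolerance = 1e-3)
    }
  }
})

test_that("score matrix dimensions are R x (F-1) with later-frame labels", {
  for (R in c(1, 3, 10)) for (F in c(2, 5)) {
    traj <- makeTrajectory(synthSpec(nResidues = R, nFrames = F))
    sm <- scoreTransitions(traj, buildSpheres(traj, 4), "raw")
    expect_equal(dim(scores(sm)), c(R, F - 1L))
    expect_equal(colnames(scores(sm)), as.character(2:F))
  }
})

test_that("selection arithmetic follows ceil(p/100 * R * (F-1))", {
  traj <- makeTrajectory(synthSpec(nResidues = 3, nFrames = 4,
                                   perturbedWindow = c(1, 3),
                                   perturbationSigma = 0.8, seed = 3))
  sm <- scoreTransitions(traj, buildSpheres(traj, 4), "superposed")
  all9 <- selectHighFluctuation(sm, 100)
  expect_equal(all9@selectedCount, 9L)
  expect_equal(all9@candidateCount, 9L)
  one <- selectHighFluctuation(sm, 10)   # ceil(0.9) = 1
  expect_equal(one@selectedCount, 1L)
  expect_equal(motifTable(one)$score, max(scores(sm)))
  expect_error(selectHighFluctuation(sm, 0), "0, 100")
  expect_error(selectHighFluctuation(sm, 101), "0, 100")
})

test_that("ties are broken by earlier transition then lower residue", {
  traj <- makeTrajectory(synthSpec(nResidues = 3, nFrames = 3))
  sm <- scoreTransitions(traj, buildSpheres(traj, 4), "raw")  # all zeros
  half <- selectHighFluctuation(sm, 50)  # ceil(3) = 3 of 6 equal cells
  m <- motifTable(half)
  expect_equal(m$transition, c(1L, 1L, 1L))
  expect_equal(m$residue, 1:3)
  # determinism: repeated calls identical
  expect_identical(m, motifTable(selectHighFluctuation(sm, 50)))
})

test_that("ranks descend with score and are unique", {
  traj <- makeTrajectory(synthSpec(nResidues = 12, nFrames = 5,
                                   perturbedWindow = c(5, 7),
                                   perturbationSigma = 1, seed = 13))
  sm <- scoreTransitions(traj, buildSpheres(traj, 4), "superposed")
  ms <- selectHighFluctuation(sm, 40)
  m <- motifTable(ms)
  expect_equal(m$rank, seq_len(nrow(m)))
  expect_true(all(diff(m$score) <= 0))
})

test_that("RMSF baseline matches hand cases and the two-pass oracle", {
  traj <- makeTrajectory(synthSpec(nResidues = 5, nFrames = 6))
  expect_equal(unname(rmsfBaseline(traj)), rep(0, 5))
  # one CA alternating between x = 0 and x = 2: RMSF exactly 1
  traj2 <- makeTrajectory(synthSpec(nResidues = 2, nFrames = 4))
  ca1 <- residueTable(traj2)$caAtom[1]
  traj2@coords[ca1, 1, ] <- traj2@coords[ca1, 1, ] + c(0, 2, 0, 2)
  expect_equal(unname(rmsfBaseline(traj2)[1]), 1.0)
  # random-walk trajectory vs explicit two-pass computation
  traj3 <- makeTrajectory(synthSpec(nResidues = 6, nFrames = 8))
  set.seed(31)
  for (f in 2:8) traj3@coords[, , f] <-
    traj3@coords[, , f - 1] + matrix(rnorm(length(traj3@coords[, , f]),
                                           sd = 0.3), ncol = 3)
  expect_equal(unname(rmsfBaseline(traj3)), twoPassRMSF(traj3))
})

test_that("perturbed-window recovery holds across seeds (superposed mode)", {
  hits <- 0L
  for (seed in 1:20) {
    traj <- makeTrajectory(synthSpec(nResidues = 30, nFrames = 5,
                                     perturbedWindow = c(10, 12),
                                     perturbationSigma = 1.5, seed = seed))
    ss <- buildSpheres(traj, 4)
    sm <- scoreTransitions(traj, ss, "superposed")
    top <- motifTable(selectHighFluctuation(sm, 1))[1, ]
    if (any(memberResidues(ss, top$residue) %in% 10:12)) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})
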