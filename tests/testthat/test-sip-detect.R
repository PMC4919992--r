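test_that("total-community reconstruction weights fractions correctly", {
  a <- matrix(c(1, 0, 0, 1), 2, dimnames = list(c("t1", "t2"), NULL))
  run <- toyRun(a, copies = c(3, 1))
  # copy weighting: (3/4, 1/4)
  expect_equal(reconstructTotalCommunity(run, "copies"),
               c(t1 = 0.75, t2 = 0.25), tolerance = 1e-12)
  expect_equal(reconstructTotalCommunity(run, "uniform"),
               c(t1 = 0.5, t2 = 0.5), tolerance = 1e-12)
  # identical fraction profiles: that profile under either weighting
  b <- matrix(c(0.3, 0.7, 0.3, 0.7), 2, dimnames = list(c("t1", "t2"), NULL))
  runb <- toyRun(b, copies = c(8, 2))
  expect_equal(reconstructTotalCommunity(runb, "copies"),
               c(t1 = 0.3, t2 = 0.7), tolerance = 1e-12)
  # equal copies make both weightings coincide
  runc <- toyRun(a, copies = c(5, 5))
  expect_equal(reconstructTotalCommunity(runc, "copies"),
               reconstructTotalCommunity(runc, "uniform"), tolerance = 1e-12)
  rund <- toyRun(a, copies = c(0, 0))
  expect_error(reconstructTotalCommunity(rund, "copies"), "copy numbers")
  expect_equal(sum(reconstructTotalCommunity(run)), 1, tolerance = 1e-12)
})

test_that("difference profiles subtract 12C from 13C fraction-wise", {
  a13 <- matrix(c(0.1, 0.9, 0.3, 0.7), 2, dimnames = list(c("t1", "t2"), NULL))
  a12 <- matrix(c(0.3, 0.7, 0.1, 0.9), 2, dimnames = list(c("t1", "t2"), NULL))
  r13 <- toyRun(a13, treatment = "13C"); r12 <- toyRun(a12)
  d <- differenceProfile(list(r13), list(r12))
  expect_equal(unname(d["t1", ]), c(-0.2, 0.2), tolerance = 1e-12)
  # identical arms: all-zero profile
  expect_true(all(differenceProfile(list(r12), list(r12)) == 0))
  # antisymmetry under swapping arms
  expect_equal(differenceProfile(list(r12), list(r13)), -d, tolerance = 1e-12)
  # replicate means equal per-replicate subtraction then averaging
  a13b <- matrix(c(0.2, 0.8, 0.4, 0.6), 2, dimnames = list(c("t1", "t2"), NULL))
  a12b <- matrix(c(0.25, 0.75, 0.15, 0.85), 2, dimnames = list(c("t1", "t2"), NULL))
  r13b <- toyRun(a13b, treatment = "13C", replicate = 2L)
  r12b <- toyRun(a12b, replicate = 2L)
  bruteforce <- ((a13 - a12) + (a13b - a12b)) / 2
  dimnames(bruteforce) <- dimnames(d)
  expect_equal(differenceProfile(list(r13, r13b), list(r12, r12b)),
               bruteforce, tolerance = 1e-12)
  # mismatched fraction counts
  short <- toyRun(matrix(c(0.5, 0.5), 2, 1, dimnames = list(c("t1", "t2"), NULL)),
                  density = 1.72, copies = 10)
  expect_error(differenceProfile(list(r13), list(short)), "fraction count")
  expect_error(differenceProfile(list(r13), list(r12), taxon = "zz"),
               "unknown taxon")
})

test_that("centre-of-mass density is the abundance-weighted mean", {
  a <- matrix(c(0.5, 0.5, 0.5, 0.5, 0, 1), 2,
              dimnames = list(c("t1", "t2"), NULL))
  run <- toyRun(a, density = c(1.74, 1.70, 1.66), copies = c(1, 1, 1))
  # equal mass at 1.74 and 1.70 (t1 absent from 1.66): midpoint
  expect_equal(bdCenterOfMass(run, "t1"), 1.72, tolerance = 1e-12)
  # entirely in one fraction: that fraction's density
  b <- matrix(c(0, 0.4, 0.6, 0, 1, 0), 3, 2,
              dimnames = list(c("x", "y", "z"), NULL))
  runb <- toyRun(b, density = c(1.73, 1.71), copies = c(2, 2))
  expect_equal(bdCenterOfMass(runb, "z"), 1.73, tolerance = 1e-12)
  # absent taxon: not evaluable
  expect_warning(com <- bdCenterOfMass(runb, "x"), "not evaluable")
  expect_true(is.na(com))
  # symmetric band about the gradient centre
  s <- matrix(c(0.2, 0.8, 0.6, 0.4, 0.2, 0.8), 2,
              dimnames = list(c("t1", "t2"), NULL))
  runs <- toyRun(s, density = c(1.74, 1.72, 1.70), copies = c(1, 1, 1))
  expect_equal(bdCenterOfMass(runs, "t1"), 1.72, tolerance = 1e-12)
  # copies weighting rescales fraction masses
  runw <- toyRun(a, density = c(1.74, 1.70, 1.66), copies = c(3, 1, 1))
  expect_equal(bdCenterOfMass(runw, "t1", weighting = "copies"),
               (1.74 * 1.5 + 1.70 * 0.5) / 2, tolerance = 1e-12)
})

test_that("identical treatment arms produce zero labelled calls", {
  p <- simPair(30, labelled = character(), communitySeed = 5, masterSeed = 50)
  st <- detectLabelled(p$r13, p$r13)   # same runs on both sides
  expect_length(labelledTaxa(st), 0)
  expect_true(all(abs(deltaProfiles(st)) < 1e-12))
})

test_that("planted fully labelled taxa are recovered from noisy gradients", {
  lab <- sprintf("T%02d", 1:5)
  p <- simPair(50, labelled = lab, communitySeed = 2, masterSeed = 20)
  st <- detectLabelled(p$r13, p$r12)
  expect_setequal(labelledTaxa(st), lab)
  r <- shiftResults(st)
  expect_true(all(r[lab, "com_shift"] >= 0.010))
  # delta profiles live in [-1, 1]
  expect_true(all(deltaProfiles(st) >= -1 & deltaProfiles(st) <= 1))
})

test_that("degenerate thresholds flag every taxon with a positive shift", {
  p <- simPair(20, labelled = "T01", communitySeed = 3, masterSeed = 30)
  st <- detectLabelled(p$r13, p$r12, comThreshold = 0, heavyK = 0L,
                       minAbund = 0)
  r <- shiftResults(st)
  expect_identical(r$labelled, r$status == "ok" & r$com_shift >= 0)
})

test_that("detection is invariant to taxon row order and replicate order", {
  lab <- sprintf("T%02d", 1:3)
  p <- simPair(25, labelled = lab, communitySeed = 11, masterSeed = 40)
  st <- detectLabelled(p$r13, p$r12)
  stRev <- detectLabelled(rev(p$r13), rev(p$r12))
  expect_identical(labelledTaxa(st), labelledTaxa(stRev))
  expect_equal(shiftResults(st)$com_shift, shiftResults(stRev)$com_shift,
               tolerance = 1e-12)
  perm <- sample(nrow(p$r13[[1]]))
  r13p <- lapply(p$r13, function(r) r[perm, ])
  r12p <- lapply(p$r12, function(r) r[perm, ])
  stPerm <- detectLabelled(r13p, r12p)
  expect_setequal(labelledTaxa(stPerm), labelledTaxa(st))
})

test_that("the optional permutation test attaches p-values and gates calls", {
  lab <- sprintf("T%02d", 1:3)
  p <- simPair(25, labelled = lab, communitySeed = 6, masterSeed = 60)
  st <- detectLabelled(p$r13, p$r12, nPerm = 19, seed = 1)
  r <- shiftResults(st)
  expect_true(all(!is.na(r$p_value)))
  expect_true(all(r$p_value >= 1 / 20 & r$p_value <= 1))
  expect_true(all(r[labelledTaxa(st), "p_value"] <= 0.05))
  # with a single replicate per arm the test is skipped with a warning
  expect_warning(detectLabelled(p$r13[1], p$r12[1], nPerm = 19, seed = 1),
                 "permutation")
})

test_that("taxa present in only one arm are reported, never auto-called", {
  a13 <- matrix(c(0.6, 0.4, 0, 0.2, 0.8, 0), 3,
                dimnames = list(c("t1", "t2", "t3"), NULL))
  a12 <- matrix(c(0.3, 0.3, 0.4, 0.1, 0.5, 0.4), 3,
                dimnames = list(c("t1", "t2", "t3"), NULL))
  st <- detectLabelled(list(toyRun(a13, treatment = "13C")),
                       list(toyRun(a12)), comThreshold = 0, heavyK = 0L)
  r <- shiftResults(st)
  expect_identical(r["t3", "status"], "absent_13C")
  expect_false(r["t3", "labelled"])
})

test_that("whole-community qPCR shifts are measured on the density scale", {
  a <- matrix(rep(0.5, 8), 2, dimnames = list(c("t1", "t2"), NULL))
  dens <- c(1.76, 1.74, 1.72, 1.70)
  c12 <- c(0, 10, 30, 10)
  c13 <- c(10, 30, 10, 0)    # same copy profile shifted one fraction heavier
  r12 <- toyRun(a, density = dens, copies = c12)
  r13 <- toyRun(a, density = dens, copies = c13, treatment = "13C")
  ts <- totalShiftCheck(list(r13), list(r12))
  expect_equal(ts$shift, 0.02, tolerance = 1e-12)   # one fraction width
  expect_true(ts$detected)
  # identical copy curves: zero, not detected
  ts0 <- totalShiftCheck(list(r12), list(r12))
  expect_equal(ts0$shift, 0, tolerance = 1e-12)
  expect_false(ts0$detected)
  # missing copies
  rbad <- toyRun(a, density = dens, copies = rep(0, 4))
  expect_error(totalShiftCheck(list(r13), list(rbad)), "copy numbers")
})

test_that("weak early labelling escapes detection that strong labelling triggers", {
  taxa <- makeCommunity(50, seed = 14)
  lab <- list(X = sprintf("T%02d", 1:5))
  runsFor <- function(af, seed) {
    runs <- simulateExperiment(taxa, gradientConfig(), soils = "X",
                               replicates = 3, labelledBySoil = lab,
                               labelAtomFraction = af, masterSeed = seed)
    list(r13 = runs[grepl("_13C_", names(runs))],
         r12 = runs[grepl("_12C_", names(runs))])
  }
  early <- runsFor(0.05, 90)
  late <- runsFor(0.90, 91)
  expect_false(totalShiftCheck(early$r13, early$r12)$detected)
  expect_true(totalShiftCheck(late$r13, late$r12)$detected)
})
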