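test_that("generated vertebra paints interior, shell and posterior labels", {
  ph <- smallPhantom(mean_hu = 100, sd_hu = 0)
  lab <- labelArray(ph$labels)
  vals <- ctValues(ph$volume)
  expect_setequal(unique(as.vector(lab)), c(0L, 1L, 101L))
  # zero-noise interior: every body voxel is either shell (800) or exactly 100
  body_vals <- vals[lab == 1L]
  expect_true(all(body_vals %in% c(100, 800)))
  expect_true(any(body_vals == 100))
  # label map co-registered with the volume
  expect_identical(dim(lab), dim(vals))
  expect_equal(voxelSpacing(ph$labels), voxelSpacing(ph$volume))
})

test_that("trabecular noise has the configured mean (law of large numbers)", {
  ph <- smallPhantom(mean_hu = 100, sd_hu = 20, seed = 11)
  vals <- ctValues(ph$volume)
  lab <- labelArray(ph$labels)
  interior <- vals[lab == 1L & vals != 800]
  expect_gt(length(interior), 1e4)
  expect_lt(abs(mean(interior) - 100), 3 * 20 / sqrt(length(interior)))
})

test_that("volume generation is deterministic under a fixed seed", {
  a <- smallPhantom(sd_hu = 20, seed = 5)
  b <- smallPhantom(sd_hu = 20, seed = 5)
  expect_identical(ctValues(a$volume), ctValues(b$volume))
  expect_identical(labelArray(a$labels), labelArray(b$labels))
  c <- smallPhantom(sd_hu = 20, seed = 6)
  expect_false(identical(ctValues(a$volume), ctValues(c$volume)))
})

test_that("geometry violations are rejected", {
  grid <- list(dim = c(48, 64, 40), spacing = c(1, 1, 1))
  expect_error(
    generateVolume(list(vertebraSpec("L1", center = c(5, 20, 20))), grid),
    "does not fit")
  tall <- list(dim = c(48, 64, 60), spacing = c(1, 1, 1))
  expect_error(
    generateVolume(list(vertebraSpec("L1", center = c(24, 20, 22)),
                        vertebraSpec("L2", center = c(24, 20, 30))), tall),
    "overlap")
  expect_error(
    generateVolume(list(vertebraSpec("L1", center = c(24, 20, 20)),
                        vertebraSpec("L1", center = c(24, 20, 20))), grid),
    "duplicate")
})

test_that("hardware changes HU only at hardware-labelled voxels", {
  ph <- smallPhantom(sd_hu = 20, seed = 2)
  hw <- hardwareSpec(screw_radius_mm = 2, screw_length_mm = 25,
                     screw_hu = 3000,
                     trajectories = list(list(entry = c(24, 45, 20),
                                              direction = c(0, -1, 0))))
  inst <- addInstrumentation(ph$volume, ph$labels, hw)
  lab2 <- labelArray(inst$labels)
  expect_true(all(ctValues(inst$volume)[lab2 == 200L] == 3000))
  changed <- ctValues(inst$volume) != ctValues(ph$volume)
  expect_true(all(lab2[changed] == 200L))
  # screw passes through the body: interior voxels were relabelled
  expect_gt(sum(labelArray(ph$labels) == 1L & lab2 == 200L), 0)
})

test_that("screw voxel count matches the cylinder-grid intersection oracle", {
  ph <- smallPhantom()
  r <- 2.5; len <- 20
  hw <- hardwareSpec(r, len, 3000,
                     trajectories = list(list(entry = c(24, 45, 20),
                                              direction = c(0, -1, 0))))
  inst <- addInstrumentation(ph$volume, ph$labels, hw)
  # geometric oracle: exhaustive scan of voxel centres against the capsule
  d <- dim(ctValues(ph$volume))
  n_oracle <- 0L
  p0 <- c(24, 45, 20); u <- c(0, -1, 0)
  for (x in 0:(d[1] - 1)) for (y in 0:(d[2] - 1)) for (z in 0:(d[3] - 1)) {
    rel <- c(x, y, z) - p0
    t <- min(max(sum(rel * u), 0), len)
    if (sum((rel - t * u)^2) <= r^2) n_oracle <- n_oracle + 1L
  }
  expect_identical(sum(labelArray(inst$labels) == 200L), n_oracle)
})

test_that("sub-threshold screws are rejected at construction", {
  expect_error(hardwareSpec(screw_hu = 1000), ">= 1400")
})

test_that("cohort simulation matches its specification", {
  # sd = 0: all case BMDs exactly the case mean
  coh0 <- simulateCohort(cohortSpec(case_bmd_sd = 0, control_bmd_sd = 0,
                                    seed = 1))
  expect_true(all(coh0$bmd[coh0$group == "case"] == 86.5))
  expect_true(all(coh0$bmd[coh0$group == "control"] == 118.2))
  # same seed -> identical records; different seed -> different draws
  expect_identical(simulateCohort(cohortSpec(seed = 9)),
                   simulateCohort(cohortSpec(seed = 9)))
  expect_false(identical(simulateCohort(cohortSpec(seed = 9)),
                         simulateCohort(cohortSpec(seed = 10))))
  # large-n group means converge to the configured group parameters
  big <- simulateCohort(cohortSpec(n_cases = 1e5, n_controls = 1e5, seed = 4))
  mc <- mean(big$bmd[big$group == "case"])
  mk <- mean(big$bmd[big$group == "control"])
  expect_lt(abs(mc - 86.5), 3 * 29.5 / sqrt(1e5))
  expect_lt(abs(mk - 118.2), 3 * 32.9 / sqrt(1e5))
  expect_lt(abs(sd(big$bmd[big$group == "case"]) - 29.5), 0.5)
  expect_lt(abs(sd(big$bmd[big$group == "control"]) - 32.9), 0.5)
})

test_that("cohort covariates are matched between paired records", {
  coh <- simulateCohort(cohortSpec(seed = 21))
  cases <- coh[coh$group == "case", ]
  ctrls <- coh[coh$group == "control", ]
  expect_identical(cases$sex, ctrls$sex)
  expect_identical(cases$construct, ctrls$construct)
  expect_lt(max(abs(cases$age - ctrls$age)), 10)
})

test_that("bmdToHu is the exact inverse of calibrate", {
  expect_equal(bmdToHu(100, identityEq()), 100)
  eq <- CalibrationEquation(120, 0.8, -5)
  expect_equal(bmdToHu(115, eq), 150)
  set.seed(42)
  x <- runif(100, 0, 300)
  expect_equal(calibrate(bmdToHu(x, eq), eq), x)
})

test_that("cohortSpec validates construct probabilities", {
  expect_error(cohortSpec(construct_distribution = c("L1-5" = 1)), "named")
  bad <- c("L1-5" = 0.5, "L2-5" = 0.2, "L2-S1" = 0.2, "L3-S1" = 0.2,
           "L4-S1" = 0.2)
  expect_error(cohortSpec(construct_distribution = bad), "sum to 1")
})
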