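# Cross-validation metrics, Fisher z, Tukey groupings, PGBV comparisons.

test_that("Fisher z is atanh with domain checking", {
  expect_equal(fisherZ(0), 0)
  expect_equal(fisherZ(0.5), atanh(0.5), tolerance = 1e-12)
  expect_equal(fisherZ(0.5), 0.5493, tolerance = 1e-4)
  r <- seq(-0.9, 0.9, by = 0.15)
  expect_equal(fisherZ(-r), -fisherZ(r))
  expect_error(fisherZ(1), "undefined")
  expect_error(fisherZ(-1.2), "undefined")
})

test_that("accuracies and reliabilities follow the stated formulas", {
  set.seed(2)
  yAdj <- rnorm(50)
  # perfectly proportional predictions: r = 1, R2 = 1/h2, flagged
  out <- accuracyReliability(2 * yAdj, NULL, yAdj, h2 = 0.4)
  expect_equal(unname(out["r_pgbv"]), 1)
  expect_equal(unname(out["R2_pgbv"]), 1 / 0.4)
  expect_identical(attr(out, "clipped"), "R2_pgbv")

  # R2 = r^2 / h2 with r computed independently
  g <- yAdj + rnorm(50, sd = 2)
  out2 <- accuracyReliability(g, g, yAdj, h2 = 0.25, e2 = 0.5)
  r <- cor(g, yAdj)
  expect_equal(unname(out2["r_pgbv"]), r)
  expect_equal(unname(out2["R2_pgbv"]), r^2 / 0.25)
  expect_equal(unname(out2["R2_eta"]), r^2 / 0.5)
  expect_identical(attr(out2, "clipped"), character(0))

  # arithmetic anchor: r = 0.3, h2 = 0.25 -> R2 = 0.36
  expect_equal(0.3^2 / 0.25, 0.36)

  # zero-variance predictions are recorded as missing
  out3 <- accuracyReliability(rep(1, 50), NULL, yAdj, h2 = 0.3)
  expect_true(is.na(out3["r_pgbv"]))
})

test_that("phenotype accuracy is the plain Pearson correlation", {
  y <- c(1.1, 2.3, 0.2, -0.8, 1.9)
  expect_equal(phenotypeAccuracy(y, y), 1)
  expect_true(is.na(phenotypeAccuracy(rep(1, 5), y)))
  yt <- c(0.9, 2.0, 0.4, -1.0, 2.2)
  byHand <- sum((yt - mean(yt)) * (y - mean(y))) /
    sqrt(sum((yt - mean(yt))^2) * sum((y - mean(y))^2))
  expect_equal(phenotypeAccuracy(yt, y), byHand, tolerance = 1e-12)
})

test_that("PGBV comparison returns Pearson, Spearman and MSD", {
  a <- c(0.5, -1.2, 2.2, 0.1)
  expect_equal(unname(comparePGBV(a, a)), c(1, 1, 0))
  expect_equal(unname(comparePGBV(a, a + 1)), c(1, 1, 1))
  b <- c(0.7, -1.0, 1.8, 0.4)
  out <- comparePGBV(a, b)
  expect_equal(unname(out["msd"]), mean((a - b)^2), tolerance = 1e-12)
  expect_equal(unname(out["spearman"]), cor(rank(a), rank(b)),
               tolerance = 1e-12)
  expect_error(comparePGBV(a, b[1:3]), "length")
})

test_that("Tukey groupings match stats::TukeyHSD as an oracle", {
  set.seed(4)
  vals <- c(rnorm(30, 0), rnorm(30, 0.05), rnorm(30, 3))
  grp <- rep(c("m1", "m2", "m3"), each = 30)
  tg <- tukeyGroups(vals, grp, alpha = 0.05)

  fit <- aov(vals ~ factor(grp))
  ref <- TukeyHSD(fit)[[1]]
  p <- attr(tg, "pMatrix")
  expect_equal(p["m2", "m1"], unname(ref["m2-m1", "p adj"]), tolerance = 1e-6)
  expect_equal(p["m3", "m1"], unname(ref["m3-m1", "p adj"]), tolerance = 1e-6)
  expect_equal(p["m3", "m2"], unname(ref["m3-m2", "p adj"]), tolerance = 1e-6)

  # m1/m2 indistinguishable, m3 separated
  lett <- setNames(tg$letters, tg$group)
  expect_identical(lett[["m1"]], lett[["m2"]])
  expect_false(lett[["m3"]] == lett[["m1"]])

  # identical samples share a letter
  v2 <- rep(rnorm(20), 2); g2 <- rep(c("x", "y"), each = 20)
  tg2 <- tukeyGroups(v2, g2)
  expect_identical(tg2$letters[1], tg2$letters[2])

  # extreme separation: different letters
  v3 <- c(rnorm(100, 0, 1), rnorm(100, 10, 1))
  tg3 <- tukeyGroups(v3, rep(c("lo", "hi"), each = 100))
  expect_false(tg3$letters[1] == tg3$letters[2])

  # Tukey-Kramer handles unequal replicate counts
  v4 <- c(rnorm(10), rnorm(25, 5)); g4 <- rep(c("s", "l"), c(10, 25))
  expect_silent(tukeyGroups(v4, g4))
})

test_that("cross-validation is deterministic, paired, and guarded", {
  dat <- makeToyData(nAnimals = 60, nSnps = 300, nFarms = 6, seed = 51)
  specs <- list(GRM = modelSpec("GRM", dat$grm),
                GRM_GPS = modelSpec("GRM_GPS", dat$grm, dat$herdKernel))
  cv1 <- crossValidate(dat, specs, nReps = 2, seed = 99)
  cv2 <- crossValidate(dat, specs, nReps = 2, seed = 99)
  expect_equal(cv1, cv2)
  expect_identical(attr(cv1, "splits"), attr(cv2, "splits"))
  # paired splits: both models share the replicate's test set by design
  expect_equal(nrow(cv1), 4L)

  expect_error(crossValidate(dat, specs, nReps = 2, trainFrac = 1.0),
               "strictly between")

  sm <- summarizeCV(cv1)
  expect_true(all(c("metric", "model", "mean", "letters") %in% names(sm)))
  expect_true(all(c("h2", "r_pgbv", "r_y") %in% sm$metric))
})

test_that("mean cross-validated h2 recovers the generating heritability", {
  dat <- makeToyData(nAnimals = 250, nSnps = 600, nFarms = 12, seed = 61,
                     sigmaG2 = 1, sigmaEta2 = 0.5, sigmaE2 = 1)
  specs <- list(GRM_GPS = modelSpec("GRM_GPS", dat$grm, dat$herdKernel))
  cv <- crossValidate(dat, specs, nReps = 8, seed = 5)
  h2True <- 1 / 2.5
  expect_lt(abs(mean(cv$h2) - h2True), 0.12)
  expect_true(all(cv$converged))
  expect_true(all(abs(cv$r_pgbv) <= 1 & abs(cv$r_y) <= 1, na.rm = TRUE))
})
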