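# Design construction, AI-REML, BLUP solving and test-set prediction.

toyPheno <- function(n, farms, seed = 1) {
  set.seed(seed)
  data.frame(animal = paste0("a", seq_len(n)),
             farm = rep_len(farms, n),
             trait = rnorm(n),
             age = sample(25:35, n, replace = TRUE),
             sex = rep_len(c(0, 1), n),
             cg_size = as.integer(n / length(farms)),
             stringsAsFactors = FALSE)
}

test_that("buildDesign produces the documented X and Z", {
  ph <- toyPheno(3, c("f1", "f2"))
  expect_warning(des <- buildDesign(ph, c("f1", "f2")), "cg_size")
  expect_identical(dim(des$Z), c(3L, 2L))
  expect_equal(rowSums(des$Z), rep(1, 3), ignore_attr = TRUE)

  # hand-built 4-animal design
  ph4 <- data.frame(animal = paste0("a", 1:4), farm = c("f1", "f1", "f2", "f2"),
                    trait = c(1.2, 0.8, -0.5, 2.0), age = c(25, 30, 28, 35),
                    sex = c(0, 1, 1, 0), cg_size = c(2L, 2L, 2L, 2L))
  expect_warning(des4 <- buildDesign(ph4, c("f1", "f2")), "cg_size")
  expect_equal(unname(des4$X[, "age"]), c(25, 30, 28, 35))
  expect_equal(unname(des4$X[, "sex"]), c(0, 1, 1, 0))
  expect_equal(unname(des4$X[, "intercept"]), rep(1, 4))
  expect_false("cg_size" %in% colnames(des4$X))   # constant -> dropped
  expect_equal(unname(des4$Z),
               matrix(c(1, 1, 0, 0, 0, 0, 1, 1), 4))

  # all animals the same sex: column dropped with a warning
  ph$sex <- 1
  expect_warning(desS <- buildDesign(ph, c("f1", "f2")), "sex")
  expect_false("sex" %in% colnames(desS$X))

  ph$farm[1] <- "f9"
  expect_error(buildDesign(ph, c("f1", "f2")), "f9")
})

test_that("REML with fixed effects only reduces to the analytic solution", {
  set.seed(5)
  ph <- toyPheno(40, "f1", seed = 5)
  ph$age <- 30; ph$sex <- 0                        # intercept-only model
  des <- suppressWarnings(buildDesign(ph, "f1"))
  fit <- remlFit(des, spec = NULL)
  expect_equal(unname(varComp(fit)["sigma_e2"]), var(ph$trait),
               tolerance = 1e-8)
  expect_equal(unname(fixedEffects(fit)["intercept"]), mean(ph$trait),
               tolerance = 1e-8)
})

test_that("AI-REML matches a Nelder-Mead oracle on a tiny instance", {
  n <- 12
  dat <- makeToyData(nAnimals = n, nSnps = 400, nFarms = 2, seed = 21,
                     sigmaG2 = 1.5, sigmaEta2 = 0, sigmaE2 = 1)
  des <- suppressWarnings(buildDesign(dat$pheno, entityIds(dat$herdKernel)))
  spec <- modelSpec("GRM", animalKernel = dat$grm)
  fit <- remlFit(des, spec, tol = 1e-10)

  comps <- list(kernelMatrix(dat$grm)[des$animalIds, des$animalIds])
  orc <- oracleRemlFit(des$X, des$y, comps)
  expect_equal(unname(varComp(fit)[c("sigma_g2", "sigma_e2")]),
               orc$theta, tolerance = 1e-3)
  expect_equal(remlLogLik(fit), orc$logLik, tolerance = 1e-6)
})

test_that("REML recovers simulated variance components within its SEs", {
  dat <- makeToyData(nAnimals = 400, nSnps = 800, nFarms = 20, seed = 31,
                     sigmaG2 = 2, sigmaEta2 = 1, sigmaE2 = 1)
  des <- buildDesign(dat$pheno, entityIds(dat$herdKernel))
  fit <- remlFit(des, modelSpec("GRM_GPS", dat$grm, dat$herdKernel))
  expect_true(fit@converged)
  vc <- varComp(fit); se <- fit@varCompSE
  truth <- c(sigma_g2 = 2, sigma_eta2 = 1, sigma_e2 = 1)
  for (k in names(truth))
    expect_lt(abs(vc[k] - truth[k]), 4 * se[k])
  # interior solution: numerical gradient of the restricted likelihood ~ 0
  comps <- list(g = geoherd:::.alignKernel(dat$grm, des$animalIds, "animal"),
                h = des$Z %*% kernelMatrix(dat$herdKernel) %*% t(des$Z))
  eps <- 1e-4
  for (k in 1:3) {
    th <- unname(vc); thp <- th; thm <- th
    thp[k] <- thp[k] + eps; thm[k] <- max(thm[k] - eps, 1e-10)
    gr <- (oracleRemlLoglik(thp, des$X, des$y, comps) -
           oracleRemlLoglik(thm, des$X, des$y, comps)) / (thp[k] - thm[k])
    expect_lt(abs(gr), 0.05)
  }
})

test_that("BLUP solutions equal a dense Henderson MME inversion", {
  n <- 5
  G <- makePDKernel(n, m = 200, seed = 13)
  ids <- paste0("a", seq_len(n))
  rownames(G@matrix) <- colnames(G@matrix) <- ids
  ph <- toyPheno(n, c("f1", "f2"), seed = 14)
  des <- suppressWarnings(buildDesign(ph, c("f1", "f2")))
  E <- identityKernel(c("f1", "f2"))
  spec <- modelSpec("GRM_FARM", G, E)
  fit <- remlFit(des, spec)
  sol <- blupSolve(fit, des, spec)

  vc <- varComp(fit)
  orc <- oracleMME(des$X, des$y, Zg = diag(n), G = kernelMatrix(G)[des$animalIds, des$animalIds],
                   sigmaG2 = unname(vc["sigma_g2"]), Zh = des$Z,
                   E = diag(2), sigmaEta2 = unname(vc["sigma_eta2"]),
                   sigmaE2 = unname(vc["sigma_e2"]))
  expect_equal(unname(sol$beta), unname(orc$beta), tolerance = 1e-8)
  expect_equal(unname(sol$gBlup), unname(orc$g), tolerance = 1e-8)
  expect_equal(unname(sol$etaBlup), unname(orc$eta), tolerance = 1e-8)
})

test_that("zero herd variance shrinks herd effects to exactly zero", {
  ph <- toyPheno(10, c("f1", "f2"), seed = 3)
  des <- suppressWarnings(buildDesign(ph, c("f1", "f2")))
  E <- identityKernel(c("f1", "f2"))
  fit <- new("ModelFit", modelName = "FARM",
             varComp = c(sigma_eta2 = 0, sigma_e2 = 1),
             varCompSE = c(sigma_eta2 = NA_real_, sigma_e2 = NA_real_),
             beta = numeric(0), gBlup = numeric(0), etaBlup = numeric(0),
             logLik = NA_real_, converged = TRUE, nIter = 0L,
             boundary = "sigma_eta2")
  sol <- blupSolve(fit, des, modelSpec("FARM", herdKernel = E))
  expect_equal(unname(sol$etaBlup), c(0, 0))
})

test_that("FARM and GPS forms coincide when the herd kernel is identity", {
  dat <- makeToyData(nAnimals = 80, nFarms = 8, seed = 17,
                     herdKernel = "identity")
  des <- buildDesign(dat$pheno, entityIds(dat$herdKernel))
  I_F <- identityKernel(entityIds(dat$herdKernel))
  fitFarm <- remlFit(des, modelSpec("GRM_FARM", dat$grm, I_F), tol = 1e-9)
  fitGps <- remlFit(des, modelSpec("GRM_GPS", dat$grm, I_F), tol = 1e-9)
  expect_equal(varComp(fitFarm), varComp(fitGps), tolerance = 1e-8)
  expect_equal(herdEffects(fitFarm), herdEffects(fitGps), tolerance = 1e-8)
})

test_that("fits are invariant to simultaneous permutation of animals", {
  dat <- makeToyData(nAnimals = 60, nFarms = 6, seed = 23)
  des <- buildDesign(dat$pheno, entityIds(dat$herdKernel))
  spec <- modelSpec("GRM_GPS", dat$grm, dat$herdKernel)
  fit1 <- remlFit(des, spec, tol = 1e-9)
  set.seed(1); perm <- sample(60)
  desP <- buildDesign(dat$pheno[perm, ], entityIds(dat$herdKernel))
  fit2 <- remlFit(desP, spec, tol = 1e-9)
  expect_equal(varComp(fit1), varComp(fit2), tolerance = 1e-6)
  expect_equal(breedingValues(fit1)[names(breedingValues(fit2))],
               breedingValues(fit2), tolerance = 1e-6)
})

test_that("scaling the phenotype scales variances but not h2/e2", {
  dat <- makeToyData(nAnimals = 80, nFarms = 8, seed = 29)
  des <- buildDesign(dat$pheno, entityIds(dat$herdKernel))
  spec <- modelSpec("GRM_GPS", dat$grm, dat$herdKernel)
  fit1 <- remlFit(des, spec, tol = 1e-9)
  ph2 <- dat$pheno; ph2$trait <- 3 * ph2$trait
  fit2 <- remlFit(buildDesign(ph2, entityIds(dat$herdKernel)), spec,
                  tol = 1e-9)
  expect_equal(varComp(fit2), 9 * varComp(fit1), tolerance = 1e-4)
  expect_equal(heritability(fit2)[c("h2", "e2")],
               heritability(fit1)[c("h2", "e2")], tolerance = 1e-5)
})

test_that("heritability composes the phenotypic variance per model", {
  mkFit <- function(name, vc) new("ModelFit", modelName = name, varComp = vc,
    varCompSE = setNames(rep(NA_real_, length(vc)), names(vc)),
    beta = numeric(0), gBlup = numeric(0), etaBlup = numeric(0),
    logLik = NA_real_, converged = TRUE, nIter = 1L, boundary = character())
  h <- heritability(mkFit("GRM", c(sigma_g2 = 1, sigma_e2 = 1)))
  expect_equal(unname(h["h2"]), 0.5)
  expect_true(is.na(h["e2"]))
  h2 <- heritability(mkFit("GRM_GPS",
                           c(sigma_g2 = 1, sigma_eta2 = 1, sigma_e2 = 2)))
  expect_equal(unname(h2[c("h2", "e2")]), c(0.25, 0.25))
  h3 <- heritability(mkFit("FARM", c(sigma_eta2 = 0.3, sigma_e2 = 0.7)))
  expect_equal(unname(h3["e2"]), 0.3)
  expect_error(heritability(mkFit("GRM", c(sigma_g2 = 0, sigma_e2 = 0))),
               "undefined")
})

test_that("test-set prediction extends the training BLUPs correctly", {
  dat <- makeToyData(nAnimals = 60, nSnps = 2500, nFarms = 5, seed = 37)
  des <- buildDesign(dat$pheno, entityIds(dat$herdKernel))
  spec <- modelSpec("GRM_GPS", dat$grm, dat$herdKernel)
  fit <- remlFit(des, spec, tol = 1e-9)

  # test set == train set -> predictions equal the training BLUPs
  pr <- predictTest(fit, des, dat$pheno, dat$grm, dat$herdKernel)
  expect_equal(pr$gTilde, breedingValues(fit), tolerance = 1e-10)

  # GRM-only model: y-tilde = X b-hat + g-tilde, no herd term
  specG <- modelSpec("GRM", dat$grm)
  fitG <- remlFit(des, specG, tol = 1e-9)
  prG <- predictTest(fitG, des, dat$pheno, dat$grm)
  expect_equal(prG$yTilde, prG$XbTest + prG$gTilde, tolerance = 1e-12)
  expect_equal(unname(prG$etaTilde), rep(0, 60))

  # held-out animals: conditional-mean extension equals the joint MME
  # solved over all animals with the test records removed
  testIdx <- c(7, 31)
  phTr <- dat$pheno[-testIdx, ]
  desTr <- buildDesign(phTr, entityIds(dat$herdKernel))
  fitTr <- remlFit(desTr, spec, tol = 1e-9)
  prT <- predictTest(fitTr, desTr, dat$pheno[testIdx, ], dat$grm,
                     dat$herdKernel)
  vc <- varComp(fitTr)
  Gm <- kernelMatrix(dat$grm) + diag(1e-8, 60)   # invertible for the oracle
  Em <- kernelMatrix(dat$herdKernel) + diag(1e-8, 5)
  Zg <- diag(60)[-testIdx, ]                     # records only for train
  useEta <- unname(vc["sigma_eta2"]) > 0         # drop boundary components
  orc <- oracleMME(desTr$X, desTr$y, Zg = Zg, G = Gm,
                   sigmaG2 = unname(vc["sigma_g2"]),
                   Zh = if (useEta) desTr$Z else NULL,
                   E = if (useEta) Em else NULL,
                   sigmaEta2 = if (useEta) unname(vc["sigma_eta2"]) else NULL,
                   sigmaE2 = unname(vc["sigma_e2"]))
  expect_equal(unname(prT$gTilde), unname(orc$g[testIdx]), tolerance = 1e-4)
})
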