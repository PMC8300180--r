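# Geodesic distances, the linear standardized-distance kernel, the Matern
# kernel, and PSD repair.

test_that("geodesic distances agree with a haversine oracle", {
  geo <- farmGeo(c("a", "b", "c"), c(0, 0, 37), c(10, 11, 127))
  dst <- farmDistance(geo)
  D <- distMeters(dst)
  expect_equal(diag(D), rep(0, 3), ignore_attr = TRUE)
  expect_equal(D, t(D))

  # 1 degree of longitude at the equator: geodesic within 0.5% of sphere
  hv <- oracleHaversine(0, 10, 0, 11)
  expect_lt(abs(D["a", "b"] - hv) / hv, 0.005)

  # near-antipodal pair stays finite, positive, symmetric
  far <- farmDistance(farmGeo(c("p", "q"), c(10, -10), c(0, 179)))
  expect_true(is.finite(distMeters(far)["p", "q"]))
  expect_gt(distMeters(far)["p", "q"], 1e7)

  expect_error(farmGeo("x", 95, 0), "latitude")
  expect_error(farmDistance(farmGeo("x", 10, 10)), "at least 2")
})

test_that("standardization maps the farthest pair to 1", {
  geo <- farmGeo(paste0("f", 1:5), c(35, 36, 37, 35.5, 36.2),
                 c(127, 127.5, 128, 128.4, 126.9))
  dst <- farmDistance(geo)
  Ds <- distStandardized(dst)
  expect_equal(max(Ds), 1)
  expect_true(all(Ds >= 0 & Ds <= 1))
})

test_that("linear kernel is 1 - D* with the specced endpoints", {
  geo <- farmGeo(paste0("f", 1:4), c(35, 36, 37, 35.5), c(127, 127.5, 128, 128.4))
  dst <- farmDistance(geo)
  E <- kernelMatrix(linearKernel(dst))
  expect_equal(diag(E), rep(1, 4), ignore_attr = TRUE)
  expect_equal(min(E), 0)                      # the pair attaining max(D)
  expect_true(all(E >= 0 & E <= 1))

  # three collinear farms at standardized distances 0, 0.5, 1
  Dm <- matrix(c(0, 50, 100, 50, 0, 50, 100, 50, 0), 3,
               dimnames = list(paste0("f", 1:3), paste0("f", 1:3))) * 1000
  dobj <- new("FarmDistance", meters = Dm, standardized = Dm / max(Dm))
  expect_equal(unname(kernelMatrix(linearKernel(dobj))[1, ]), c(1, 0.5, 0))

  # uniform rescaling of all distances leaves the kernel unchanged
  dobj2 <- new("FarmDistance", meters = 7 * Dm,
               standardized = (7 * Dm) / max(7 * Dm))
  expect_equal(kernelMatrix(linearKernel(dobj2)),
               kernelMatrix(linearKernel(dobj)))

  co <- farmDistance(farmGeo(c("x", "y"), c(10, 10), c(20, 20)))
  expect_error(linearKernel(co), "degenerate geometry")
})

test_that("Matern kernel matches its closed forms and limits", {
  Dm <- matrix(c(0, 2e4, 2e4, 0), 2,
               dimnames = list(c("f1", "f2"), c("f1", "f2")))
  dobj <- new("FarmDistance", meters = Dm, standardized = Dm / max(Dm))

  # nu = 1/2 reduces to the exponential kernel
  rho <- 1.5e4
  Khalf <- kernelMatrix(maternKernel(dobj, nu = 0.5, rho = rho))
  expect_equal(Khalf[1, 2], exp(-2e4 / rho), tolerance = 1e-12)
  expect_equal(diag(Khalf), rep(1, 2), ignore_attr = TRUE)

  # nu = 3/2 at d = rho: (1 + sqrt(3)) exp(-sqrt(3))
  K32 <- kernelMatrix(maternKernel(dobj, nu = 1.5, rho = 2e4))
  expect_equal(K32[1, 2], (1 + sqrt(3)) * exp(-sqrt(3)), tolerance = 1e-10)

  # rho -> Inf approaches all-ones; rho -> 0 approaches identity
  expect_equal(kernelMatrix(maternKernel(dobj, nu = 1.5, rho = 1e12))[1, 2],
               1, tolerance = 1e-4)
  expect_equal(kernelMatrix(maternKernel(dobj, nu = 1.5, rho = 1e-6))[1, 2],
               0, tolerance = 1e-12)

  expect_error(maternKernel(dobj, nu = -1), "nu")
  expect_error(maternKernel(dobj, nu = 0.5, rho = 0), "rho")
})

test_that("PSD repair clips negative eigenvalues minimally", {
  ok <- identityKernel(c("a", "b"))
  fixed <- ensurePSD(ok)
  expect_false(fixed@repaired)
  expect_identical(kernelMatrix(fixed), kernelMatrix(ok))

  m <- matrix(c(1, 1.2, 1.2, 1), 2, dimnames = list(c("x", "y"), c("x", "y")))
  K <- covarianceKernel(m, kind = "custom")
  rep <- ensurePSD(K)
  expect_true(rep@repaired)
  expect_equal(rep@minEigenvalue, -0.2, tolerance = 1e-12)
  ev <- eigen(kernelMatrix(rep), symmetric = TRUE)$values
  expect_equal(ev, c(2.2, 0), tolerance = 1e-12)
  expect_equal(kernelMatrix(rep),
               matrix(1.1, 2, 2, dimnames = dimnames(m)), tolerance = 1e-12)
  # single negative eigenvalue: ||repair - original||_F = |lambda_min|
  expect_equal(norm(kernelMatrix(rep) - m, "F"), 0.2, tolerance = 1e-12)
})

test_that("compact geography yields near-one linear kernel entries", {
  set.seed(3)
  geo <- farmGeo(paste0("f", 1:30), runif(30, 36, 36.3), runif(30, 127, 127.3))
  # make one distant pair dominate the standardization
  geo@latitude[1] <- 33; geo@longitude[1] <- 125
  E <- kernelMatrix(linearKernel(farmDistance(geo)))
  inner <- E[-1, -1]
  expect_gt(mean(inner[upper.tri(inner)]), 0.9)
})
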