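## Farm-level covariance kernels from GPS coordinates.

#' Pairwise geodesic distances between farms
#'
#' Computes the WGS84 ellipsoidal geodesic distance (meters) between every
#' pair of farms via \code{geosphere::distm(fun = distGeo)}, and the
#' standardized matrix D* = D / max(D) whose entries lie in [0, 1].
#'
#' @param geo a [FarmGeo-class].
#' @return A [FarmDistance-class].
#' @examples
#' geo <- farmGeo(c("a", "b"), c(36, 36), c(127, 128))
#' distMeters(farmDistance(geo))
#' @export
farmDistance <- function(geo) {
  stopifnot(is(geo, "FarmGeo"))
  if (length(farmIds(geo)) < 2L)
    stop("need at least 2 farms to compute pairwise distances")
  ## geosphere expects (lon, lat) columns
  pts <- cbind(geo@longitude, geo@latitude)
  D <- geosphere::distm(pts, fun = geosphere::distGeo)
  D <- (D + t(D)) / 2
  diag(D) <- 0
  dimnames(D) <- list(farmIds(geo), farmIds(geo))
  mx <- max(D)
  Dstar <- if (mx > 0) D / mx else D
  new("FarmDistance", meters = D, standardized = Dstar)
}

#' Linear (standardized-distance) herd covariance kernel
#'
#' E_ij = 1 - D*_ij where D* is the geodesic distance standardized by the
#' maximum pairwise distance: identical locations have covariance 1, the
#' farthest pair has covariance 0, and covariance decreases linearly with
#' distance. The construction does not guarantee positive semi-definiteness;
#' pass the result through [ensurePSD()] before model fitting.
#'
#' @param dist a [FarmDistance-class].
#' @return A [CovarianceKernel-class] of kind "gps_linear".
#' @export
linearKernel <- function(dist) {
  stopifnot(is(dist, "FarmDistance"))
  if (max(dist@meters) <= 0)
    stop("degenerate geometry: all farms coincide (max distance is 0)")
  E <- 1 - dist@standardized
  covarianceKernel(E, kind = "gps_linear")
}

#' Matern herd covariance kernel
#'
#' K(d) = 2^(1-nu)/Gamma(nu) * (sqrt(2 nu) d / rho)^nu *
#' BesselK(sqrt(2 nu) d / rho, nu), with K(0) = 1. nu = 1/2 gives the
#' exponential kernel exp(-d/rho); nu -> infinity approaches the Gaussian
#' kernel. Positive semi-definite by construction for any point set.
#'
#' @param dist a [FarmDistance-class].
#' @param nu smoothness (> 0), default 3/2.
#' @param rho range in meters (> 0); default half the maximum inter-farm
#'   distance.
#' @return A [CovarianceKernel-class] of kind "matern".
#' @export
maternKernel <- function(dist, nu = 1.5, rho = NULL) {
  stopifnot(is(dist, "FarmDistance"))
  if (is.null(rho)) rho <- max(dist@meters) / 2
  if (!is.numeric(nu) || nu <= 0) stop("Matern smoothness nu must be > 0")
  if (!is.numeric(rho) || rho <= 0) stop("Matern range rho must be > 0")
  d <- dist@meters
  s <- sqrt(2 * nu) * d / rho
  K <- matrix(1, nrow(d), ncol(d), dimnames = dimnames(d))
  pos <- s > 0
  K[pos] <- 2^(1 - nu) / gamma(nu) * s[pos]^nu * besselK(s[pos], nu)
  K[!is.finite(K)] <- 0                  # far-field underflow of BesselK
  K <- (K + t(K)) / 2
  diag(K) <- 1
  covarianceKernel(K, kind = "matern")
}

#' Repair a kernel to positive semi-definiteness
#'
#' Eigendecomposes the kernel, clips eigenvalues below zero to zero, and
#' reconstitutes the matrix — the nearest PSD matrix in Frobenius norm.
#' Inputs already PSD (all eigenvalues >= -tol) are returned unchanged.
#' The repair is recorded in the \code{repaired} and \code{minEigenvalue}
#' slots so users can see when the linear GPS kernel needed fixing.
#'
#' @param K a [CovarianceKernel-class].
#' @param tol eigenvalues above \code{-tol} are considered nonnegative
#'   (default 1e-8, relative to the largest eigenvalue).
#' @return A [CovarianceKernel-class], possibly repaired.
#' @export
ensurePSD <- function(K, tol = 1e-8) {
  stopifnot(is(K, "CovarianceKernel"))
  m <- kernelMatrix(K)
  e <- eigen(m, symmetric = TRUE)
  minEig <- min(e$values)
  K@minEigenvalue <- minEig
  if (minEig >= -tol * max(abs(e$values), 1)) return(K)
  lam <- pmax(e$values, 0)
  m2 <- e$vectors %*% (lam * t(e$vectors))
  m2 <- (m2 + t(m2)) / 2
  dimnames(m2) <- dimnames(m)
  K@matrix <- m2
  K@repaired <- TRUE
  K
}
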