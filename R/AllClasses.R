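#' @import methods
#' @importFrom stats cor optim plnorm ptukey rbinom rlnorm rnorm runif sd setNames var
#' @importFrom tools md5sum
NULL

setClassUnion("kernelOrNULL", "NULL")

#' Genotype dosage matrix with allele frequencies
#'
#' Holds an animals x SNPs matrix of allele dosages coded 0/1/2 (NA for
#' missing), with animal and SNP identifiers as dimnames and per-SNP
#' reference allele frequencies estimated from the non-missing dosages.
#'
#' @slot dosages numeric matrix, animals in rows, SNPs in columns, values in
#'   \{0, 1, 2, NA\}.
#' @slot alleleFreqs numeric vector of per-SNP allele frequencies in [0, 1],
#'   one per column of \code{dosages}.
#'
#' @seealso [genotypeData()], [qcFilter()], [computeGRM()]
#' @export
setClass("GenotypeData",
  representation(dosages = "matrix", alleleFreqs = "numeric"),
  validity = function(object) {
    d <- object@dosages
    msg <- character()
    if (is.null(rownames(d)) || is.null(colnames(d)))
      msg <- c(msg, "dosages must have animal row names and SNP column names")
    else {
      if (anyDuplicated(rownames(d))) msg <- c(msg, "animal ids must be unique")
      if (anyDuplicated(colnames(d))) msg <- c(msg, "SNP ids must be unique")
    }
    v <- d[!is.na(d)]
    if (length(v) && !all(v %in% c(0, 1, 2)))
      msg <- c(msg, "dosages must be coded 0/1/2 (NA for missing)")
    if (length(object@alleleFreqs) != ncol(d))
      msg <- c(msg, "alleleFreqs length must equal number of SNPs")
    if (length(msg)) msg else TRUE
  }
)

#' Symmetric covariance kernel over animals or farms
#'
#' A symmetric positive semi-definite covariance matrix with entity
#' identifiers as dimnames. \code{kind} records its construction:
#' \code{"grm"} (genomic relationship matrix over animals),
#' \code{"farm_identity"} (independent herds), \code{"gps_linear"}
#' (1 - standardized geodesic distance) or \code{"matern"}.
#'
#' @slot matrix symmetric numeric matrix with identical row/col names.
#' @slot kind character, one of grm, farm_identity, gps_linear, matern,
#'   identity, custom.
#' @slot repaired logical, whether eigenvalue clipping was applied by
#'   [ensurePSD()].
#' @slot minEigenvalue numeric, most negative eigenvalue found before repair
#'   (NA if never checked).
#'
#' @export
setClass("CovarianceKernel",
  representation(matrix = "matrix", kind = "character",
                 repaired = "logical", minEigenvalue = "numeric"),
  prototype(repaired = FALSE, minEigenvalue = NA_real_, kind = "custom"),
  validity = function(object) {
    m <- object@matrix
    msg <- character()
    if (nrow(m) != ncol(m)) msg <- c(msg, "kernel must be square")
    if (is.null(rownames(m)))
      msg <- c(msg, "kernel must carry entity ids as dimnames")
    else if (!identical(rownames(m), colnames(m)))
      msg <- c(msg, "row and column ids must match")
    else if (anyDuplicated(rownames(m)))
      msg <- c(msg, "entity ids must be unique")
    if (nrow(m) && max(abs(m - t(m))) > 1e-8 * max(1, max(abs(m))))
      msg <- c(msg, "kernel must be symmetric")
    if (length(msg)) msg else TRUE
  }
)
setIs("CovarianceKernel", "kernelOrNULL")

#' Farm GPS coordinates
#'
#' Farm identifiers with latitude/longitude in decimal degrees (WGS84).
#'
#' @slot farmIds character vector of unique farm identifiers.
#' @slot latitude,longitude numeric, decimal degrees; latitude in
#'   [-90, 90], longitude in [-180, 180].
#'
#' @export
setClass("FarmGeo",
  representation(farmIds = "character", latitude = "numeric",
                 longitude = "numeric"),
  validity = function(object) {
    msg <- character()
    n <- length(object@farmIds)
    if (anyDuplicated(object@farmIds)) msg <- c(msg, "farm ids must be unique")
    if (length(object@latitude) != n || length(object@longitude) != n)
      msg <- c(msg, "latitude/longitude must match farmIds in length")
    if (any(abs(object@latitude) > 90, na.rm = TRUE))
      msg <- c(msg, "latitude out of [-90, 90]")
    if (any(abs(object@longitude) > 180, na.rm = TRUE))
      msg <- c(msg, "longitude out of [-180, 180]")
    if (length(msg)) msg else TRUE
  }
)

#' Pairwise geodesic farm distances
#'
#' Raw WGS84 geodesic distances in meters (\code{meters}) and the
#' standardized version \code{standardized = meters / max(meters)} whose
#' largest entry is exactly 1.
#'
#' @slot meters symmetric nonnegative matrix of distances in meters, zero
#'   diagonal, farm ids as dimnames.
#' @slot standardized the same matrix divided by its maximum.
#'
#' @export
setClass("FarmDistance",
  representation(meters = "matrix", standardized = "matrix"),
  validity = function(object) {
    D <- object@meters
    msg <- character()
    if (nrow(D) != ncol(D)) msg <- c(msg, "distance matrix must be square")
    if (any(D < 0)) msg <- c(msg, "distances must be nonnegative")
    if (nrow(D) && max(abs(diag(D))) > 1e-9)
      msg <- c(msg, "diagonal must be zero")
    if (nrow(D) && max(abs(D - t(D))) > 1e-6)
      msg <- c(msg, "distance matrix must be symmetric")
    if (!identical(dim(D), dim(object@standardized)))
      msg <- c(msg, "standardized matrix must match meters in dimension")
    if (length(msg)) msg else TRUE
  }
)

#' Model specification for the herd-effect GBLUP variants
#'
#' Names one of the five model forms and carries the covariance kernels its
#' random terms use: \code{GRM} (breeding values only), \code{FARM}
#' (independent herd effects only), \code{GPS} (correlated herd effects
#' only), \code{GRM_FARM} and \code{GRM_GPS} (both terms).
#'
#' @slot name model name.
#' @slot animalKernel genomic relationship [CovarianceKernel-class] or NULL.
#' @slot herdKernel farm-level [CovarianceKernel-class] or NULL.
#'
#' @export
setClass("ModelSpec",
  representation(name = "character", animalKernel = "kernelOrNULL",
                 herdKernel = "kernelOrNULL"),
  validity = function(object) {
    msg <- character()
    valid <- c("GRM", "FARM", "GPS", "GRM_FARM", "GRM_GPS")
    if (!object@name %in% valid)
      msg <- c(msg, paste("name must be one of", paste(valid, collapse = ", ")))
    needsG <- object@name %in% c("GRM", "GRM_FARM", "GRM_GPS")
    needsH <- object@name != "GRM"
    if (needsG && is.null(object@animalKernel))
      msg <- c(msg, paste(object@name, "requires an animal kernel"))
    if (needsH && is.null(object@herdKernel))
      msg <- c(msg, paste(object@name, "requires a herd kernel"))
    if (is.null(object@animalKernel) && is.null(object@herdKernel))
      msg <- c(msg, "at least one random kernel must be present")
    if (length(msg)) msg else TRUE
  }
)

#' Fitted mixed model: REML variance components and BLUPs
#'
#' @slot modelName one of GRM, FARM, GPS, GRM_FARM, GRM_GPS.
#' @slot varComp named numeric vector of variance components; names are a
#'   subset of \code{sigma_g2}, \code{sigma_eta2}, \code{sigma_e2}.
#'   Components absent from the model are absent from the vector.
#' @slot varCompSE approximate standard errors from the inverse
#'   average-information matrix (NA for components fixed at the boundary).
#' @slot beta named fixed-effect solutions.
#' @slot gBlup named vector of animal breeding-value BLUPs (length 0 when
#'   the model has no genomic term).
#' @slot etaBlup named vector of herd-effect BLUPs (length 0 when absent).
#' @slot logLik restricted log-likelihood at the estimates.
#' @slot converged logical convergence flag.
#' @slot nIter iterations used.
#' @slot boundary names of components fixed at the zero boundary.
#'
#' @export
setClass("ModelFit",
  representation(modelName = "character", varComp = "numeric",
                 varCompSE = "numeric", beta = "numeric", gBlup = "numeric",
                 etaBlup = "numeric", logLik = "numeric",
                 converged = "logical", nIter = "integer",
                 boundary = "character"),
  validity = function(object) {
    msg <- character()
    if (any(object@varComp < 0)) msg <- c(msg, "variance components must be >= 0")
    ok <- c("sigma_g2", "sigma_eta2", "sigma_e2")
    if (!all(names(object@varComp) %in% ok))
      msg <- c(msg, "varComp names must be among sigma_g2, sigma_eta2, sigma_e2")
    if (length(msg)) msg else TRUE
  }
)

#' Configuration for the synthetic herd-structured population
#'
#' Defines the simulated population: genotypes under Hardy-Weinberg
#' equilibrium, farms scattered over a geographic rectangle with a
#' configurable farm-size law, and phenotypes generated from the additive
#' model y = Xb + g + Z eta + epsilon with multivariate-normal breeding
#' values and (possibly spatially correlated) herd effects.
#'
#' @slot nAnimals,nSnps,nFarms population dimensions.
#' @slot farmSizeLaw "uniform" (near-equal herd sizes) or "table1_skewed"
#'   (discretized log-normal matched to the heavily skewed herd-size
#'   distribution of the motivating beef-cattle population: most herds under
#'   10 animals, a few above 100).
#' @slot regionBounds numeric c(latMin, latMax, lonMin, lonMax) in decimal
#'   degrees; defaults to a South-Korea-like rectangle.
#' @slot sigmaG2,sigmaEta2,sigmaE2 genomic, herd and residual variances
#'   (trait units squared).
#' @slot herdKernel "identity", "linear_gps" or "matern" — covariance of the
#'   simulated herd effects.
#' @slot maternNu,maternRho Matern smoothness and range (meters) when
#'   \code{herdKernel = "matern"}.
#' @slot fixedEffects named numeric c(intercept, age, sex, cg_size) —
#'   regression coefficients of the fixed part Xb.
#' @slot mafRange length-2 numeric, allele frequencies drawn uniformly in
#'   this interval (equal endpoints give a point mass).
#' @slot missingRate fraction of dosages set missing completely at random.
#' @slot seed integer seed making every draw reproducible.
#'
#' @seealso [simConfig()], [simulateGenotypes()], [simulateFarms()],
#'   [simulatePhenotypes()]
#' @export
setClass("SimConfig",
  representation(nAnimals = "integer", nSnps = "integer", nFarms = "integer",
                 farmSizeLaw = "character", regionBounds = "numeric",
                 sigmaG2 = "numeric", sigmaEta2 = "numeric",
                 sigmaE2 = "numeric", herdKernel = "character",
                 maternNu = "numeric", maternRho = "numeric",
                 fixedEffects = "numeric", mafRange = "numeric",
                 missingRate = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@nAnimals < 1L) msg <- c(msg, "nAnimals must be >= 1")
    if (object@nFarms > object@nAnimals)
      msg <- c(msg, "nFarms must not exceed nAnimals")
    if (any(c(object@sigmaG2, object@sigmaEta2, object@sigmaE2) < 0))
      msg <- c(msg, "variances must be >= 0")
    if (!object@farmSizeLaw %in% c("uniform", "table1_skewed"))
      msg <- c(msg, "farmSizeLaw must be 'uniform' or 'table1_skewed'")
    if (!object@herdKernel %in% c("identity", "linear_gps", "matern"))
      msg <- c(msg, "herdKernel must be identity, linear_gps or matern")
    rb <- object@regionBounds
    if (length(rb) != 4 || rb[1] > rb[2] || rb[3] > rb[4] ||
        abs(rb[1]) > 90 || abs(rb[2]) > 90 || abs(rb[3]) > 180 || abs(rb[4]) > 180)
      msg <- c(msg, "regionBounds must be c(latMin, latMax, lonMin, lonMax) within valid ranges")
    mr <- object@mafRange
    if (length(mr) != 2 || mr[1] <= 0 || mr[2] > 0.5 || mr[1] > mr[2])
      msg <- c(msg, "mafRange must lie in (0, 0.5] with min <= max")
    if (object@missingRate < 0 || object@missingRate >= 1)
      msg <- c(msg, "missingRate must be in [0, 1)")
    if (length(msg)) msg else TRUE
  }
)

## ---- show methods ---------------------------------------------------------

setMethod("show", "GenotypeData", function(object) {
  d <- object@dosages
  cat("GenotypeData:", nrow(d), "animals x", ncol(d), "SNPs\n")
  nm <- sum(is.na(d))
  cat(sprintf("  missing dosages: %d (%.2f%%)\n", nm, 100 * nm / length(d)))
  if (ncol(d))
    cat(sprintf("  allele freq range: [%.3f, %.3f]\n",
                min(object@alleleFreqs), max(object@alleleFreqs)))
})

setMethod("show", "CovarianceKernel", function(object) {
  cat(sprintf("CovarianceKernel <%s>: %d x %d\n", object@kind,
              nrow(object@matrix), ncol(object@matrix)))
  if (nrow(object@matrix))
    cat(sprintf("  mean diagonal: %.4f\n", mean(diag(object@matrix))))
  if (isTRUE(object@repaired))
    cat(sprintf("  PSD-repaired (most negative eigenvalue %.3e)\n",
                object@minEigenvalue))
})

setMethod("show", "FarmGeo", function(object) {
  cat("FarmGeo:", length(object@farmIds), "farms\n")
  if (length(object@farmIds))
    cat(sprintf("  lat [%.3f, %.3f], lon [%.3f, %.3f]\n",
                min(object@latitude), max(object@latitude),
                min(object@longitude), max(object@longitude)))
})

setMethod("show", "FarmDistance", function(object) {
  cat("FarmDistance:", nrow(object@meters), "farms\n")
  if (nrow(object@meters) > 1)
    cat(sprintf("  max pairwise distance: %.1f km\n",
                max(object@meters) / 1000))
})

setMethod("show", "ModelSpec", function(object) {
  cat("ModelSpec:", object@name, "\n")
  if (!is.null(object@animalKernel))
    cat("  animal kernel:", object@animalKernel@kind,
        paste0("(", nrow(object@animalKernel@matrix), " animals)\n"))
  if (!is.null(object@herdKernel))
    cat("  herd kernel:", object@herdKernel@kind,
        paste0("(", nrow(object@herdKernel@matrix), " farms)\n"))
})

setMethod("show", "ModelFit", function(object) {
  cat("ModelFit:", object@modelName,
      if (object@converged) "(converged" else "(NOT converged",
      paste0("in ", object@nIter, " iterations)\n"))
  vc <- object@varComp
  se <- object@varCompSE[names(vc)]
  for (k in names(vc))
    cat(sprintf("  %-10s %8.4f  (SE %s)%s\n", k, vc[k],
                ifelse(is.na(se[k]), "--", sprintf("%.4f", se[k])),
                if (k %in% object@boundary) "  [boundary]" else ""))
  cat(sprintf("  REML logLik: %.4f\n", object@logLik))
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nAnimals, "animals,", object@nSnps, "SNPs,",
      object@nFarms, "farms\n")
  cat(sprintf("  farm sizes: %s; herd kernel: %s\n",
              object@farmSizeLaw, object@herdKernel))
  cat(sprintf("  sigma_g2 = %.3g, sigma_eta2 = %.3g, sigma_e2 = %.3g; seed = %d\n",
              object@sigmaG2, object@sigmaEta2, object@sigmaE2, object@seed))
})
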