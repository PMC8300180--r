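## Constructors and accessor generics for the S4 classes.

#' Construct a GenotypeData object
#'
#' @param dosages numeric matrix of allele dosages (0/1/2, NA = missing),
#'   animals in rows. Row/column names are used as animal/SNP ids; default
#'   ids are generated when absent.
#'
#' @return A [GenotypeData-class] object with allele frequencies estimated
#'   as column means of non-missing dosages divided by 2.
#' @examples
#' m <- matrix(c(0, 1, 2, 1, 0, 1), nrow = 2)
#' genotypeData(m)
#' @export
genotypeData <- function(dosages) {
  dosages <- as.matrix(dosages)
  if (is.null(rownames(dosages)))
    rownames(dosages) <- paste0("animal_", seq_len(nrow(dosages)))
  if (is.null(colnames(dosages)))
    colnames(dosages) <- paste0("snp_", seq_len(ncol(dosages)))
  p <- colMeans(dosages, na.rm = TRUE) / 2
  p[is.nan(p)] <- NA_real_
  new("GenotypeData", dosages = dosages, alleleFreqs = unname(p))
}

#' Construct a CovarianceKernel
#'
#' @param m symmetric numeric matrix; dimnames are the entity ids (defaults
#'   generated when absent).
#' @param kind construction label, e.g. "grm", "farm_identity",
#'   "gps_linear", "matern", "identity", "custom".
#' @param repaired,minEigenvalue PSD-repair bookkeeping, see [ensurePSD()].
#' @return A [CovarianceKernel-class].
#' @export
covarianceKernel <- function(m, kind = "custom", repaired = FALSE,
                             minEigenvalue = NA_real_) {
  m <- as.matrix(m)
  if (is.null(rownames(m))) {
    ids <- colnames(m)
    if (is.null(ids)) ids <- paste0("entity_", seq_len(nrow(m)))
    dimnames(m) <- list(ids, ids)
  } else if (is.null(colnames(m))) colnames(m) <- rownames(m)
  new("CovarianceKernel", matrix = m, kind = kind, repaired = repaired,
      minEigenvalue = minEigenvalue)
}

#' Identity kernel over a set of entities
#'
#' Covariance of independent herd effects (the FARM model's herd kernel).
#'
#' @param ids character vector of entity (farm) ids.
#' @return A [CovarianceKernel-class] with an identity matrix.
#' @export
identityKernel <- function(ids) {
  ids <- as.character(ids)
  m <- diag(length(ids))
  dimnames(m) <- list(ids, ids)
  covarianceKernel(m, kind = "farm_identity")
}

#' Construct a FarmGeo object
#'
#' @param farmIds character farm identifiers.
#' @param latitude,longitude decimal degrees (WGS84). Note the (lat, lon)
#'   order — many GIS tools use (lon, lat).
#' @return A [FarmGeo-class].
#' @export
farmGeo <- function(farmIds, latitude, longitude) {
  new("FarmGeo", farmIds = as.character(farmIds),
      latitude = as.numeric(latitude), longitude = as.numeric(longitude))
}

#' Specify one of the five prediction models
#'
#' @param name "GRM", "FARM", "GPS", "GRM_FARM" or "GRM_GPS" (aliases
#'   "GRM+FARM"/"GRM+GPS" accepted).
#' @param animalKernel genomic relationship kernel (required for GRM*).
#' @param herdKernel farm-level kernel (required for all but GRM); for
#'   FARM/GRM_FARM an identity kernel, for GPS/GRM_GPS a distance-derived
#'   kernel.
#' @return A [ModelSpec-class].
#' @export
modelSpec <- function(name, animalKernel = NULL, herdKernel = NULL) {
  name <- toupper(gsub("[+ ]", "_", name))
  new("ModelSpec", name = name, animalKernel = animalKernel,
      herdKernel = herdKernel)
}

#' @rdname accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))
#' @rdname accessors
#' @export
setGeneric("alleleFreqs", function(x) standardGeneric("alleleFreqs"))
#' @rdname accessors
#' @export
setGeneric("animalIds", function(x) standardGeneric("animalIds"))
#' @rdname accessors
#' @export
setGeneric("snpIds", function(x) standardGeneric("snpIds"))
#' @rdname accessors
#' @export
setGeneric("kernelMatrix", function(x) standardGeneric("kernelMatrix"))
#' @rdname accessors
#' @export
setGeneric("kernelKind", function(x) standardGeneric("kernelKind"))
#' @rdname accessors
#' @export
setGeneric("entityIds", function(x) standardGeneric("entityIds"))
#' @rdname accessors
#' @export
setGeneric("farmIds", function(x) standardGeneric("farmIds"))
#' @rdname accessors
#' @export
setGeneric("distMeters", function(x) standardGeneric("distMeters"))
#' @rdname accessors
#' @export
setGeneric("distStandardized", function(x) standardGeneric("distStandardized"))
#' @rdname accessors
#' @export
setGeneric("varComp", function(x) standardGeneric("varComp"))
#' @rdname accessors
#' @export
setGeneric("fixedEffects", function(x) standardGeneric("fixedEffects"))
#' @rdname accessors
#' @export
setGeneric("breedingValues", function(x) standardGeneric("breedingValues"))
#' @rdname accessors
#' @export
setGeneric("herdEffects", function(x) standardGeneric("herdEffects"))
#' @rdname accessors
#' @export
setGeneric("remlLogLik", function(x) standardGeneric("remlLogLik"))

#' Accessors for geoherd S4 classes
#'
#' Small read-only accessors: \code{dosages}, \code{alleleFreqs},
#' \code{animalIds}, \code{snpIds} for [GenotypeData-class];
#' \code{kernelMatrix}, \code{kernelKind}, \code{entityIds} for
#' [CovarianceKernel-class]; \code{farmIds} for [FarmGeo-class];
#' \code{distMeters}, \code{distStandardized} for [FarmDistance-class];
#' \code{varComp}, \code{fixedEffects}, \code{breedingValues},
#' \code{herdEffects}, \code{remlLogLik} for [ModelFit-class].
#'
#' @param x the object.
#' @name accessors
#' @aliases dosages alleleFreqs animalIds snpIds kernelMatrix kernelKind
#'   entityIds farmIds distMeters distStandardized varComp fixedEffects
#'   breedingValues herdEffects remlLogLik
NULL

setMethod("dosages", "GenotypeData", function(x) x@dosages)
setMethod("alleleFreqs", "GenotypeData", function(x)
  setNames(x@alleleFreqs, colnames(x@dosages)))
setMethod("animalIds", "GenotypeData", function(x) rownames(x@dosages))
setMethod("snpIds", "GenotypeData", function(x) colnames(x@dosages))
setMethod("kernelMatrix", "CovarianceKernel", function(x) x@matrix)
setMethod("kernelKind", "CovarianceKernel", function(x) x@kind)
setMethod("entityIds", "CovarianceKernel", function(x) rownames(x@matrix))
setMethod("farmIds", "FarmGeo", function(x) x@farmIds)
setMethod("distMeters", "FarmDistance", function(x) x@meters)
setMethod("distStandardized", "FarmDistance", function(x) x@standardized)
setMethod("varComp", "ModelFit", function(x) x@varComp)
setMethod("fixedEffects", "ModelFit", function(x) x@beta)
setMethod("breedingValues", "ModelFit", function(x) x@gBlup)
setMethod("herdEffects", "ModelFit", function(x) x@etaBlup)
setMethod("remlLogLik", "ModelFit", function(x) x@logLik)
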