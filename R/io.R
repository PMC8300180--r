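## File-format readers and writers. All tabular I/O is UTF-8 CSV with
## explicit headers; genotypes are additionally readable from the PLINK
## .raw dialect. Farm coordinate files use (lat, lon) column order in
## decimal degrees — note that many GIS tools use (lon, lat).

#' Read genotypes from a PLINK .raw file
#'
#' Expects the standard --recode A layout: header row with FID IID PAT MAT
#' SEX PHENOTYPE followed by one column per SNP; dosages 0/1/2 with NA for
#' missing. The IID column provides animal ids.
#'
#' @param path file path (whitespace-separated, uncompressed).
#' @return A [GenotypeData-class].
#' @export
readGenotypeRaw <- function(path) {
  tab <- utils::read.table(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  meta <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (!all(meta %in% names(tab)))
    stop("malformed .raw header: expected columns ",
         paste(meta, collapse = " "))
  snps <- setdiff(names(tab), meta)
  if (!length(snps)) stop("no SNP columns found in ", path)
  d <- as.matrix(tab[, snps, drop = FALSE])
  storage.mode(d) <- "numeric"
  rownames(d) <- as.character(tab$IID)
  genotypeData(d)
}

#' Read genotypes from a plain CSV matrix
#'
#' First column = animal id, remaining columns = SNP dosages 0/1/2 (empty
#' or NA for missing), header row carries SNP ids.
#'
#' @param path CSV file path.
#' @return A [GenotypeData-class].
#' @export
readGenotypeCSV <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("genotype CSV needs an id column plus SNP columns")
  d <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(d) <- "numeric"
  rownames(d) <- as.character(tab[[1]])
  genotypeData(d)
}

#' @rdname readGenotypeCSV
#' @param geno a [GenotypeData-class] to write.
#' @export
writeGenotypeCSV <- function(geno, path) {
  d <- dosages(geno)
  out <- data.frame(animal = rownames(d), d, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a phenotype table
#'
#' CSV with columns animal, farm, trait, age, sex, cg_size.
#'
#' @param path CSV file path.
#' @return data.frame suitable for [buildDesign()].
#' @export
readPhenotypes <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal", "farm", "trait", "age", "sex", "cg_size")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("phenotype CSV lacks columns: ", paste(miss, collapse = ", "))
  tab$animal <- as.character(tab$animal)
  tab$farm <- as.character(tab$farm)
  tab
}

#' @rdname readPhenotypes
#' @param pheno phenotype data.frame to write.
#' @export
writePhenotypes <- function(pheno, path) {
  utils::write.csv(pheno, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read farm GPS coordinates
#'
#' CSV with columns farm, lat, lon — latitude before longitude, decimal
#' degrees WGS84.
#'
#' @param path CSV file path.
#' @return A [FarmGeo-class].
#' @export
readFarmGPS <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("farm", "lat", "lon")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("farm GPS CSV lacks columns: ", paste(miss, collapse = ", "),
         " (expected farm, lat, lon)")
  farmGeo(tab$farm, tab$lat, tab$lon)
}

#' @rdname readFarmGPS
#' @param geo a [FarmGeo-class] to write.
#' @export
writeFarmGPS <- function(geo, path) {
  utils::write.csv(data.frame(farm = farmIds(geo), lat = geo@latitude,
                              lon = geo@longitude),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write/read a covariance kernel as square CSV
#'
#' The first column holds entity ids, the header repeats them; values are
#' written with full double precision so a round trip reproduces the
#' kernel to better than 1e-12.
#'
#' @param K a [CovarianceKernel-class].
#' @param path CSV file path.
#' @param kind kernel kind to stamp on the re-read object.
#' @export
writeKernelCSV <- function(K, path) {
  m <- kernelMatrix(K)
  out <- data.frame(id = rownames(m),
                    format(m, digits = 17, trim = TRUE, scientific = TRUE),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeKernelCSV
#' @export
readKernelCSV <- function(path, kind = "custom") {
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "numeric"
  rownames(m) <- as.character(tab[[1]])
  m <- (m + t(m)) / 2                    # symmetrize away print round-off
  covarianceKernel(m, kind = kind)
}

#' Write a simulated dataset to disk
#'
#' Writes the genotype CSV, phenotype CSV, farm GPS CSV and a truth JSON
#' (variance components, fixed-effect coefficients, per-animal breeding
#' values and per-farm herd effects) into a directory.
#'
#' @param dat output of [simulateHerdData()].
#' @param dir output directory (created if needed).
#' @return invisible character vector of the files written.
#' @export
writeSimulation <- function(dat, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  truth <- attr(dat$pheno, "truth")
  cfg <- dat$config
  files <- c(
    genotypes = writeGenotypeCSV(dat$geno, file.path(dir, "genotypes.csv")),
    phenotypes = writePhenotypes(dat$pheno, file.path(dir, "phenotypes.csv")),
    gps = writeFarmGPS(dat$geo, file.path(dir, "farm_gps.csv")))
  truthPath <- file.path(dir, "truth.json")
  jsonlite::write_json(list(
    sigma_g2 = cfg@sigmaG2, sigma_eta2 = cfg@sigmaEta2,
    sigma_e2 = cfg@sigmaE2, herd_kernel = cfg@herdKernel,
    seed = cfg@seed, beta = as.list(truth$beta),
    g = as.list(truth$g), eta = as.list(truth$eta)),
    truthPath, auto_unbox = TRUE, digits = NA)
  invisible(c(files, truth = truthPath))
}

#' Write a run manifest
#'
#' Records input file hashes, the seed, package version and timings so a
#' run can be re-executed and checked byte for byte.
#'
#' @param path output JSON path.
#' @param inputs named character vector of input file paths (hashed).
#' @param seed integer seed of the run.
#' @param extra optional named list merged into the manifest.
#' @export
writeManifest <- function(path, inputs = character(), seed = NA_integer_,
                          extra = list()) {
  hashes <- lapply(inputs, function(f)
    if (file.exists(f)) unname(tools::md5sum(f)) else NA_character_)
  manifest <- c(list(
    package = "geoherd",
    version = as.character(utils::packageVersion("geoherd")),
    seed = seed, timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    inputs = hashes), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
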