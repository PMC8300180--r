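## Genotype QC and genomic relationship matrix (VanRaden method 1).

#' Quality-control filter for SNP genotypes
#'
#' Removes individuals with too many missing genotypes, then recomputes
#' allele frequencies and removes SNPs with low minor allele frequency.
#' Individuals are filtered first because their removal changes the
#' per-SNP allele frequencies on which the MAF filter operates.
#'
#' @param geno a [GenotypeData-class].
#' @param mafMin minimum minor allele frequency to keep a SNP (default 0.01).
#' @param maxIndMissing maximum tolerated fraction of missing genotypes per
#'   individual (default 0.02).
#' @param verbose print a removal report.
#'
#' @return A filtered [GenotypeData-class] with attribute \code{"qcReport"}
#'   (list: \code{animalsRemoved}, \code{snpsRemoved}).
#' @examples
#' g <- simulateGenotypes(simConfig(nAnimals = 20, nSnps = 50, seed = 1))
#' qcFilter(g, mafMin = 0.05)
#' @export
qcFilter <- function(geno, mafMin = 0.01, maxIndMissing = 0.02,
                     verbose = FALSE) {
  stopifnot(is(geno, "GenotypeData"))
  if (mafMin < 0 || mafMin > 0.5)
    stop("mafMin must be in [0, 0.5]")
  if (maxIndMissing < 0 || maxIndMissing > 1)
    stop("maxIndMissing must be in [0, 1]")
  d <- dosages(geno)

  indMiss <- rowMeans(is.na(d))
  keepInd <- indMiss <= maxIndMissing
  d <- d[keepInd, , drop = FALSE]
  if (nrow(d) == 0L) stop("all individuals removed by missingness filter")

  p <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(p)] <- 0          # SNPs with no calls carry no information
  keepSnp <- maf >= mafMin
  if (!any(keepSnp))
    stop("empty panel: all SNPs removed by the MAF filter")
  d <- d[, keepSnp, drop = FALSE]

  out <- genotypeData(d)
  attr(out, "qcReport") <- list(animalsRemoved = sum(!keepInd),
                                snpsRemoved = sum(!keepSnp))
  if (verbose)
    message(sprintf("QC: removed %d individuals (> %.1f%% missing), %d SNPs (MAF < %g)",
                    sum(!keepInd), 100 * maxIndMissing, sum(!keepSnp), mafMin))
  out
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' G = W W' / (2 * sum p_j (1 - p_j)) where W is the dosage matrix centred
#' by twice the allele frequency of each SNP. Under Hardy-Weinberg
#' equilibrium the mean diagonal is close to 1. Missing dosages are imputed
#' by the SNP mean (2 p_j) before centring, which maps them to zero in W.
#'
#' @param geno a [GenotypeData-class]; allele frequencies are taken from the
#'   current sample.
#' @return A [CovarianceKernel-class] of kind "grm" over the animals.
#' @examples
#' g <- simulateGenotypes(simConfig(nAnimals = 50, nSnps = 500, seed = 1))
#' G <- computeGRM(g)
#' mean(diag(kernelMatrix(G)))
#' @export
computeGRM <- function(geno) {
  stopifnot(is(geno, "GenotypeData"))
  d <- dosages(geno)
  p <- colMeans(d, na.rm = TRUE) / 2
  poly <- !is.nan(p) & p > 0 & p < 1
  if (sum(poly) < 1L)
    stop("cannot build GRM: no polymorphic SNPs (2*sum(p(1-p)) would be 0)")
  d <- d[, poly, drop = FALSE]
  p <- p[poly]
  W <- sweep(d, 2L, 2 * p)
  W[is.na(W)] <- 0                       # mean imputation, centred scale
  denom <- 2 * sum(p * (1 - p))
  G <- tcrossprod(W) / denom
  G <- (G + t(G)) / 2
  covarianceKernel(G, kind = "grm")
}

#' Principal components of a covariance kernel
#'
#' Eigendecomposes a symmetric kernel and returns scores
#' \eqn{U \Lambda^{1/2}} in descending eigenvalue order, the standard PCA
#' of a relationship matrix. Eigenvector signs are fixed so that each
#' column's largest-magnitude element is positive.
#'
#' @param K a [CovarianceKernel-class].
#' @param nComponents number of components to return.
#' @return list with \code{scores} (entities x components, rownames = ids),
#'   \code{values} (all eigenvalues, descending), and \code{varExplained}
#'   (fractions, nonnegative part).
#' @export
kernelPCA <- function(K, nComponents = 2L) {
  stopifnot(is(K, "CovarianceKernel"))
  m <- kernelMatrix(K)
  if (nComponents > nrow(m))
    stop("nComponents exceeds the kernel dimension")
  e <- eigen(m, symmetric = TRUE)
  U <- e$vectors[, seq_len(nComponents), drop = FALSE]
  for (j in seq_len(ncol(U))) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) U[, j] <- -U[, j]
  }
  lam <- pmax(e$values[seq_len(nComponents)], 0)
  scores <- sweep(U, 2L, sqrt(lam), "*")
  dimnames(scores) <- list(entityIds(K), paste0("PC", seq_len(nComponents)))
  pos <- pmax(e$values, 0)
  list(scores = scores, values = e$values,
       varExplained = if (sum(pos) > 0) pos / sum(pos) else pos)
}
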