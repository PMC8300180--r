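## Eigenstructure-based confounding diagnostic between the genomic
## relationship structure and the herd covariance structure.

#' Animal-level herd covariance structure
#'
#' Lifts a farm-level kernel to animal level: W = Z K Z', the n x n
#' covariance structure the herd term induces across animals. With the
#' identity kernel this is the block matrix of shared-herd indicators
#' (ZZ'); with a GPS-derived kernel it is Z E Z'.
#'
#' @param Z n x F herd incidence matrix (one 1 per row), as built by
#'   [buildDesign()].
#' @param herdKernel a farm-level [CovarianceKernel-class].
#' @return An animal-level [CovarianceKernel-class].
#' @export
animalHerdCovariance <- function(Z, herdKernel) {
  stopifnot(is(herdKernel, "CovarianceKernel"))
  K <- kernelMatrix(herdKernel)
  if (ncol(Z) != nrow(K))
    stop("Z has ", ncol(Z), " farm columns but the kernel is ",
         nrow(K), " x ", nrow(K))
  W <- Z %*% K %*% t(Z)
  W <- (W + t(W)) / 2
  ids <- rownames(Z)
  if (is.null(ids)) ids <- paste0("animal_", seq_len(nrow(Z)))
  dimnames(W) <- list(ids, ids)
  covarianceKernel(W, kind = "custom")
}

#' Kappa confounding statistic between two covariance structures
#'
#' For each eigenvector U_eta,i of the herd structure W_eta, the statistic
#' kappa_i = sum_j (U_eta,i' U_G,j)^2 lambda_G,j measures how much of G's
#' variance lies along that direction (algebraically,
#' kappa_i = U_eta,i' G U_eta,i). When kappa is approximately 1 everywhere
#' there is no confounding between the structures; when kappa aligns with
#' the herd eigenvalues lambda_eta the two structures are confounded. The
#' completeness identity sum(kappa) = trace(G) always holds.
#'
#' Within blocks of tied herd eigenvalues the individual kappa values
#' depend on the (arbitrary) orthonormal basis of the eigenspace; block
#' sums are rotation-invariant and are reported alongside.
#'
#' @param Weta animal-level herd structure (from [animalHerdCovariance()]).
#' @param G genomic relationship [CovarianceKernel-class] over the same
#'   animals.
#' @param tieTol relative tolerance for declaring herd eigenvalues tied.
#' @return list: \code{kappa} (n values), \code{lambdaEta} (herd-structure
#'   eigenvalues, descending), \code{lambdaG}, \code{alignment}
#'   (correlation of kappa with lambdaEta), \code{blocks} (data.frame of
#'   tied-eigenvalue blocks with rotation-invariant kappa sums), and
#'   \code{scatter} (data.frame lambda_eta, kappa, ready for plotting or
#'   CSV export).
#' @export
kappaStatistic <- function(Weta, G, tieTol = 1e-8) {
  stopifnot(is(Weta, "CovarianceKernel"), is(G, "CovarianceKernel"))
  Wm <- kernelMatrix(Weta); Gm <- kernelMatrix(G)
  if (!all(dim(Wm) == dim(Gm)))
    stop("structures differ in dimension: ", nrow(Wm), " vs ", nrow(Gm))
  eEta <- eigen(Wm, symmetric = TRUE)
  eG <- eigen(Gm, symmetric = TRUE)
  ## kappa_i = U_eta,i' G U_eta,i  (= sum_j (U_eta,i' U_G,j)^2 lambda_G,j)
  kappa <- colSums(eEta$vectors * (Gm %*% eEta$vectors))
  lamEta <- eEta$values
  alignment <- .safeCor(kappa, lamEta)

  scale <- max(abs(lamEta), 1)
  blockId <- cumsum(c(TRUE, diff(lamEta) < -tieTol * scale))
  blocks <- data.frame(block = unique(blockId))
  blocks$lambdaEta <- tapply(lamEta, blockId, mean)
  blocks$size <- as.integer(table(blockId))
  blocks$kappaSum <- tapply(kappa, blockId, sum)

  list(kappa = kappa, lambdaEta = lamEta, lambdaG = eG$values,
       alignment = alignment, blocks = blocks,
       scatter = data.frame(lambda_eta = lamEta, kappa = kappa))
}
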