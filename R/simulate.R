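## Synthetic population generator: HWE genotypes, farms on a map with a
## skewed size distribution, and phenotypes from y = Xb + g + Z eta + eps.

#' Build a simulation configuration
#'
#' Defaults describe a desk-scale version of a commercial beef-cattle
#' population: a few hundred animals on tens of farms inside a compact
#' South-Korea-like region, four-ish fixed effects (intercept, age in
#' months, sex, contemporary-group size), heritability and
#' environmentability in the 0.2-0.4 / 0.05-0.5 ranges typical of carcass
#' traits, and herd effects correlated through the linear GPS kernel.
#'
#' @param nAnimals,nSnps,nFarms population dimensions.
#' @param farmSizeLaw "uniform" or "table1_skewed" (discretized log-normal
#'   with most herds under 10 animals and a long upper tail).
#' @param regionBounds c(latMin, latMax, lonMin, lonMax) decimal degrees.
#' @param sigmaG2,sigmaEta2,sigmaE2 genomic, herd and residual variances.
#' @param herdKernel "identity", "linear_gps" or "matern" for the simulated
#'   herd-effect covariance.
#' @param maternNu,maternRho Matern parameters (rho in meters, NULL = half
#'   the maximum inter-farm distance).
#' @param fixedEffects named coefficients c(intercept, age, sex, cg_size).
#' @param mafRange allele frequencies are drawn uniformly in this interval;
#'   equal endpoints give a point mass.
#' @param missingRate fraction of dosages set to NA completely at random.
#' @param seed integer master seed.
#' @return A [SimConfig-class].
#' @examples
#' simConfig(nAnimals = 100, nFarms = 10, seed = 42)
#' @export
simConfig <- function(nAnimals = 400L, nSnps = 1000L, nFarms = 40L,
                      farmSizeLaw = "table1_skewed",
                      regionBounds = c(34.5, 38.0, 126.5, 129.0),
                      sigmaG2 = 0.3, sigmaEta2 = 0.2, sigmaE2 = 0.5,
                      herdKernel = "linear_gps",
                      maternNu = 1.5, maternRho = NULL,
                      fixedEffects = c(intercept = 0, age = 0.05,
                                       sex = 0.5, cg_size = 0.002),
                      mafRange = c(0.05, 0.5), missingRate = 0,
                      seed = 1L) {
  if (length(nSnps) != 1L || nSnps < 1L)
    stop("configuration error: nSnps must be >= 1")
  if (length(mafRange) != 2L || mafRange[1] <= 0)
    stop("configuration error: MAF law must be bounded away from 0")
  new("SimConfig",
      nAnimals = as.integer(nAnimals), nSnps = as.integer(nSnps),
      nFarms = as.integer(nFarms), farmSizeLaw = farmSizeLaw,
      regionBounds = as.numeric(regionBounds),
      sigmaG2 = sigmaG2, sigmaEta2 = sigmaEta2, sigmaE2 = sigmaE2,
      herdKernel = herdKernel, maternNu = maternNu,
      maternRho = if (is.null(maternRho)) NA_real_ else maternRho,
      fixedEffects = fixedEffects, mafRange = as.numeric(mafRange),
      missingRate = missingRate, seed = as.integer(seed))
}

#' Simulate SNP genotypes under Hardy-Weinberg equilibrium
#'
#' Each SNP j gets an allele frequency p_j drawn from the configured MAF
#' law; dosages are Binomial(2, p_j), independently across animals and SNPs
#' (no linkage disequilibrium). A fraction \code{missingRate} of entries is
#' then set missing completely at random.
#'
#' @param config a [SimConfig-class].
#' @return A [GenotypeData-class].
#' @export
simulateGenotypes <- function(config) {
  stopifnot(is(config, "SimConfig"))
  set.seed(config@seed)
  n <- config@nAnimals; m <- config@nSnps
  p <- runif(m, config@mafRange[1], config@mafRange[2])
  d <- matrix(rbinom(n * m, 2L, rep(p, each = n)), nrow = n, ncol = m)
  if (config@missingRate > 0) {
    nmiss <- round(config@missingRate * length(d))
    d[sample.int(length(d), nmiss)] <- NA_integer_
  }
  dimnames(d) <- list(sprintf("animal_%04d", seq_len(n)),
                      sprintf("snp_%05d", seq_len(m)))
  genotypeData(d)
}

## Herd-size bins of the motivating population (size range -> farm count):
## <=5: 41, 6-10: 34, 11-20: 14, 21-50: 22, 51-100: 8, 101-350: 4, >350: 1.
.herdSizeBins <- data.frame(lo = c(1, 6, 11, 21, 51, 101, 351),
                            hi = c(5, 10, 20, 50, 100, 350, Inf),
                            farms = c(41, 34, 14, 22, 8, 4, 1))

## Least-squares fit of a discretized log-normal to the herd-size bin
## proportions above. Cached after first use.
.simEnv <- new.env(parent = emptyenv())
.fitHerdSizeLognormal <- function() {
  if (!is.null(.simEnv$lnormFit)) return(.simEnv$lnormFit)
  b <- .herdSizeBins
  prop <- b$farms / sum(b$farms)
  obj <- function(par) {
    mu <- par[1]; sg <- exp(par[2])
    pr <- plnorm(b$hi + 0.5, mu, sg) - plnorm(pmax(b$lo - 0.5, 0), mu, sg)
    sum((pr - prop)^2)
  }
  fit <- optim(c(2, log(1.5)), obj, method = "Nelder-Mead")
  .simEnv$lnormFit <- c(meanlog = fit$par[1], sdlog = exp(fit$par[2]))
  .simEnv$lnormFit
}

#' Simulate farm locations and animal-to-farm assignment
#'
#' Farm coordinates are uniform in the configured lat/lon rectangle.
#' Animal counts per farm follow the configured law: "uniform" splits the
#' animals as evenly as possible; "table1_skewed" draws relative sizes from
#' a discretized log-normal fitted by least squares to the motivating
#' population's herd-size histogram (most farms tiny, a long upper tail),
#' then allocates animals multinomially in proportion. Every farm receives
#' at least one animal.
#'
#' @param config a [SimConfig-class].
#' @return list with \code{geo} ([FarmGeo-class]), \code{assignment}
#'   (character vector, one farm id per animal, named by animal id) and
#'   \code{sizes} (named integer farm sizes).
#' @export
simulateFarms <- function(config) {
  stopifnot(is(config, "SimConfig"))
  n <- config@nAnimals; F <- config@nFarms
  if (F < 2L) stop("configuration error: need at least 2 farms")
  if (n < F) stop("configuration error: nAnimals < nFarms leaves empty farms")
  set.seed(config@seed + 1000003L)
  rb <- config@regionBounds
  ids <- sprintf("farm_%03d", seq_len(F))
  geo <- farmGeo(ids, runif(F, rb[1], rb[2]), runif(F, rb[3], rb[4]))

  counts <- integer(F)
  if (config@farmSizeLaw == "uniform") {
    counts <- rep(n %/% F, F)
    extra <- n - sum(counts)
    if (extra > 0) counts[sample.int(F, extra)] <- counts[sample.int(F, extra)] + 1L
  } else {
    par <- .fitHerdSizeLognormal()
    counts <- pmax(round(rlnorm(F, par["meanlog"], par["sdlog"])), 1L)
    diff <- n - sum(counts)
    if (diff > 0) {
      ## surplus animals go to the upper tail (the size law's body cannot
      ## produce the lone mega-herd of the target histogram)
      add <- tabulate(sample.int(F, diff, replace = TRUE,
                                 prob = as.numeric(counts)^2), F)
      counts <- counts + add
    } else if (diff < 0) {
      for (i in seq_len(-diff)) {        # shrink the largest herds first
        j <- which.max(counts)
        counts[j] <- counts[j] - 1L
      }
      counts <- pmax(counts, 1L)
      while (sum(counts) > n) {          # guard: re-trim if the floor bit
        j <- which.max(counts); counts[j] <- counts[j] - 1L
      }
    }
  }
  assignment <- rep(ids, counts)[sample.int(n)]    # shuffle animal order
  names(assignment) <- sprintf("animal_%04d", seq_len(n))
  list(geo = geo, assignment = assignment,
       sizes = setNames(as.integer(table(factor(assignment, levels = ids))), ids))
}

## Draw one N(0, sigma2 * K) vector from a PSD kernel via eigendecomposition.
.rmvnormKernel <- function(K, sigma2, kernelName = "kernel") {
  n <- nrow(K)
  if (sigma2 == 0) return(numeric(n))
  e <- eigen(K, symmetric = TRUE)
  if (min(e$values) < -1e-6 * max(abs(e$values), 1))
    stop(sprintf("kernel '%s' is not positive semi-definite (min eigenvalue %.3e)",
                 kernelName, min(e$values)))
  lam <- pmax(e$values, 0)
  drop(e$vectors %*% (sqrt(lam * sigma2) * rnorm(n)))
}

#' Simulate phenotypes from the additive herd-effect model
#'
#' Draws g ~ N(0, G sigma_g2), eta ~ N(0, E sigma_eta2) and
#' eps ~ N(0, I sigma_e2) independently and forms
#' y = X b + g + Z eta + eps. The fixed-effect design X holds an
#' intercept, age (uniform integers 25-35 months), sex (bull = 0 / steer =
#' 1, steer fraction 3810/4168) and the realized contemporary-group (herd)
#' size. The realized g, eta, eps, X and b are kept as simulation truth.
#'
#' @param G animal [CovarianceKernel-class] (n x n).
#' @param herdKernel farm [CovarianceKernel-class] (F x F).
#' @param assignment character vector mapping each animal (names) to a farm
#'   id present in \code{herdKernel}.
#' @param config a [SimConfig-class].
#' @return data.frame (animal, farm, trait, age, sex, cg_size) with
#'   attribute \code{"truth"}: list(g, eta, eps, beta, Xb, X).
#' @export
simulatePhenotypes <- function(G, herdKernel, assignment, config) {
  stopifnot(is(G, "CovarianceKernel"), is(herdKernel, "CovarianceKernel"),
            is(config, "SimConfig"))
  n <- length(assignment)
  if (nrow(kernelMatrix(G)) != n)
    stop("animal kernel dimension does not match the assignment length")
  farms <- entityIds(herdKernel)
  if (!all(assignment %in% farms))
    stop("assignment references farms absent from the herd kernel: ",
         paste(utils::head(setdiff(assignment, farms), 3), collapse = ", "))
  set.seed(config@seed + 2000003L)

  steerFrac <- 3810 / 4168
  age <- sample(25:35, n, replace = TRUE)
  sex <- rbinom(n, 1L, steerFrac)
  cg <- as.integer(table(factor(assignment, levels = farms))[assignment])
  b <- config@fixedEffects
  X <- cbind(intercept = 1, age = age, sex = sex, cg_size = cg)
  Xb <- drop(X %*% b[colnames(X)])

  g <- .rmvnormKernel(kernelMatrix(G), config@sigmaG2, "G")
  eta <- .rmvnormKernel(kernelMatrix(herdKernel), config@sigmaEta2,
                        kernelKind(herdKernel))
  names(eta) <- farms
  eps <- rnorm(n, 0, sqrt(config@sigmaE2))
  y <- Xb + g + eta[assignment] + eps

  ids <- names(assignment)
  if (is.null(ids)) ids <- sprintf("animal_%04d", seq_len(n))
  out <- data.frame(animal = ids, farm = unname(assignment), trait = y,
                    age = age, sex = sex, cg_size = cg,
                    stringsAsFactors = FALSE)
  attr(out, "truth") <- list(g = setNames(g, ids), eta = eta,
                             eps = setNames(eps, ids), beta = b, Xb = Xb, X = X)
  out
}

#' Simulate a complete herd-structured dataset
#'
#' Convenience pipeline: genotypes -> GRM, farms -> geodesic distances ->
#' herd kernel of the configured family, then phenotypes. The returned
#' pieces plug directly into [buildDesign()], [remlFit()] and
#' [crossValidate()].
#'
#' @param config a [SimConfig-class].
#' @return list: \code{geno}, \code{grm}, \code{geo}, \code{dist},
#'   \code{herdKernel}, \code{assignment}, \code{pheno} (with truth
#'   attribute), \code{config}.
#' @examples
#' dat <- simulateHerdData(simConfig(nAnimals = 60, nSnps = 200,
#'                                   nFarms = 6, seed = 7))
#' str(attr(dat$pheno, "truth")$beta)
#' @export
simulateHerdData <- function(config) {
  stopifnot(is(config, "SimConfig"))
  geno <- simulateGenotypes(config)
  grm <- computeGRM(geno)
  fm <- simulateFarms(config)
  dst <- farmDistance(fm$geo)
  hk <- switch(config@herdKernel,
    identity = identityKernel(farmIds(fm$geo)),
    linear_gps = ensurePSD(linearKernel(dst)),
    matern = maternKernel(dst, nu = config@maternNu,
                          rho = if (is.na(config@maternRho)) NULL
                                else config@maternRho))
  rownames(grm@matrix) <- colnames(grm@matrix) <- names(fm$assignment)
  pheno <- simulatePhenotypes(grm, hk, fm$assignment, config)
  list(geno = geno, grm = grm, geo = fm$geo, dist = dst, herdKernel = hk,
       assignment = fm$assignment, pheno = pheno, config = config)
}
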