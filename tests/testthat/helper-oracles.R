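# Independent oracle implementations used to cross-check the package.
# These deliberately avoid the package's own code paths: plain solve() /
# determinant() linear algebra, general-purpose optimizers, and textbook
# formulas.

# Restricted log-likelihood of y ~ N(Xb, sum_k theta_k A_k + theta_e I),
# computed with base solve()/determinant() (no Cholesky shortcuts).
oracleRemlLoglik <- function(theta, X, y, comps) {
  n <- length(y); p <- ncol(X)
  V <- diag(theta[length(theta)], n)
  for (k in seq_along(comps)) V <- V + theta[k] * comps[[k]]
  Vinv <- solve(V)
  XtVX <- t(X) %*% Vinv %*% X
  beta <- solve(XtVX, t(X) %*% Vinv %*% y)
  r <- y - X %*% beta
  as.numeric(-0.5 * ((n - p) * log(2 * pi) +
                     determinant(V, logarithm = TRUE)$modulus +
                     determinant(XtVX, logarithm = TRUE)$modulus +
                     t(r) %*% Vinv %*% r))
}

# Brute-force REML: Nelder-Mead on log-variances, multi-start.
oracleRemlFit <- function(X, y, comps, starts = NULL) {
  nPar <- length(comps) + 1L
  if (is.null(starts))
    starts <- list(rep(var(y) / nPar, nPar),
                   rep(var(y), nPar),
                   c(rep(var(y) / 10, nPar - 1), var(y)))
  best <- NULL
  for (s in starts) {
    opt <- optim(log(s), function(lp)
      -oracleRemlLoglik(exp(lp), X, y, comps),
      method = "Nelder-Mead",
      control = list(maxit = 5000, reltol = 1e-14))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  list(theta = exp(best$par), logLik = -best$value)
}

# Henderson's mixed model equations solved by one dense inversion.
# Random terms: g with covariance sigmaG2 * G and incidence Zg (identity
# for an animal model; a selector matrix when some animals have no
# records), and eta with covariance sigmaEta2 * E and incidence Zh.
# Either term may be NULL.
oracleMME <- function(X, y, Zg = NULL, G = NULL, sigmaG2 = NULL,
                      Zh = NULL, E = NULL, sigmaEta2 = NULL, sigmaE2) {
  blocks <- list(X)
  if (!is.null(Zg)) blocks <- c(blocks, list(Zg))
  if (!is.null(Zh)) blocks <- c(blocks, list(Zh))
  W <- do.call(cbind, blocks)
  C <- crossprod(W) / sigmaE2
  rhs <- crossprod(W, y) / sigmaE2
  off <- ncol(X)
  if (!is.null(Zg)) {
    idx <- off + seq_len(ncol(Zg))
    C[idx, idx] <- C[idx, idx] + solve(G) / sigmaG2
    off <- off + ncol(Zg)
  }
  if (!is.null(Zh)) {
    idx <- off + seq_len(ncol(Zh))
    C[idx, idx] <- C[idx, idx] + solve(E) / sigmaEta2
  }
  sol <- drop(solve(C, rhs))
  out <- list(beta = sol[seq_len(ncol(X))])
  off <- ncol(X)
  if (!is.null(Zg)) { out$g <- sol[off + seq_len(ncol(Zg))]; off <- off + ncol(Zg) }
  if (!is.null(Zh)) out$eta <- sol[off + seq_len(ncol(Zh))]
  out
}

# Great-circle distance on a 6371 km sphere.
oracleHaversine <- function(lat1, lon1, lat2, lon2, R = 6371000) {
  toRad <- pi / 180
  dlat <- (lat2 - lat1) * toRad; dlon <- (lon2 - lon1) * toRad
  a <- sin(dlat / 2)^2 + cos(lat1 * toRad) * cos(lat2 * toRad) * sin(dlon / 2)^2
  2 * R * asin(sqrt(a))
}

# Small simulated dataset shared across tests.
makeToyData <- function(nAnimals = 120, nSnps = 400, nFarms = 10, seed = 42,
                        sigmaG2 = 1, sigmaEta2 = 0.5, sigmaE2 = 1,
                        herdKernel = "linear_gps", ...) {
  simulateHerdData(simConfig(nAnimals = nAnimals, nSnps = nSnps,
                             nFarms = nFarms, seed = seed,
                             sigmaG2 = sigmaG2, sigmaEta2 = sigmaEta2,
                             sigmaE2 = sigmaE2, herdKernel = herdKernel, ...))
}

# A deterministic PD kernel from a seeded SNP panel.
makePDKernel <- function(n, m = 40 * n, seed = 1) {
  g <- simulateGenotypes(simConfig(nAnimals = n, nSnps = m, nFarms = 2,
                                   seed = seed))
  K <- computeGRM(g)
  Km <- kernelMatrix(K) + diag(1e-3, n)   # keep strictly PD for inversion
  covarianceKernel(Km, kind = "grm")
}
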