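## Mixed-model machinery: design construction, AI-REML variance-component
## estimation, BLUP solving via the GLS/conditional-expectation form, and
## prediction for held-out animals.

#' Build fixed-effect and herd design matrices
#'
#' X columns are intercept, age, sex and contemporary-group size; columns
#' (other than the intercept) that are constant in the data are dropped
#' with a warning to preserve full column rank. Z is the n x F herd
#' incidence matrix in the order of \code{farmLevels}, one 1 per row.
#'
#' @param pheno data.frame with columns animal, farm, trait, age, sex,
#'   cg_size (as produced by [simulatePhenotypes()] or [readPhenotypes()]).
#' @param farmLevels character vector of farm ids fixing the column order
#'   of Z (usually the herd kernel's entity ids).
#' @return list with \code{X}, \code{Z}, \code{y}, \code{animalIds},
#'   \code{farmLevels}.
#' @export
buildDesign <- function(pheno, farmLevels = sort(unique(pheno$farm))) {
  need <- c("animal", "farm", "trait", "age", "sex", "cg_size")
  miss <- setdiff(need, names(pheno))
  if (length(miss))
    stop("phenotype table lacks columns: ", paste(miss, collapse = ", "))
  unknown <- setdiff(unique(pheno$farm), farmLevels)
  if (length(unknown))
    stop("phenotypes reference farms absent from the kernel: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  if (anyNA(pheno[need]))
    stop("missing values in phenotype/covariate columns are not supported")
  n <- nrow(pheno)
  X <- cbind(intercept = 1, age = as.numeric(pheno$age),
             sex = as.numeric(pheno$sex), cg_size = as.numeric(pheno$cg_size))
  keep <- c(TRUE, apply(X[, -1, drop = FALSE], 2L,
                        function(col) length(unique(col)) > 1L))
  if (!all(keep)) {
    warning("dropping constant fixed-effect column(s): ",
            paste(colnames(X)[!keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  f <- factor(pheno$farm, levels = farmLevels)
  Z <- matrix(0, n, length(farmLevels),
              dimnames = list(pheno$animal, farmLevels))
  Z[cbind(seq_len(n), as.integer(f))] <- 1
  list(X = X, Z = Z, y = as.numeric(pheno$trait),
       animalIds = as.character(pheno$animal), farmLevels = farmLevels)
}

## Reorder a kernel matrix to a given id vector, erroring on absent ids.
.alignKernel <- function(K, ids, what) {
  m <- kernelMatrix(K)
  missing <- setdiff(ids, rownames(m))
  if (length(missing))
    stop(what, " kernel lacks ids: ", paste(utils::head(missing, 5), collapse = ", "))
  m[ids, ids, drop = FALSE]
}

## Assemble the list of n x n covariance structures for a model spec.
.varStructures <- function(design, spec) {
  comps <- list()
  if (!is.null(spec) && !is.null(spec@animalKernel))
    comps$sigma_g2 <- .alignKernel(spec@animalKernel, design$animalIds, "animal")
  if (!is.null(spec) && !is.null(spec@herdKernel)) {
    E <- .alignKernel(spec@herdKernel, design$farmLevels, "herd")
    comps$sigma_eta2 <- design$Z %*% E %*% t(design$Z)
  }
  comps
}

## One evaluation of the REML quantities at variance components theta.
## Returns P, Py, logLik, and the GLS beta-hat.
.remlEval <- function(theta, X, y, comps) {
  n <- length(y)
  V <- diag(theta[["sigma_e2"]], n)
  for (k in names(comps)) V <- V + theta[[k]] * comps[[k]]
  cV <- tryCatch(chol(V), error = function(e)
    stop("covariance matrix not positive definite at theta = ",
         paste(signif(unlist(theta), 4), collapse = ", ")))
  Vinv <- chol2inv(cV)
  VinvX <- Vinv %*% X
  XtVX <- crossprod(X, VinvX)
  cXtVX <- tryCatch(chol(XtVX), error = function(e)
    stop("singular fixed-effect design (X'V^-1 X not invertible)"))
  beta <- drop(chol2inv(cXtVX) %*% crossprod(VinvX, y))
  P <- Vinv - VinvX %*% chol2inv(cXtVX) %*% t(VinvX)
  P <- (P + t(P)) / 2
  Py <- drop(P %*% y)
  p <- ncol(X)
  ll <- -0.5 * ((n - p) * log(2 * pi) + 2 * sum(log(diag(cV))) +
                2 * sum(log(diag(cXtVX))) + sum(y * Py))
  list(P = P, Py = Py, logLik = ll, beta = setNames(beta, colnames(X)))
}

#' REML variance components by average information with EM fallback
#'
#' Maximizes the restricted likelihood of
#' y ~ N(X b, sigma_g2 G + sigma_eta2 Z E Z' + sigma_e2 I) for whichever
#' random terms the model spec includes, by Newton steps on the
#' average-information (AI) matrix. When an AI step would leave the
#' parameter space, the guaranteed-ascent EM update
#' theta + theta^2/n * (y'P A P y - tr(P A)) is used instead. Components
#' shrinking to the zero boundary are fixed at 0 and flagged. Approximate
#' standard errors come from the inverse AI matrix at convergence.
#'
#' @param design output of [buildDesign()].
#' @param spec a [ModelSpec-class], or NULL for a fixed-effects-only model
#'   (residual variance then equals the ordinary least-squares
#'   RSS / (n - p), the analytic REML solution).
#' @param tol convergence tolerance on the change in restricted
#'   log-likelihood (default 1e-6).
#' @param maxIter maximum iterations (default 200).
#' @param startVal optional named starting values.
#' @return A [ModelFit-class] including BLUPs of all included random terms.
#' @examples
#' dat <- simulateHerdData(simConfig(nAnimals = 80, nSnps = 300,
#'                                   nFarms = 8, seed = 3))
#' des <- buildDesign(dat$pheno, entityIds(dat$herdKernel))
#' fit <- remlFit(des, modelSpec("GRM_GPS", dat$grm, dat$herdKernel))
#' varComp(fit)
#' @export
remlFit <- function(design, spec, tol = 1e-6, maxIter = 200L,
                    startVal = NULL) {
  X <- design$X; y <- design$y; n <- length(y)
  if (n <= ncol(X)) stop("need more observations than fixed effects")
  comps <- .varStructures(design, spec)
  parNames <- c(names(comps), "sigma_e2")
  vy <- var(y)
  theta <- setNames(rep(vy / length(parNames), length(parNames)), parNames)
  if (!is.null(startVal)) theta[names(startVal)] <- startVal
  floorVal <- 1e-8 * max(vy, .Machine$double.eps)
  evalSafe <- function(th) tryCatch(.remlEval(as.list(th), X, y, comps),
                                    error = function(e) NULL)

  ## AI-REML loop over the components not fixed at the boundary. Steps are
  ## accepted only if the restricted likelihood does not decrease
  ## (step-halving line search); components the AI step drives negative
  ## decay geometrically toward zero instead.
  aiLoop <- function(theta, boundary) {
    free <- setdiff(parNames, boundary)
    theta[boundary] <- 0
    ev <- .remlEval(as.list(theta), X, y, comps)
    llOld <- ev$logLik
    converged <- FALSE
    iter <- 0L
    AIfree <- NULL
    while (iter < maxIter && length(free)) {
      iter <- iter + 1L
      Py <- ev$Py; P <- ev$P
      score <- numeric(length(free)); names(score) <- free
      quads <- trs <- score
      Av <- list()                       # A_k %*% Py per free component
      for (k in free) {
        Ak <- if (k == "sigma_e2") NULL else comps[[k]]
        if (is.null(Ak)) {
          trs[k] <- sum(diag(P)); quads[k] <- sum(Py * Py); Av[[k]] <- Py
        } else {
          trs[k] <- sum(P * Ak)
          Av[[k]] <- drop(Ak %*% Py)
          quads[k] <- sum(Py * Av[[k]])
        }
        score[k] <- -0.5 * (trs[k] - quads[k])
      }
      AI <- matrix(0, length(free), length(free),
                   dimnames = list(free, free))
      W <- vapply(Av, function(v) drop(P %*% v), numeric(n))  # P A_k P y
      for (i in seq_along(free)) for (j in i:length(free)) {
        AI[i, j] <- AI[j, i] <- 0.5 * sum(Av[[free[i]]] * W[, free[j]])
      }
      AIfree <- AI

      delta <- tryCatch(solve(AI, score), error = function(e) NULL)
      proposal <- theta
      clamped <- FALSE
      neg <- character()
      if (!is.null(delta)) {
        proposal[free] <- theta[free] + delta
        neg <- free[proposal[free] < 0]
        if (length(neg)) {
          proposal[neg] <- theta[neg] / 10
          clamped <- TRUE
        }
      } else {                           # EM step if AI matrix is singular
        proposal[free] <- theta[free] +
          theta[free]^2 / n * (quads[free] - trs[free])
        clamped <- TRUE
      }
      proposal["sigma_e2"] <- max(proposal["sigma_e2"], floorVal)
      evNew <- evalSafe(proposal)
      halvings <- 0L
      relax <- setdiff(free, neg)        # decayed components stay put
      while ((is.null(evNew) || evNew$logLik < llOld - 1e-8) &&
             halvings < 15L) {
        proposal[relax] <- (proposal[relax] + theta[relax]) / 2
        evNew <- evalSafe(proposal)
        halvings <- halvings + 1L
        clamped <- TRUE
      }
      if (is.null(evNew) || evNew$logLik < llOld - 1e-8) {
        proposal <- theta; evNew <- ev   # no admissible step this round
      }

      hitZero <- setdiff(free[proposal[free] < floorVal], "sigma_e2")
      if (length(hitZero)) {
        proposal[hitZero] <- 0
        boundary <- union(boundary, hitZero)
        free <- setdiff(free, hitZero)
        evNew <- .remlEval(as.list(proposal), X, y, comps)
      }
      theta <- proposal
      ev <- evNew
      if (!clamped && abs(ev$logLik - llOld) < tol) { converged <- TRUE; break }
      llOld <- ev$logLik
    }
    list(theta = theta, boundary = boundary, free = free, ev = ev,
         converged = converged, iter = iter, AI = AIfree)
  }

  run <- aiLoop(theta, character())
  ## boundary polish: a component lingering near zero is tested against
  ## the profiled fit with it fixed at the boundary; the higher restricted
  ## likelihood wins
  for (k in setdiff(run$free, "sigma_e2")) {
    if (run$theta[k] < 1e-3 * vy) {
      alt <- aiLoop(run$theta, union(run$boundary, k))
      if (alt$ev$logLik >= run$ev$logLik - tol) {
        alt$iter <- alt$iter + run$iter
        run <- alt
      }
    }
  }
  theta <- run$theta
  boundary <- run$boundary
  ev <- run$ev
  converged <- run$converged
  iter <- run$iter

  ## standard errors from the inverse AI matrix of the free components
  se <- setNames(rep(NA_real_, length(parNames)), parNames)
  if (length(run$free) && !is.null(run$AI)) {
    AIinv <- tryCatch(solve(run$AI[run$free, run$free, drop = FALSE]),
                      error = function(e) NULL)
    if (!is.null(AIinv)) se[run$free] <- sqrt(pmax(diag(AIinv), 0))
  }

  ## BLUPs at the final estimates (conditional-expectation form)
  gB <- numeric(0); eB <- numeric(0)
  if ("sigma_g2" %in% parNames) {
    gB <- drop(theta[["sigma_g2"]] * comps$sigma_g2 %*% ev$Py)
    names(gB) <- design$animalIds
  }
  if ("sigma_eta2" %in% parNames) {
    E <- .alignKernel(spec@herdKernel, design$farmLevels, "herd")
    eB <- drop(theta[["sigma_eta2"]] * E %*% crossprod(design$Z, ev$Py))
    names(eB) <- design$farmLevels
  }
  new("ModelFit",
      modelName = if (is.null(spec)) "FIXED_ONLY" else spec@name,
      varComp = theta, varCompSE = se, beta = ev$beta,
      gBlup = gB, etaBlup = eB, logLik = ev$logLik,
      converged = converged, nIter = iter, boundary = boundary)
}

#' BLUP solutions at fixed variance components
#'
#' Solves for fixed effects and random-effect BLUPs at the variance
#' components stored in a fit (or supplied directly), using the
#' GLS/conditional-expectation form g-hat = sigma_g2 G P y,
#' eta-hat = sigma_eta2 E Z' P y, which coincides with the solution of
#' Henderson's mixed model equations.
#'
#' @param fit a [ModelFit-class] (its \code{varComp} is used).
#' @param design output of [buildDesign()] (the data to solve on).
#' @param spec the [ModelSpec-class] the fit used.
#' @return list with \code{beta}, \code{gBlup}, \code{etaBlup}, \code{Py}.
#' @export
blupSolve <- function(fit, design, spec) {
  theta <- as.list(varComp(fit))
  comps <- .varStructures(design, spec)
  ev <- .remlEval(theta, design$X, design$y, comps)
  gB <- numeric(0); eB <- numeric(0)
  if (!is.null(comps$sigma_g2)) {
    gB <- drop(theta$sigma_g2 * comps$sigma_g2 %*% ev$Py)
    names(gB) <- design$animalIds
  }
  if (!is.null(spec) && !is.null(spec@herdKernel)) {
    E <- .alignKernel(spec@herdKernel, design$farmLevels, "herd")
    eB <- drop(theta$sigma_eta2 * E %*% crossprod(design$Z, ev$Py))
    names(eB) <- design$farmLevels
  }
  list(beta = ev$beta, gBlup = gB, etaBlup = eB, Py = ev$Py)
}

#' Predict breeding values, herd effects and phenotypes for test animals
#'
#' Test-set breeding values are the conditional mean extension
#' g-tilde_test = sigma_g2 G(test, train) P_train y_train, which equals
#' G(test,train) G(train,train)^-1 g-hat_train when the training block is
#' invertible. Herd effects for test animals are their herd's trained BLUP
#' (herds span both sets when the split is by animal); herds unobserved in
#' training get 0 under the identity kernel and the kernel-regression
#' extension under a correlated kernel — both arise automatically from
#' eta-hat = sigma_eta2 E Z_train' P y. Predicted phenotypes are composed
#' per model: X b-hat + g-tilde (GRM), X b-hat + Z eta-tilde (FARM/GPS),
#' or the sum of all three terms (combined models), with b-hat taken from
#' the training fit.
#'
#' @param fit training [ModelFit-class].
#' @param designTrain training design from [buildDesign()].
#' @param phenoTest data.frame of test-animal rows (same columns as the
#'   training phenotype table).
#' @param Gfull animal kernel covering train and test animals (required
#'   for models with a genomic term).
#' @param herdKernel farm kernel used by the fit (required for models with
#'   a herd term).
#' @return list with \code{gTilde}, \code{etaTilde} (both per test animal),
#'   \code{yTilde}, \code{XbTest}.
#' @export
predictTest <- function(fit, designTrain, phenoTest, Gfull = NULL,
                        herdKernel = NULL) {
  theta <- as.list(varComp(fit))
  hasG <- "sigma_g2" %in% names(theta)
  hasH <- "sigma_eta2" %in% names(theta)
  if (hasG && is.null(Gfull))
    stop("Gfull is required for models with a genomic term")
  if (hasH && is.null(herdKernel))
    stop("herdKernel is required for models with a herd term")

  spec <- NULL
  if (hasG || hasH) {
    nm <- fit@modelName
    spec <- new("ModelSpec", name = if (nm %in% c("GRM", "FARM", "GPS",
                                                  "GRM_FARM", "GRM_GPS"))
                  nm else "GRM",
                animalKernel = if (hasG) Gfull else NULL,
                herdKernel = if (hasH) herdKernel else NULL)
  }
  comps <- .varStructures(designTrain, spec)
  ev <- .remlEval(theta, designTrain$X, designTrain$y, comps)

  testIds <- as.character(phenoTest$animal)
  nT <- length(testIds)
  XbTest <- {
    Xt <- cbind(intercept = 1, age = as.numeric(phenoTest$age),
                sex = as.numeric(phenoTest$sex),
                cg_size = as.numeric(phenoTest$cg_size))
    drop(Xt[, names(fixedEffects(fit)), drop = FALSE] %*% fixedEffects(fit))
  }

  gT <- rep(0, nT)
  if (hasG) {
    Gm <- kernelMatrix(Gfull)
    missing <- setdiff(c(testIds, designTrain$animalIds), rownames(Gm))
    if (length(missing))
      stop("animal kernel lacks ids: ",
           paste(utils::head(missing, 5), collapse = ", "))
    gT <- drop(theta$sigma_g2 *
                 Gm[testIds, designTrain$animalIds, drop = FALSE] %*% ev$Py)
  }
  eT <- rep(0, nT)
  if (hasH) {
    E <- .alignKernel(herdKernel, designTrain$farmLevels, "herd")
    etaHat <- drop(theta$sigma_eta2 * E %*% crossprod(designTrain$Z, ev$Py))
    names(etaHat) <- designTrain$farmLevels
    unknown <- setdiff(unique(phenoTest$farm), designTrain$farmLevels)
    if (length(unknown)) {
      if (kernelKind(herdKernel) == "farm_identity") {
        warning("test herds absent from the kernel get eta = 0: ",
                paste(utils::head(unknown, 3), collapse = ", "))
        etaHat <- c(etaHat, setNames(rep(0, length(unknown)), unknown))
      } else {
        stop("test herds absent from the correlated herd kernel: ",
             paste(utils::head(unknown, 3), collapse = ", "))
      }
    }
    eT <- unname(etaHat[as.character(phenoTest$farm)])
  }
  yT <- XbTest + (if (hasG) gT else 0) + (if (hasH) eT else 0)
  list(gTilde = setNames(gT, testIds), etaTilde = setNames(eT, testIds),
       yTilde = setNames(yT, testIds), XbTest = setNames(XbTest, testIds))
}

#' Heritability and environmentability of a fitted model
#'
#' h2 = sigma_g2 / sigma_y2 and e2 = sigma_eta2 / sigma_y2, with the
#' phenotypic variance composed from exactly the components the model
#' includes: sigma_g2 + sigma_e2 (GRM), sigma_eta2 + sigma_e2 (FARM, GPS),
#' sigma_g2 + sigma_eta2 + sigma_e2 (combined models). Ratios for absent
#' components are returned as NA.
#'
#' @param fit a [ModelFit-class].
#' @return named numeric c(h2, e2, sigma_y2).
#' @examples
#' ## a GRM_GPS fit with sigma_g2 = 1, sigma_eta2 = 1, sigma_e2 = 2
#' ## gives h2 = 0.25, e2 = 0.25
#' @export
heritability <- function(fit) {
  vc <- varComp(fit)
  sy2 <- sum(vc)
  if (sy2 <= 0) stop("undefined ratio: total phenotypic variance is 0")
  h2 <- if ("sigma_g2" %in% names(vc)) unname(vc["sigma_g2"]) / sy2 else NA_real_
  e2 <- if ("sigma_eta2" %in% names(vc)) unname(vc["sigma_eta2"]) / sy2 else NA_real_
  c(h2 = h2, e2 = e2, sigma_y2 = sy2)
}
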