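## Cross-validation and model-comparison statistics: prediction accuracies,
## reliabilities, Fisher z, Tukey compact-letter groupings, PGBV comparison.

.safeCor <- function(a, b, method = "pearson") {
  if (length(a) < 3L || sd(a) == 0 || sd(b) == 0) return(NA_real_)
  cor(a, b, method = method)
}

#' Fisher z-transformation of a correlation
#'
#' z = atanh(r), the variance-stabilizing transform applied to accuracies
#' (and to square roots of reliabilities) before Tukey comparisons.
#'
#' @param r numeric vector of correlations with |r| < 1 (NA passed through).
#' @return numeric vector of z values.
#' @examples
#' fisherZ(0.5)  # 0.5493
#' @export
fisherZ <- function(r) {
  bad <- !is.na(r) & abs(r) >= 1
  if (any(bad)) stop("Fisher z is undefined for |r| >= 1")
  atanh(r)
}

#' Accuracy and reliability of predicted breeding values and herd effects
#'
#' Accuracies are Pearson correlations with the adjusted test phenotype
#' y_test - X_test b-hat: r_PGBV = cor(g-tilde, y_adj) and
#' r_eta = cor(Z eta-tilde, y_adj). Reliabilities divide the squared
#' accuracy by the corresponding variance fraction of the training fit,
#' R2_PGBV = r_PGBV^2 / h2 and R2_eta = r_eta^2 / e2. Reliabilities are
#' reported raw; values exceeding 1 (possible when r^2 > h2-hat) are
#' flagged in the \code{"clipped"} attribute rather than silently
#' truncated.
#'
#' @param gTilde,etaTilde per-test-animal predicted breeding values and
#'   herd effects (either may be NULL when the model lacks the term).
#' @param yAdj adjusted test phenotypes y_test - X_test b-hat.
#' @param h2,e2 heritability/environmentability of the training fit.
#' @return named numeric c(r_pgbv, r_eta, R2_pgbv, R2_eta) (NA for absent
#'   terms or zero-variance predictions), with attribute \code{clipped}
#'   naming reliabilities that exceed 1.
#' @export
accuracyReliability <- function(gTilde, etaTilde, yAdj, h2 = NA, e2 = NA) {
  rP <- if (is.null(gTilde)) NA_real_ else .safeCor(gTilde, yAdj)
  rE <- if (is.null(etaTilde)) NA_real_ else .safeCor(etaTilde, yAdj)
  R2P <- if (!is.na(rP) && !is.na(h2) && h2 > 0) rP^2 / h2 else NA_real_
  R2E <- if (!is.na(rE) && !is.na(e2) && e2 > 0) rE^2 / e2 else NA_real_
  out <- c(r_pgbv = rP, r_eta = rE, R2_pgbv = R2P, R2_eta = R2E)
  clipped <- names(out)[c(FALSE, FALSE, !is.na(R2P) && R2P > 1,
                          !is.na(R2E) && R2E > 1)]
  attr(out, "clipped") <- clipped
  out
}

#' Accuracy of phenotypic prediction
#'
#' r_y = cor(y-tilde_test, y_test), the Pearson correlation of predicted
#' and observed phenotypes on the test set. Undefined (NA) for
#' zero-variance predictions or fewer than 3 test animals.
#'
#' @param yTilde predicted test phenotypes.
#' @param yTest observed test phenotypes.
#' @return scalar correlation or NA.
#' @export
phenotypeAccuracy <- function(yTilde, yTest) {
  if (length(yTilde) != length(yTest))
    stop("predicted and observed phenotypes differ in length")
  .safeCor(yTilde, yTest)
}

#' Compare two sets of predicted breeding values
#'
#' Pearson and Spearman correlations (average ranks for ties) and the mean
#' squared difference MSD = mean((g_a - g_b)^2) between PGBVs of the same
#' test animals under two models.
#'
#' @param a,b numeric vectors of PGBVs for the same animals in the same
#'   order (names, when present on both, must agree).
#' @return named numeric c(pearson, spearman, msd).
#' @examples
#' comparePGBV(1:4, 1:4 + 1)  # shift: cor 1, 1, MSD 1
#' @export
comparePGBV <- function(a, b) {
  if (length(a) != length(b))
    stop("PGBV vectors differ in length (", length(a), " vs ", length(b), ")")
  if (!is.null(names(a)) && !is.null(names(b)) && !identical(names(a), names(b)))
    stop("PGBV vectors are not aligned to the same animals")
  c(pearson = .safeCor(a, b),
    spearman = .safeCor(a, b, method = "spearman"),
    msd = mean((a - b)^2))
}

#' Tukey multiple comparison with compact letter display
#'
#' One-way comparison of models on replicate-level values using the
#' studentized range: q_ij = |m_i - m_j| / sqrt(MSE/2 (1/n_i + 1/n_j))
#' (Tukey-Kramer for unequal replicate counts), with p-values from the
#' studentized-range distribution. Letters are assigned so that models
#' sharing a letter are not significantly different at \code{alpha}:
#' letters correspond to maximal sets of mutually non-significant models.
#'
#' Callers should pre-transform correlations with [fisherZ()] (and take
#' square roots of reliabilities first); REML heritabilities are compared
#' untransformed.
#'
#' @param values numeric replicate-level values.
#' @param groups factor/character of the model each value belongs to.
#' @param alpha significance level (default 0.05).
#' @return data.frame (group, mean, n, letters) ordered by decreasing
#'   mean, with attributes \code{qMatrix} and \code{pMatrix}.
#' @export
tukeyGroups <- function(values, groups, alpha = 0.05) {
  ok <- !is.na(values)
  values <- values[ok]; groups <- factor(groups[ok])
  k <- nlevels(groups)
  if (k < 2L) stop("need at least 2 groups")
  n <- tapply(values, groups, length)
  if (any(n < 2L)) stop("need at least 2 replicates per group")
  m <- tapply(values, groups, mean)
  N <- length(values)
  dfE <- N - k
  mse <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2))) / dfE
  q <- p <- matrix(NA_real_, k, k, dimnames = list(levels(groups), levels(groups)))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    se <- sqrt(mse / 2 * (1 / n[i] + 1 / n[j]))
    qij <- if (se > 0) abs(m[i] - m[j]) / se else Inf
    q[i, j] <- q[j, i] <- qij
    p[i, j] <- p[j, i] <- ptukey(qij, k, dfE, lower.tail = FALSE)
  }
  ## non-significance graph -> letters are its maximal cliques
  nonsig <- is.na(p) | p >= alpha
  diag(nonsig) <- TRUE
  cliques <- list()
  for (s in seq_len(2^k) - 1L) {
    members <- which(bitwAnd(s, 2^(seq_len(k) - 1L)) > 0)
    if (!length(members)) next
    if (all(nonsig[members, members])) cliques[[length(cliques) + 1L]] <- members
  }
  maximal <- Filter(function(ci) !any(vapply(cliques, function(cj)
    length(cj) > length(ci) && all(ci %in% cj), logical(1))), cliques)
  ## order letter sets by the best (largest) member mean
  maximal <- maximal[order(vapply(maximal, function(ci) -max(m[ci]), numeric(1)))]
  letterOf <- vapply(seq_len(k), function(g) {
    paste(letters[which(vapply(maximal, function(ci) g %in% ci, logical(1)))],
          collapse = "")
  }, character(1))
  out <- data.frame(group = levels(groups), mean = as.numeric(m),
                    n = as.integer(n), letters = letterOf,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$mean), ]
  rownames(out) <- NULL
  attr(out, "qMatrix") <- q
  attr(out, "pMatrix") <- p
  out
}

#' Replicated cross-validation over a set of models
#'
#' Repeatedly reassigns \code{trainFrac} of the animals to a training set
#' and the rest to a test set, fits every model spec on the training data
#' (all specs see identical splits — required for paired Tukey
#' comparisons), predicts the test set, and records heritability,
#' environmentability, prediction accuracies and reliabilities per
#' replicate and model. Replicate seeds are spawned deterministically from
#' the master seed. A training set in which a fixed-effect column is
#' constant (e.g. one sex absent) is logged and re-drawn.
#'
#' @param data list as returned by [simulateHerdData()], or any list with
#'   \code{pheno} (phenotype data.frame) and the kernels named by
#'   \code{specs}.
#' @param specs named list of [ModelSpec-class] objects; names label the
#'   models in the output.
#' @param nReps number of replicates (default 100).
#' @param trainFrac training fraction in (0, 1) (default 0.8).
#' @param seed master seed for the split sequence.
#' @param tol,maxIter passed to [remlFit()].
#' @return data.frame with one row per replicate x model: replicate,
#'   model, h2, e2, r_pgbv, r_eta, R2_pgbv, R2_eta, r_y, converged; PGBV
#'   vectors per replicate/model in attribute \code{"pgbv"}, test index
#'   sets in attribute \code{"splits"}.
#' @export
crossValidate <- function(data, specs, nReps = 100L, trainFrac = 0.8,
                          seed = 1L, tol = 1e-6, maxIter = 200L) {
  pheno <- data$pheno
  n <- nrow(pheno)
  if (trainFrac <= 0 || trainFrac >= 1)
    stop("trainFrac must be strictly between 0 and 1")
  nTest <- n - floor(trainFrac * n)
  if (nTest < 3L) stop("test sets would have fewer than 3 animals")
  if (is.null(names(specs)))
    names(specs) <- vapply(specs, function(s) s@name, character(1))

  farmLevelsOf <- function(spec) {
    if (!is.null(spec@herdKernel)) entityIds(spec@herdKernel)
    else sort(unique(pheno$farm))
  }
  rows <- list(); splits <- list(); pgbvs <- list()
  for (rep in seq_len(nReps)) {
    ## redraw splits whose training design would be rank-deficient
    for (attempt in 1:25) {
      set.seed(seed + 7919L * rep + attempt)
      testIdx <- sort(sample.int(n, nTest))
      tr <- pheno[-testIdx, ]
      okCols <- vapply(c("age", "sex", "cg_size"), function(cn)
        length(unique(tr[[cn]])) > 1L, logical(1))
      fullOk <- vapply(c("age", "sex", "cg_size"), function(cn)
        length(unique(pheno[[cn]])) > 1L, logical(1))
      if (all(okCols == fullOk)) break
      message("replicate ", rep, ": constant fixed-effect column in the ",
              "training split, re-drawing")
    }
    splits[[rep]] <- testIdx
    te <- pheno[testIdx, ]
    for (mn in names(specs)) {
      spec <- specs[[mn]]
      des <- buildDesign(pheno[-testIdx, ], farmLevelsOf(spec))
      fit <- remlFit(des, spec, tol = tol, maxIter = maxIter)
      h <- heritability(fit)
      pr <- predictTest(fit, des, te, Gfull = spec@animalKernel,
                        herdKernel = spec@herdKernel)
      yAdj <- te$trait - pr$XbTest
      ar <- accuracyReliability(
        if ("sigma_g2" %in% names(varComp(fit))) pr$gTilde else NULL,
        if ("sigma_eta2" %in% names(varComp(fit))) pr$etaTilde else NULL,
        yAdj, h2 = h[["h2"]], e2 = h[["e2"]])
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = rep, model = mn, h2 = h[["h2"]], e2 = h[["e2"]],
        r_pgbv = ar[["r_pgbv"]], r_eta = ar[["r_eta"]],
        R2_pgbv = ar[["R2_pgbv"]], R2_eta = ar[["R2_eta"]],
        r_y = phenotypeAccuracy(pr$yTilde, te$trait),
        converged = fit@converged, stringsAsFactors = FALSE)
      pgbvs[[paste(rep, mn, sep = ".")]] <- pr$gTilde
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "splits") <- splits
  attr(out, "pgbv") <- pgbvs
  attr(out, "seed") <- seed
  out
}

#' Summarize a cross-validation run with Tukey letter groupings
#'
#' Per metric and model: the mean over replicates and the compact-letter
#' group from [tukeyGroups()]. Accuracies are Fisher-z transformed before
#' the comparison; reliabilities are square-rooted first and then
#' transformed (values at or above 1 are clamped just below 1 so the
#' transform is defined); REML heritabilities and environmentabilities are
#' compared untransformed.
#'
#' @param cv output of [crossValidate()].
#' @param alpha significance level for the groupings.
#' @return data.frame (metric, model, mean, letters).
#' @export
summarizeCV <- function(cv, alpha = 0.05) {
  metrics <- c("h2", "e2", "r_pgbv", "r_eta", "R2_pgbv", "R2_eta", "r_y")
  clamp <- function(r) pmin(pmax(r, -1 + 1e-10), 1 - 1e-10)
  transformOf <- function(metric, v) {
    if (metric %in% c("r_pgbv", "r_eta", "r_y")) fisherZ(clamp(v))
    else if (metric %in% c("R2_pgbv", "R2_eta")) fisherZ(clamp(sqrt(pmax(v, 0))))
    else v
  }
  res <- list()
  for (metric in metrics) {
    v <- cv[[metric]]
    if (all(is.na(v))) next
    keep <- !is.na(v)
    mods <- unique(cv$model[keep])
    means <- tapply(v[keep], cv$model[keep], mean)
    lett <- rep(NA_character_, length(mods)); names(lett) <- mods
    if (length(mods) >= 2L) {
      tg <- tukeyGroups(transformOf(metric, v[keep]), cv$model[keep], alpha)
      lett[tg$group] <- tg$letters
    }
    res[[metric]] <- data.frame(metric = metric, model = mods,
                                mean = as.numeric(means[mods]),
                                letters = unname(lett[mods]),
                                stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
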