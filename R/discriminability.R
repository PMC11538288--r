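# Multivariate layer: standardized PCA with eigenvalue retention,
# discriminant classification (optimal scoring / LDA) with CCR and
# conditional-frequency confusion matrices, and the univariate test harness.

.variableSets <- list(
  set6  = c("duration_ms", "n_pulses", "f0_hz", "fpeak_hz", "period_ms",
            "lastpulse_ms"),
  set8  = c("duration_ms", "n_pulses", "f0_hz", "fpeak_hz", "period_ms",
            "lastpulse_ms", "n_blocks", "pct_pattern"),
  set10 = c("duration_ms", "n_pulses", "f0_hz", "fpeak_hz", "period_ms",
            "lastpulse_ms", "n_blocks", "pct_pattern", "interval_ms",
            "pulses_per_block")
)

#' Variable-set presets
#'
#' The three analysis presets: \code{set6} (the six variables unrelated to
#' pattern: duration, pulse count, fundamental and dominant frequency, pulse
#' period, last-pulse duration), \code{set8} (plus block count and percentage
#' of sounds with pattern) and \code{set10} (plus interval and pulses per
#' block). Higher taxonomic levels use set8; within-genus comparisons use
#' set6; only the pattern-rich Myripristis group-2 species support set10.
#'
#' @param name "set6", "set8", "set10", or a character vector of variable
#'   names passed through unchanged.
#' @return character vector of variable names.
#' @export
variableSet <- function(name = c("set6", "set8", "set10")) {
  if (length(name) == 1 && name %in% names(.variableSets))
    return(.variableSets[[name]])
  if (all(name %in% c("set6", "set8", "set10")))
    return(.variableSets[[match.arg(name)]])
  name
}

#' Standardized PCA of individual summaries
#'
#' Correlation-matrix PCA (variables centered and scaled to unit variance --
#' they mix ms, Hz, counts and percent). Rows with an absent value in any
#' chosen variable are dropped and counted. The number of retained components
#' follows the eigenvalue-greater-than-one rule. Loading signs follow a
#' deterministic convention: the largest-magnitude loading of each PC is
#' positive.
#'
#' @param summaries individual-summary data.frame.
#' @param variables variable names or a preset name (see [variableSet()]).
#' @return an [AcousticSpace-class]; attribute \code{"dropped"} holds the
#'   row names dropped for missing values.
#' @export
acousticPCA <- function(summaries, variables = "set8") {
  vars <- variableSet(variables)
  miss <- setdiff(vars, names(summaries))
  if (length(miss))
    hcStop("holocall_bad_variables", "summaries lack variables: %s",
           paste(miss, collapse = ", "))
  X <- as.matrix(summaries[, vars])
  complete <- stats::complete.cases(X)
  if (sum(complete) < length(vars))
    hcStop("holocall_too_few_rows",
           "%d complete rows for %d variables: PCA undefined",
           sum(complete), length(vars))
  dropped <- if ("specimen_id" %in% names(summaries))
    summaries$specimen_id[!complete] else which(!complete)
  X <- X[complete, , drop = FALSE]
  if ("specimen_id" %in% names(summaries))
    rownames(X) <- summaries$specimen_id[complete]
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  # deterministic sign: largest-magnitude loading positive per PC
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  eig <- pc$sdev^2
  space <- new("AcousticSpace",
               scores = pc$x,
               loadings = pc$rotation,
               varExplained = 100 * eig / sum(eig),
               retained = max(1L, sum(eig > 1)),
               variableSet = vars)
  attr(space, "dropped") <- dropped
  space
}

# ---- discriminant classification ------------------------------------------

# Optimal-scoring discriminant fit. With a linear basis this is linear
# discriminant analysis computed through regression on the class-indicator
# matrix; a polynomial basis gives the flexible variant. Classification is
# by Mahalanobis distance (pooled within-class covariance) in the variate
# space, with log-prior correction -- invariant to any invertible linear map
# of the discriminant subspace, hence exactly LDA-equivalent for the linear
# basis.
fdaFit <- function(X, y, basis = c("linear", "poly"), degree = 2) {
  basis <- match.arg(basis)
  y <- droplevels(as.factor(y))
  K <- nlevels(y)
  H <- expandBasis(X, basis, degree)
  n <- nrow(H)
  Y <- stats::model.matrix(~ y - 1)
  colnames(Y) <- levels(y)
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, H), Y)
  fit$coefficients[is.na(fit$coefficients)] <- 0  # collinear basis columns
  Yhat <- cbind(1, H) %*% fit$coefficients
  M <- crossprod(Y, Yhat) / n
  d <- colMeans(Y)
  # optimal scores live in the D-orthogonal complement of the trivial
  # constant score: parameterize there so degenerate eigenvalues (perfect
  # separation) can never mix the constant direction back in
  C <- stats::contr.helmert(K)
  Z <- C - outer(rep(1, K), as.numeric(crossprod(d, C)))
  Mz <- crossprod(Z, M %*% Z)
  Dz <- crossprod(Z, diag(d, K) %*% Z)
  R <- chol(Dz)
  Rz <- backsolve(R, diag(K - 1L))
  Az <- crossprod(Rz, ((Mz + t(Mz)) / 2) %*% Rz)
  e <- eigen((Az + t(Az)) / 2, symmetric = TRUE)
  theta <- Z %*% (Rz %*% e$vectors)
  B <- fit$coefficients %*% theta              # (1+p') x (K-1)
  eta <- cbind(1, H) %*% B                     # discriminant variates
  centroids <- apply(eta, 2, function(col) tapply(col, y, mean))
  centroids <- matrix(centroids, nrow = K,
                      dimnames = list(levels(y), NULL))
  within <- eta - centroids[as.integer(y), , drop = FALSE]
  W <- crossprod(within) / (n - K)
  # guard against exact separation (zero within-class variance)
  ridge <- 1e-10 * mean(diag(W))
  if (!is.finite(ridge) || ridge <= 0) ridge <- 1e-12
  if (rcond(W) < 1e-12) W <- W + diag(ridge, nrow(W))
  structure(list(B = B, W = W, centroids = centroids,
                 priors = as.numeric(table(y)) / n, levels = levels(y),
                 basis = basis, degree = degree),
            class = "holocallFda")
}

fdaPredict <- function(fit, X) {
  H <- expandBasis(X, fit$basis, fit$degree)
  eta <- cbind(1, H) %*% fit$B
  Winv <- solve(fit$W)
  K <- nrow(fit$centroids)
  d2 <- sapply(seq_len(K), function(k) {
    df <- sweep(eta, 2, fit$centroids[k, ])
    rowSums((df %*% Winv) * df) - 2 * log(fit$priors[k])
  })
  d2 <- matrix(d2, ncol = K)
  factor(fit$levels[max.col(-d2, ties.method = "first")],
         levels = fit$levels)
}

expandBasis <- function(X, basis, degree) {
  X <- as.matrix(X)
  if (basis == "linear") return(X)
  cols <- list(X)
  for (d in 2:degree) cols[[d]] <- X^d
  H <- do.call(cbind, cols)
  # pairwise products complete the quadratic basis
  if (degree >= 2 && ncol(X) >= 2) {
    pr <- utils::combn(ncol(X), 2)
    H <- cbind(H, X[, pr[1, ], drop = FALSE] * X[, pr[2, ], drop = FALSE])
  }
  H
}

#' Discriminant classification of taxa from acoustic variables
#'
#' Fits a discriminant model on the standardized variables and reports the
#' correct classification rate and conditional-frequency confusion matrix.
#' The default method is optimal scoring with a linear basis (flexible
#' discriminant analysis in its linear flavor, equivalent to linear
#' discriminant analysis); \code{method = "lda"} routes through
#' \code{MASS::lda} instead and serves as an independent cross-check. The
#' headline number is the resubstitution CCR (matching the "classified x out
#' of y individuals" convention); leave-one-out cross-validation is available
#' with \code{cv = "loo"}.
#'
#' @param summaries individual-summary data.frame.
#' @param labels class (taxon) label per row.
#' @param variables variable names or preset (see [variableSet()]).
#' @param method "fda" (optimal scoring) or "lda" (MASS).
#' @param basis basis for the fda method: "linear" (default) or "poly".
#' @param cv "none" (resubstitution, default) or "loo".
#' @param level name of the taxonomic grouping, carried into the report.
#' @return a [ClassificationReport-class].
#' @export
discriminantCCR <- function(summaries, labels, variables = "set8",
                            method = c("fda", "lda"),
                            basis = c("linear", "poly"),
                            cv = c("none", "loo"), level = "taxon") {
  method <- match.arg(method)
  basis <- match.arg(basis)
  cv <- match.arg(cv)
  vars <- variableSet(variables)
  X <- as.matrix(summaries[, vars])
  y <- as.factor(labels)
  complete <- stats::complete.cases(X) & !is.na(y)
  X <- X[complete, , drop = FALSE]
  y <- droplevels(y[complete])
  if (nlevels(y) < 2)
    hcStop("holocall_single_class",
           "need at least 2 classes, got %d", nlevels(y))
  X <- scale(X)
  keep <- apply(X, 2, function(c) all(is.finite(c)))
  X <- X[, keep, drop = FALSE]

  classify <- function(trainX, trainY, testX) {
    if (method == "fda") {
      fdaPredict(fdaFit(trainX, trainY, basis = basis), testX)
    } else {
      fit <- MASS::lda(trainX, grouping = trainY)
      stats::predict(fit, testX)$class
    }
  }
  assigned <- if (cv == "none") {
    classify(X, y, X)
  } else {
    factor(vapply(seq_len(nrow(X)), function(i) {
      as.character(classify(X[-i, , drop = FALSE], y[-i],
                            X[i, , drop = FALSE]))
    }, character(1)), levels = levels(y))
  }

  tab <- table(truth = y, assigned = factor(assigned, levels = levels(y)))
  conf <- sweep(tab, 1, pmax(rowSums(tab), 1), "/")
  conf <- matrix(conf, nrow = nrow(tab), dimnames = dimnames(tab))
  new("ClassificationReport",
      level = level, method = method,
      nTotal = length(y), nCorrect = sum(as.character(assigned) == as.character(y)),
      perClassCCR = stats::setNames(diag(conf), rownames(conf)),
      confusion = conf,
      truth = y, assigned = assigned)
}

# ---- univariate harness ----------------------------------------------------

# Dunn's post-hoc z statistics (rank sums with tie correction); p-values are
# one-sided P(Z >= |z|), compared against alpha = 0.025, with
# Benjamini-Hochberg adjustment across the pairs of one variable's family.
dunnTest <- function(x, g) {
  g <- droplevels(as.factor(g))
  N <- length(x)
  r <- rank(x)
  ties <- table(r)
  tieCorr <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(r, g, mean)
  ns <- table(g)
  pairs <- utils::combn(levels(g), 2)
  z <- apply(pairs, 2, function(p) {
    (rbar[p[1]] - rbar[p[2]]) /
      sqrt((N * (N + 1) / 12 - tieCorr) * (1 / ns[p[1]] + 1 / ns[p[2]]))
  })
  p <- 1 - stats::pnorm(abs(z))
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
             z = as.numeric(z), p_value = as.numeric(p),
             p_adjusted = stats::p.adjust(p, "BH"),
             stringsAsFactors = FALSE)
}

#' Univariate comparison of acoustic variables between taxa
#'
#' Per variable: normality (Shapiro-Wilk on model residuals) and
#' homoscedasticity (Bartlett) are gated at p < 0.05; if the raw data fail,
#' log and square-root transforms are tried in turn and used only when both
#' criteria are then met. The parametric path runs a t test (2 groups) or
#' ANOVA with Tukey post hoc (alpha 0.05); the non-parametric path runs a
#' Wilcoxon-Mann-Whitney or Kruskal-Wallis test with Dunn post hoc under
#' Benjamini-Hochberg correction (alpha 0.025, one-sided convention). Groups
#' with fewer than 3 values route the variable non-parametric with a
#' warning. The decision trail (transform tried, gate p-values, route) is
#' recorded per variable.
#'
#' @param summaries individual-summary data.frame.
#' @param grouping taxon label per row.
#' @param variables variable names or preset (see [variableSet()]).
#' @return data.frame with one row per variable: variable, n_groups,
#'   transform, route, test, statistic, p_value; attribute \code{"posthoc"}
#'   is a named list of post-hoc tables, attribute \code{"trail"} the
#'   decision log.
#' @export
univariateSuite <- function(summaries, grouping, variables = "set8") {
  vars <- variableSet(variables)
  g0 <- as.factor(grouping)
  if (nlevels(droplevels(g0)) < 2)
    hcStop("holocall_single_class", "need at least 2 groups")
  rows <- list(); posthoc <- list(); trail <- character(0)

  for (v in vars) {
    xv <- summaries[[v]]
    okRow <- !is.na(xv) & !is.na(g0)
    x <- xv[okRow]; g <- droplevels(g0[okRow])
    if (nlevels(g) < 2 || length(x) < 4) {
      trail <- c(trail, sprintf("%s: too few data, skipped", v))
      next
    }
    smallGroup <- any(table(g) < 3)
    route <- "nonparametric"; transform <- "identity"; xw <- x
    if (smallGroup) {
      hcWarn("%s: a group has < 3 values; routed non-parametric", v)
      trail <- c(trail, sprintf("%s: group n < 3 -> non-parametric", v))
    } else {
      for (tr in c("identity", "log", "sqrt")) {
        xt <- switch(tr,
                     identity = x,
                     log = if (all(x > 0)) log(x) else NULL,
                     sqrt = if (all(x >= 0)) sqrt(x) else NULL)
        if (is.null(xt)) next
        resid <- xt - stats::ave(xt, g)
        pSW <- tryCatch(stats::shapiro.test(resid)$p.value,
                        error = function(e) 0)
        pB <- tryCatch(stats::bartlett.test(xt, g)$p.value,
                       error = function(e) 0)
        trail <- c(trail, sprintf("%s [%s]: Shapiro p=%.3g, Bartlett p=%.3g",
                                  v, tr, pSW, pB))
        if (pSW >= 0.05 && pB >= 0.05) {
          route <- "parametric"; transform <- tr; xw <- xt
          break
        }
      }
    }
    K <- nlevels(g)
    if (route == "parametric") {
      if (K == 2) {
        tt <- stats::t.test(xw ~ g, var.equal = TRUE)
        rows[[v]] <- data.frame(variable = v, n_groups = K,
                                transform = transform, route = route,
                                test = "t", statistic = unname(tt$statistic),
                                p_value = tt$p.value)
      } else {
        fit <- stats::aov(xw ~ g)
        an <- summary(fit)[[1]]
        rows[[v]] <- data.frame(variable = v, n_groups = K,
                                transform = transform, route = route,
                                test = "ANOVA", statistic = an[1, "F value"],
                                p_value = an[1, "Pr(>F)"])
        tk <- stats::TukeyHSD(fit)$g
        posthoc[[v]] <- data.frame(comparison = rownames(tk),
                                   diff = tk[, "diff"],
                                   p_adjusted = tk[, "p adj"],
                                   significant = tk[, "p adj"] < 0.05,
                                   row.names = NULL)
      }
    } else {
      if (K == 2) {
        wt <- suppressWarnings(stats::wilcox.test(x ~ g))
        rows[[v]] <- data.frame(variable = v, n_groups = K,
                                transform = "identity", route = route,
                                test = "Wilcoxon-Mann-Whitney",
                                statistic = unname(wt$statistic),
                                p_value = wt$p.value)
      } else {
        kw <- stats::kruskal.test(x, g)
        rows[[v]] <- data.frame(variable = v, n_groups = K,
                                transform = "identity", route = route,
                                test = "Kruskal-Wallis",
                                statistic = unname(kw$statistic),
                                p_value = kw$p.value)
        dn <- dunnTest(x, g)
        dn$significant <- dn$p_adjusted < 0.025
        posthoc[[v]] <- dn
      }
    }
    trail <- c(trail, sprintf("%s: route=%s transform=%s", v, route, transform))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "posthoc") <- posthoc
  attr(out, "trail") <- trail
  out
}
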