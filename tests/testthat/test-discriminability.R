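makeSummaries <- function(n, p = 6, shift = 0, classes = NULL) {
  X <- matrix(rnorm(n * p), n)
  if (!is.null(classes)) X[, 1] <- X[, 1] + shift * as.integer(classes)
  d <- as.data.frame(X)
  names(d) <- variableSet("set6")[seq_len(p)]
  d
}

test_that("standardized PCA: isotropy, rank-1 limit, duplication invariance", {
  set.seed(5)
  iso <- makeSummaries(1000)
  sp <- acousticPCA(iso, variableSet("set6"))
  expect_true(all(abs(varExplained(sp) - 100 / 6) < 5))
  expect_equal(sum(varExplained(sp)), 100)

  planted <- iso
  z <- rnorm(1000, 0, 20)
  for (v in names(planted)) planted[[v]] <- planted[[v]] + z
  sp1 <- acousticPCA(planted, variableSet("set6"))
  expect_gt(varExplained(sp1)[1], 90)
  expect_equal(nRetained(sp1), 1)

  dup <- rbind(iso, iso)
  spd <- acousticPCA(dup, variableSet("set6"))
  expect_equal(pcLoadings(spd), pcLoadings(sp), tolerance = 1e-9)
  expect_equal(varExplained(spd), varExplained(sp), tolerance = 1e-9)

  # deterministic sign convention
  for (j in seq_len(ncol(pcLoadings(sp)))) {
    l <- pcLoadings(sp)[, j]
    expect_gt(l[which.max(abs(l))], 0)
  }

  expect_error(acousticPCA(iso[1:3, ], variableSet("set6")),
               class = "holocall_too_few_rows")
})

test_that("hull occupancy: closed forms, RCHS/RCHI, invariances", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(hullVolume(sq), 1)
  cube <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  expect_equal(hullVolume(cube), 1)

  # monotone under added points; translation/rotation invariant
  set.seed(8)
  pts <- matrix(rnorm(36), 12)
  v0 <- hullVolume(pts)
  expect_gte(hullVolume(rbind(pts, matrix(rnorm(9), 3))), v0 - 1e-12)
  expect_equal(hullVolume(sweep(pts, 2, c(5, -3, 2), "+")), v0,
               tolerance = 1e-9)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  expect_equal(hullVolume(pts %*% R), v0, tolerance = 1e-9)

  # degenerate (coplanar) sets: volume 0 with a warning, not an error
  flat <- cbind(matrix(rnorm(20), 10), 0)
  expect_warning(vf <- hullVolume(flat), "degenerate")
  expect_equal(vf, 0)

  # RCHS / RCHI arithmetic through an AcousticSpace
  scores <- rbind(cube + 0, cube + 10)  # two unit cubes, disjoint
  space <- new("AcousticSpace", scores = cbind(scores, 0)[, 1:3],
               loadings = diag(3), varExplained = c(50, 30, 20),
               retained = 2L, variableSet = c("a", "b", "c"))
  hs <- hullOccupancy(space, rep(c("g1", "g2"), each = 8), dim = 3,
                      speciesOf = rep(c("s1", "s2", "s3", "s4"), each = 4))
  expect_equal(hs$volume, c(1, 1))
  expect_equal(hs$rchs, c(0.5, 0.5))
  expect_equal(hs$rchi, c(1 / 8, 1 / 8))
})

test_that("discriminant classification: separable limit and report contract", {
  set.seed(10)
  y <- factor(rep(c("A", "B"), each = 30))
  d <- makeSummaries(60, shift = 10, classes = y)
  rep1 <- discriminantCCR(d, y, names(d), level = "demo")
  expect_equal(ccr(rep1), 1.0)
  expect_equal(rep1@nCorrect, 60)
  cm <- confusionMatrix(rep1)
  expect_equal(unname(rowSums(cm)), c(1, 1))
  expect_equal(unname(diag(cm)), unname(perClassCCR(rep1)[rownames(cm)]))

  expect_error(discriminantCCR(d, rep("A", 60), names(d)),
               class = "holocall_single_class")
})

test_that("shuffled labels give chance-level CCR", {
  set.seed(11)
  ccrs <- replicate(60, {
    y <- factor(rep(c("A", "B"), each = 100)[sample(200)])
    d <- makeSummaries(200, p = 4)
    ccr(discriminantCCR(d, y, names(d)[1:4]))
  })
  expect_lt(abs(mean(ccrs) - 0.5), 0.1)
})

test_that("optimal scoring equals LDA; polynomial basis is available", {
  set.seed(12)
  for (i in 1:60) {
    K <- sample(2:4, 1)
    y <- factor(sample(letters[1:K], 50, replace = TRUE))
    d <- makeSummaries(50, p = 4, shift = runif(1, 0.5, 4), classes = y)
    a <- discriminantCCR(d, y, names(d)[1:4], method = "fda")
    b <- discriminantCCR(d, y, names(d)[1:4], method = "lda")
    expect_equal(as.character(assignedClasses(a)),
                 as.character(assignedClasses(b)))
  }
  # quadratic boundary: the polynomial basis can beat the linear one
  set.seed(13)
  x <- matrix(rnorm(400), 200)
  y <- factor(ifelse(rowSums(x^2) > 2, "out", "in"))
  d <- data.frame(duration_ms = x[, 1], n_pulses = x[, 2])
  lin <- discriminantCCR(d, y, c("duration_ms", "n_pulses"), basis = "linear")
  pol <- discriminantCCR(d, y, c("duration_ms", "n_pulses"), basis = "poly")
  expect_gt(ccr(pol), ccr(lin))
})

test_that("leave-one-out mode is available and sane", {
  set.seed(14)
  y <- factor(rep(c("A", "B"), each = 25))
  d <- makeSummaries(50, shift = 3, classes = y)
  rloo <- discriminantCCR(d, y, names(d), cv = "loo")
  expect_gte(ccr(rloo), 0.8)
  expect_lte(ccr(rloo), ccr(discriminantCCR(d, y, names(d))))
})

test_that("univariate harness routes by the normality/homoscedasticity gate", {
  set.seed(15)
  d <- data.frame(duration_ms = c(rnorm(25, 0), rnorm(25, 5)))
  g <- rep(c("A", "B"), each = 25)
  out <- univariateSuite(d, g, "duration_ms")
  expect_equal(out$route, "parametric")
  expect_equal(out$test, "t")
  expect_lt(out$p_value, 0.001)

  # heavy-tailed groups that no transform fixes go non-parametric
  set.seed(16)
  dh <- data.frame(duration_ms = c(exp(rnorm(30, 0, 2)),
                                   -exp(rnorm(30, 0.5, 2))))
  gh <- rep(c("A", "B"), each = 30)
  outh <- univariateSuite(dh, gh, "duration_ms")
  expect_equal(outh$route, "nonparametric")
  expect_equal(outh$test, "Wilcoxon-Mann-Whitney")

  # >2 skewed groups: Kruskal-Wallis with Dunn-BH post hoc
  set.seed(17)
  dk <- data.frame(duration_ms = exp(rnorm(90, rep(c(0, 0.2, 2), each = 30), 1.5)))
  dk$duration_ms[1:30] <- dk$duration_ms[1:30] * sample(c(1, 50), 30, TRUE)
  gk <- rep(c("A", "B", "C"), each = 30)
  outk <- univariateSuite(dk, gk, "duration_ms")
  if (outk$route == "nonparametric") {
    expect_equal(outk$test, "Kruskal-Wallis")
    ph <- attr(outk, "posthoc")$duration_ms
    expect_equal(nrow(ph), 3)
    expect_true(all(ph$p_adjusted >= ph$p_value - 1e-12))
  }

  # small groups route non-parametric with a warning
  ds <- data.frame(duration_ms = rnorm(7))
  gs <- c("A", "A", "B", "B", "B", "B", "B")
  expect_warning(outs <- univariateSuite(ds, gs, "duration_ms"), "< 3")
  expect_equal(outs$route, "nonparametric")
})

test_that("identical groups rarely show significant post-hoc differences", {
  set.seed(18)
  anySig <- replicate(100, {
    d <- data.frame(duration_ms = rnorm(50))
    g <- rep(paste0("g", 1:5), each = 10)
    out <- univariateSuite(d, g, "duration_ms")
    ph <- attr(out, "posthoc")$duration_ms
    !is.null(ph) && any(ph$significant)
  })
  expect_gte(mean(!anySig), 0.95)
})
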