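test_that("the interval rule reproduces the worked examples", {
  b1 <- segmentBlocks(c(10, 10, 25, 10, 10))
  expect_equal(nBlocks(b1), 2)
  expect_true(hasPattern(b1))
  expect_equal(intervalsMs(b1), 25)
  expect_equal(unname(blockSpans(b1)[, 1]), c(0, 3))
  expect_equal(unname(blockSpans(b1)[, 2]), c(2, 5))

  # the last period is never an interval even above threshold
  b2 <- segmentBlocks(c(10, 10, 10, 25))
  expect_equal(nBlocks(b2), 1)
  expect_false(hasPattern(b2))

  # three or fewer pulses: one block, never patterned
  b3 <- segmentBlocks(c(10, 30))
  expect_equal(nBlocks(b3), 1)
  expect_false(hasPattern(b3))

  # degenerate single-pulse sound
  b4 <- segmentBlocks(numeric(0))
  expect_equal(nBlocks(b4), 1)
  expect_equal(nPulses(b4), 1)

  expect_error(segmentBlocks(c(10, -1, 10)), class = "holocall_bad_periods")
  expect_error(segmentBlocks(c(10, 10), ratio = 0.9),
               class = "holocall_bad_ratio")
})

test_that("segmentation matches the brute-force oracle and is scale-free", {
  set.seed(20)
  for (i in 1:2000) {
    np <- sample(1:12, 1)
    periods <- round(runif(np - 1, 5, 30), 2)
    bl <- segmentBlocks(periods)
    expect_equal(nBlocks(bl), bruteForceBlocks(periods))
    # scale invariance
    k <- runif(1, 0.1, 12)
    expect_equal(nBlocks(segmentBlocks(periods * k)), nBlocks(bl))
  }
})

test_that("P1-P4 classes partition any corpus", {
  expect_equal(classifyPGroup(1, FALSE), "P1")
  expect_equal(classifyPGroup(2, FALSE), "P2")
  expect_equal(classifyPGroup(7, FALSE), "P3")
  expect_equal(classifyPGroup(6, TRUE), "P4")
  expect_error(classifyPGroup(3, TRUE), class = "holocall_inconsistent_pattern")
  expect_error(classifyPGroup(0, FALSE), class = "holocall_bad_pulse_count")

  set.seed(3)
  classes <- sapply(1:500, function(i) {
    periods <- runif(sample(0:9, 1), 4, 30)
    bl <- segmentBlocks(periods)
    classifyPGroup(nPulses(bl), hasPattern(bl))
  })
  counts <- table(factor(classes, levels = c("P1", "P2", "P3", "P4")))
  expect_equal(sum(counts), 500)
  expect_true(all(counts > 0))
})

test_that("threshold calibration recovers 1.25 and honors tie rules", {
  ann <- makeCalibrationSounds(100, seed = 5)
  best <- calibrateIntervalRatio(annotated = ann)
  expect_equal(as.numeric(best), 1.25)
  agg <- attr(best, "agreement")
  expect_equal(agg$n_agree[agg$candidate == 1.25], 100)
  expect_true(all(agg$n_agree[agg$candidate != 1.25] < 100))

  expect_equal(as.numeric(calibrateIntervalRatio(1.25, ann)), 1.25)

  # two candidates with equal agreement: the smaller wins
  flat <- list(list(periods_ms = rep(10, 5), visual_block_count = 1L))
  expect_equal(as.numeric(calibrateIntervalRatio(c(1.30, 1.20), flat)), 1.20)

  expect_error(calibrateIntervalRatio(numeric(0), ann),
               class = "holocall_empty_input")
  expect_error(calibrateIntervalRatio(annotated = list()),
               class = "holocall_empty_input")
})

test_that("pattern percentage is plain arithmetic on block structures", {
  expect_equal(patternPercentage(rep(FALSE, 20)), 0)
  expect_equal(patternPercentage(c(rep(TRUE, 13), rep(FALSE, 7))), 65)
  blocks <- list(segmentBlocks(c(10, 10, 25, 10, 10)), segmentBlocks(c(10, 10)))
  expect_equal(patternPercentage(blocks), 50)
  expect_error(patternPercentage(logical(0)), class = "holocall_empty_input")
})

test_that("cohort pattern frequency converges to the template probability", {
  tpl <- holocentridTemplates()$Myripristis_group2  # pattern-rich group
  sim <- synthFeatureCohort(list(tpl), nIndividuals = 30, nSounds = 20, seed = 2)
  summ <- summarizeIndividuals(sim$features)
  se <- sd(summ$pct_pattern) / sqrt(nrow(summ))
  expect_lt(abs(mean(summ$pct_pattern) - 57), 2 * se + 1e-9)
})
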