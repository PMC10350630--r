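test_that("already-stable models skip the scan with identity multipliers", {
  m <- nearCapacityModel(deficit = 1)
  expect_identical(detectAccumulation(m), character(0))
  cand <- scanStabilizingVmax(m, targets = "V_drain")
  expect_true(attr(cand, "alreadyStable"))
  res <- selectMinimalChange(cand)
  expect_true(res@alreadyStable)
  expect_identical(unname(res@chosen), 1)
  expect_identical(res@normalizedDistance, 0)
})

test_that("a pool whose only consumer is silenced is flagged accumulating", {
  m <- nearCapacityModel(deficit = 4)
  expect_identical(detectAccumulation(m), "A")
})

test_that("the scan recovers a planted consumer deficit within one grid step", {
  # consumer at 0.909 saturation, planted 4x deficit: the smallest
  # stabilizing multiplier is 4 * (2/2.2) = 3.64, i.e. grid point 4
  m <- nearCapacityModel(deficit = 4)
  cand <- scanStabilizingVmax(m, targets = "V_drain")
  expect_gt(nrow(cand), 0)
  expect_true(all(cand$V_drain >= 4))          # candidate set contains >= 4x
  res <- selectMinimalChange(cand)
  expect_lte(abs(log2(res@chosen[["V_drain"]]) - log2(4)), 1)
  expect_lt(res@maxRealEigen, 0)
})

test_that("selection minimizes normalized distance with documented ties", {
  cand <- data.frame(V_a = c(2, 8), V_b = c(1, 1), nChanged = c(1L, 1L),
                     maxRe = c(-0.1, -0.2), scannedAxes = c(1L, 1L))
  res <- selectMinimalChange(cand, targets = c("V_a", "V_b"))
  expect_identical(unname(res@chosen["V_a"]), 2)
  expect_equal(res@normalizedDistance, 1)       # |log2 2| / sqrt(1)
  # ties on distance break by fewest changed parameters
  cand2 <- data.frame(V_a = c(2, 2), V_b = c(2, 1), nChanged = c(2L, 1L),
                      maxRe = c(-0.1, -0.1), scannedAxes = c(2L, 1L))
  res2 <- selectMinimalChange(cand2, targets = c("V_a", "V_b"))
  expect_identical(res2@chosen[["V_b"]], 1)
  expect_error(selectMinimalChange(cand[0, ]), "empty candidate list")
})

test_that("planted Vmax deficits in the rice model are found on their axis", {
  cfg <- generatorConfig(seed = 3, variant = "II",
                         plantedDeficit = c(V_r11 = 8))
  bundle <- makeGroundTruthBundle(cfg)
  acc <- detectAccumulation(bundle$model)
  expect_true("DXP" %in% acc)
  st <- stabilizeModel(bundle$model)
  expect_gt(st$result@chosen[["V_r11"]], 1)     # the deficit axis is changed
  ss <- findSteadyState(st$model)
  expect_true(isStable(ss))
  expect_true(all(concentrations(ss) > 0))
})

test_that("mutant median models accumulate only MEP intermediates", {
  for (v in c("I", "II", "III")) {
    cfg <- generatorConfig(seed = 1, variant = v)
    model <- buildVariantModel(v, generateParameterSet(cfg),
                               provenance = "synthetic")
    scaled <- scaleLine(model, medianLine(generateLines(cfg)))
    acc <- detectAccumulation(scaled)
    expect_gt(length(acc), 0)
    expect_true(all(acc %in% c("DXP", "CDPMEP", "MECPP")))
  }
})

test_that("an empty candidate set is an explicit status, never silent", {
  # production beyond any multiplier on a non-limiting axis: scanning the
  # feed reaction of the saturated drain cannot stabilize
  m <- nearCapacityModel(deficit = 100)
  cand <- scanStabilizingVmax(m, targets = "V_feed")
  expect_identical(nrow(cand), 0L)
  expect_false(attr(cand, "alreadyStable"))
  expect_error(selectMinimalChange(cand), "empty")
})
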