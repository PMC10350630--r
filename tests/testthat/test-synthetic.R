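test_that("generation is fully deterministic under a fixed seed", {
  cfg <- generatorConfig(seed = 51, variant = "II")
  l1 <- generateLines(cfg)
  l2 <- generateLines(cfg)
  f1 <- tempfile(); f2 <- tempfile()
  writeLineProfiles(l1, f1)
  writeLineProfiles(l2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  p1 <- generateParameterSet(cfg)
  p2 <- generateParameterSet(cfg)
  expect_identical(p1, p2)
  unlink(c(f1, f2))
})

test_that("wild-type cohorts carry no exogenous expression", {
  lines <- generateLines(generatorConfig(seed = 52, variant = "WT"))
  for (ln in lines) {
    exo <- intersect(names(ln@expressionRatio),
                     c("BjHMGS", "tHMGR", "CrMK", "CrPMK", "CrMVD"))
    expect_true(all(ln@expressionRatio[exo] == 0))
  }
  # Type I lines express only tHMGR among the transgenes
  lines1 <- generateLines(generatorConfig(seed = 52, variant = "I"))
  for (ln in lines1) {
    expect_gt(ln@expressionRatio[["tHMGR"]], 0)
    expect_identical(unname(ln@expressionRatio[c("BjHMGS", "CrMK")]), c(0, 0))
  }
})

test_that("synthetic parameter sets give stable models near the basal table", {
  # the calibration pins the wild-type backbone to the basal concentration
  # table; engineered variants shift their steady state (that is the point
  # of the engineering) but must remain stable and positive
  cfg <- generatorConfig(seed = 53, variant = "WT")
  params <- generateParameterSet(cfg)
  expect_identical(attr(params, "provenance"), "synthetic")
  m <- buildVariantModel("WT", params, provenance = "synthetic")
  expect_identical(provenance(m), "synthetic")
  ss <- findSteadyState(m)
  expect_true(isStable(ss))
  basal <- mvamep:::.basalDynamic
  got <- concentrations(ss)[names(basal)]
  expect_true(all(abs(got - basal) / basal < 0.2))
  cfg3 <- generatorConfig(seed = 53, variant = "III")
  m3 <- buildVariantModel("III", generateParameterSet(cfg3),
                          provenance = "synthetic")
  ss3 <- findSteadyState(m3)
  expect_true(isStable(ss3))
  expect_true(all(concentrations(ss3) > 0))
  # the ectopic pathway raises plastid IPP at the basal expression state
  expect_gt(concentrations(ss3)[["IPP_pla"]], got[["IPP_pla"]])
})

test_that("empirical log-spreads match the configured values", {
  cfg <- generatorConfig(seed = 54, variant = "WT", nLines = 120,
                         plantedLinks = NULL)
  lines <- generateLines(cfg)
  lsd <- sd(log(vapply(lines, function(p) p@expressionRatio[["OsDXS"]], 0)))
  se <- 0.3 / sqrt(2 * 120)
  expect_lt(abs(lsd - 0.3), 3 * se)
  hsd <- sd(log10(vapply(lines, function(p)
    p@hormones$level[match("IAA", p@hormones$hormone)], 0)))
  seH <- 0.2 / sqrt(2 * 120)
  expect_lt(abs(hsd - 0.2), 3 * seH)
})

test_that("censored hormones are reported at the detection limit", {
  cfg <- generatorConfig(seed = 55, variant = "I", nLines = 60)
  lines <- generateLines(cfg)
  ga3 <- vapply(lines, function(p) {
    i <- match("GA3", p@hormones$hormone)
    c(p@hormones$level[i], p@hormones$belowDetection[i])
  }, c(0, 0))
  flagged <- ga3[2, ] == 1
  expect_gt(sum(flagged), 0)                 # some censoring does occur
  expect_true(all(ga3[1, flagged] == 0.25))  # recorded at the limit
  expect_true(all(ga3[1, !flagged] >= 0.25))
})

test_that("ground-truth bundles support the documented edge cases", {
  # zero planted links: nothing to assess downstream
  cfg0 <- generatorConfig(seed = 56, variant = "I", plantedLinks = NULL)
  b0 <- makeGroundTruthBundle(cfg0)
  expect_null(b0$links)
  # everything censored: coupling leaves the model basal
  cfgC <- generatorConfig(seed = 56, variant = "I",
                          detectionLimits = c(iP = 1e9))
  linesC <- generateLines(cfgC)
  links <- fitHormoneCorrelations(linesC)
  expect_false("iP" %in% links$hormone)
  m <- buildVariantModel("I")
  bd <- c(iP = TRUE)
  link <- data.frame(hormone = "iP", response = "OsDXS",
                     responseType = "gene", g = 0.8, alphaScale = 1.5^(-0.8),
                     K = NA_real_, formalism = "power_law", r2adj = 0.8,
                     p = 0.01, n = 12, hormoneRef = 1.5)
  m2 <- attachHormoneModifiers(m, link, c(iP = 1e9), belowDetection = bd)
  expect_equal(mvamep:::.modelParameters(m2), mvamep:::.modelParameters(m))
  expect_true(all(vapply(reactions(m2), function(r) r@multiplier, 0) == 1))
})

test_that("generated profiles always satisfy the line-profile invariants", {
  for (v in c("WT", "I", "II", "III")) {
    lines <- generateLines(generatorConfig(seed = 57, variant = v))
    for (ln in lines) {
      expect_true(validObject(ln, test = TRUE))
      expect_true(all(ln@expressionRatio >= 0))
      expect_true(all(ln@hormones$level >= 0))
      expect_identical(ln@phenotype[["leaves"]],
                       round(ln@phenotype[["leaves"]]))
    }
  }
})
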