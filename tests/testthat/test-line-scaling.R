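test_that("unit expression ratios leave the model untouched", {
  m <- buildVariantModel("I")
  genes <- unique(na.omit(vapply(reactions(m), function(r) r@gene, "")))
  ln <- mkProfile("L1", "I", setNames(rep(1, length(genes)), genes))
  m2 <- scaleLine(m, ln)
  expect_identical(mvamep:::.modelParameters(m2), mvamep:::.modelParameters(m))
})

test_that("a single-gene ratio scales only that reaction's V", {
  m <- buildVariantModel("I")
  ln <- mkProfile("L1", "I", c(tHMGR = 2))
  m2 <- scaleLine(m, ln)
  p1 <- mvamep:::.modelParameters(m)
  p2 <- mvamep:::.modelParameters(m2)
  expect_identical(p2[["V_e_HMGR_pla"]], 2 * p1[["V_e_HMGR_pla"]])
  other <- setdiff(names(p1), "V_e_HMGR_pla")
  expect_identical(p2[other], p1[other])
})

test_that("a zero exogenous ratio silences the ectopic reaction", {
  m <- buildVariantModel("I")
  ln <- mkProfile("L1", "I", c(tHMGR = 0))
  m2 <- scaleLine(m, ln)
  cm <- mvamep:::.compileModel(m2)
  v <- mvamep:::.cmRates(cm, cm$basal)
  expect_identical(v[match("e_HMGR_pla", cm$ids)], 0)
})

test_that("scaling then reciprocal scaling restores parameters bit-for-bit", {
  m <- buildVariantModel("II")
  ratios <- c(tHMGR = 1.7, BjHMGS = 0.4, CrMK = 2.3, OsDXS = 0.8,
              OsHDR = 1.2)
  ln <- mkProfile("L1", "II", ratios)
  back <- mkProfile("L2", "II", 1 / ratios)
  m2 <- scaleLine(scaleLine(m, ln), back)
  expect_identical(mvamep:::.modelParameters(m2), mvamep:::.modelParameters(m))
})

test_that("variant mismatch and missing exogenous ratios are errors", {
  m <- buildVariantModel("I")
  expect_error(scaleLine(m, mkProfile("L1", "II", c(tHMGR = 1, BjHMGS = 1,
                                                    CrMK = 1))),
               "does not match")
  # the variant's own transgene must be reported
  expect_error(scaleLine(m, mkProfile("L1", "I", c(OsDXS = 1))), "tHMGR")
})

test_that("median line takes element-wise medians with midpoint convention", {
  ps <- list(mkProfile("a", "I", c(tHMGR = 1, OsDXS = 1), c(iP = 1),
                       c(height = 50)),
             mkProfile("b", "I", c(tHMGR = 2, OsDXS = 3), c(iP = 2),
                       c(height = 60)),
             mkProfile("c", "I", c(tHMGR = 4, OsDXS = 5), c(iP = 8),
                       c(height = 70)))
  med <- medianLine(ps)
  expect_equal(med@expressionRatio[["tHMGR"]], 2)   # median of {1,2,4}
  expect_equal(med@hormones$level, 2)
  expect_equal(med@phenotype[["height"]], 60)
  # even count: arithmetic mean of the two middle values
  med2 <- medianLine(ps[1:2])
  expect_equal(med2@expressionRatio[["tHMGR"]], 1.5)
  expect_equal(med2@expressionRatio[["OsDXS"]], 2)
  # identical profiles give back any input
  med3 <- medianLine(list(ps[[1]], ps[[1]]))
  expect_equal(med3@expressionRatio, ps[[1]]@expressionRatio)
})

test_that("median line flags a hormone censored only on majority", {
  h <- function(bd) data.frame(hormone = "GA3", level = 0.25,
                               belowDetection = bd)
  ps <- lapply(1:3, function(i)
    lineProfile(paste0("l", i), "I", c(tHMGR = 1), hormones = h(i <= 2)))
  expect_true(medianLine(ps)@hormones$belowDetection)
  ps2 <- lapply(1:4, function(i)
    lineProfile(paste0("l", i), "I", c(tHMGR = 1), hormones = h(i <= 2)))
  expect_false(medianLine(ps2)@hormones$belowDetection)  # exactly half
})

test_that("median line rejects empty and mixed-variant inputs", {
  expect_error(medianLine(list()), "non-empty")
  ps <- list(mkProfile("a", "I", c(tHMGR = 1)),
             mkProfile("b", "II", c(tHMGR = 1, BjHMGS = 1, CrMK = 1)))
  expect_error(medianLine(ps), "mixed variants")
})
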