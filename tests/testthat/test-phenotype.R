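test_that("leaf area applies the 0.75 shape correction", {
  expect_identical(leafArea(1, 1), 0.75)
  expect_identical(leafArea(0, 3), 0)
  expect_identical(leafArea(10, 1), 7.5)
  expect_error(leafArea(-1, 1), "non-negative")
})

test_that("published models evaluate to their printed coefficients", {
  m1 <- shippedPhenotypeModels("I")
  expect_equal(evaluatePhenotype(m1$height, c(MDS = 0, DXP = 0)), 56.028)
  expect_equal(evaluatePhenotype(m1$height, c(MDS = 1, DXP = 0.5)),
               56.028 - 22.688 + 1.590 * 0.5)
  # leaf-count models round to the nearest integer
  expect_identical(evaluatePhenotype(m1$leaves, c(DXP = 0, MEcPP = 0)), 5)
  m3 <- shippedPhenotypeModels("III")
  expect_equal(evaluatePhenotype(m3$chlorophyll, c(HDR = 0, DMAPP = 0)),
               33.218)
  m2 <- shippedPhenotypeModels("II")
  expect_equal(evaluatePhenotype(m2$leaf_width, c(HMGS = 1, MVD = 1)),
               0.596 + 0.124 + 0.0464)
  expect_error(evaluatePhenotype(m1$height, c(MDS = 0)), "DXP")
})

test_that("prediction is affine in each predictor apart from leaf rounding", {
  m <- shippedPhenotypeModels("III")$height
  at <- function(g) evaluatePhenotype(m, c(GA4 = g, HMGS = 0.5))
  # equal increments in a predictor give equal increments in the prediction
  expect_equal(at(2) - at(1), at(3) - at(2))
  expect_equal(at(1) - at(0), 25.445)
})

test_that("forward stepwise recovers a planted predictor among decoys", {
  set.seed(31)
  n <- 30
  d <- as.data.frame(matrix(rnorm(n * 6), n, 6,
                            dimnames = list(NULL, paste0("x", 1:6))))
  d$y <- 2 * d$x1 + rnorm(n, 0, 0.8)
  fit <- forwardStepwise(d, "y")
  expect_false(is.null(fit$model))
  expect_true("x1" %in% names(fit$model@coefficients))
  expect_equal(fit$model@coefficients[["x1"]], 2, tolerance = 0.3)
})

test_that("pure-noise responses return no model", {
  set.seed(32)
  n <- 30
  d <- as.data.frame(matrix(rnorm(n * 5), n, 5,
                            dimnames = list(NULL, paste0("x", 1:5))))
  d$y <- rnorm(n)
  fit <- forwardStepwise(d, "y")
  expect_null(fit$model)
  expect_true(nrow(fit$trace) > 0)
})

test_that("stepwise never violates its own gates", {
  set.seed(33)
  n <- 30
  d <- as.data.frame(matrix(rnorm(n * 4), n, 4,
                            dimnames = list(NULL, paste0("x", 1:4))))
  d$x5 <- d$x1 + rnorm(n, 0, 0.1)          # collinear decoy (|r| > 0.7)
  d$y <- 1.5 * d$x1 - 1 * d$x2 + rnorm(n, 0, 0.7)
  fit <- forwardStepwise(d, "y")
  expect_false(is.null(fit$model))
  sel <- names(fit$model@coefficients)[-1]
  expect_false(all(c("x1", "x5") %in% sel))  # collinear pair excluded
  sm <- summary(lm(reformulate(sel, "y"), data = d))
  expect_true(all(sm$coefficients[-1, 4] < 0.05))
  expect_gt(fit$model@adjR2, 0.2)
  # accepted steps strictly improve adjusted R2 along the trace
  acc <- fit$trace[fit$trace$action == "accept", ]
  if (nrow(acc) > 1) expect_true(all(diff(acc$adjR2) > 0))
})

test_that("the multilevel chain predicts synthetic line phenotypes", {
  cfg <- generatorConfig(seed = 41, variant = "I")
  bundle <- makeGroundTruthBundle(cfg)
  model <- buildVariantModel("I", generateParameterSet(cfg),
                             provenance = "synthetic")
  ln <- bundle$lines[[1]]
  pred <- predictLinePhenotype(ln, model,
                               phenotypeModels = bundle$phenotypeModels)
  # predictions from the generating models fall within the planted noise band
  for (resp in c("height", "leaf_length", "chlorophyll")) {
    expect_false(is.na(pred[[resp]]))
    obs <- ln@phenotype[[resp]]
    expect_lt(abs(pred[[resp]] - obs) / abs(obs), 0.35)
  }
  # a line identical to the median predicts like the median line
  med <- medianLine(bundle$lines)
  p1 <- predictLinePhenotype(med, model,
                             phenotypeModels = bundle$phenotypeModels)
  med2 <- med; med2@lineId <- "copy"
  p2 <- predictLinePhenotype(med2, model,
                             phenotypeModels = bundle$phenotypeModels)
  expect_identical(p1, p2)
})

test_that("small-sample AICc penalizes added parameters", {
  set.seed(34)
  d <- data.frame(x1 = rnorm(12), x2 = rnorm(12))
  d$y <- d$x1 + rnorm(12, 0, 0.5)
  f1 <- lm(y ~ x1, data = d)
  f2 <- lm(y ~ x1 + x2, data = d)
  expect_gt(mvamep:::.aicc(f2) - AIC(f2), mvamep:::.aicc(f1) - AIC(f1))
})
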