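test_that("formalism choice follows the 0.5 decision ratio", {
  expect_identical(chooseFormalism(0.8, 1), "power_law")    # ratio 0.8
  expect_identical(chooseFormalism(0.2, 2), "saturating")   # ratio 0.1
  expect_identical(chooseFormalism(0.5, 1), "saturating")   # boundary
  expect_identical(chooseFormalism(-0.1, 0.1), "power_law") # ratio 1
  expect_error(chooseFormalism(0.5, 0), "nonzero")
  expect_error(chooseFormalism(NaN, 1), "finite")
})

test_that("a planted exponent is recovered from synthetic lines", {
  cfg <- generatorConfig(seed = 21, variant = "I", nLines = 30)
  lines <- generateLines(cfg)
  links <- fitHormoneCorrelations(lines)
  row <- links[links$hormone == "iP" & links$response == "OsDXS", ]
  expect_identical(nrow(row), 1L)
  # slope SE at these settings is ~0.12; allow three of them
  expect_lt(abs(row$g - 0.8), 0.36)
  expect_lt(row$p, 0.05)
})

test_that("constant hormones and all-censored hormones yield no link", {
  cfg <- generatorConfig(seed = 22, variant = "I", nLines = 12,
                         hormoneLogSD = 0)
  lines <- generateLines(cfg)
  expect_identical(nrow(fitHormoneCorrelations(lines)), 0L)
  # detection limit above every draw: the hormone is skipped entirely
  cfg2 <- generatorConfig(seed = 22, variant = "I", nLines = 12,
                          detectionLimits = c(iP = 1e6))
  lines2 <- generateLines(cfg2)
  links2 <- fitHormoneCorrelations(lines2)
  expect_false("iP" %in% links2$hormone)
})

test_that("attaching and removing links restores the basal model exactly", {
  m <- buildVariantModel("I")
  link <- data.frame(hormone = "iP", response = "OsDXS",
                     responseType = "gene", g = 0.7, alphaScale = 1.5^(-0.7),
                     K = NA_real_, formalism = "power_law", r2adj = 0.8,
                     p = 0.01, n = 12, hormoneRef = 1.5)
  m2 <- attachHormoneModifiers(m, link, c(iP = 3))
  mult <- vapply(reactions(m2), function(r) r@multiplier, 0)
  ids <- vapply(reactions(m2), function(r) r@id, "")
  expect_equal(mult[ids == "r10"], (3 / 1.5)^0.7, ignore_attr = TRUE)
  expect_true(all(mult[ids != "r10"] == 1))
  m3 <- removeHormoneModifiers(m2)
  expect_equal(m3, m)
})

test_that("hormones below detection revert the kinetics to basal", {
  m <- buildVariantModel("I")
  link <- data.frame(hormone = "GA3", response = "OsDXR",
                     responseType = "gene", g = 1.2, alphaScale = 0.3^(-1.2),
                     K = NA_real_, formalism = "power_law", r2adj = 0.9,
                     p = 0.01, n = 12, hormoneRef = 0.3)
  m2 <- attachHormoneModifiers(m, link, c(GA3 = 0.25),
                               belowDetection = c(GA3 = TRUE))
  expect_true(all(vapply(reactions(m2), function(r) r@multiplier, 0) == 1))
})

test_that("the multiplier is anchored at 1, monotone, and saturates to alpha", {
  satLink <- list(formalism = "saturating", alphaScale = ((2 + 1.5) / 1.5)^0.9,
                  K = 2, g = 0.9)
  f <- vapply(c(0.1, 0.5, 1.5, 5, 50, 1e9),
              function(H) mvamep:::.hormoneFactor(satLink, H), 0)
  expect_true(all(diff(f) > 0))
  expect_equal(f[3], 1)                        # anchored at the reference
  expect_equal(f[6], satLink$alphaScale, tolerance = 1e-6)
  powLink <- list(formalism = "power_law", alphaScale = 1.5^(-0.7), g = 0.7)
  g <- vapply(c(0.1, 1.5, 10), function(H) mvamep:::.hormoneFactor(powLink, H), 0)
  expect_true(all(diff(g) > 0))
  expect_equal(g[2], 1)
})

test_that("metabolite links attach to producers and validate by sign", {
  cfg <- generatorConfig(seed = 23, variant = "I")
  lines <- generateLines(cfg)
  model <- buildVariantModel("I", generateParameterSet(cfg),
                             provenance = "synthetic")
  st <- stabilizeModel(scaleLine(model, medianLine(lines)))
  # a positive link into the entry of the MVA chain: raising the hormone
  # raises HMG-CoA production, so the simulated correlation must be positive
  link <- data.frame(hormone = "iP", response = "HMGCoA_cyt",
                     responseType = "metabolite", g = 0.8,
                     alphaScale = 1.5^(-0.8), K = NA_real_,
                     formalism = "power_law", r2adj = 0.8, p = 0.01, n = 12,
                     hormoneRef = 1.5)
  rec <- validateCorrelationRecovery(st$model, link, lines)
  expect_identical(rec$assessed, 1L)
  expect_identical(rec$matched, 1L)
  # no links: nothing assessed
  rec0 <- validateCorrelationRecovery(st$model, link[0, ], lines)
  expect_identical(unlist(rec0[c("assessed", "matched", "ambiguous")]),
                   c(assessed = 0L, matched = 0L, ambiguous = 0L))
})

test_that("links to pools with no producing reaction are configuration errors", {
  m <- buildVariantModel("I")
  bad <- data.frame(hormone = "iP", response = "NOT_A_POOL",
                    responseType = "metabolite", g = 1, alphaScale = 1,
                    K = NA_real_, formalism = "power_law", r2adj = 0.8,
                    p = 0.01, n = 12, hormoneRef = 1.5)
  expect_error(attachHormoneModifiers(m, bad, c(iP = 1.5)),
               "no matching reaction|no producing reaction")
})
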