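# For the one-pool model with constant production flux c and a
# Michaelis-Menten consumer (V, K), the steady state M* = cK/(V - c) gives
# closed-form logarithmic sensitivities:
#   d log M* / d log K_out = 1
#   d log M* / d log V_out = -V/(V - c)
#   d log M* / d log V_in  = +V/(V - c)      (c is proportional to V_in)
test_that("log-sensitivities match closed-form values on the one-pool model", {
  Vin <- 4; Kin <- 1; Vout <- 5; Kout <- 2
  cflux <- Vin * 1 / (Kin + 1)
  m <- toyOnePool(Vin = Vin, Kin = Kin, Vout = Vout, Kout = Kout)
  ss <- findSteadyState(m)
  sm <- logSensitivities(m, ss)
  S <- sensitivities(sm)
  expect_equal(S["M", "K_out_M"], 1, tolerance = 1e-3)
  expect_equal(S["M", "V_out"], -Vout / (Vout - cflux), tolerance = 1e-3)
  expect_equal(S["M", "V_in"], Vout / (Vout - cflux), tolerance = 1e-3)
  # fixed-substrate K of the producer: c scales by -Kin/(Kin+s)
  expect_equal(S["M", "K_in_S"],
               Vout / (Vout - cflux) * (-Kin / (Kin + 1)), tolerance = 1e-3)
})

test_that("halving the perturbation changes entries below 1e-4 relative", {
  m <- toyChain3()
  ss <- findSteadyState(m)
  s1 <- sensitivities(logSensitivities(m, ss, delta = 0.005))
  s2 <- sensitivities(logSensitivities(m, ss, delta = 0.0025))
  rel <- abs(s1 - s2) / pmax(abs(s1), 1)
  expect_lt(max(rel), 1e-4)
})

test_that("a planted hormone power law is recovered as its exponent", {
  # consumer far from saturation, so M*(H) is a pure power law alpha * H^g
  m <- kineticModel(
    c(M = 1),
    list(reactionSpec("in", c(S = 1L), c(M = 1L), V = 4, K = c(S = 1),
                      gene = "GENE1"),
         reactionSpec("out", c(M = 1L), V = 1000, K = c(M = 1000))),
    fixed = c(S = 1))
  g <- 2
  link <- data.frame(hormone = "iP", response = "GENE1",
                     responseType = "gene", g = g, alphaScale = 1.5^(-g),
                     K = NA_real_, formalism = "power_law", r2adj = 1,
                     p = 0, n = 30, hormoneRef = 1.5)
  solveAt <- function(H) {
    mm <- attachHormoneModifiers(m, link, c(iP = H))
    concentrations(findSteadyState(mm))[["M"]]
  }
  d <- 0.01
  slope <- (log(solveAt(1.5 * (1 + d))) - log(solveAt(1.5 / (1 + d)))) /
    (2 * log1p(d))
  expect_equal(slope, g, tolerance = 0.01)
})

test_that("aggregation is the Euclidean norm divided by the count", {
  expect_equal(unname(aggregateSensitivities(matrix(c(3, 4), 2, 1))$perParameter),
               2.5)
  z <- matrix(0, 3, 4)
  expect_true(all(aggregateSensitivities(z)$perParameter == 0))
  expect_true(all(aggregateSensitivities(z)$perMetabolite == 0))
  set.seed(7)
  r <- matrix(rnorm(12), 3, 4)
  agg <- aggregateSensitivities(r)
  expect_equal(unname(agg$perParameter), sqrt(colSums(r^2)) / 3)
  expect_equal(unname(agg$perMetabolite), sqrt(rowSums(r^2)) / 4)
})

test_that("aggregates are invariant under row/column permutation", {
  set.seed(8)
  r <- matrix(rnorm(20), 4, 5,
              dimnames = list(paste0("m", 1:4), paste0("p", 1:5)))
  agg <- aggregateSensitivities(r)
  perm <- r[c(3, 1, 4, 2), c(5, 2, 1, 4, 3)]
  aggP <- aggregateSensitivities(perm)
  expect_equal(sort(unname(agg$perParameter)), sort(unname(aggP$perParameter)))
  expect_equal(sort(unname(agg$perMetabolite)), sort(unname(aggP$perMetabolite)))
})

test_that("eigenvalue sensitivities behave as expected on the one-pool model", {
  # with the consumer nearly linear (K >> M*), |lambda| = V K/(K + M*)^2 is
  # homogeneous of degree ~1 in V_out and nearly independent of V_in
  m <- toyOnePool(Vin = 4, Kin = 1, Vout = 400, Kout = 200)
  ss <- findSteadyState(m)
  es <- eigenvalueSensitivities(m, ss)
  expect_equal(unname(es[1, "V_out"]), 1, tolerance = 0.05)
  expect_lt(abs(es[1, "V_in"]), 0.05)
  # two perturbation sizes agree
  es2 <- eigenvalueSensitivities(m, ss, delta = 0.005)
  expect_equal(es[1, ], es2[1, ], tolerance = 1e-3)
})

test_that("wild-type sensitivity matrix is mostly insensitive", {
  wt <- buildVariantModel("WT")
  ss <- findSteadyState(wt)
  sm <- logSensitivities(wt, ss)
  S <- sensitivities(sm)
  expect_identical(nrow(S), 14L)
  # a plausible biosynthetic model: the vast majority of |S| below one
  expect_gt(mean(abs(S) <= 1, na.rm = TRUE), 0.9)
  # aggregates recomputable from entries
  agg <- aggregateSensitivities(S)
  expect_equal(agg$perParameter, perParameterIndex(sm))
  expect_equal(agg$perMetabolite, perMetaboliteIndex(sm))
})
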