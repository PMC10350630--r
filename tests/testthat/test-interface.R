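test_that("model documents round-trip with bit-equal parameters", {
  m <- buildVariantModel("III")
  f <- tempfile(fileext = ".json")
  writePathwayModel(m, f)
  m2 <- readPathwayModel(f)
  expect_s4_class(m2, "PathwayModel")
  expect_identical(variant(m2), "III")
  expect_identical(mvamep:::.modelParameters(m2), mvamep:::.modelParameters(m))
  expect_identical(pools(m2)$name, pools(m)$name)
  expect_equal(pools(m2)$basal, pools(m)$basal)
  # write -> read -> write is byte-stable
  f2 <- tempfile(fileext = ".json")
  writePathwayModel(m2, f2)
  expect_identical(readLines(f), readLines(f2))
  unlink(c(f, f2))
})

test_that("malformed model documents name the offending element", {
  f <- tempfile(fileext = ".json")
  writeLines('{"variant": "WT"}', f)
  expect_error(readPathwayModel(f), "pools")
  writeLines(jsonlite::toJSON(list(
    pools = data.frame(name = "A", compartment = "cytosol",
                       role = "dynamic", basal = 1),
    reactions = list(list(substrates = list(A = 1)))), auto_unbox = TRUE), f)
  expect_error(readPathwayModel(f), "reactions\\[1\\]\\$id")
  unlink(f)
})

test_that("SBML export carries every species and reaction", {
  m <- buildVariantModel("II")
  f <- tempfile(fileext = ".xml")
  writeSBML(m, f)
  doc <- xml2::read_xml(f)
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core")
  species <- xml2::xml_find_all(doc, "//s:species", ns)
  rxns <- xml2::xml_find_all(doc, "//s:reaction", ns)
  expect_identical(length(species), nrow(pools(m)))
  expect_identical(length(rxns), length(reactions(m)))
  # kinetic laws are explicit MathML rational expressions
  maths <- xml2::xml_find_all(doc, "//s:kineticLaw", ns)
  expect_identical(length(maths), length(reactions(m)))
  unlink(f)
})

test_that("line-profile TSV round-trips levels, flags and phenotypes", {
  lines <- generateLines(generatorConfig(seed = 61, variant = "II"))
  f <- tempfile(fileext = ".tsv")
  writeLineProfiles(lines, f)
  back <- readLineProfiles(f)
  expect_identical(length(back), length(lines))
  for (i in seq_along(lines)) {
    expect_equal(back[[i]]@expressionRatio[names(lines[[i]]@expressionRatio)],
                 lines[[i]]@expressionRatio)
    expect_equal(back[[i]]@hormones$level, lines[[i]]@hormones$level)
    expect_identical(back[[i]]@hormones$belowDetection,
                     lines[[i]]@hormones$belowDetection)
    expect_equal(back[[i]]@phenotype, lines[[i]]@phenotype)
  }
  unlink(f)
})

test_that("the pipeline runs end-to-end and is reproducible", {
  d1 <- file.path(tempdir(), "pipe1"); d2 <- file.path(tempdir(), "pipe2")
  cfg <- generatorConfig(seed = 7, variant = "WT", nLines = 10)
  r1 <- runPipeline(variant = "WT", seed = 7, outDir = d1, config = cfg,
                    sensitivity = FALSE)
  expect_true(r1$summary$stable)
  expect_false(r1$summary$stabilized)
  expect_true(file.exists(file.path(d1, "summary.json")))
  expect_true(file.exists(file.path(d1, "lines.tsv")))
  # provenance is recorded in every report
  expect_identical(r1$summary$provenance$parameters, "synthetic")
  expect_identical(r1$summary$provenance$seed, 7)
  r2 <- runPipeline(variant = "WT", seed = 7, outDir = d2, config = cfg,
                    sensitivity = FALSE)
  expect_identical(readLines(file.path(d1, "summary.json")),
                   readLines(file.path(d2, "summary.json")))
  unlink(c(d1, d2), recursive = TRUE)
})
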