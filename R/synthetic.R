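#' @include line-profile.R phenotype.R hormones.R stabilization.R
NULL

## Type-level median expression ratios emulating the engineered lines:
## DXS is induced while the later MEP steps (DXR, MDS, HDS) are repressed,
## increasingly so from Type I to Type III, which is what destabilizes the
## line models and is later compensated by the Vmax stabilization scan.
.typeExpressionMedians <- list(
  WT  = c(),
  I   = c(OsDXS = 1.4, OsDXR = 0.25, OsMDS = 0.80, OsHDS = 0.90, OsWR1 = 1.2),
  II  = c(OsDXS = 1.6, OsDXR = 0.15, OsMDS = 0.30, OsHDS = 0.35, OsWR1 = 1.3),
  III = c(OsDXS = 1.8, OsDXR = 0.12, OsMDS = 0.20, OsHDS = 0.25, OsWR1 = 1.4))

## log10 medians of the hormone panel (relative units)
.hormoneLogMedians <- c(trans_zeatin = log10(2), zeatin_riboside = log10(5),
                        iP = log10(1.5), GA1 = log10(0.5), GA3 = log10(0.3),
                        GA4 = log10(0.2), IAA = log10(20), ABA = log10(50),
                        salicylic_acid = log10(200), jasmonic_acid = log10(30),
                        ACC = log10(100))

.defaultDetectionLimits <- c(GA3 = 0.25, GA4 = 0.15)

.defaultPlantedLinks <- function(variant) {
  links <- data.frame(
    hormone = c("iP", "iP", "ABA"),
    gene = c("OsDXS", "OsDXR", "OsMCT"),
    g = c(0.8, 0.6, 0.5), stringsAsFactors = FALSE)
  if (variant == "I")
    links <- rbind(links, data.frame(hormone = "iP", gene = "OsHMGR", g = 0.5))
  links
}

.defaultPlantedPhenotypes <- function() list(
  height      = list(intercept = 60, beta = c(OsDXR = -12, iP = 2),
                     targetR2 = 0.6),
  leaves      = list(intercept = 4.5, beta = c(OsDXS = 1.2, OsMDS = -0.8),
                     targetR2 = 0.7),
  leaf_length = list(intercept = 32, beta = c(OsHMGS = -4, ABA = 0.05),
                     targetR2 = 0.7),
  leaf_width  = list(intercept = 0.9, beta = c(OsMCT = 0.3,
                                               salicylic_acid = 0.002),
                     targetR2 = 0.5),
  chlorophyll = list(intercept = 35, beta = c(iP = 2, OsHDR = -3),
                     targetR2 = 0.7))

#' Configuration for the synthetic-data generator
#'
#' Collects every knob of the generator: cohort size (defaulting to the study
#' cohort sizes of 12, 10 and 12 independent lines for Types I, II and III),
#' log-scale expression variability (endogenous genes 0.3; exogenous
#' transgenes a shared per-line integration effect of 0.5 plus per-gene noise
#' of 0.33, reflecting non-targeted transgene integration), the hormone
#' panel's log10 medians and spread with detection limits, planted
#' hormone-to-gene links, and planted linear phenotype models with noise
#' calibrated to a target R-squared.
#'
#' @param seed integer random seed; recorded in the output.
#' @param variant variant to generate (\code{WT}, \code{I}, \code{II},
#'   \code{III}).
#' @param nLines number of lines (default 12/10/12 for I/II/III, 5 for WT).
#' @param endoLogSD log-scale SD of endogenous expression ratios.
#' @param exoLineSD,exoGeneSD log-scale SDs of the shared per-line and
#'   per-gene exogenous expression components.
#' @param exoMedian median activity ratio of exogenous transgenes (relative
#'   to the endogenous counterpart's basal activity).
#' @param hormoneLogSD log10-scale SD of hormone levels.
#' @param detectionLimits named numeric vector of hormone detection limits.
#' @param plantedLinks data.frame(hormone, gene, g) of planted hormone-gene
#'   couplings (power-law exponents), or NULL for none.
#' @param plantedPhenotypes list of planted phenotype models (intercept,
#'   beta, targetR2), or NULL for none.
#' @param plantedDeficit named numeric vector of Vmax deficit factors applied
#'   to the model (for stabilization ground-truth bundles), or NULL.
#' @return a \code{GeneratorConfig} list.
#' @export
generatorConfig <- function(seed = 1L, variant = "I", nLines = NULL,
                            endoLogSD = 0.3, exoLineSD = 0.5,
                            exoGeneSD = 0.33, exoMedian = 0.5,
                            hormoneLogSD = 0.2,
                            detectionLimits = .defaultDetectionLimits,
                            plantedLinks = .defaultPlantedLinks(variant),
                            plantedPhenotypes = .defaultPlantedPhenotypes(),
                            plantedDeficit = NULL) {
  if (is.null(nLines))
    nLines <- c(WT = 5L, I = 12L, II = 10L, III = 12L)[[variant]]
  stopifnot(nLines >= 1, endoLogSD >= 0, exoLineSD >= 0, exoGeneSD >= 0,
            hormoneLogSD >= 0)
  structure(list(seed = as.integer(seed), variant = variant,
                 nLines = as.integer(nLines), endoLogSD = endoLogSD,
                 exoLineSD = exoLineSD, exoGeneSD = exoGeneSD,
                 exoMedian = exoMedian, hormoneLogSD = hormoneLogSD,
                 detectionLimits = detectionLimits,
                 plantedLinks = plantedLinks,
                 plantedPhenotypes = plantedPhenotypes,
                 plantedDeficit = plantedDeficit),
            class = "GeneratorConfig")
}

#' Generate a synthetic calibrated parameter set
#'
#' Samples substrate binding constants log-uniformly within a factor of two
#' around their calibration defaults and re-solves the saturation rate
#' constants V so that the Table-of-basal concentrations remain an exact
#' steady state of the wild-type design flux distribution; the resulting
#' variant model is required to be stable (resampled otherwise, up to
#' \code{maxAttempts}). Provenance is recorded as \code{"synthetic"}.
#'
#' @param config a \code{GeneratorConfig}.
#' @param maxAttempts resampling budget before failing with diagnostics.
#' @return named parameter vector with attributes \code{provenance} and
#'   \code{seed}.
#' @export
generateParameterSet <- function(config, maxAttempts = 20L) {
  stopifnot(inherits(config, "GeneratorConfig"))
  set.seed(config$seed + 104729L)
  base <- defaultParameterSet(config$variant)
  kNames <- grep("^K_", names(base), value = TRUE)
  ## exchange-export K's are derived quantities, not sampled
  kNames <- kNames[!grepl("^K_x_(IPP|DMAPP)_exp", kNames)]
  lastErr <- NULL
  for (attempt in seq_len(maxAttempts)) {
    kScale <- stats::setNames(10^stats::runif(length(kNames), -0.3, 0.3), kNames)
    params <- .calibrateParameterSet(config$variant, kScale)
    model <- buildVariantModel(config$variant, params, provenance = "synthetic")
    ss <- findSteadyState(model, quick = TRUE)
    if (ss@converged && ss@stable) {
      attr(params, "provenance") <- "synthetic"
      attr(params, "seed") <- config$seed
      return(params)
    }
    lastErr <- sprintf("attempt %d: converged=%s stable=%s", attempt,
                       ss@converged, ss@stable)
  }
  stop("parameter calibration failed after ", maxAttempts, " attempts (",
       lastErr, ")")
}

#' Generate synthetic line profiles
#'
#' Draws per-line hormone levels (log10-normal, censored at the detection
#' limits), gene expression ratios (log-normal around the type medians, with
#' planted hormone couplings acting multiplicatively and exogenous genes
#' present only in the matching variant), and phenotypes from the planted
#' linear models plus Gaussian noise calibrated to each model's target
#' R-squared; leaf counts are rounded. Fully deterministic under the
#' config seed.
#'
#' @param config a \code{GeneratorConfig}.
#' @return list of \linkS4class{LineProfile} objects.
#' @export
generateLines <- function(config) {
  stopifnot(inherits(config, "GeneratorConfig"))
  set.seed(config$seed)
  n <- config$nLines
  variant <- config$variant
  medians <- stats::setNames(rep(1, length(.endogenousGenes) + 1),
                             c(.endogenousGenes, "OsWR1"))
  tm <- .typeExpressionMedians[[variant]]
  medians[names(tm)] <- tm
  exo <- .variantExogenous(variant)
  hormNames <- names(.hormoneLogMedians)
  ## hormones first (they drive planted expression couplings)
  hormLevels <- matrix(0, n, length(hormNames),
                       dimnames = list(NULL, hormNames))
  for (h in hormNames)
    hormLevels[, h] <- 10^(.hormoneLogMedians[[h]] +
                             stats::rnorm(n, 0, config$hormoneLogSD))
  hormMed <- 10^.hormoneLogMedians
  ## expression ratios
  exprMat <- matrix(0, n, length(medians) + length(exo),
                    dimnames = list(NULL, c(names(medians), exo)))
  links <- config$plantedLinks
  for (i in seq_len(n)) {
    for (g in names(medians)) {
      fac <- 1
      if (!is.null(links) && nrow(links)) {
        gl <- links[links$gene == g, , drop = FALSE]
        for (k in seq_len(nrow(gl)))
          fac <- fac * (hormLevels[i, gl$hormone[k]] /
                          hormMed[[gl$hormone[k]]])^gl$g[k]
      }
      exprMat[i, g] <- medians[[g]] * fac *
        exp(stats::rnorm(1, 0, config$endoLogSD))
    }
    if (length(exo)) {
      u <- stats::rnorm(1, 0, config$exoLineSD)
      for (g in exo)
        exprMat[i, g] <- config$exoMedian *
          exp(u + stats::rnorm(1, 0, config$exoGeneSD))
    }
  }
  ## phenotypes from the planted models
  phenMat <- matrix(NA_real_, n, length(.phenotypeNames),
                    dimnames = list(NULL, .phenotypeNames))
  for (resp in names(config$plantedPhenotypes)) {
    pm <- config$plantedPhenotypes[[resp]]
    signal <- rep(pm$intercept, n)
    for (p in names(pm$beta)) {
      x <- if (p %in% colnames(exprMat)) exprMat[, p]
           else if (p %in% hormNames) hormLevels[, p]
           else stop("planted phenotype predictor not generated: ", p)
      signal <- signal + pm$beta[[p]] * x
    }
    noiseSD <- if (is.null(pm$noiseSD)) {
      s <- stats::sd(signal)
      if (s == 0) 1 else s * sqrt((1 - pm$targetR2) / pm$targetR2)
    } else pm$noiseSD
    y <- signal + stats::rnorm(n, 0, noiseSD)
    if (resp == "leaves") y <- pmax(round(y), 1)
    phenMat[, resp] <- y
  }
  limits <- config$detectionLimits
  lapply(seq_len(n), function(i) {
    lev <- hormLevels[i, ]
    bd <- stats::setNames(rep(FALSE, length(hormNames)), hormNames)
    for (h in intersect(names(limits), hormNames)) {
      if (lev[[h]] < limits[[h]]) { bd[h] <- TRUE; lev[h] <- limits[[h]] }
    }
    lineProfile(sprintf("%s_%02d", variant, i), variant,
                expressionRatio = exprMat[i, ],
                hormones = data.frame(hormone = hormNames,
                                      level = unname(lev),
                                      belowDetection = unname(bd)),
                phenotype = phenMat[i, ])
  })
}

#' Generate a paired dataset and ground-truth bundle
#'
#' Produces the synthetic lines together with the truth objects needed for
#' recovery tests across all pipeline stages: the planted hormone links, the
#' planted phenotype models (as \linkS4class{PhenotypeModel} objects), the
#' variant model (with any planted Vmax deficit applied) and the deficit
#' factors themselves (whose reciprocals are the multipliers a stabilization
#' scan should recover).
#'
#' @param config a \code{GeneratorConfig}.
#' @return list with \code{lines}, \code{links}, \code{phenotypeModels},
#'   \code{model}, \code{plantedDeficit} and \code{config}.
#' @export
makeGroundTruthBundle <- function(config) {
  stopifnot(inherits(config, "GeneratorConfig"))
  lines <- generateLines(config)
  params <- generateParameterSet(config)
  model <- buildVariantModel(config$variant, params, provenance = "synthetic")
  if (!is.null(config$plantedDeficit)) {
    pars <- .modelParameters(model)
    hit <- names(config$plantedDeficit)
    stopifnot(all(hit %in% names(pars)))
    model <- .withParameters(model, pars[hit] / config$plantedDeficit)
  }
  phenModels <- lapply(names(config$plantedPhenotypes), function(resp) {
    pm <- config$plantedPhenotypes[[resp]]
    co <- c("(Intercept)" = pm$intercept, pm$beta)
    new("PhenotypeModel", response = resp, coefficients = co,
        predictorType = stats::setNames(
          ifelse(names(pm$beta) %in% names(.hormoneLogMedians),
                 "hormone", "gene"), names(pm$beta)),
        rounded = resp == "leaves")
  })
  names(phenModels) <- names(config$plantedPhenotypes)
  list(lines = lines, links = config$plantedLinks,
       phenotypeModels = phenModels, model = model,
       plantedDeficit = config$plantedDeficit, config = config)
}
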