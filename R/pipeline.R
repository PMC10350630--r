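#' @include synthetic.R io.R flux.R sensitivity.R
NULL

#' Run the multilevel modelling pipeline for one variant
#'
#' Executes the full stage order on synthetic (or supplied) line data:
#' build the variant model, form the median line and personalize the model,
#' solve the steady state (stabilizing by minimal Vmax intervention when
#' needed), compute log-sensitivities and the flux decomposition, fit
#' hormone-response correlations and validate their sign recovery on the
#' coupled model, fit forward-stepwise phenotype models, and predict each
#' line's phenotype through the multilevel chain. Per-stage artifacts are
#' written under \code{outDir} and a machine-readable JSON summary is
#' returned (and written) with provenance (seed, parameter source,
#' tolerances) on every report.
#'
#' @param variant variant to analyse.
#' @param seed integer seed controlling every random draw.
#' @param outDir output directory (created if needed), or NULL to skip
#'   writing artifacts.
#' @param lines optional list of \linkS4class{LineProfile}s; defaults to a
#'   synthetic cohort generated under \code{seed}.
#' @param config optional \code{GeneratorConfig} overriding the default.
#' @param sensitivity logical; compute the (comparatively expensive)
#'   sensitivity matrix stage.
#' @return the summary list, invisibly when \code{outDir} is set.
#' @export
runPipeline <- function(variant = "I", seed = 1L, outDir = NULL, lines = NULL,
                        config = NULL, sensitivity = TRUE) {
  stage <- "configure"
  result <- tryCatch({
    if (is.null(config)) config <- generatorConfig(seed = seed, variant = variant)
    stage <- "generate"
    if (is.null(lines)) lines <- generateLines(config)
    params <- generateParameterSet(config)
    stage <- "build"
    model <- buildVariantModel(variant, params, provenance = "synthetic")
    stage <- "scale"
    med <- medianLine(lines, variant)
    scaled <- scaleLine(model, med)
    stage <- "steady"
    ss <- findSteadyState(scaled)
    stab <- NULL
    if (!ss@converged || !ss@stable) {
      stage <- "stabilize"
      st <- stabilizeModel(scaled)
      if (!nrow(st$result@candidates))
        stop("no stable candidate found on the stabilization grid")
      scaled <- st$model
      stab <- st$result
      ss <- findSteadyState(scaled)
    }
    stage <- "sens"
    sens <- if (sensitivity && ss@stable) logSensitivities(scaled, ss) else NULL
    stage <- "flux"
    flux <- if (ss@converged) fluxDecomposition(scaled, ss) else NULL
    stage <- "hormones"
    links <- fitHormoneCorrelations(lines)
    ## metabolite responses come from the line-specific model steady states
    metConc <- .lineSteadyConcs(model, lines)
    metLinks <- if (!is.null(metConc))
      fitHormoneCorrelations(lines, responses = metConc,
                             responseType = stats::setNames(
                               rep("metabolite", ncol(metConc)),
                               names(metConc)))
    else links[0, ]
    allLinks <- rbind(links, metLinks)
    recovery <- validateCorrelationRecovery(scaled, allLinks, lines)
    stage <- "phenotype"
    phenData <- .phenotypeData(lines)
    phenModels <- list()
    for (resp in .phenotypeNames) {
      if (all(is.na(phenData[[resp]]))) next
      d <- phenData[, c(setdiff(names(phenData), .phenotypeNames), resp)]
      fit <- tryCatch(
        forwardStepwise(d[stats::complete.cases(d), ], resp,
                        predictorType = .phenotypePredictorTypes(phenData)),
        error = function(e) list(model = NULL))
      if (!is.null(fit$model)) phenModels[[resp]] <- fit$model
    }
    stage <- "predict"
    fallback <- !length(phenModels) &&
      variant %in% names(.shippedModelSpecs)
    preds <- if (length(phenModels) || fallback) {
      lapply(lines, function(ln)
        predictLinePhenotype(ln, model,
                             phenotypeModels = if (length(phenModels))
                               phenModels else NULL))
    } else {
      lapply(lines, function(ln) stats::setNames(numeric(0), character(0)))
    }
    predDf <- do.call(rbind, lapply(seq_along(lines), function(i) {
      data.frame(line_id = lines[[i]]@lineId, response = names(preds[[i]]),
                 predicted = unname(preds[[i]]),
                 observed = lines[[i]]@phenotype[names(preds[[i]])],
                 row.names = NULL)
    }))
    summary <- list(
      variant = variant, seed = seed,
      provenance = list(parameters = "synthetic", seed = seed,
                        residual_tolerance = 1e-8, relative_tolerance = 1e-9),
      n_lines = length(lines),
      stable = isTRUE(ss@stable),
      stabilized = !is.null(stab),
      stabilization = if (!is.null(stab)) list(
        chosen = as.list(stab@chosen),
        normalized_distance = stab@normalizedDistance,
        max_real_eigenvalue = stab@maxRealEigen) else NULL,
      steady_state = as.list(ss@concentrations),
      n_links = nrow(allLinks),
      correlation_recovery = recovery[c("assessed", "matched", "ambiguous")],
      phenotype_models = lapply(phenModels, function(m)
        list(coefficients = as.list(m@coefficients), adjR2 = m@adjR2,
             AICc = m@aicc)),
      fluxes = if (!is.null(flux)) as.list(flux@fluxes) else NULL)
    list(summary = summary, model = scaled, steadyState = ss,
         sensitivities = sens, links = allLinks, stabilization = stab,
         phenotypeModels = phenModels, predictions = predDf, lines = lines)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeLineProfiles(result$lines, file.path(outDir, "lines.tsv"))
    writePathwayModel(result$model, file.path(outDir, "model.json"))
    if (!is.null(result$sensitivities))
      utils::write.table(result$sensitivities@entries,
                         file.path(outDir, "sensitivities.tsv"),
                         sep = "\t", quote = FALSE)
    if (nrow(result$links))
      utils::write.table(result$links, file.path(outDir, "hormone_links.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(result$predictions,
                       file.path(outDir, "predictions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(jsonlite::toJSON(result$summary, auto_unbox = TRUE, digits = NA,
                                null = "null", pretty = TRUE),
               file.path(outDir, "summary.json"))
    return(invisible(result))
  }
  result
}

## steady-state metabolite concentrations per line (rows = lines), NULL when
## fewer than 4 lines have a stable personalized model
.lineSteadyConcs <- function(model, lines) {
  rows <- lapply(lines, function(ln) {
    m <- scaleLine(model, ln)
    ss <- findSteadyState(m, quick = TRUE)
    if (!ss@converged || !ss@stable) {
      st <- tryCatch(stabilizeModel(m), error = function(e) NULL)
      if (is.null(st) || !nrow(st$result@candidates)) return(NULL)
      ss <- findSteadyState(st$model, quick = TRUE)
      if (!ss@converged || !ss@stable) return(NULL)
    }
    ss@concentrations
  })
  ok <- !vapply(rows, is.null, NA)
  if (sum(ok) < 4) return(NULL)
  template <- rows[ok][[1]]
  mat <- matrix(NA_real_, length(lines), length(template),
                dimnames = list(NULL, names(template)))
  for (i in which(ok)) mat[i, ] <- rows[[i]][names(template)]
  as.data.frame(mat)
}

## per-line predictor/response table for stepwise fitting
.phenotypeData <- function(lines) {
  genes <- unique(unlist(lapply(lines, function(p) names(p@expressionRatio))))
  genes <- genes[vapply(genes, function(g)
    stats::sd(vapply(lines, function(p)
      if (g %in% names(p@expressionRatio)) p@expressionRatio[[g]] else NA_real_,
      0), na.rm = TRUE) > 0, NA)]
  hs <- unique(unlist(lapply(lines, function(p) p@hormones$hormone)))
  df <- data.frame(row.names = seq_along(lines))
  for (g in genes)
    df[[g]] <- vapply(lines, function(p)
      if (g %in% names(p@expressionRatio)) p@expressionRatio[[g]] else NA_real_, 0)
  for (h in hs)
    df[[h]] <- vapply(lines, function(p) {
      i <- match(h, p@hormones$hormone)
      if (is.na(i)) NA_real_ else p@hormones$level[i]
    }, 0)
  for (ph in .phenotypeNames)
    df[[ph]] <- vapply(lines, function(p) p@phenotype[[ph]], 0)
  df
}

.phenotypePredictorTypes <- function(phenData) {
  preds <- setdiff(names(phenData), .phenotypeNames)
  stats::setNames(ifelse(preds %in% names(.hormoneLogMedians), "hormone",
                         "gene"), preds)
}
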