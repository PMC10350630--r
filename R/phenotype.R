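#' @include line-profile.R
NULL

## small-sample corrected AIC for an lm fit (k = coefficients + error variance)
.aicc <- function(fit) {
  n <- length(stats::residuals(fit))
  k <- length(stats::coef(fit)) + 1
  if (n - k - 1 <= 0) return(Inf)
  stats::AIC(fit) + 2 * k * (k + 1) / (n - k - 1)
}

#' Estimate leaf area from length and maximum width
#'
#' Leaf area is estimated as length times maximum width times a correction
#' factor of 0.75 accounting for the non-rectangular leaf shape.
#'
#' @param length leaf length (cm), non-negative.
#' @param width maximum leaf width (cm), non-negative.
#' @return estimated leaf area (cm^2).
#' @examples
#' leafArea(1, 1)   # 0.75
#' leafArea(10, 1)  # 7.5
#' @export
leafArea <- function(length, width) {
  if (any(length < 0) || any(width < 0))
    stop("leaf length and width must be non-negative")
  0.75 * length * width
}

#' Forward stepwise construction of a phenotype model
#'
#' Builds a multivariate linear phenotype predictor by forward selection.
#' Step one fits every single-predictor model; candidates must have a
#' significant slope (alpha = 0.05) and adjusted R-squared above 0.2. Among
#' candidates the highest adjusted R-squared wins; when adjusted R-squared
#' values are similar (within \code{r2Tie}) the lowest AICc wins (the lower
#' the score, the lower the chance of overfitting). Subsequent steps extend
#' the selected set by one variable at a time, excluding variables collinear
#' with an included predictor (pairwise |r| >= \code{collinearR}), and stop
#' when no addition improves adjusted R-squared by at least \code{minGain}
#' with a significant new coefficient.
#'
#' @param data data.frame, one row per line: predictor columns plus the
#'   response column.
#' @param response name of the response column (\code{leaves} responses get
#'   rounded predictions).
#' @param predictorType optional named character typing each predictor
#'   (\code{gene}/\code{hormone}/\code{metabolite}); defaults to
#'   \code{"gene"}.
#' @param alpha significance gate for each added coefficient.
#' @param minAdjR2 adjusted R-squared gate for the first predictor.
#' @param r2Tie adjusted R-squared difference treated as "similar".
#' @param aiccTie AICc difference treated as "similar".
#' @param collinearR pairwise Pearson correlation above which two predictors
#'   are considered collinear.
#' @param minGain minimum adjusted R-squared improvement to accept a step.
#' @return list with \code{model} (a \linkS4class{PhenotypeModel}, or NULL
#'   when no candidate passes the gates) and \code{trace} (a data.frame of
#'   per-step candidate evaluations with accept/reject reasons).
#' @export
forwardStepwise <- function(data, response, predictorType = NULL,
                            alpha = 0.05, minAdjR2 = 0.2, r2Tie = 0.02,
                            aiccTie = 2, collinearR = 0.7, minGain = 0.02) {
  stopifnot(response %in% names(data))
  if (nrow(data) < 6) stop("at least 6 lines are required")
  preds <- setdiff(names(data), response)
  preds <- preds[vapply(preds, function(p)
    is.numeric(data[[p]]) && stats::sd(data[[p]], na.rm = TRUE) > 0, NA)]
  if (is.null(predictorType))
    predictorType <- stats::setNames(rep("gene", length(preds)), preds)
  y <- data[[response]]
  trace <- list()
  note <- function(step, cand, p, r2, aicc, action, reason) {
    trace[[length(trace) + 1L]] <<- data.frame(
      step = step, candidate = cand, p = p, adjR2 = r2, AICc = aicc,
      action = action, reason = reason, stringsAsFactors = FALSE)
  }
  evalCand <- function(vars) {
    fml <- stats::reformulate(vars, response = response)
    fit <- stats::lm(fml, data = data)
    sm <- summary(fit)
    pNew <- sm$coefficients[length(vars) + 1, 4]
    list(fit = fit, p = pNew, r2 = sm$adj.r.squared, aicc = .aicc(fit))
  }
  pickBest <- function(cands) {
    ## highest adjusted R2; similar R2 -> lowest AICc; similar AICc -> R2
    r2 <- vapply(cands, `[[`, 0, "r2")
    top <- max(r2)
    near <- which(r2 >= top - r2Tie)
    if (length(near) > 1) {
      aicc <- vapply(cands[near], `[[`, 0, "aicc")
      best <- min(aicc)
      nearA <- near[aicc <= best + aiccTie]
      near <- nearA[which.max(r2[nearA])]
    }
    near[1]
  }
  selected <- character(0)
  current <- NULL
  step <- 0L
  repeat {
    step <- step + 1L
    pool <- setdiff(preds, selected)
    ## collinearity gate against already-included predictors
    if (length(selected)) {
      keep <- vapply(pool, function(p) {
        all(abs(stats::cor(data[[p]], data[selected])) < collinearR)
      }, NA)
      for (p in pool[!keep]) note(step, p, NA, NA, NA, "reject", "collinear")
      pool <- pool[keep]
    }
    if (!length(pool)) break
    cands <- list()
    for (p in pool) {
      ev <- tryCatch(evalCand(c(selected, p)), error = function(e) NULL)
      if (is.null(ev) || !is.finite(ev$p)) next
      gate <- if (step == 1L) ev$r2 > minAdjR2 else
        ev$r2 >= (if (is.null(current)) -Inf else current$r2) + minGain
      if (ev$p < alpha && gate) {
        cands[[p]] <- ev
        note(step, p, ev$p, ev$r2, ev$aicc, "candidate", "passes gates")
      } else {
        note(step, p, ev$p, ev$r2, ev$aicc, "reject",
             if (ev$p >= alpha) "not significant" else "insufficient adjusted R2")
      }
    }
    if (!length(cands)) break
    best <- pickBest(cands)
    bestName <- names(cands)[best]
    selected <- c(selected, bestName)
    current <- cands[[best]]
    note(step, bestName, current$p, current$r2, current$aicc, "accept",
         "best candidate")
  }
  traceDf <- if (length(trace)) do.call(rbind, trace) else
    data.frame(step = integer(0), candidate = character(0), p = numeric(0),
               adjR2 = numeric(0), AICc = numeric(0), action = character(0),
               reason = character(0))
  if (!length(selected)) return(list(model = NULL, trace = traceDf))
  co <- stats::coef(current$fit)
  model <- new("PhenotypeModel", response = response, coefficients = co,
               predictorType = predictorType[selected],
               adjR2 = current$r2, aicc = current$aicc,
               rounded = response == "leaves")
  list(model = model, trace = traceDf)
}

#' Evaluate a phenotype model
#'
#' Computes the affine prediction \eqn{\hat y = \beta_0 + \sum \beta_i x_i};
#' leaf-count models round the result to the nearest integer.
#'
#' @param model a \linkS4class{PhenotypeModel}.
#' @param inputs named numeric vector (or single-row data.frame) covering all
#'   predictors of the model.
#' @return the predicted phenotype value.
#' @export
evaluatePhenotype <- function(model, inputs) {
  stopifnot(is(model, "PhenotypeModel"))
  if (is.data.frame(inputs)) inputs <- unlist(inputs[1, ])
  co <- model@coefficients
  preds <- names(co)[-1]
  missing <- setdiff(preds, names(inputs))
  if (length(missing))
    stop("missing predictor value(s): ", paste(missing, collapse = ", "))
  yhat <- unname(co[1] + sum(co[-1] * inputs[preds]))
  if (model@rounded) round(yhat) else yhat
}

## Table of transcribed type-specific phenotype models: response, predictor
## terms (name = coefficient), predictor types, adjusted R2 as published.
.shippedModelSpecs <- list(
  I = list(
    list(response = "height", intercept = 56.028,
         beta = c(MDS = -22.688, DXP = 1.590),
         type = c(MDS = "gene", DXP = "metabolite"), adjR2 = 0.53),
    list(response = "leaves", intercept = 4.738,
         beta = c(DXP = 0.318, MEcPP = -0.245),
         type = c(DXP = "metabolite", MEcPP = "metabolite"), adjR2 = 0.72),
    list(response = "leaf_length", intercept = 31.045,
         beta = c(HMGS = -3.135, HMBPP = 1549.320),
         type = c(HMGS = "gene", HMBPP = "metabolite"), adjR2 = 0.69),
    list(response = "chlorophyll", intercept = 32.218,
         beta = c(IAA = 0.154, HMGS = -1.571),
         type = c(IAA = "hormone", HMGS = "gene"), adjR2 = 0.74)),
  II = list(
    list(response = "leaves", intercept = 3.325,
         beta = c(ACC = -0.00312, HMGCoA_cyt = 0.0557),
         type = c(ACC = "hormone", HMGCoA_cyt = "metabolite"), adjR2 = 0.70),
    list(response = "leaf_length", intercept = 41.621,
         beta = c(HMGS = 6.048, MEP = -116.641),
         type = c(HMGS = "gene", MEP = "metabolite"), adjR2 = 0.77),
    list(response = "leaf_width", intercept = 0.596,
         beta = c(HMGS = 0.124, MVD = 0.0464),
         type = c(HMGS = "gene", MVD = "gene"), adjR2 = 0.61),
    list(response = "chlorophyll", intercept = 39.29,
         beta = c(iP = 1.620, HDR = -1.446),
         type = c(iP = "hormone", HDR = "gene"), adjR2 = 0.75)),
  III = list(
    list(response = "height", intercept = 76.626,
         beta = c(GA4 = 25.445, HMGS = 0.432),
         type = c(GA4 = "hormone", HMGS = "gene"), adjR2 = 0.60),
    list(response = "leaf_length", intercept = 50.826,
         beta = c(WR1 = 0.197, MVPP_cyt = 9071.25),
         type = c(WR1 = "gene", MVPP_cyt = "metabolite"), adjR2 = 0.43),
    list(response = "leaf_width", intercept = 0.881,
         beta = c(HMGS = 0.005, HMGCoA_cyt = 0.007),
         type = c(HMGS = "gene", HMGCoA_cyt = "metabolite"), adjR2 = 0.40),
    list(response = "chlorophyll", intercept = 33.218,
         beta = c(HDR = 10.968, DMAPP = 75003),
         type = c(HDR = "gene", DMAPP = "metabolite"), adjR2 = 0.46)))

#' Published type-specific phenotype models
#'
#' The transcribed multivariate linear phenotype models for the three
#' engineered variants: predictors are gene expression levels, hormone
#' levels and model steady-state metabolite concentrations; leaf-count
#' models round their predictions. AICc is not available for transcribed
#' models.
#'
#' @param variant \code{"I"}, \code{"II"} or \code{"III"}.
#' @return named list of \linkS4class{PhenotypeModel} objects (by response).
#' @examples
#' m <- shippedPhenotypeModels("I")$height
#' evaluatePhenotype(m, c(MDS = 0, DXP = 0))  # the intercept, 56.028
#' @export
shippedPhenotypeModels <- function(variant) {
  specs <- .shippedModelSpecs[[variant]]
  if (is.null(specs)) stop("no published models for variant ", variant)
  out <- lapply(specs, function(s) {
    co <- c("(Intercept)" = s$intercept, s$beta)
    new("PhenotypeModel", response = s$response, coefficients = co,
        predictorType = s$type, adjR2 = s$adjR2, aicc = NA_real_,
        rounded = s$response == "leaves")
  })
  stats::setNames(out, vapply(specs, `[[`, "", "response"))
}

## map a shipped-model predictor name to a value from line data + steady state
.predictorValue <- function(name, type, line, conc) {
  if (type == "hormone") {
    key <- switch(name, iP = "iP", IAA = "IAA", ACC = "ACC", GA4 = "GA4", name)
    i <- match(key, line@hormones$hormone)
    if (is.na(i)) return(NA_real_)
    return(line@hormones$level[i])
  }
  if (type == "metabolite") {
    key <- switch(name, MEcPP = "MECPP", DMAPP = "DMAPP_pla", name)
    if (!key %in% names(conc)) return(NA_real_)
    return(conc[[key]])
  }
  ## gene expression: prefer the variant's exogenous transgene, fall back to
  ## the endogenous rice gene
  er <- line@expressionRatio
  cands <- switch(name,
                  HMGS = c("BjHMGS", "OsHMGS"), HMGR = c("tHMGR", "OsHMGR"),
                  MVK = c("CrMK", "OsMK"), PMK = c("CrPMK", "OsPMK"),
                  MVD = c("CrMVD", "OsMVD"), MDS = "OsMDS", HDR = "OsHDR",
                  DXS = "OsDXS", DXR = "OsDXR", WR1 = "OsWR1", name)
  for (g in cands) {
    if (g %in% names(er) && (!g %in% .exogenousGenes || er[[g]] > 0))
      return(er[[g]])
  }
  if (cands[length(cands)] %in% names(er)) return(er[[cands[length(cands)]]])
  NA_real_
}

#' Predict a line's macroscopic phenotype through the multilevel chain
#'
#' Chains the multilevel model: personalizes the variant kinetic model with
#' the line's expression ratios, stabilizes it if needed, solves the steady
#' state, gathers metabolite, gene and hormone predictor values, and
#' evaluates each phenotype model. When the line's kinetic model cannot be
#' stabilized, metabolite-dependent responses are returned as NA
#' (unpredictable) while purely gene/hormone-based models still evaluate.
#'
#' @param line a \linkS4class{LineProfile}.
#' @param kineticModel the basal \linkS4class{PathwayModel} for the line's
#'   variant.
#' @param phenotypeModels named list of \linkS4class{PhenotypeModel} objects
#'   (defaults to the published models for the variant).
#' @param stabilize logical; scan for a minimal stabilizing Vmax change when
#'   the personalized model has no stable steady state.
#' @return named numeric vector of predicted phenotypes.
#' @export
predictLinePhenotype <- function(line, kineticModel,
                                 phenotypeModels = NULL, stabilize = TRUE) {
  if (is.null(phenotypeModels))
    phenotypeModels <- shippedPhenotypeModels(line@variant)
  m <- scaleLine(kineticModel, line)
  ss <- findSteadyState(m)
  if ((!ss@converged || !ss@stable) && stabilize) {
    st <- tryCatch(stabilizeModel(m), error = function(e) NULL)
    if (!is.null(st) && nrow(st$result@candidates)) {
      m <- st$model
      ss <- findSteadyState(m)
    }
  }
  conc <- if (ss@converged && ss@stable) ss@concentrations else NULL
  out <- vapply(phenotypeModels, function(pm) {
    needsMet <- any(pm@predictorType == "metabolite")
    if (needsMet && is.null(conc)) return(NA_real_)
    preds <- names(pm@coefficients)[-1]
    vals <- vapply(preds, function(p)
      .predictorValue(p, pm@predictorType[[p]], line, conc), 0)
    if (anyNA(vals)) return(NA_real_)
    evaluatePhenotype(pm, vals)
  }, 0)
  stats::setNames(out, names(phenotypeModels))
}
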