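#' @include AllClasses.R
NULL

#' @rdname PathwayModel-class
#' @param object,x a \linkS4class{PathwayModel}
#' @export
setGeneric("variant", function(object) standardGeneric("variant"))

#' @rdname PathwayModel-class
#' @export
setGeneric("pools", function(object) standardGeneric("pools"))

#' @rdname PathwayModel-class
#' @export
setGeneric("reactions", function(object) standardGeneric("reactions"))

#' @rdname PathwayModel-class
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))

#' @rdname SteadyState-class
#' @param object a \linkS4class{SteadyState}
#' @export
setGeneric("concentrations", function(object) standardGeneric("concentrations"))

#' @rdname SteadyState-class
#' @export
setGeneric("eigenvalues", function(object) standardGeneric("eigenvalues"))

#' @rdname SteadyState-class
#' @export
setGeneric("isStable", function(object) standardGeneric("isStable"))

#' @rdname SteadyState-class
#' @export
setGeneric("isConverged", function(object) standardGeneric("isConverged"))

#' @rdname SensitivityMatrix-class
#' @param object a \linkS4class{SensitivityMatrix}
#' @export
setGeneric("sensitivities", function(object) standardGeneric("sensitivities"))

#' @rdname SensitivityMatrix-class
#' @export
setGeneric("perParameterIndex", function(object) standardGeneric("perParameterIndex"))

#' @rdname SensitivityMatrix-class
#' @export
setGeneric("perMetaboliteIndex", function(object) standardGeneric("perMetaboliteIndex"))

#' @rdname FluxReport-class
#' @param object a \linkS4class{FluxReport}
#' @export
setGeneric("fluxes", function(object) standardGeneric("fluxes"))

setMethod("variant", "PathwayModel", function(object) object@variant)
setMethod("pools", "KineticModel", function(object) object@pools)
setMethod("reactions", "KineticModel", function(object) object@reactions)
setMethod("provenance", "PathwayModel", function(object) object@provenance)

setMethod("variant", "LineProfile", function(object) object@variant)

setMethod("concentrations", "SteadyState", function(object) object@concentrations)
setMethod("eigenvalues", "SteadyState", function(object) object@eigenvalues)
setMethod("isStable", "SteadyState", function(object) object@stable)
setMethod("isConverged", "SteadyState", function(object) object@converged)

setMethod("sensitivities", "SensitivityMatrix", function(object) object@entries)
setMethod("perParameterIndex", "SensitivityMatrix", function(object) object@perParameter)
setMethod("perMetaboliteIndex", "SensitivityMatrix", function(object) object@perMetabolite)

setMethod("fluxes", "FluxReport", function(object) object@fluxes)

setMethod("show", "KineticModel", function(object) {
  p <- object@pools
  if (is(object, "PathwayModel"))
    cat(sprintf("PathwayModel variant %s (%s parameters)\n", object@variant,
                object@provenance))
  else cat("KineticModel\n")
  cat(sprintf("  %d dynamic + %d fixed pools, %d reactions\n",
              sum(p$role == "dynamic"), sum(p$role == "fixed"),
              length(object@reactions)))
  genes <- unique(stats::na.omit(vapply(object@reactions, function(r) r@gene, "")))
  if (length(genes)) cat("  gene tags:", paste(genes, collapse = ", "), "\n")
})

setMethod("show", "LineProfile", function(object) {
  cat(sprintf("LineProfile %s (variant %s): %d gene ratios, %d hormones\n",
              object@lineId, object@variant, length(object@expressionRatio),
              nrow(object@hormones)))
})

setMethod("show", "SteadyState", function(object) {
  if (object@converged) {
    cat(sprintf("SteadyState: converged (residual %.3g), %s\n",
                object@residualNorm,
                if (isTRUE(object@stable)) "stable" else "unstable"))
    print(signif(object@concentrations, 4))
  } else {
    cat("SteadyState: NOT converged\n")
    acc <- object@diagnostics$accumulating
    if (length(acc)) cat("  accumulating pools:", paste(acc, collapse = ", "), "\n")
  }
})

setMethod("show", "SensitivityMatrix", function(object) {
  cat(sprintf("SensitivityMatrix: %d metabolites x %d parameters\n",
              nrow(object@entries), ncol(object@entries)))
  cat(sprintf("  |S| > 1 in %d of %d entries\n",
              sum(abs(object@entries) > 1, na.rm = TRUE),
              sum(!is.na(object@entries))))
})

setMethod("show", "FluxReport", function(object) {
  cat(sprintf("FluxReport (variant %s)\n", object@variant))
  print(signif(object@fluxes, 4))
})

setMethod("show", "StabilizationResult", function(object) {
  if (object@alreadyStable) {
    cat("StabilizationResult: model already stable, identity multipliers\n")
  } else {
    cat(sprintf("StabilizationResult: %d stable candidates, distance %.3f\n",
                nrow(object@candidates), object@normalizedDistance))
    print(object@chosen)
  }
})

setMethod("show", "PhenotypeModel", function(object) {
  co <- object@coefficients
  terms <- paste(sprintf("%+.4g %s", co[-1], names(co)[-1]), collapse = " ")
  rhs <- sprintf("%.4g %s", co[1], terms)
  if (object@rounded) rhs <- paste0("Round(", rhs, ")")
  cat(sprintf("PhenotypeModel: %s = %s\n", object@response, rhs))
  if (!is.na(object@adjR2))
    cat(sprintf("  adjusted R2 %.3f, AICc %.2f\n", object@adjR2, object@aicc))
})
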