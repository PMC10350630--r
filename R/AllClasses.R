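#' @import methods
NULL

#' Saturating rate law
#'
#' Rational rate expression used for every process in the pathway models:
#' \deqn{v = V \prod_i x_i / \left(\prod_i (K_i + x_i) + \prod_b (x_b + K_b)\right)}
#' where the \eqn{x_i} are substrate concentrations with apparent binding
#' constants \eqn{K_i} and the \eqn{x_b} are inhibitor concentrations with
#' binding constants \eqn{K_b}. When the reaction has no inhibitors the second
#' denominator product is omitted entirely, so a one-substrate law reduces to
#' classical Michaelis-Menten kinetics.
#'
#' @slot V apparent saturation rate constant (mM per model-time unit).
#' @slot substrateK named numeric, apparent binding constant per substrate (mM).
#' @slot inhibitorK named numeric, binding constant per inhibitor (mM); may be
#'   empty.
#'
#' @exportClass SaturatingRateLaw
setClass("SaturatingRateLaw",
  representation(V = "numeric", substrateK = "numeric", inhibitorK = "numeric"),
  prototype(V = 0, substrateK = c(x = 1), inhibitorK = numeric(0)))

setValidity("SaturatingRateLaw", function(object) {
  msg <- character(0)
  if (length(object@V) != 1L || is.na(object@V) || object@V < 0)
    msg <- c(msg, "V must be a single non-negative number")
  if (length(object@substrateK) == 0L)
    msg <- c(msg, "substrateK must name at least one substrate")
  if (is.null(names(object@substrateK)) || any(!nzchar(names(object@substrateK))))
    msg <- c(msg, "substrateK must be a named vector")
  if (any(object@substrateK <= 0))
    msg <- c(msg, "all substrate binding constants must be > 0")
  if (length(object@inhibitorK) &&
      (is.null(names(object@inhibitorK)) || any(object@inhibitorK <= 0)))
    msg <- c(msg, "all inhibitor binding constants must be named and > 0")
  if (length(msg)) msg else TRUE
})

#' A single reaction of a pathway model
#'
#' @slot id reaction identifier (\code{r1}..\code{r18} for enzymatic steps,
#'   \code{x_*} for compartment exchanges, \code{sink_*} for sinks,
#'   \code{e_*} for ectopic transgene-encoded steps).
#' @slot substrates named integer, substrate stoichiometries.
#' @slot products named integer, product stoichiometries (may be empty for
#'   sinks).
#' @slot gene gene tag (\code{NA} for exchanges and sinks); endogenous tags are
#'   \code{Os*}, exogenous ones \code{BjHMGS}, \code{tHMGR}, \code{CrMK},
#'   \code{CrPMK}, \code{CrMVD}.
#' @slot law a \linkS4class{SaturatingRateLaw}.
#' @slot multiplier dimensionless hormone multiplier applied to the rate
#'   (1 when no hormone link is attached).
#' @slot links list of hormone-link descriptors attached to this reaction.
#'
#' @exportClass Reaction
setClass("Reaction",
  representation(id = "character", substrates = "integer", products = "integer",
                 gene = "character", law = "SaturatingRateLaw",
                 multiplier = "numeric", links = "list"),
  prototype(gene = NA_character_, multiplier = 1, links = list()))

setValidity("Reaction", function(object) {
  msg <- character(0)
  if (length(object@id) != 1L || !nzchar(object@id))
    msg <- c(msg, "id must be a single non-empty string")
  if (is.null(names(object@substrates)) || any(object@substrates <= 0L))
    msg <- c(msg, "substrates must be named positive integers")
  if (length(object@products) &&
      (is.null(names(object@products)) || any(object@products <= 0L)))
    msg <- c(msg, "products must be named positive integers")
  missing <- setdiff(names(object@law@substrateK), names(object@substrates))
  if (length(missing))
    msg <- c(msg, paste0("law references substrates absent from the reaction: ",
                         paste(missing, collapse = ", ")))
  if (length(object@multiplier) != 1L || object@multiplier < 0)
    msg <- c(msg, "multiplier must be a single non-negative number")
  if (length(msg)) msg else TRUE
})

#' General kinetic reaction-network model
#'
#' A set of metabolite pools (dynamic or homeostatically fixed) and reactions
#' with saturating rate laws, compiling to one ODE per dynamic pool. The
#' variant-specific rice models are \linkS4class{PathwayModel} objects, which
#' extend this class with the variant tag and its pool-count invariant; plain
#' \code{KineticModel} objects are useful for small constructed systems.
#'
#' @slot pools data.frame with columns \code{name}, \code{compartment}
#'   (\code{cytosol}/\code{plastid}), \code{role} (\code{dynamic}/\code{fixed})
#'   and \code{basal} (mM; initial value for dynamic pools, constant for fixed
#'   pools).
#' @slot reactions list of \linkS4class{Reaction} objects.
#'
#' @exportClass KineticModel
setClass("KineticModel",
  representation(pools = "data.frame", reactions = "list"))

setValidity("KineticModel", function(object) {
  msg <- character(0)
  p <- object@pools
  need <- c("name", "compartment", "role", "basal")
  if (!all(need %in% names(p)))
    return("pools must have columns name, compartment, role, basal")
  if (anyDuplicated(paste(p$name, p$compartment)))
    msg <- c(msg, "(name, compartment) pairs must be unique")
  if (anyDuplicated(p$name))
    msg <- c(msg, "pool names must be unique")
  if (any(p$basal <= 0))
    msg <- c(msg, "all basal concentrations must be > 0")
  dyn <- p$name[p$role == "dynamic"]
  produced <- unlist(lapply(object@reactions, function(r) names(r@products)))
  consumed <- unlist(lapply(object@reactions, function(r) names(r@substrates)))
  orphan <- dyn[!(dyn %in% produced) | !(dyn %in% consumed)]
  if (length(orphan))
    msg <- c(msg, paste0("dynamic pools without both a producer and a consumer: ",
                         paste(orphan, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Variant-specific pathway model
#'
#' Reaction network of IPP/DMAPP biosynthesis for one rice variant: the wild
#' type (endogenous MVA + MEP pathways) or one of the three engineered types
#' carrying a plastid-targeted ectopic MVA pathway (Type I: HMGR; Type II:
#' + HMGS and MVK; Type III: + PMK and MVD). Compiles to an ODE system with
#' one equation per dynamic metabolite pool: 14 (WT), 16 (I), 17 (II) or
#' 18 (III).
#'
#' @slot variant one of \code{"WT"}, \code{"I"}, \code{"II"}, \code{"III"}.
#' @slot provenance parameter-set provenance tag: \code{"calibrated"} or
#'   \code{"synthetic"}.
#'
#' @exportClass PathwayModel
setClass("PathwayModel", contains = "KineticModel",
  representation(variant = "character", provenance = "character"),
  prototype(provenance = "calibrated"))

.expectedPoolCount <- c(WT = 14L, I = 16L, II = 17L, III = 18L)

setValidity("PathwayModel", function(object) {
  if (!object@variant %in% names(.expectedPoolCount))
    return("variant must be one of WT, I, II, III")
  ndyn <- sum(object@pools$role == "dynamic")
  if (ndyn != .expectedPoolCount[[object@variant]])
    return(sprintf("variant %s must have exactly %d dynamic pools, found %d",
                   object@variant, .expectedPoolCount[[object@variant]], ndyn))
  TRUE
})

#' One rice line's molecular and macroscopic profile
#'
#' @slot lineId line identifier.
#' @slot variant the line's transgene class (\code{WT}, \code{I}, \code{II},
#'   \code{III}).
#' @slot expressionRatio named numeric, per-gene expression ratio relative to
#'   the wild type. For exogenous genes the ratio is activity relative to the
#'   endogenous counterpart enzyme's basal activity; exogenous genes absent
#'   from the line's variant have ratio 0.
#' @slot hormones data.frame with columns \code{hormone}, \code{level}
#'   (non-negative, as-measured relative units) and \code{belowDetection}
#'   (logical).
#' @slot phenotype named numeric: \code{height} (cm), \code{leaves} (count),
#'   \code{leaf_length} (cm), \code{leaf_width} (cm), \code{chlorophyll}
#'   (SPAD units).
#'
#' @exportClass LineProfile
setClass("LineProfile",
  representation(lineId = "character", variant = "character",
                 expressionRatio = "numeric", hormones = "data.frame",
                 phenotype = "numeric"))

setValidity("LineProfile", function(object) {
  msg <- character(0)
  if (!object@variant %in% c("WT", "I", "II", "III"))
    msg <- c(msg, "variant must be one of WT, I, II, III")
  er <- object@expressionRatio
  if (is.null(names(er)) || any(er < 0) || anyNA(er))
    msg <- c(msg, "expression ratios must be named, non-negative and non-missing")
  exo <- intersect(names(er), .exogenousGenes)
  allowed <- .variantExogenous(object@variant)
  bad <- exo[!(exo %in% allowed) & er[exo] != 0]
  if (length(bad))
    msg <- c(msg, paste0("exogenous genes absent from variant ", object@variant,
                         " must have ratio 0: ", paste(bad, collapse = ", ")))
  h <- object@hormones
  if (!all(c("hormone", "level", "belowDetection") %in% names(h)))
    msg <- c(msg, "hormones must have columns hormone, level, belowDetection")
  else if (any(h$level < 0))
    msg <- c(msg, "hormone levels must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Steady state of a pathway model
#'
#' @slot concentrations named numeric, dynamic-pool concentrations (mM).
#' @slot residualNorm infinity norm of the time derivatives at the state.
#' @slot converged logical, whether the solver reached the residual tolerance.
#' @slot stable logical, all Jacobian eigenvalues have negative real part.
#' @slot eigenvalues complex vector of Jacobian eigenvalues (empty when the
#'   solve did not converge).
#' @slot diagnostics list; on divergence carries \code{accumulating}, the names
#'   of pools that grow without bound.
#'
#' @exportClass SteadyState
setClass("SteadyState",
  representation(concentrations = "numeric", residualNorm = "numeric",
                 converged = "logical", stable = "logical",
                 eigenvalues = "complex", diagnostics = "list"),
  prototype(diagnostics = list()))

#' Logarithmic steady-state sensitivity matrix
#'
#' Entries are dimensionless log-sensitivities
#' \eqn{S_{ij} = (\partial X_i / \partial p_j)(p_j / X_i)} of metabolite
#' steady-state concentrations to kinetic parameters, computed by re-solving
#' the steady state under a log-centred relative perturbation. Aggregates are
#' the Euclidean norm of each column divided by the number of metabolites
#' (per-parameter index) and of each row divided by the number of parameters
#' (per-metabolite index).
#'
#' @slot entries numeric matrix, metabolites x parameters; entries whose
#'   perturbed re-solve lost stability are NA.
#' @slot perParameter named numeric, per-parameter aggregate index.
#' @slot perMetabolite named numeric, per-metabolite aggregate index.
#'
#' @exportClass SensitivityMatrix
setClass("SensitivityMatrix",
  representation(entries = "matrix", perParameter = "numeric",
                 perMetabolite = "numeric"))

#' Steady-state flux decomposition
#'
#' Named IPP-production and entry fluxes at a steady state: production by HDR,
#' by IDI per compartment, by MVD (endogenous cytosolic and ectopic plastidic),
#' plastid-to-cytosol export, entry fluxes into the MVA, MEP and ectopic
#' pathways, per-compartment totals and the overall total.
#'
#' @slot fluxes named numeric (mM per model-time unit).
#' @slot present named logical; FALSE for categories the variant lacks (their
#'   flux is reported as 0).
#' @slot variant model variant the report was computed for.
#'
#' @exportClass FluxReport
setClass("FluxReport",
  representation(fluxes = "numeric", present = "logical", variant = "character"))

setValidity("FluxReport", function(object) {
  if (is.null(names(object@fluxes))) "fluxes must be named" else TRUE
})

#' Result of a minimal-intervention Vmax stabilization scan
#'
#' @slot scanned parameter names of the scanned Vmax axes.
#' @slot candidates data.frame of stable grid points: one multiplier column per
#'   axis plus \code{distance}, \code{nChanged} and \code{maxRe}.
#' @slot chosen named numeric, the selected multiplier vector (all 1 when the
#'   model was already stable).
#' @slot normalizedDistance Euclidean norm of the log2 multipliers divided by
#'   the square root of the number of scanned axes.
#' @slot maxRealEigen largest eigenvalue real part of the chosen model.
#' @slot alreadyStable logical; TRUE when no intervention was needed.
#'
#' @exportClass StabilizationResult
setClass("StabilizationResult",
  representation(scanned = "character", candidates = "data.frame",
                 chosen = "numeric", normalizedDistance = "numeric",
                 maxRealEigen = "numeric", alreadyStable = "logical"))

#' Multivariate linear phenotype model
#'
#' A linear predictor \eqn{\hat y = \beta_0 + \beta_1 x_1 + \ldots + \beta_n x_n}
#' over typed predictors (gene expression ratios, hormone levels, model
#' steady-state metabolite concentrations). Leaf-count responses are rounded
#' to the nearest integer.
#'
#' @slot response one of \code{height}, \code{leaves}, \code{leaf_length},
#'   \code{leaf_width}, \code{chlorophyll}.
#' @slot coefficients named numeric; first element \code{(Intercept)}.
#' @slot predictorType named character mapping each non-intercept predictor to
#'   \code{gene}, \code{hormone} or \code{metabolite}.
#' @slot adjR2 adjusted R-squared of the fit (NA for transcribed models).
#' @slot aicc small-sample-corrected AIC of the fit (NA for transcribed models).
#' @slot rounded logical, TRUE when predictions are rounded (leaf counts).
#'
#' @exportClass PhenotypeModel
setClass("PhenotypeModel",
  representation(response = "character", coefficients = "numeric",
                 predictorType = "character", adjR2 = "numeric",
                 aicc = "numeric", rounded = "logical"),
  prototype(adjR2 = NA_real_, aicc = NA_real_, rounded = FALSE))

setValidity("PhenotypeModel", function(object) {
  msg <- character(0)
  if (names(object@coefficients)[1] != "(Intercept)")
    msg <- c(msg, "first coefficient must be the intercept")
  preds <- names(object@coefficients)[-1]
  if (!all(preds %in% names(object@predictorType)))
    msg <- c(msg, "every predictor must have a declared type")
  if (length(msg)) msg else TRUE
})
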