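#' @include rate-law.R
NULL

.exogenousGenes <- c("BjHMGS", "tHMGR", "CrMK", "CrPMK", "CrMVD")
.endogenousGenes <- c("OsHMGS", "OsHMGR", "OsMK", "OsPMK", "OsMVD", "OsDXS",
                      "OsDXR", "OsMCT", "OsCMK", "OsMDS", "OsHDS", "OsHDR",
                      "OsIPPI")

.variantExogenous <- function(variant) {
  switch(variant,
         WT  = character(0),
         I   = "tHMGR",
         II  = c("tHMGR", "BjHMGS", "CrMK"),
         III = c("tHMGR", "BjHMGS", "CrMK", "CrPMK", "CrMVD"),
         stop("unknown variant: ", variant))
}

## Basal concentrations: the 14 dynamic pools of the wild-type model plus
## homeostatically fixed precursor pools and initial guesses for the ectopic
## plastid pools of the engineered variants.
.basalDynamic <- c(
  HMGCoA_cyt = 0.983, MVA_cyt = 3.5e-5, MVP_cyt = 3.98e-4, MVPP_cyt = 3.36e-5,
  IPP_cyt = 0.109, IPP_pla = 0.0801, DMAPP_cyt = 0.136, DMAPP_pla = 0.124,
  DXP = 0.0133, MEP = 1.15e-3, CDPME = 1.11e-4, CDPMEP = 0.0920,
  MECPP = 0.657, HMBPP = 3.52e-4)

.basalFixed <- c(AcCoA_cyt = 0.5, AcAcCoA_cyt = 0.01, G3P = 0.15,
                 Pyruvate = 0.5, AcCoA_pla = 0.5, AcAcCoA_pla = 0.01)

.basalEctopic <- c(HMGCoA_pla = 0.01, MVA_pla = 1e-4, MVP_pla = 1e-4,
                   MVPP_pla = 1e-4)

.plastidPools <- c("IPP_pla", "DMAPP_pla", "DXP", "MEP", "CDPME", "CDPMEP",
                   "MECPP", "HMBPP", "G3P", "Pyruvate", "AcCoA_pla",
                   "AcAcCoA_pla", "HMGCoA_pla", "MVA_pla", "MVP_pla",
                   "MVPP_pla")

## Reaction inventory with the design fluxes used for calibration. The design
## fluxes form a consistent steady-state flux distribution at the basal
## concentrations: MVA chain carries 1, MEP chain 2, HDR splits 1.4/0.6
## between IPP and DMAPP, IPP/DMAPP exchange is ten-fold asymmetric
## (plastid-to-cytosol export over import), and sinks close every balance.
.rxn <- function(id, sub, prod, gene = NA_character_, flux = NA_real_,
                 kind = "enzyme") {
  list(id = id, sub = sub, prod = prod, gene = gene, flux = flux, kind = kind)
}

.wtReactions <- list(
  .rxn("r1",  c(AcCoA_cyt = 1L, AcAcCoA_cyt = 1L), c(HMGCoA_cyt = 1L), "OsHMGS", 1),
  .rxn("r2",  c(HMGCoA_cyt = 1L), c(MVA_cyt = 1L),  "OsHMGR", 1),
  .rxn("r3",  c(MVA_cyt = 1L),  c(MVP_cyt = 1L),  "OsMK",   1),
  .rxn("r4",  c(MVP_cyt = 1L),  c(MVPP_cyt = 1L), "OsPMK",  1),
  .rxn("r5",  c(MVPP_cyt = 1L), c(IPP_cyt = 1L),  "OsMVD",  1),
  .rxn("r6",  c(IPP_cyt = 1L),  c(DMAPP_cyt = 1L), "OsIPPI", 0.85),
  .rxn("r10", c(G3P = 1L, Pyruvate = 1L), c(DXP = 1L), "OsDXS", 2),
  .rxn("r11", c(DXP = 1L),    c(MEP = 1L),    "OsDXR", 2),
  .rxn("r12", c(MEP = 1L),    c(CDPME = 1L),  "OsMCT", 2),
  .rxn("r13", c(CDPME = 1L),  c(CDPMEP = 1L), "OsCMK", 2),
  .rxn("r14", c(CDPMEP = 1L), c(MECPP = 1L),  "OsMDS", 2),
  .rxn("r15", c(MECPP = 1L),  c(HMBPP = 1L),  "OsHDS", 2),
  .rxn("r16", c(HMBPP = 1L),  c(IPP_pla = 1L),   "OsHDR", 1.4),
  .rxn("r17", c(HMBPP = 1L),  c(DMAPP_pla = 1L), "OsHDR", 0.6),
  .rxn("r18", c(IPP_pla = 1L), c(DMAPP_pla = 1L), "OsIPPI", 0.65),
  .rxn("x_IPP_exp",   c(IPP_pla = 1L),   c(IPP_cyt = 1L),   flux = 0.5,
       kind = "export"),
  .rxn("x_IPP_imp",   c(IPP_cyt = 1L),   c(IPP_pla = 1L),   flux = 0.05,
       kind = "import"),
  .rxn("x_DMAPP_exp", c(DMAPP_pla = 1L), c(DMAPP_cyt = 1L), flux = 0.25,
       kind = "export"),
  .rxn("x_DMAPP_imp", c(DMAPP_cyt = 1L), c(DMAPP_pla = 1L), flux = 0.025,
       kind = "import"),
  .rxn("sink_IPP_cyt",   c(IPP_cyt = 1L),   integer(0), flux = 0.60,  kind = "sink"),
  .rxn("sink_DMAPP_cyt", c(DMAPP_cyt = 1L), integer(0), flux = 1.075, kind = "sink"),
  .rxn("sink_IPP_pla",   c(IPP_pla = 1L),   integer(0), flux = 0.30,  kind = "sink"),
  .rxn("sink_DMAPP_pla", c(DMAPP_pla = 1L), integer(0), flux = 1.025, kind = "sink"))

## Ectopic reactions per variant; each copies the kinetic parameters of its
## endogenous counterpart (the exogenous expression ratio then scales V).
.ectopicCounterpart <- c(e_HMGS_pla = "r1", e_HMGR_pla = "r2", e_MVK_pla = "r3",
                         e_PMK_pla = "r4", e_MVD_pla = "r5")

.ectopicReactions <- list(
  e_HMGR_pla = .rxn("e_HMGR_pla", c(HMGCoA_pla = 1L), c(MVA_pla = 1L),
                    "tHMGR", kind = "ectopic"),
  e_HMGS_pla = .rxn("e_HMGS_pla", c(AcCoA_pla = 1L, AcAcCoA_pla = 1L),
                    c(HMGCoA_pla = 1L), "BjHMGS", kind = "ectopic"),
  e_MVK_pla  = .rxn("e_MVK_pla", c(MVA_pla = 1L), c(MVP_pla = 1L),
                    "CrMK", kind = "ectopic"),
  e_PMK_pla  = .rxn("e_PMK_pla", c(MVP_pla = 1L), c(MVPP_pla = 1L),
                    "CrPMK", kind = "ectopic"),
  e_MVD_pla  = .rxn("e_MVD_pla", c(MVPP_pla = 1L), c(IPP_pla = 1L),
                    "CrMVD", kind = "ectopic"))

## MVA-intermediate exchanges added with the ectopic pathway. `pathwayRef`
## names the endogenous reaction whose V sets the exchange scale (1% for slow
## exchanges; the terminal pool of a truncated ectopic chain instead gets the
## full reference V so it can carry the ectopic flux out of the plastid).
.intermediateExchanges <- list(
  x_HMGCoA_imp = list(id = "x_HMGCoA_imp", sub = c(HMGCoA_cyt = 1L),
                      prod = c(HMGCoA_pla = 1L), ref = "r2", metab = "HMGCoA"),
  x_HMGCoA_exp = list(id = "x_HMGCoA_exp", sub = c(HMGCoA_pla = 1L),
                      prod = c(HMGCoA_cyt = 1L), ref = "r2", metab = "HMGCoA"),
  x_MVA_imp    = list(id = "x_MVA_imp", sub = c(MVA_cyt = 1L),
                      prod = c(MVA_pla = 1L), ref = "r3", metab = "MVA"),
  x_MVA_exp    = list(id = "x_MVA_exp", sub = c(MVA_pla = 1L),
                      prod = c(MVA_cyt = 1L), ref = "r3", metab = "MVA"),
  x_MVP_imp    = list(id = "x_MVP_imp", sub = c(MVP_cyt = 1L),
                      prod = c(MVP_pla = 1L), ref = "r4", metab = "MVP"),
  x_MVP_exp    = list(id = "x_MVP_exp", sub = c(MVP_pla = 1L),
                      prod = c(MVP_cyt = 1L), ref = "r4", metab = "MVP"),
  x_MVPP_imp   = list(id = "x_MVPP_imp", sub = c(MVPP_cyt = 1L),
                      prod = c(MVPP_pla = 1L), ref = "r5", metab = "MVPP"),
  x_MVPP_exp   = list(id = "x_MVPP_exp", sub = c(MVPP_pla = 1L),
                      prod = c(MVPP_cyt = 1L), ref = "r5", metab = "MVPP"))

.variantEctopic <- function(variant) {
  switch(variant,
    WT  = character(0),
    I   = "e_HMGR_pla",
    II  = c("e_HMGR_pla", "e_HMGS_pla", "e_MVK_pla"),
    III = c("e_HMGR_pla", "e_HMGS_pla", "e_MVK_pla", "e_PMK_pla", "e_MVD_pla"),
    stop("unknown variant: ", variant))
}

.variantExchanges <- function(variant) {
  switch(variant,
    WT  = character(0),
    I   = c("x_HMGCoA_imp", "x_HMGCoA_exp", "x_MVA_imp", "x_MVA_exp"),
    II  = c("x_HMGCoA_imp", "x_HMGCoA_exp", "x_MVA_imp", "x_MVA_exp",
            "x_MVP_imp", "x_MVP_exp"),
    III = c("x_HMGCoA_imp", "x_HMGCoA_exp", "x_MVA_imp", "x_MVA_exp",
            "x_MVP_imp", "x_MVP_exp", "x_MVPP_imp", "x_MVPP_exp"),
    stop("unknown variant: ", variant))
}

## terminal pool of the truncated ectopic chain: its export is the chain's
## only outlet and carries the full reference V rather than 1%.
.terminalExchange <- function(variant) {
  switch(variant, WT = character(0), I = "x_MVA_exp", II = "x_MVP_exp",
         III = character(0))
}

.variantDynamicPools <- function(variant) {
  extra <- switch(variant,
    WT  = character(0),
    I   = c("HMGCoA_pla", "MVA_pla"),
    II  = c("HMGCoA_pla", "MVA_pla", "MVP_pla"),
    III = c("HMGCoA_pla", "MVA_pla", "MVP_pla", "MVPP_pla"),
    stop("unknown variant: ", variant))
  c(names(.basalDynamic), extra)
}

.variantFixedPools <- function(variant) {
  if (variant %in% c("II", "III")) names(.basalFixed)
  else setdiff(names(.basalFixed), c("AcCoA_pla", "AcAcCoA_pla"))
}

.variantReactionDefs <- function(variant) {
  defs <- .wtReactions
  for (id in .variantEctopic(variant)) defs[[length(defs) + 1L]] <- .ectopicReactions[[id]]
  for (id in .variantExchanges(variant)) {
    x <- .intermediateExchanges[[id]]
    defs[[length(defs) + 1L]] <- .rxn(x$id, x$sub, x$prod, kind = "mva_exchange")
  }
  names(defs) <- vapply(defs, `[[`, "", "id")
  defs
}

.poolBasal <- function(pool) {
  b <- c(.basalDynamic, .basalFixed, .basalEctopic)
  b[[pool]]
}

#' Default calibrated parameter set for a variant
#'
#' Builds the deterministic calibrated parameter set: enzymatic substrate
#' binding constants at three times the basal concentration of their substrate
#' (each step operates at quarter saturation, i.e. with four-fold capacity
#' reserve), transporter binding constants at basal, sink binding constants at
#' nine times basal (sinks operate in their first-order regime with ten-fold
#' capacity reserve), and saturation rate constants V solved so that the basal
#' concentrations are an exact steady state of the wild-type design flux
#' distribution. IPP and DMAPP plastid export V is
#' exactly ten times the import V. Ectopic reactions copy the V and K of
#' their endogenous counterparts; MVA-intermediate exchanges run at 1% of the
#' corresponding pathway V except the terminal pool of a truncated ectopic
#' chain, whose export carries the full reference V.
#'
#' @param variant one of \code{"WT"}, \code{"I"}, \code{"II"}, \code{"III"}.
#' @return named numeric vector with elements \code{V_<id>} and
#'   \code{K_<id>_<pool>}.
#' @export
defaultParameterSet <- function(variant = "WT") {
  .calibrateParameterSet(variant, kScale = NULL)
}

## kScale: optional named multiplier on the default K values (names
## "K_<id>_<pool>"); V is re-solved so the basal state remains an exact
## steady state of the design fluxes.
.calibrateParameterSet <- function(variant, kScale = NULL) {
  defs <- .variantReactionDefs(variant)
  params <- numeric(0)
  kOf <- function(def) {
    ks <- vapply(names(def$sub), function(s) {
      base <- switch(def$kind,
                     sink = 9 * .poolBasal(s),        # first-order regime
                     export = , import = , mva_exchange = .poolBasal(s),
                     3 * .poolBasal(s))               # enzymes: 4x headroom
      nm <- paste0("K_", def$id, "_", s)
      if (!is.null(kScale) && nm %in% names(kScale)) base * kScale[[nm]] else base
    }, 0)
    names(ks) <- names(def$sub)
    ks
  }
  satAtBasal <- function(def, ks) {
    x <- vapply(names(def$sub), .poolBasal, 0)
    prod(x / (ks + x))
  }
  ## wild-type backbone: V from design fluxes
  wtIds <- vapply(.wtReactions, `[[`, "", "id")
  for (def in defs[names(defs) %in% wtIds]) {
    ks <- kOf(def)
    for (s in names(ks)) params[paste0("K_", def$id, "_", s)] <- ks[[s]]
    if (def$kind == "export") next  # derived from the paired import below
    params[paste0("V_", def$id)] <- def$flux / satAtBasal(def, ks)
  }
  ## ten-fold export/import asymmetry: V_exp = 10 * V_imp exactly, K_exp
  ## solved so the design export flux is met at the basal state.
  for (met in c("IPP", "DMAPP")) {
    imp <- defs[[paste0("x_", met, "_imp")]]
    exp <- defs[[paste0("x_", met, "_exp")]]
    vimp <- params[[paste0("V_x_", met, "_imp")]]
    vexp <- 10 * vimp
    params[paste0("V_x_", met, "_exp")] <- vexp
    sub <- names(exp$sub)
    x <- .poolBasal(sub)
    kexp <- x * (vexp / exp$flux - 1)
    stopifnot(kexp > 0)
    params[paste0("K_x_", met, "_exp", "_", sub)] <- kexp
  }
  ## ectopic reactions copy their endogenous counterpart
  for (id in .variantEctopic(variant)) {
    def <- defs[[id]]
    cp <- .ectopicCounterpart[[id]]
    params[paste0("V_", id)] <- params[[paste0("V_", cp)]]
    cpdef <- defs[[cp]]
    cpK <- vapply(names(cpdef$sub),
                  function(s) params[[paste0("K_", cp, "_", s)]], 0)
    for (i in seq_along(def$sub))
      params[paste0("K_", id, "_", names(def$sub)[i])] <- cpK[[i]]
  }
  ## MVA-intermediate exchanges
  terminal <- .terminalExchange(variant)
  for (id in .variantExchanges(variant)) {
    x <- .intermediateExchanges[[id]]
    refV <- params[[paste0("V_", x$ref)]]
    params[paste0("V_", id)] <- if (id %in% terminal) refV else 0.01 * refV
    sub <- names(x$sub)
    refK <- params[[paste0("K_", x$ref, "_", names(defs[[x$ref]]$sub)[1])]]
    params[paste0("K_", id, "_", sub)] <- refK
  }
  params
}

#' Build the kinetic model for a rice variant
#'
#' Assembles the variant-specific reaction network: the wild type carries the
#' endogenous cytosolic MVA chain (r1-r5, with cytosolic IDI r6), the plastid
#' MEP chain (r10-r15, HDR r16/r17, plastid IDI r18), ten-fold asymmetric
#' IPP/DMAPP compartment exchange and sink reactions in both compartments.
#' Type I adds plastid HMGR plus HMG-CoA/MVA exchange; Type II adds plastid
#' HMGS and MVK plus MVP exchange; Type III adds plastid PMK and MVD (and the
#' MVPP_pla pool) plus MVPP exchange.
#'
#' @param variant one of \code{"WT"}, \code{"I"}, \code{"II"}, \code{"III"}.
#' @param params named parameter vector (\code{V_<id>}, \code{K_<id>_<pool>});
#'   defaults to \code{\link{defaultParameterSet}}.
#' @param provenance provenance tag recorded on the model
#'   (\code{"calibrated"} or \code{"synthetic"}).
#' @return a \linkS4class{PathwayModel} with 14/16/17/18 dynamic pools for
#'   WT/I/II/III.
#' @examples
#' wt <- buildVariantModel("WT")
#' sum(pools(wt)$role == "dynamic")  # 14
#' @export
buildVariantModel <- function(variant, params = defaultParameterSet(variant),
                              provenance = "calibrated") {
  if (!variant %in% c("WT", "I", "II", "III"))
    stop("unknown variant: ", variant)
  defs <- .variantReactionDefs(variant)
  needed <- unlist(lapply(defs, function(def) {
    c(paste0("V_", def$id), paste0("K_", def$id, "_", names(def$sub)))
  }))
  gaps <- setdiff(needed, names(params))
  if (length(gaps))
    stop("parameter set is missing ", length(gaps), " entries: ",
         paste(gaps, collapse = ", "))
  dyn <- .variantDynamicPools(variant)
  fixed <- .variantFixedPools(variant)
  poolNames <- c(dyn, fixed)
  poolsDf <- data.frame(
    name = poolNames,
    compartment = ifelse(poolNames %in% .plastidPools, "plastid", "cytosol"),
    role = c(rep("dynamic", length(dyn)), rep("fixed", length(fixed))),
    basal = vapply(poolNames, .poolBasal, 0),
    stringsAsFactors = FALSE, row.names = NULL)
  rxns <- lapply(defs, function(def) {
    ks <- vapply(names(def$sub),
                 function(s) params[[paste0("K_", def$id, "_", s)]], 0)
    names(ks) <- names(def$sub)
    new("Reaction", id = def$id, substrates = def$sub,
        products = if (length(def$prod)) def$prod else integer(0),
        gene = def$gene,
        law = new("SaturatingRateLaw", V = params[[paste0("V_", def$id)]],
                  substrateK = ks, inhibitorK = numeric(0)))
  })
  new("PathwayModel", variant = variant, pools = poolsDf,
      reactions = rxns, provenance = provenance)
}

#' Construct a reaction
#'
#' Convenience constructor for a \linkS4class{Reaction} with a saturating
#' rate law. Substrate binding constants default to 1 mM each.
#'
#' @param id reaction identifier.
#' @param substrates named integer vector of substrate stoichiometries.
#' @param products named integer vector of product stoichiometries (empty for
#'   a sink).
#' @param V saturation rate constant.
#' @param K named numeric vector of substrate binding constants; must cover
#'   the substrates.
#' @param gene optional gene tag.
#' @param inhibitorK optional named numeric vector of inhibitor binding
#'   constants.
#' @return a \linkS4class{Reaction}.
#' @export
reactionSpec <- function(id, substrates, products = integer(0), V = 1,
                         K = NULL, gene = NA_character_,
                         inhibitorK = numeric(0)) {
  substrates <- stats::setNames(as.integer(substrates), names(substrates))
  products <- if (length(products))
    stats::setNames(as.integer(products), names(products)) else integer(0)
  if (is.null(K)) K <- stats::setNames(rep(1, length(substrates)),
                                       names(substrates))
  new("Reaction", id = id, substrates = substrates, products = products,
      gene = gene,
      law = new("SaturatingRateLaw", V = as.numeric(V), substrateK = unlist(K),
                inhibitorK = unlist(inhibitorK)))
}

#' Construct a general kinetic model
#'
#' Builds a \linkS4class{KineticModel} from a pool table and a reaction
#' list; intended for small constructed systems (the rice variant models are
#' built with \code{\link{buildVariantModel}}).
#'
#' @param pools data.frame with columns \code{name}, \code{compartment},
#'   \code{role}, \code{basal}, or a named numeric vector of basal
#'   concentrations of dynamic cytosolic pools.
#' @param reactions list of \linkS4class{Reaction} objects.
#' @param fixed optional named numeric vector of fixed-pool concentrations.
#' @return a \linkS4class{KineticModel}.
#' @examples
#' toy <- kineticModel(c(M = 1),
#'   list(reactionSpec("in", c(S = 1L), c(M = 1L), V = 2, K = c(S = 1)),
#'        reactionSpec("out", c(M = 1L), V = 2, K = c(M = 1))),
#'   fixed = c(S = 1))
#' @export
kineticModel <- function(pools, reactions, fixed = numeric(0)) {
  if (is.numeric(pools)) {
    pools <- data.frame(name = c(names(pools), names(fixed)),
                        compartment = "cytosol",
                        role = c(rep("dynamic", length(pools)),
                                 rep("fixed", length(fixed))),
                        basal = c(unname(pools), unname(fixed)),
                        stringsAsFactors = FALSE)
  }
  new("KineticModel", pools = pools, reactions = reactions)
}

## parameter vector of a built model (inverse of buildVariantModel)
.modelParameters <- function(model) {
  params <- numeric(0)
  for (r in model@reactions) {
    params[paste0("V_", r@id)] <- r@law@V
    for (s in names(r@law@substrateK))
      params[paste0("K_", r@id, "_", s)] <- r@law@substrateK[[s]]
  }
  params
}

## return a copy of the model with parameters replaced from a named vector
.withParameters <- function(model, params) {
  model@reactions <- lapply(model@reactions, function(r) {
    nmV <- paste0("V_", r@id)
    if (nmV %in% names(params)) r@law@V <- params[[nmV]]
    for (s in names(r@law@substrateK)) {
      nmK <- paste0("K_", r@id, "_", s)
      if (nmK %in% names(params)) r@law@substrateK[s] <- params[[nmK]]
    }
    r
  })
  model
}
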