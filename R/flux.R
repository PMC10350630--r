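#' @include steady-state.R
NULL

#' Decompose IPP/DMAPP production fluxes at a steady state
#'
#' Reports the steady-state production rates of IPP by HDR, by IDI (per
#' compartment) and by MVD (endogenous cytosolic and, where the variant has
#' one, ectopic plastidic), the IPP and DMAPP plastid-to-cytosol export
#' fluxes, the entry fluxes into the MVA pathway (r1), the MEP pathway (r10)
#' and the ectopic plastid pathway, per-compartment production totals and the
#' overall total. Categories absent from the variant (for example ectopic MVD
#' in Type I) are reported as 0 and flagged absent.
#'
#' @param model a \linkS4class{PathwayModel}.
#' @param ss a converged \linkS4class{SteadyState} of the model.
#' @return a \linkS4class{FluxReport}.
#' @export
fluxDecomposition <- function(model, ss) {
  stopifnot(is(ss, "SteadyState"))
  if (!isTRUE(ss@converged)) stop("flux decomposition requires a converged steady state")
  cm <- .compileModel(model)
  v <- stats::setNames(.cmRates(cm, ss@concentrations[cm$dyn]), cm$ids)
  rate <- function(id) if (id %in% names(v)) unname(v[[id]]) else 0
  has <- function(id) id %in% names(v)
  ## entry flux into the ectopic pathway: the first committed ectopic step
  entryEctopic <- if (has("e_HMGS_pla")) rate("e_HMGS_pla")
                  else if (has("e_HMGR_pla")) rate("e_HMGR_pla") else 0
  fl <- c(
    IPP_by_HDR            = rate("r16"),
    DMAPP_by_HDR          = rate("r17"),
    DMAPP_by_IDI_cytosol  = rate("r6"),
    DMAPP_by_IDI_plastid  = rate("r18"),
    IPP_by_MVD_endogenous = rate("r5"),
    IPP_by_MVD_ectopic    = if (has("e_MVD_pla")) rate("e_MVD_pla") else 0,
    IPP_export_pl_to_cyt  = rate("x_IPP_exp"),
    DMAPP_export_pl_to_cyt = rate("x_DMAPP_exp"),
    entry_MVA             = rate("r1"),
    entry_MEP             = rate("r10"),
    entry_ectopic         = entryEctopic)
  ## per-compartment IPP+DMAPP production totals (de novo synthesis only;
  ## IDI isomerization and exchange move material between existing pools)
  fl["total_cytosol"] <- fl[["IPP_by_MVD_endogenous"]]
  fl["total_plastid"] <- fl[["IPP_by_HDR"]] + fl[["DMAPP_by_HDR"]] +
    fl[["IPP_by_MVD_ectopic"]]
  fl["total_overall"] <- fl[["total_cytosol"]] + fl[["total_plastid"]]
  present <- !vapply(names(fl), function(nm) {
    (nm == "IPP_by_MVD_ectopic" && !has("e_MVD_pla")) ||
      (nm == "entry_ectopic" && !has("e_HMGR_pla"))
  }, NA)
  vt <- if (is(model, "PathwayModel")) model@variant else "custom"
  new("FluxReport", fluxes = fl, present = present, variant = vt)
}
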