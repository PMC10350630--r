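#' @include AllClasses.R
NULL

#' Construct a saturating rate law
#'
#' @param V apparent saturation rate constant (mM per model-time unit).
#' @param substrateK named numeric vector of substrate binding constants (mM).
#' @param inhibitorK named numeric vector of inhibitor binding constants (mM);
#'   defaults to none, in which case the law reduces to a (multi-substrate)
#'   Michaelis-Menten expression.
#' @return a \linkS4class{SaturatingRateLaw}.
#' @examples
#' law <- saturatingRateLaw(V = 1, substrateK = c(S = 1))
#' evaluateRate(law, c(S = 1))  # 0.5
#' @export
saturatingRateLaw <- function(V, substrateK, inhibitorK = numeric(0)) {
  new("SaturatingRateLaw", V = as.numeric(V),
      substrateK = unlist(substrateK), inhibitorK = unlist(inhibitorK))
}

#' Evaluate a saturating rate law at given concentrations
#'
#' Computes \eqn{v = V \prod x_i / (\prod (K_i + x_i) + \prod (x_b + K_b))};
#' the inhibitor product is present only when the law has inhibitors. The flux
#' is non-negative, tends to \eqn{V} as all substrates saturate (with no
#' inhibitors) and decreases monotonically in every inhibitor concentration.
#'
#' @param law a \linkS4class{SaturatingRateLaw}.
#' @param conc named numeric vector of concentrations (mM) covering every pool
#'   the law references.
#' @return flux (mM per model-time unit).
#' @export
evaluateRate <- function(law, conc) {
  stopifnot(is(law, "SaturatingRateLaw"))
  need <- unique(c(names(law@substrateK), names(law@inhibitorK)))
  missing <- need[!(need %in% names(conc)) | is.na(conc[need])]
  if (length(missing))
    stop("missing concentration for pool(s): ", paste(missing, collapse = ", "))
  if (any(conc[need] < 0))
    stop("negative concentration supplied for pool(s): ",
         paste(need[conc[need] < 0], collapse = ", "))
  xs <- conc[names(law@substrateK)]
  num <- law@V * prod(xs)
  den <- prod(law@substrateK + xs)
  if (length(law@inhibitorK))
    den <- den + prod(conc[names(law@inhibitorK)] + law@inhibitorK)
  as.numeric(num / den)
}

## Rate and its partial derivatives w.r.t. each referenced pool, in one pass.
## Returns list(v, dv) with dv named by pool. Used by the analytic Jacobian.
.rateWithGrad <- function(V, subK, inhK, conc) {
  xs <- conc[names(subK)]
  num <- V * prod(xs)
  d1 <- prod(subK + xs)
  den <- d1
  if (length(inhK)) {
    xb <- conc[names(inhK)]
    d2 <- prod(xb + inhK)
    den <- d1 + d2
  }
  v <- num / den
  dv <- numeric(0)
  for (s in names(subK)) {
    dnum <- V * prod(xs[names(subK) != s])
    dden <- d1 / (subK[[s]] + xs[[s]])
    if (length(inhK) && s %in% names(inhK))
      dden <- dden + d2 / (conc[[s]] + inhK[[s]])
    dv[s] <- (dnum * den - num * dden) / den^2
  }
  if (length(inhK)) for (b in names(inhK)) {
    if (b %in% names(subK)) next  # handled above
    dden <- d2 / (conc[[b]] + inhK[[b]])
    dv[b] <- -num * dden / den^2
  }
  list(v = v, dv = dv)
}
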