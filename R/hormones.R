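#' @include line-profile.R steady-state.R
NULL

#' Fit hormone-response correlations across lines
#'
#' Ordinary least-squares log10-log10 regression of each response variable
#' (gene expression ratio or metabolite concentration) on each hormone level
#' across the lines of one variant. Lines censored below the detection limit
#' are excluded from the fit for that hormone; pairs with fewer than
#' \code{minLines} detected observations, zero responses, or a
#' non-significant slope (p >= alpha) are dropped. The fitted slope is the
#' exponent estimate g; the formalism (power law vs saturating) is chosen per
#' link by \code{\link{chooseFormalism}}.
#'
#' @param lines list of \linkS4class{LineProfile} objects (one variant).
#' @param responses data.frame of response values, one row per line, columns
#'   named by response id; defaults to the lines' gene expression ratios.
#' @param responseType named character giving each response column's type
#'   (\code{"gene"} or \code{"metabolite"}); defaults to \code{"gene"}.
#' @param alpha significance level for retaining a link (default 0.05; no
#'   multiple-testing correction is applied).
#' @param minLines minimum number of detected lines per fit (default 4).
#' @return data.frame of hormone links: \code{hormone}, \code{response},
#'   \code{responseType}, \code{g} (slope), \code{alphaScale}, \code{K},
#'   \code{formalism}, \code{r2adj}, \code{p}, \code{n}, \code{hormoneRef}
#'   (anchor level at which the multiplier is 1).
#' @export
fitHormoneCorrelations <- function(lines, responses = NULL,
                                   responseType = NULL, alpha = 0.05,
                                   minLines = 4L) {
  stopifnot(length(lines) >= 1)
  if (is.null(responses)) {
    genes <- unique(unlist(lapply(lines, function(p) names(p@expressionRatio))))
    genes <- genes[vapply(genes, function(g)
      all(vapply(lines, function(p) g %in% names(p@expressionRatio), NA)), NA)]
    responses <- as.data.frame(lapply(genes, function(g)
      vapply(lines, function(p) p@expressionRatio[[g]], 0)))
    names(responses) <- genes
  }
  if (is.null(responseType))
    responseType <- stats::setNames(rep("gene", ncol(responses)), names(responses))
  hs <- unique(unlist(lapply(lines, function(p) p@hormones$hormone)))
  out <- list()
  for (h in hs) {
    lev <- vapply(lines, function(p) {
      i <- match(h, p@hormones$hormone)
      if (is.na(i)) NA_real_ else p@hormones$level[i]
    }, 0)
    det <- vapply(lines, function(p) {
      i <- match(h, p@hormones$hormone)
      if (is.na(i)) FALSE else !p@hormones$belowDetection[i]
    }, NA)
    use <- det & !is.na(lev) & lev > 0
    if (sum(use) < minLines) next  # all-censored or too few: skipped
    for (resp in names(responses)) {
      y <- responses[[resp]][use]
      ok <- !is.na(y) & y > 0
      if (sum(ok) < minLines) next
      x <- log10(lev[use][ok]); yy <- log10(y[ok])
      if (stats::sd(x) == 0 || stats::sd(yy) == 0) next  # constant: no link
      fit <- stats::lm(yy ~ x)
      sm <- summary(fit)
      pval <- sm$coefficients["x", "Pr(>|t|)"]
      if (is.na(pval) || pval >= alpha) next
      g <- unname(stats::coef(fit)[["x"]])
      if (g == 0) next
      r2 <- sm$adj.r.squared
      K <- stats::median(lev[use][ok])
      form <- chooseFormalism(r2, g)
      href <- stats::median(lev[use][ok])
      alphaScale <- if (form == "power_law") href^(-g)
                    else ((K + href) / href)^g
      out[[length(out) + 1L]] <- data.frame(
        hormone = h, response = resp,
        responseType = unname(responseType[[resp]]),
        g = g, alphaScale = alphaScale, K = K, formalism = form,
        r2adj = r2, p = pval, n = sum(ok), hormoneRef = href,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(hormone = character(0), response = character(0),
               responseType = character(0), g = numeric(0),
               alphaScale = numeric(0), K = numeric(0),
               formalism = character(0), r2adj = numeric(0), p = numeric(0),
               n = integer(0), hormoneRef = numeric(0))
}

#' Choose the hormone-coupling formalism
#'
#' A link with high adjusted R-squared relative to its exponent is modelled
#' as a power law (fewer parameters, less overfitting); a combination of low
#' adjusted R-squared and high |g| suggests the hormone range only probes a
#' saturating response, modelled with a half-saturation term. The decision
#' ratio is |R2adj / g| with threshold 0.5: strictly greater selects the
#' power law, the boundary and below select saturation.
#'
#' @param r2adj adjusted R-squared of the log-log fit (finite).
#' @param g fitted exponent (nonzero).
#' @return \code{"power_law"} or \code{"saturating"}.
#' @examples
#' chooseFormalism(0.8, 1)  # ratio 0.8 -> power_law
#' chooseFormalism(0.2, 2)  # ratio 0.1 -> saturating
#' chooseFormalism(0.5, 1)  # boundary  -> saturating
#' @export
chooseFormalism <- function(r2adj, g) {
  if (!is.finite(r2adj) || !is.finite(g)) stop("r2adj and g must be finite")
  if (g == 0) stop("g must be nonzero; a zero exponent attaches no link")
  if (abs(r2adj / g) > 0.5) "power_law" else "saturating"
}

## multiplier contributed by one link at hormone level H
.hormoneFactor <- function(link, H) {
  if (link$formalism == "power_law") link$alphaScale * H^link$g
  else link$alphaScale * (H / (link$K + H))^link$g
}

#' Attach hormone multipliers to a kinetic model
#'
#' Multiplies the rates of the affected reactions by each link's hormone
#' factor, evaluated at the supplied hormone levels. Gene links multiply the
#' reactions tagged with that gene; metabolite links multiply the reactions
#' producing that metabolite. The factors are anchored to 1 at the link's
#' reference (wild-type/median) hormone level, so the basal model is
#' preserved at reference conditions; hormones flagged below the detection
#' limit contribute a factor of exactly 1 (piecewise reversion to the basal
#' kinetics).
#'
#' @param model a \linkS4class{KineticModel}.
#' @param links data.frame from \code{\link{fitHormoneCorrelations}}.
#' @param hormoneLevels named numeric vector of hormone levels.
#' @param belowDetection named logical vector (or NULL): TRUE entries revert
#'   the corresponding links to the basal model.
#' @return the model with multipliers set (existing multipliers are reset to
#'   1 first, so the operation is idempotent and removable with
#'   \code{\link{removeHormoneModifiers}}).
#' @export
attachHormoneModifiers <- function(model, links, hormoneLevels,
                                   belowDetection = NULL) {
  model <- removeHormoneModifiers(model)
  if (!nrow(links)) return(model)
  geneOf <- vapply(model@reactions, function(r) r@gene, "")
  producers <- lapply(model@reactions, function(r) names(r@products))
  dynPools <- model@pools$name[model@pools$role == "dynamic"]
  for (i in seq_len(nrow(links))) {
    link <- links[i, ]
    if (link$responseType == "gene") {
      affected <- which(geneOf == link$response)
      if (!length(affected)) next  # gene outside the kinetic model (e.g. WR1)
    } else {
      if (!link$response %in% dynPools)
        stop("hormone link targets pool with no matching reaction: ",
             link$response)
      affected <- which(vapply(producers, function(p) link$response %in% p, NA))
      if (!length(affected))
        stop("hormone link targets pool with no producing reaction: ",
             link$response)
    }
    if (!link$hormone %in% names(hormoneLevels))
      stop("no level supplied for hormone ", link$hormone)
    censored <- !is.null(belowDetection) &&
      isTRUE(belowDetection[[link$hormone]])
    fac <- if (censored) 1 else .hormoneFactor(link, hormoneLevels[[link$hormone]])
    for (j in affected) {
      model@reactions[[j]]@multiplier <- model@reactions[[j]]@multiplier * fac
      model@reactions[[j]]@links <-
        c(model@reactions[[j]]@links, list(as.list(link)))
    }
  }
  model
}

#' Remove all hormone multipliers from a model
#'
#' Resets every reaction multiplier to 1 and clears the attached links,
#' restoring the basal kinetics exactly.
#'
#' @param model a \linkS4class{KineticModel}.
#' @return the basal model.
#' @export
removeHormoneModifiers <- function(model) {
  model@reactions <- lapply(model@reactions, function(r) {
    r@multiplier <- 1; r@links <- list(); r
  })
  model
}

#' Validate hormone-metabolite correlation recovery
#'
#' Qualitative assessment of the coupled models: for each significant
#' (hormone, metabolite) link, the hormone is swept over its observed range
#' in the lines (others held at their median), the coupled median model is
#' re-solved at each level, and the sign of the simulated metabolite-hormone
#' correlation is compared with the experimentally fitted sign. Links whose
#' model loses stability at some hormone level are counted ambiguous.
#'
#' @param model the (stabilized) median \linkS4class{KineticModel} for the
#'   variant.
#' @param links data.frame of metabolite links (responseType
#'   \code{"metabolite"}) together with any gene links to apply alongside.
#' @param lines list of \linkS4class{LineProfile}s supplying the observed
#'   hormone ranges.
#' @param nGrid number of hormone levels per sweep.
#' @return list with counts \code{assessed}, \code{matched},
#'   \code{ambiguous} and a per-link detail data.frame.
#' @export
validateCorrelationRecovery <- function(model, links, lines, nGrid = 5L) {
  metLinks <- links[links$responseType == "metabolite", , drop = FALSE]
  if (!nrow(metLinks))
    return(list(assessed = 0L, matched = 0L, ambiguous = 0L,
                detail = data.frame()))
  hs <- unique(unlist(lapply(lines, function(p) p@hormones$hormone)))
  levOf <- function(h) {
    v <- vapply(lines, function(p) {
      i <- match(h, p@hormones$hormone)
      if (is.na(i) || p@hormones$belowDetection[i]) NA_real_ else p@hormones$level[i]
    }, 0)
    v[!is.na(v) & v > 0]
  }
  medLev <- vapply(hs, function(h) {
    v <- levOf(h); if (length(v)) stats::median(v) else NA_real_
  }, 0)
  names(medLev) <- hs
  detail <- list()
  matched <- 0L; ambiguous <- 0L
  for (i in seq_len(nrow(metLinks))) {
    link <- metLinks[i, ]
    obs <- levOf(link$hormone)
    if (length(obs) < 2) { ambiguous <- ambiguous + 1L; next }
    sweep <- exp(seq(log(min(obs)), log(max(obs)), length.out = nGrid))
    conc <- rep(NA_real_, nGrid)
    okAll <- TRUE
    for (k in seq_len(nGrid)) {
      hl <- medLev
      hl[link$hormone] <- sweep[k]
      m <- attachHormoneModifiers(model, links, hl)
      ss <- findSteadyState(m, quick = TRUE)
      if (!ss@converged || !ss@stable) { okAll <- FALSE; break }
      conc[k] <- ss@concentrations[[link$response]]
    }
    if (!okAll) {
      ambiguous <- ambiguous + 1L
      detail[[length(detail) + 1L]] <- data.frame(
        hormone = link$hormone, response = link$response, outcome = "ambiguous")
      next
    }
    simSign <- if (stats::sd(log(conc)) == 0) NA_real_ else
      sign(stats::cor(log(sweep), log(conc), method = "spearman"))
    expSign <- sign(link$g)
    hit <- !is.na(simSign) && simSign == expSign
    if (is.na(simSign) || simSign == 0) {
      ambiguous <- ambiguous + 1L
      outcome <- "ambiguous"
    } else if (hit) {
      matched <- matched + 1L
      outcome <- "matched"
    } else outcome <- "mismatched"
    detail[[length(detail) + 1L]] <- data.frame(
      hormone = link$hormone, response = link$response, outcome = outcome)
  }
  list(assessed = nrow(metLinks), matched = matched, ambiguous = ambiguous,
       detail = if (length(detail)) do.call(rbind, detail) else data.frame())
}
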