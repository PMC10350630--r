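#' @include steady-state.R
NULL

## default scan targets: Vmax of the reactions consuming the three MEP
## intermediates that accumulate in destabilized lines (DXP -> DXR step r11,
## CDP-MEP -> MDS step r14, MEcPP -> HDS step r15)
.defaultScanTargets <- c("V_r11", "V_r14", "V_r15")

#' Detect accumulating metabolite pools
#'
#' Attempts to find a stable steady state from the basal concentrations; when
#' none exists, integrates the trajectory and reports the pools that grow
#' without bound (exceed 1000 times basal within the horizon, or grow
#' monotonically over its final decade).
#'
#' @param model a \linkS4class{KineticModel}.
#' @return character vector of accumulating pool names; empty when a stable
#'   steady state is found.
#' @export
detectAccumulation <- function(model) {
  cm <- .compileModel(model)
  ss <- .steadyStateFromCompiled(cm, cm$basal)
  if (ss@converged && ss@stable) return(character(0))
  acc <- ss@diagnostics$accumulating
  if (ss@converged && !ss@stable) acc <- .accumulatingPools(cm, cm$basal)
  if (!length(acc)) acc <- ss@diagnostics$accumulating
  unique(acc)
}

#' Scan Vmax multipliers that stabilize a model
#'
#' Minimal-intervention stabilization: scans log2-spaced multipliers
#' \eqn{2^k, k = -3..6} over all one-, two- and three-dimensional subsets of
#' the target Vmax parameters (by default the consumers of DXP, CDP-MEP and
#' MEcPP), pooling every multiplier vector whose model reaches a stable
#' steady state with positive concentrations. For an already-stable model the
#' scan is skipped and the identity multiplier returned.
#'
#' @param model a \linkS4class{KineticModel}.
#' @param targets character vector of Vmax parameter names to scan (default
#'   \code{V_r11}, \code{V_r14}, \code{V_r15}).
#' @param grid numeric vector of candidate multipliers per axis.
#' @return data.frame with one multiplier column per target, plus
#'   \code{nChanged}, \code{maxRe} (largest eigenvalue real part) and
#'   \code{scannedAxes}; attribute \code{"alreadyStable"} is TRUE when no
#'   intervention was needed. An unstable model with no stable grid point
#'   yields a zero-row data.frame (explicit empty result, never silent).
#' @export
scanStabilizingVmax <- function(model, targets = .defaultScanTargets,
                                grid = 2^seq(-3, 6)) {
  cm <- .compileModel(model)
  pars <- .modelParameters(model)
  missing <- setdiff(targets, names(pars))
  if (length(missing))
    stop("scan targets absent from the model: ", paste(missing, collapse = ", "))
  empty <- stats::setNames(
    as.data.frame(matrix(numeric(0), 0, length(targets) + 3)),
    c(targets, "nChanged", "maxRe", "scannedAxes"))
  base <- .steadyStateFromCompiled(cm, cm$basal, quick = TRUE)
  if (base@converged && base@stable) {
    out <- empty[0, ]
    out[1, targets] <- 1
    out$nChanged <- 0L; out$maxRe <- max(Re(base@eigenvalues))
    out$scannedAxes <- 0L
    attr(out, "alreadyStable") <- TRUE
    return(out)
  }
  rows <- list()
  tryPoint <- function(mult) {
    cmMod <- cm
    for (t in names(mult)) {
      j <- match(substring(t, 3), cm$ids)
      cmMod$V[j] <- cm$V[j] * mult[[t]]
    }
    ss <- .steadyStateFromCompiled(cmMod, cm$basal, quick = TRUE)
    if (ss@converged && ss@stable && all(ss@concentrations > 0)) {
      full <- stats::setNames(rep(1, length(targets)), targets)
      full[names(mult)] <- mult
      row <- as.data.frame(as.list(full))
      names(row) <- targets
      row$nChanged <- sum(full != 1)
      row$maxRe <- max(Re(ss@eigenvalues))
      row$scannedAxes <- length(mult)
      row
    } else NULL
  }
  for (d in 1:min(3, length(targets))) {
    subsets <- utils::combn(targets, d, simplify = FALSE)
    for (sub in subsets) {
      pts <- expand.grid(rep(list(grid), d))
      for (i in seq_len(nrow(pts))) {
        mult <- stats::setNames(as.numeric(pts[i, ]), sub)
        row <- tryPoint(mult)
        if (!is.null(row)) rows[[length(rows) + 1L]] <- row
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  attr(out, "alreadyStable") <- FALSE
  out
}

#' Select the minimal-change stabilizing multiplier vector
#'
#' Chooses, among the stable candidates, the multiplier vector with minimum
#' normalized Euclidean distance to the original parameter values: the norm
#' of the log2 multipliers divided by the square root of the number of
#' scanned axes. Ties are broken by the fewest changed parameters, then
#' lexicographically on the multipliers.
#'
#' @param candidates data.frame from \code{\link{scanStabilizingVmax}}.
#' @param targets the scanned parameter names (defaults to the multiplier
#'   columns of \code{candidates}).
#' @return a \linkS4class{StabilizationResult}.
#' @export
selectMinimalChange <- function(candidates, targets = NULL) {
  if (is.null(targets))
    targets <- setdiff(names(candidates), c("nChanged", "maxRe", "scannedAxes"))
  if (!nrow(candidates))
    stop("no stable candidate found on the grid: empty candidate list")
  alreadyStable <- isTRUE(attr(candidates, "alreadyStable"))
  lg <- as.matrix(log2(candidates[, targets, drop = FALSE]))
  axes <- pmax(candidates$scannedAxes, 1L)
  dist <- sqrt(rowSums(lg^2)) / sqrt(axes)
  ord <- do.call(order, c(list(dist, candidates$nChanged),
                          unname(as.list(candidates[, targets, drop = FALSE]))))
  best <- ord[1]
  new("StabilizationResult", scanned = targets,
      candidates = cbind(candidates, distance = dist),
      chosen = stats::setNames(as.numeric(candidates[best, targets]), targets),
      normalizedDistance = unname(dist[best]),
      maxRealEigen = unname(candidates$maxRe[best]),
      alreadyStable = alreadyStable)
}

#' Stabilize a model by minimal Vmax intervention
#'
#' Convenience wrapper: scans the target Vmax space and applies the chosen
#' minimal-change multiplier vector to the model.
#'
#' @param model a \linkS4class{KineticModel}.
#' @param targets Vmax parameter names to scan.
#' @return list with \code{model} (stabilized) and \code{result}
#'   (\linkS4class{StabilizationResult}).
#' @export
stabilizeModel <- function(model, targets = .defaultScanTargets) {
  cand <- scanStabilizingVmax(model, targets)
  res <- selectMinimalChange(cand, targets)
  pars <- .modelParameters(model)
  newPars <- pars[res@scanned] * res@chosen
  list(model = .withParameters(model, newPars), result = res)
}
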