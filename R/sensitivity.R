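#' @include steady-state.R
NULL

## map parameter names to (reaction index, slot) setters on a compiled model;
## returns closures: setPar(cm, name, value) -> cm
.cmSetParameter <- function(cm, model, name, value) {
  if (startsWith(name, "V_")) {
    j <- match(substring(name, 3), cm$ids)
    if (is.na(j)) stop("unknown parameter: ", name)
    cm$V[j] <- value
    return(cm)
  }
  ## K_<id>_<pool>: ids and pools both contain underscores, so match against
  ## the known reaction ids by longest prefix.
  body <- substring(name, 3)
  hit <- NA_integer_; pool <- NA_character_
  for (j in order(nchar(cm$ids), decreasing = TRUE)) {
    pre <- paste0(cm$ids[j], "_")
    if (startsWith(body, pre)) { hit <- j; pool <- substring(body, nchar(pre) + 1); break }
  }
  if (is.na(hit)) stop("unknown parameter: ", name)
  r <- model@reactions[[hit]]
  ks <- r@law@substrateK
  if (!pool %in% names(ks)) stop("unknown parameter: ", name)
  posDyn <- match(pool, cm$dyn)
  if (!is.na(posDyn)) {
    a <- match(posDyn, cm$subIdx[[hit]])
    cm$subK[[hit]][a] <- value
  } else {
    ## fixed-pool K: recompute the fixed-substrate prefactor
    p <- model@pools
    fixedConc <- stats::setNames(p$basal[p$role == "fixed"], p$name[p$role == "fixed"])
    ks[pool] <- value
    dynSub <- names(ks)[names(ks) %in% cm$dyn]
    pre <- 1
    for (s in setdiff(names(ks), dynSub)) {
      x <- fixedConc[[s]]
      pre <- pre * x / (ks[[s]] + x)
    }
    cm$subFixed[[hit]] <- pre
  }
  cm
}

## core log-sensitivity engine: for a function solve(cm) -> named state (or
## NULL on failure), compute d log(state) / d log(param) by re-solving at
## p * (1 + delta) and p / (1 + delta) (log-centred).
.logSensColumn <- function(cm, model, par, value, base, delta) {
  up <- .cmSetParameter(cm, model, par, value * (1 + delta))
  dn <- .cmSetParameter(cm, model, par, value / (1 + delta))
  sUp <- .newtonSolve(up, base, tol = 1e-10)
  sDn <- .newtonSolve(dn, base, tol = 1e-10)
  ok <- sUp$converged && sDn$converged &&
    max(Re(eigen(.cmJacobian(up, sUp$x), only.values = TRUE)$values)) < 0 &&
    max(Re(eigen(.cmJacobian(dn, sDn$x), only.values = TRUE)$values)) < 0
  if (!ok) return(NULL)
  (log(sUp$x) - log(sDn$x)) / (2 * log1p(delta))
}

#' Logarithmic steady-state parameter sensitivities
#'
#' Computes \eqn{S_{ij} = \partial \log X_i / \partial \log p_j} for every
#' dynamic metabolite \eqn{X_i} and every kinetic parameter \eqn{p_j} (all V
#' and K values) by re-solving the steady state under a log-centred relative
#' perturbation of each parameter, and aggregates them per parameter and per
#' metabolite (Euclidean norm divided by the vector length). Entries whose
#' perturbed system loses stability are set to NA, excluded from the
#' aggregates, and reported with a warning.
#'
#' @param model a \linkS4class{KineticModel} or \linkS4class{PathwayModel}.
#' @param ss a stable \linkS4class{SteadyState} of the model.
#' @param delta relative perturbation (default 0.01, i.e. 1\%).
#' @param parameters optional character vector restricting the parameter set.
#' @return a \linkS4class{SensitivityMatrix}.
#' @export
logSensitivities <- function(model, ss, delta = 0.01, parameters = NULL) {
  stopifnot(is(ss, "SteadyState"))
  if (!isTRUE(ss@stable)) stop("sensitivities require a stable steady state")
  cm <- .compileModel(model)
  pars <- .modelParameters(model)
  if (!is.null(parameters)) pars <- pars[parameters]
  base <- ss@concentrations[cm$dyn]
  entries <- matrix(NA_real_, cm$nDyn, length(pars),
                    dimnames = list(cm$dyn, names(pars)))
  lost <- character(0)
  for (k in seq_along(pars)) {
    col <- .logSensColumn(cm, model, names(pars)[k], pars[[k]], base, delta)
    if (is.null(col)) lost <- c(lost, names(pars)[k]) else entries[, k] <- col
  }
  if (length(lost))
    warning("perturbed re-solve lost stability for: ",
            paste(lost, collapse = ", "), " (excluded from aggregates)")
  agg <- aggregateSensitivities(entries)
  new("SensitivityMatrix", entries = entries,
      perParameter = agg$perParameter, perMetabolite = agg$perMetabolite)
}

#' Aggregate a sensitivity matrix
#'
#' Per-parameter index: Euclidean norm of each column divided by the number
#' of metabolites; per-metabolite index: Euclidean norm of each row divided
#' by the number of parameters. The division by the count makes the indices
#' comparable between model variants with different numbers of metabolites
#' and parameters. NA entries are excluded.
#'
#' @param matrix numeric matrix (metabolites x parameters) or a
#'   \linkS4class{SensitivityMatrix}.
#' @return list with \code{perParameter} and \code{perMetabolite} named
#'   vectors.
#' @examples
#' aggregateSensitivities(matrix(c(3, 4), 2, 1))$perParameter  # 5/2 = 2.5
#' @export
aggregateSensitivities <- function(matrix) {
  if (is(matrix, "SensitivityMatrix")) matrix <- matrix@entries
  n <- nrow(matrix); m <- ncol(matrix)
  perParameter <- apply(matrix, 2, function(col) sqrt(sum(col^2, na.rm = TRUE)) / n)
  perMetabolite <- apply(matrix, 1, function(row) sqrt(sum(row^2, na.rm = TRUE)) / m)
  list(perParameter = perParameter, perMetabolite = perMetabolite)
}

#' Logarithmic sensitivities of Jacobian eigenvalue moduli
#'
#' For each parameter, re-solves the steady state at a log-centred relative
#' perturbation and differentiates the modulus of each Jacobian eigenvalue
#' with respect to the log parameter. Eigenvalues are tracked between the
#' perturbed systems by nearest-neighbour matching in the complex plane;
#' entries whose matching is ambiguous (eigenvalue crossing) are NA.
#'
#' @param model a \linkS4class{KineticModel}.
#' @param ss a stable \linkS4class{SteadyState} with simple eigenvalues.
#' @param delta relative perturbation (default 0.01).
#' @return numeric matrix, eigenvalues (sorted by decreasing real part at the
#'   base state) x parameters.
#' @export
eigenvalueSensitivities <- function(model, ss, delta = 0.01) {
  stopifnot(is(ss, "SteadyState"), isTRUE(ss@stable))
  cm <- .compileModel(model)
  pars <- .modelParameters(model)
  base <- ss@concentrations[cm$dyn]
  ev0 <- ss@eigenvalues[order(-Re(ss@eigenvalues), Im(ss@eigenvalues))]
  n <- length(ev0)
  out <- matrix(NA_real_, n, length(pars),
                dimnames = list(paste0("lambda", seq_len(n)), names(pars)))
  evAt <- function(cmMod, start) {
    s <- .newtonSolve(cmMod, start, tol = 1e-10)
    if (!s$converged) return(NULL)
    eigen(.cmJacobian(cmMod, s$x), only.values = TRUE)$values
  }
  matchTo <- function(ref, ev) {
    ## greedy nearest matching; NA where assignment conflicts
    idx <- rep(NA_integer_, length(ref))
    used <- logical(length(ev))
    for (i in seq_along(ref)) {
      d <- Mod(ev - ref[i]); d[used] <- Inf
      j <- which.min(d)
      ## ambiguous when the second-nearest is nearly as close
      d2 <- sort(d)[2]
      if (is.finite(d2) && d2 < 1.05 * d[j]) next
      idx[i] <- j; used[j] <- TRUE
    }
    idx
  }
  for (k in seq_along(pars)) {
    up <- .cmSetParameter(cm, model, names(pars)[k], pars[[k]] * (1 + delta))
    dn <- .cmSetParameter(cm, model, names(pars)[k], pars[[k]] / (1 + delta))
    evUp <- evAt(up, base); evDn <- evAt(dn, base)
    if (is.null(evUp) || is.null(evDn)) next
    iUp <- matchTo(ev0, evUp); iDn <- matchTo(ev0, evDn)
    s <- (log(Mod(evUp[iUp])) - log(Mod(evDn[iDn]))) / (2 * log1p(delta))
    s[is.na(iUp) | is.na(iDn)] <- NA_real_
    out[, k] <- s
  }
  out
}
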