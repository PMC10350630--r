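#' @include pathway-model.R
NULL

#' Assemble the ODE right-hand side of a pathway model
#'
#' Each dynamic metabolite pool gets one differential equation,
#' \eqn{dM_i/dt = \sum_j f_j - \sum_k f_k}: every producing flux enters with
#' its stoichiometric weight and every consuming flux with a negative weight.
#' Fixed pools (Ac-CoA, acetoacetyl-CoA, G3P, pyruvate) contribute to the
#' rates but never acquire an equation.
#'
#' @param model a \linkS4class{PathwayModel}.
#' @return a function \code{f(state)} mapping a named concentration vector of
#'   the dynamic pools (mM) to their time derivatives (mM per model-time
#'   unit), with the model's basal state attached as attribute
#'   \code{"basal"}.
#' @export
assembleOdes <- function(model) {
  validObject(model)
  cm <- .compileModel(model)
  f <- function(state) {
    if (!is.null(names(state))) state <- state[cm$dyn]
    stats::setNames(.cmDeriv(cm, as.numeric(state)), cm$dyn)
  }
  attr(f, "basal") <- cm$basal
  f
}

#' Jacobian matrix of a pathway model at a state
#'
#' Analytic partial derivatives \eqn{\partial f_i / \partial x_j} of the ODE
#' right-hand side with respect to each dynamic pool, evaluated at the given
#' state. The analytic form is exact for the saturating rate law and is
#' validated against central finite differences in the test suite.
#'
#' @param model a \linkS4class{PathwayModel}.
#' @param state named numeric vector of dynamic-pool concentrations (> 0).
#' @return an n x n matrix, n = number of dynamic pools.
#' @export
jacobianMatrix <- function(model, state) {
  cm <- .compileModel(model)
  if (!is.null(names(state))) state <- state[cm$dyn]
  if (any(state < 0)) stop("state concentrations must be non-negative")
  .cmJacobian(cm, as.numeric(state))
}

#' Classify steady-state stability from Jacobian eigenvalues
#'
#' A steady state is stable precisely when all eigenvalues of the Jacobian
#' have negative real part.
#'
#' @param eigenvalues complex (or numeric) vector of eigenvalues.
#' @return \code{"stable"} or \code{"unstable"}.
#' @export
classifyStability <- function(eigenvalues) {
  if (!length(eigenvalues)) stop("eigenvalue list must be non-empty")
  if (max(Re(eigenvalues)) < 0) "stable" else "unstable"
}

#' Solve for the steady state of a pathway model
#'
#' Finds a non-negative fixed point of the ODE system by damped Newton
#' iteration with the analytic Jacobian, starting from \code{init}; if Newton
#' fails, the system is integrated from \code{init} towards quasi-stationarity
#' and root-polished from the trajectory endpoint. On divergence the returned
#' object is flagged non-converged and carries the accumulating-pool
#' diagnosis (pools exceeding 1000 times basal within the horizon or still
#' growing monotonically over its final decade).
#'
#' @param model a \linkS4class{PathwayModel}.
#' @param init named numeric initial concentrations; defaults to the model's
#'   basal concentrations.
#' @param tol residual tolerance (infinity norm of the derivatives, mM per
#'   model-time unit).
#' @param quick logical; skip the integration fallback (used inside grid
#'   scans where divergence is an expected, frequent outcome).
#' @return a \linkS4class{SteadyState}.
#' @examples
#' wt <- buildVariantModel("WT")
#' ss <- findSteadyState(wt)
#' isStable(ss)
#' @export
findSteadyState <- function(model, init = NULL, tol = 1e-8, quick = FALSE) {
  cm <- .compileModel(model)
  x0 <- if (is.null(init)) cm$basal else {
    if (!is.null(names(init))) init <- init[cm$dyn]
    as.numeric(init)
  }
  if (any(x0 <= 0)) stop("initial concentrations must be > 0")
  .steadyStateFromCompiled(cm, x0, tol = tol, quick = quick)
}

.steadyStateFromCompiled <- function(cm, x0, tol = 1e-8, quick = FALSE) {
  res <- .newtonSolve(cm, x0, tol = tol, maxit = if (quick) 60L else 200L)
  if (!res$converged && !quick) {
    horizon <- 10^seq(0, 4, by = 0.5)
    traj <- tryCatch(.cmIntegrate(cm, x0, c(0, horizon)),
                     error = function(e) NULL)
    if (!is.null(traj) && nrow(traj) == length(horizon) + 1L) {
      endpoint <- pmax(as.numeric(traj[nrow(traj), -1]), 1e-15)
      res2 <- .newtonSolve(cm, endpoint, tol = tol)
      if (res2$converged) res <- res2
    }
  }
  if (!res$converged) {
    acc <- if (quick) character(0) else .accumulatingPools(cm, x0)
    return(new("SteadyState", concentrations = stats::setNames(res$x, cm$dyn),
               residualNorm = res$fnorm, converged = FALSE, stable = FALSE,
               eigenvalues = complex(0),
               diagnostics = list(accumulating = acc)))
  }
  x <- stats::setNames(res$x, cm$dyn)
  ev <- eigen(.cmJacobian(cm, res$x), only.values = TRUE)$values
  ev <- as.complex(ev)
  new("SteadyState", concentrations = x, residualNorm = res$fnorm,
      converged = TRUE, stable = classifyStability(ev) == "stable",
      eigenvalues = ev, diagnostics = list())
}

## pools that grow without bound along the trajectory from x0
.accumulatingPools <- function(cm, x0) {
  horizon <- 10^seq(0, 3, by = 0.25)
  traj <- tryCatch(.cmIntegrate(cm, x0, c(0, horizon)),
                   error = function(e) NULL)
  if (is.null(traj)) return(cm$dyn)  # integrator overwhelmed: all suspect
  traj <- traj[, -1, drop = FALSE]
  nT <- nrow(traj)
  last <- traj[nT, ]
  exceed <- last > 1e3 * cm$basal
  ## monotone growth over the final decade of the horizon (t in [100, 1000])
  dec <- which(horizon >= 100) + 1L
  dec <- dec[dec <= nT]
  mono <- rep(FALSE, cm$nDyn)
  if (length(dec) >= 3) {
    seg <- traj[dec, , drop = FALSE]
    growth <- seg[nrow(seg), ] / pmax(seg[1, ], 1e-300)
    mono <- apply(seg, 2, function(z) all(diff(z) > 0)) & growth > 1.05
  }
  cm$dyn[exceed | mono]
}
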