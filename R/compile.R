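## Internal compiled representation of a PathwayModel: plain numeric vectors
## and index lists so that rate, derivative and Jacobian evaluation inside
## solvers and scans avoids any S4 dispatch.

.compileModel <- function(model) {
  p <- model@pools
  dyn <- p$name[p$role == "dynamic"]
  fixedConc <- stats::setNames(p$basal[p$role == "fixed"],
                               p$name[p$role == "fixed"])
  nDyn <- length(dyn)
  rxns <- model@reactions
  nR <- length(rxns)
  S <- matrix(0, nDyn, nR, dimnames = list(dyn, vapply(rxns, slot, "", "id")))
  V <- numeric(nR); mult <- numeric(nR)
  subIdx <- vector("list", nR); subK <- vector("list", nR)
  subFixed <- vector("list", nR)  # fixed-substrate saturation prefactor
  for (j in seq_len(nR)) {
    r <- rxns[[j]]
    V[j] <- r@law@V; mult[j] <- r@multiplier
    for (s in names(r@substrates)) {
      i <- match(s, dyn)
      if (!is.na(i)) S[i, j] <- S[i, j] - r@substrates[[s]]
    }
    for (s in names(r@products)) {
      i <- match(s, dyn)
      if (!is.na(i)) S[i, j] <- S[i, j] + r@products[[s]]
    }
    ks <- r@law@substrateK
    dynSub <- names(ks)[names(ks) %in% dyn]
    fixSub <- setdiff(names(ks), dynSub)
    subIdx[[j]] <- match(dynSub, dyn)
    subK[[j]] <- unname(ks[dynSub])
    pre <- 1
    for (s in fixSub) {
      x <- fixedConc[[s]]
      pre <- pre * x / (ks[[s]] + x)
    }
    subFixed[[j]] <- pre
  }
  list(dyn = dyn, nDyn = nDyn, S = S, V = V, mult = mult,
       subIdx = subIdx, subK = subK, subFixed = subFixed,
       basal = stats::setNames(p$basal[p$role == "dynamic"], dyn),
       ids = colnames(S))
}

## per-reaction fluxes at dynamic state x (non-negative-clamped)
.cmRates <- function(cm, x) {
  x <- pmax(x, 0)
  v <- numeric(length(cm$V))
  for (j in seq_along(v)) {
    idx <- cm$subIdx[[j]]
    f <- cm$V[j] * cm$mult[j] * cm$subFixed[[j]]
    if (length(idx)) {
      xs <- x[idx]; ks <- cm$subK[[j]]
      f <- f * prod(xs / (ks + xs))
    }
    v[j] <- f
  }
  v
}

.cmDeriv <- function(cm, x) as.numeric(cm$S %*% .cmRates(cm, x))

## analytic Jacobian of the derivative vector w.r.t. the dynamic state
.cmJacobian <- function(cm, x) {
  x <- pmax(x, 0)
  n <- cm$nDyn
  J <- matrix(0, n, n, dimnames = list(cm$dyn, cm$dyn))
  for (j in seq_along(cm$V)) {
    idx <- cm$subIdx[[j]]
    if (!length(idx)) next
    xs <- x[idx]; ks <- cm$subK[[j]]
    sat <- xs / (ks + xs)
    f <- cm$V[j] * cm$mult[j] * cm$subFixed[[j]] * prod(sat)
    col <- cm$S[, j]
    for (a in seq_along(idx)) {
      ## d f / d x_a = f * K_a / (x_a (K_a + x_a)); finite at x_a -> 0 via
      ## the product form below.
      others <- prod(sat[-a])
      dfdx <- cm$V[j] * cm$mult[j] * cm$subFixed[[j]] * others *
        ks[a] / (ks[a] + xs[a])^2
      J[, idx[a]] <- J[, idx[a]] + col * dfdx
    }
  }
  J
}

## Damped Newton root solve with positivity control. Returns list(x, fnorm,
## converged, iter). Divergence (unbounded growth or max iterations) leaves
## converged = FALSE.
.newtonSolve <- function(cm, x0, tol = 1e-8, maxit = 200L) {
  x <- pmax(x0, 1e-12)
  cap <- 1e7 * max(cm$basal)
  for (it in seq_len(maxit)) {
    f <- .cmDeriv(cm, x)
    fn <- max(abs(f))
    if (fn < tol) {
      return(list(x = x, fnorm = fn, converged = TRUE, iter = it))
    }
    J <- .cmJacobian(cm, x)
    dx <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(dx)) return(list(x = x, fnorm = fn, converged = FALSE, iter = it))
    ## damp so no component drops below 10% of its value in one step
    lam <- 1
    bad <- dx < 0
    if (any(bad)) lam <- min(1, 0.9 * min(-x[bad] / dx[bad]))
    ## backtracking on the residual norm
    for (k in 1:8) {
      xn <- x + lam * dx
      fnNew <- max(abs(.cmDeriv(cm, xn)))
      if (fnNew < fn || fnNew < tol) break
      lam <- lam / 2
    }
    x <- pmax(xn, 1e-15)
    if (max(x) > cap) return(list(x = x, fnorm = fnNew, converged = FALSE,
                                  iter = it))
  }
  f <- .cmDeriv(cm, x)
  list(x = x, fnorm = max(abs(f)), converged = max(abs(f)) < tol, iter = maxit)
}

## integrate the compiled system with deSolve from x0 over the given times
.cmIntegrate <- function(cm, x0, times) {
  derivs <- function(t, y, parms) list(.cmDeriv(cm, y))
  jac <- function(t, y, parms) .cmJacobian(cm, y)
  out <- deSolve::ode(y = x0, times = times, func = derivs, parms = NULL,
                      jacfunc = jac, jactype = "fullusr", method = "lsoda",
                      rtol = 1e-9, atol = 1e-14)
  out
}
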