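# Small constructed kinetic systems used as oracles across the test files.

# One dynamic pool M fed at a constant rate and drained by a single
# Michaelis-Menten consumer. With production flux c = V_in * s/(K_in + s)
# and consumer (V, K), the steady state has the closed form
#   M* = c K / (V - c),
# which several tests use as a hand-derived oracle.
toyOnePool <- function(Vin = 4, Kin = 1, Vout = 4, Kout = 1, basalM = 1,
                       s = 1) {
  kineticModel(
    c(M = basalM),
    list(reactionSpec("in", c(S = 1L), c(M = 1L), V = Vin, K = c(S = Kin)),
         reactionSpec("out", c(M = 1L), V = Vout, K = c(M = Kout))),
    fixed = c(S = s))
}

toyOnePoolStar <- function(Vin = 4, Kin = 1, Vout = 4, Kout = 1, s = 1) {
  cflux <- Vin * s / (Kin + s)
  cflux * Kout / (Vout - cflux)
}

# Three-pool linear chain S -> A -> B -> C -> (sink); used to check ODE
# assembly and the analytic Jacobian against hand-written expressions.
toyChain3 <- function(V = c(4, 3, 3, 3), K = c(1, 0.5, 0.8, 1.2)) {
  kineticModel(
    c(A = 1, B = 1, C = 1),
    list(reactionSpec("r_in", c(S = 1L), c(A = 1L), V = V[1], K = c(S = K[1])),
         reactionSpec("r_ab", c(A = 1L), c(B = 1L), V = V[2], K = c(A = K[2])),
         reactionSpec("r_bc", c(B = 1L), c(C = 1L), V = V[3], K = c(B = K[3])),
         reactionSpec("r_c",  c(C = 1L), V = V[4], K = c(C = K[4]))),
    fixed = c(S = 1))
}

# hand-written right-hand side of toyChain3 (independent of the package's
# assembly path)
toyChain3Deriv <- function(x, V = c(4, 3, 3, 3), K = c(1, 0.5, 0.8, 1.2),
                           s = 1) {
  fin <- V[1] * s / (K[1] + s)
  fab <- V[2] * x[["A"]] / (K[2] + x[["A"]])
  fbc <- V[3] * x[["B"]] / (K[3] + x[["B"]])
  fc  <- V[4] * x[["C"]] / (K[4] + x[["C"]])
  c(A = fin - fab, B = fab - fbc, C = fbc - fc)
}

# A consumer running near capacity: constant production flux 2, consumer
# saturation 0.909 at basal, capacity V = 2.2. Dividing the consumer V by
# `deficit` > 1.1 removes the steady state; the minimal stabilizing
# multiplier is deficit * 2/2.2, so a 4x deficit needs ~3.64 (grid point 4).
nearCapacityModel <- function(deficit = 1) {
  kineticModel(
    c(A = 1),
    list(reactionSpec("feed", c(S = 1L), c(A = 1L), V = 4, K = c(S = 1)),
         reactionSpec("drain", c(A = 1L), V = 2.2 / deficit, K = c(A = 0.1))),
    fixed = c(S = 1))
}

# central finite-difference Jacobian, the independent oracle for the
# analytic one
fdJacobian <- function(model, state, h = 1e-6) {
  f <- assembleOdes(model)
  n <- length(state)
  J <- matrix(0, n, n, dimnames = list(names(state), names(state)))
  for (j in seq_len(n)) {
    hp <- h * max(abs(state[[j]]), 1e-3)
    up <- state; up[j] <- up[j] + hp
    dn <- state; dn[j] <- dn[j] - hp
    J[, j] <- (f(up) - f(dn)) / (2 * hp)
  }
  J
}

# simple profiles for median/scaling tests
mkProfile <- function(id, variant = "I", ratios, hormones = c(iP = 1.5),
                      phenotype = c(height = 60)) {
  lineProfile(id, variant, ratios, hormones = hormones, phenotype = phenotype)
}
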