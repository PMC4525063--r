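# Shared oracles and generators for the test suite.
# All randomized tests run under fixed seeds set in the tests themselves.

# Strain energy as a function of C (independent of the package's F-based
# path): invariants computed directly from C, fiber integrals by
# adaptive numerical quadrature of the raw stress-stretch integrands.
energy_from_C_quadrature <- function(C, N, mat, zeta) {
  J <- sqrt(det(C))
  I1b <- sum(diag(C)) * det(C)^(-1 / 3)
  lam <- sqrt(drop(t(N) %*% C %*% N))
  lfb <- J^(-1 / 3) * lam
  f_pe <- function(x) ifelse(x > 1, mat$A * (x - 1)^2, 0)
  f_se <- function(x) {
    ifelse(x > 1 + zeta, 0.1 * (exp(100 * (x - 1 - zeta)) - 1), 0)
  }
  int <- function(f) {
    if (abs(lfb - 1) < 1e-14) return(0)
    stats::integrate(f, 1, lfb, rel.tol = 1e-12, abs.tol = 1e-14)$value
  }
  mat$G / 2 * (I1b - 3) + mat$K / 2 * log(J)^2 +
    mat$sigma0 * (int(f_pe) + int(f_se))
}

# Package energy re-expressed as a function of C (via a Cholesky square
# root), for finite-difference stress checks.
energy_from_C <- function(C, N, mat, zeta) {
  F <- chol(C)                       # C = F' F with det F > 0
  strain_energy(fiber_kinematics(F, N), mat, zeta)
}

# Central finite-difference approximation of S = 2 dU/dC (symmetric
# perturbations; for off-diagonal entries the directional derivative
# along E_ij + E_ji picks up both symmetric partners, hence the extra
# factor of 2 in the divisor).
fd_pk2 <- function(C, N, mat, zeta, h = 1e-5) {
  S <- matrix(0, 3, 3)
  for (i in 1:3) for (j in i:3) {
    dC <- matrix(0, 3, 3)
    if (i == j) dC[i, i] <- h else { dC[i, j] <- h; dC[j, i] <- h }
    up <- energy_from_C(C + dC, N, mat, zeta)
    dn <- energy_from_C(C - dC, N, mat, zeta)
    S[i, j] <- S[j, i] <- if (i == j) (up - dn) / h else (up - dn) / (2 * h)
  }
  S
}

# Random deformation gradient with J in [0.9, 1.1] and random unit N.
random_state <- function() {
  F <- diag(3) + matrix(stats::runif(9, -0.05, 0.05), 3, 3)
  Jt <- stats::runif(1, 0.9, 1.1)
  F <- F * (Jt / det(F))^(1 / 3)
  N <- stats::rnorm(3)
  list(F = F, N = N / sqrt(sum(N^2)))
}

random_rotation <- function() {
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, 0, 2 * pi)
  Kx <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  diag(3) + sin(th) * Kx + (1 - cos(th)) * Kx %*% Kx
}

# Terzaghi double-drainage consolidation series (uniform column, step
# load): excess pressure at heights z, time t.
terzaghi_pressure <- function(z, t, H, cv, p0, n_terms = 200) {
  s <- 0
  for (m in seq(1, 2 * n_terms - 1, by = 2)) {
    s <- s + 4 * p0 / (m * pi) * sin(m * pi * z / H) *
      exp(-m^2 * pi^2 * cv * t / H^2)
  }
  s
}

# Small standing run used by several coupled tests.
quick_standing <- function(model, n_steps = 6, ...) {
  run_standing(model, ramp_seconds = 60, n_steps = n_steps, ...)
}
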