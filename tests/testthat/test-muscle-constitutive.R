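# Muscle constitutive law: stress-stretch branches, activation,
# energy-stress consistency and frame indifference.

mats <- muscle_materials()
mf <- mats$MF

test_that("shipped material sets satisfy their invariants", {
  expect_setequal(names(mats), c("MF", "LTpL", "LTpTh", "ILpL", "PS"))
  for (m in mats) {
    expect_gt(m$G, 0); expect_gt(m$K, 0); expect_gt(m$sigma0, 0)
    expect_gte(m$A, 0)
    expect_gt(m$c_ce1, m$c_ce2)
    expect_equal(m$K, 1000 * m$G)
  }
  expect_error(muscle_material("X", G = -1, c_ce1 = 1, c_ce2 = 0.5), "G")
})

test_that("passive fiber factor is tension-only, quadratic, monotone", {
  expect_identical(passive_fiber_factor(1.0, 4.0), 0)
  expect_identical(passive_fiber_factor(0.9, 4.0), 0)
  expect_equal(passive_fiber_factor(1.1, 4.0), 0.04)
  # C1 continuity at the threshold
  h <- 1e-8
  expect_lt(passive_fiber_factor(1 + h, 4.0) / h, 1e-6)
  x <- seq(0.5, 1.6, by = 0.01)
  expect_true(all(diff(passive_fiber_factor(x, 4.0)) >= 0))
  expect_error(passive_fiber_factor(-0.1, 4.0), "positive")
})

test_that("active fiber factor switches at 1 + zeta and is monotone", {
  for (z in c(-0.05, 0, 0.02)) {
    expect_identical(active_fiber_factor(1 + z, z), 0)
    expect_identical(active_fiber_factor(1 + z - 1e-9, z), 0)
    expect_lt(active_fiber_factor(1 + z + 1e-9, z), 1e-6)  # continuous
  }
  expect_equal(active_fiber_factor(1.02, 0), 0.63890560989306502,
               tolerance = 1e-12)
  # concentric activation: negative zeta enables stress at lambda = 1
  expect_equal(active_fiber_factor(1.0, -0.01), 0.17182818284590452,
               tolerance = 1e-12)
  x <- seq(0.9, 1.1, by = 0.002)
  expect_true(all(diff(active_fiber_factor(x, -0.03)) >= 0))
})

test_that("contractile strain selects the branch by strain sign", {
  a0 <- contractile_strain(0, mf)
  expect_identical(a0$zeta, 0)
  expect_identical(a0$branch, "inactive")
  ae <- contractile_strain(0.015, mf)
  expect_equal(ae$zeta, 0.006975)
  expect_identical(ae$branch, "eccentric")
  ac <- contractile_strain(-0.02, mf)
  expect_equal(ac$zeta, -0.01412)
  expect_identical(ac$branch, "concentric")
  expect_error(contractile_strain(-1, mf), "annihilated")
})

test_that("active parameter equals sarcomere length ratio", {
  expect_equal(active_parameter_from_sarcomere(2.8, 2.8), 1.0)
  expect_equal(active_parameter_from_sarcomere(3.1108), 1.111)
  expect_equal(active_parameter_from_sarcomere(2.2708), 0.811)
  expect_error(active_parameter_from_sarcomere(-1), "> 0")
})

test_that("group-to-group activation scaling of the active parameters is constant", {
  sub <- mats[c("MF", "LTpL", "ILpL", "PS")]
  cv <- function(x) stats::sd(x) / mean(x)
  r1 <- vapply(sub, function(m) m$c_ce1 / m$c_ce_ref, numeric(1))
  r2 <- vapply(sub, function(m) m$c_ce2 / m$c_ce_ref, numeric(1))
  expect_lt(cv(r1), 0.001)
  expect_lt(cv(r2), 0.001)
})

test_that("strain energy vanishes in the reference state and matches quadrature", {
  kin0 <- fiber_kinematics(diag(3), c(0, 0, 1))
  expect_identical(strain_energy(kin0, mf, 0), 0)

  # pure dilatation: only the volumetric term survives
  kin_d <- fiber_kinematics(1.1^(1 / 3) * diag(3), c(0, 0, 1))
  expect_equal(strain_energy(kin_d, mf, 0), mf$K / 2 * log(1.1)^2,
               tolerance = 1e-12)
  expect_equal(strain_energy(kin_d, mf, 0), 0.0074579889373271750,
               tolerance = 1e-10)

  # closed-form fiber integrals against adaptive quadrature
  set.seed(41)
  for (i in 1:12) {
    st <- random_state()
    for (z in c(0, 0.01, -0.02)) {
      kin <- fiber_kinematics(st$F, st$N)
      expect_equal(strain_energy(kin, mf, z),
                   energy_from_C_quadrature(kin$C, st$N, mf, z),
                   tolerance = 1e-10)
    }
  }
  # isochoric uniaxial stretch along the fiber
  lam <- 1.05
  Fu <- diag(c(lam^(-1 / 2), lam^(-1 / 2), lam))
  kin <- fiber_kinematics(Fu, c(0, 0, 1))
  expect_equal(strain_energy(kin, mf, 0),
               energy_from_C_quadrature(kin$C, c(0, 0, 1), mf, 0),
               tolerance = 1e-10)
})

test_that("second Piola-Kirchhoff stress equals 2 dU/dC (finite differences)", {
  kin0 <- fiber_kinematics(diag(3), c(0, 0, 1))
  expect_lt(max(abs(second_piola_kirchhoff(kin0, mf, 0)$S)), 1e-12)

  set.seed(42)
  for (i in 1:100) {
    st <- random_state()
    kin <- fiber_kinematics(st$F, st$N)
    zeta <- sample(c(0, 0.01, -0.015), 1)
    S <- second_piola_kirchhoff(kin, mf, zeta)$S
    S_fd <- fd_pk2(kin$C, st$N, mf, zeta)
    expect_lt(norm(S - S_fd, "F") / max(norm(S_fd, "F"), 1e-8), 1e-6)
    expect_lt(max(abs(S - t(S))), 1e-10)
  }
})

test_that("Cauchy stress is the push-forward and frame-indifferent", {
  set.seed(43)
  st <- random_state()
  kin <- fiber_kinematics(st$F, st$N)
  res <- cauchy_stress(kin, mf, 0.01)
  expect_equal(res$sigma,
               kin$F %*% res$S %*% t(kin$F) / kin$J, tolerance = 1e-10)
  expect_lt(max(abs(res$sigma - t(res$sigma))), 1e-10)
  # frame indifference under 10 seeded rotations
  for (i in 1:10) {
    Q <- random_rotation()
    kinQ <- fiber_kinematics(Q %*% st$F, st$N)
    sQ <- cauchy_stress(kinQ, mf, 0.01)$sigma
    expect_lt(max(abs(sQ - Q %*% res$sigma %*% t(Q))), 1e-9)
  }
})

test_that("fascicle axial force: thresholds, parts, and the free-contract value", {
  z0 <- contractile_strain(0, mf)
  f0 <- fascicle_axial_force(1, z0, mf, 100)
  expect_equal(f0$total, 0)
  expect_equal(f0$active, 0)
  expect_equal(f0$matrix, 0)

  # eccentric activation, laterally free: frozen arbitrary-precision value
  a <- contractile_strain(0.015, mf)
  f <- fascicle_axial_force(1.015, a, mf, 100)
  expect_equal(f$active, 5.5794226705129636, tolerance = 1e-12)
  expect_equal(f$passive_fiber,
               0.46 * 4 * 0.015^2 * 100 / 1.015, tolerance = 1e-12)

  # concentric shortening with the free contract: active branch off
  # (lambda = 0.98 < 1 + zeta = 0.98588), matrix-only compression
  ac <- contractile_strain(-0.02, mf)
  fc <- fascicle_axial_force(0.98, ac, mf, 100)
  expect_equal(fc$active, 0)
  expect_equal(fc$passive_fiber, 0)
  expect_lt(fc$total, 0)

  # confined contract agrees with the full tensor law
  lam <- 0.995
  acl <- contractile_strain(lam - 1, mf)
  fcl <- fascicle_axial_force(lam, acl, mf, 120, lateral = "confined")
  kin <- fiber_kinematics(diag(c(1, 1, lam)), c(0, 0, 1))
  sig <- cauchy_stress(kin, mf, acl$zeta)$sigma
  expect_equal(fcl$total, sig[3, 3] * 120, tolerance = 1e-9)
  # confined shortening activates the concentric branch (C_CE1 > 2/3)
  expect_gt(fcl$active, 0)
  expect_lt(fcl$matrix, 0)

  expect_error(fascicle_axial_force(-1, z0, mf, 100), "lambda")
  expect_error(fascicle_axial_force(1, z0, mf, -5), "csa")
})
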