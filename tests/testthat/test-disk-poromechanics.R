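# 1D osmo-poroelastic disk column: permeability law, consolidation
# against the closed-form series solution, swelling, stiffness.

np <- disk_tissue_params("NP")
cep <- disk_tissue_params("CEP")

test_that("tissue parameter defaults match the shipped table", {
  expect_equal(unlist(np[c("G", "K", "e0", "k0", "M")]),
               c(G = 0.47, K = 0.16, e0 = 4.9, k0 = 0.0009, M = 8.5))
  af <- disk_tissue_params("AF")
  expect_equal(unlist(af[c("G", "K", "e0", "k0", "M")]),
               c(G = 0.95, K = 0.37, e0 = 3.0, k0 = 0.0002, M = 8.5))
  expect_equal(unlist(cep[c("G", "K", "e0", "k0", "M")]),
               c(G = 8.55, K = 10.10, e0 = 4.0, k0 = 0.0025, M = 8.5))
})

test_that("permeability is normalized at e0, increasing, and vanishes at e -> 0", {
  expect_identical(permeability(np$e0, np), np$k0)
  expect_identical(permeability(cep$e0, cep), cep$k0)
  e <- seq(0.5, 12, by = 0.1)
  expect_true(all(diff(permeability(e, np)) > 0))
  expect_lt(permeability(1e-6, np), 1e-12)
  # frozen arbitrary-precision evaluation at e = 2 e0
  expect_equal(permeability(2 * np$e0, np), 1.2502118712375174,
               tolerance = 1e-12)
  expect_error(permeability(-1, np), "> 0")
})

test_that("column constructor validates dimensions and is mirror-symmetric", {
  col <- build_column(8, 0.8, 1800, delta_pi = 0.15, n_per_layer = 11)
  expect_s3_class(col, "disk_column")
  expect_equal(col$H, 9.6)
  expect_error(build_column(0, 0.8, 1800), "dimensions")
  expect_error(build_column(8, 0.8, 1800, n_per_layer = 3), ">= 5")
  # symmetric about mid-height: layers and osmotic field mirror
  expect_equal(col$pi_field, rev(col$pi_field), tolerance = 1e-12)
  expect_equal(col$H_A, rev(col$H_A), tolerance = 1e-12)
  # osmotic field: plateau in NP, linear ramp to zero across the CEP
  expect_equal(max(col$pi_field), 0.15)
  expect_equal(col$pi_field[1], 0)
})

test_that("zero load and zero osmotic gradient leave the column unchanged", {
  col <- build_column(delta_pi = 0)
  res <- solve_consolidation(col, 0, duration = 1000, dt = 10)
  final <- res$states[[length(res$states)]]
  expect_lt(max(abs(final$p)), 1e-12)
  expect_lt(max(abs(final$u)), 1e-12)
  expect_equal(intradiscal_pressure(final, col), 0)
})

test_that("linear constant-permeability column matches the consolidation series", {
  # uniform material so the closed-form applies; small load keeps the
  # problem linear
  col <- build_column(np_height = 4, cep_height = 2.8, area = 100,
                      np_params = np, cep_params = np, delta_pi = 0,
                      n_per_layer = 31, constant_permeability = TRUE)
  cv <- np$k0 * np$H_A
  Hd <- col$H / 2
  F <- 5                                   # 0.05 MPa, ~6% strain drained
  Tv <- c(0.05, 0.1, 0.2, 0.5, 1)
  times <- Tv * Hd^2 / cv
  res <- solve_consolidation(col, F, duration = max(times),
                             dt = times[1] / 200, dt_max = 1e5,
                             growth = 1.05, record_times = times)
  p0 <- F / col$area
  num <- sapply(times, function(tt) {
    i <- which.min(abs(res$summary$time - tt))
    res$states[[i]]$p
  })
  ana <- sapply(times, function(tt) terzaghi_pressure(col$z, tt, col$H, cv, p0))
  expect_lt(sqrt(sum((num - ana)^2) / sum(ana^2)), 0.01)
})

test_that("instantaneous response to a step load is undrained (p ~ F/A)", {
  col <- build_column(np_height = 4, cep_height = 2.8, area = 100,
                      np_params = np, cep_params = np, delta_pi = 0,
                      n_per_layer = 21, constant_permeability = TRUE)
  st <- column_step(col, column_state(col), dt = 1, force = 5)
  expect_equal(intradiscal_pressure(st, col), 5 / col$area, tolerance = 0.01)
})

test_that("NP pressure relaxes monotonically under a constant load", {
  col <- build_column(np_height = 4, cep_height = 2.8, area = 100,
                      np_params = np, cep_params = np, delta_pi = 0,
                      n_per_layer = 21, constant_permeability = TRUE)
  res <- solve_consolidation(col, 5, duration = 2e5, dt = 50,
                             dt_max = 2e4, growth = 1.2)
  idp <- res$summary$idp
  # after the initial (undrained) step the excess pressure decays
  # without oscillation
  expect_true(all(diff(idp[-1]) < 1e-12))
})

test_that("overnight free swelling raises the NP pressure toward the gradient", {
  col <- build_column()                    # defaults: 8/0.8 mm, 0.15 MPa
  res <- solve_consolidation(col, 0, duration = 8 * 3600,
                             dt = 1, dt_max = 600, growth = 1.2)
  idp <- res$summary$idp
  final <- idp[length(idp)]
  expect_gt(final, 0.11)
  expect_lte(final, 0.15)                  # cannot exceed the driving gradient
  # monotone rise once the endplate/nucleus interface layer has spread
  # over more than one element of the default mesh (~1 h; with finer
  # meshes the early dip disappears, see the vignette)
  late <- idp[res$summary$time > 3600]
  expect_true(all(diff(late) > -1e-12))
  # swelling lengthens the column
  expect_gt(res$summary$top_disp[length(idp)], 0)
})

test_that("halving the node spacing changes the 8-h NP pressure by < 1%", {
  run8 <- function(npl) {
    col <- build_column(n_per_layer = npl)
    res <- solve_consolidation(col, 0, duration = 8 * 3600,
                               dt = 1, dt_max = 600, growth = 1.2)
    res$summary$idp[nrow(res$summary)]
  }
  expect_equal(run8(7), run8(13), tolerance = 0.01)
})

test_that("doubling the osmotic gradient doubles the pressure rise in the linear regime", {
  rise <- function(dpi) {
    col <- build_column(delta_pi = dpi, constant_permeability = TRUE)
    res <- solve_consolidation(col, 0, duration = 2 * 3600,
                               dt = 1, dt_max = 600, growth = 1.2)
    res$summary$idp[nrow(res$summary)]
  }
  expect_equal(rise(0.02), 2 * rise(0.01), tolerance = 0.05)
})

test_that("axial tangent stiffness: drained limit, positivity, poroelastic ordering", {
  col <- build_column(np_height = 4, cep_height = 2.8, area = 100,
                      np_params = np, cep_params = np, delta_pi = 0,
                      n_per_layer = 11, constant_permeability = TRUE)
  st <- column_state(col)
  k_drained <- axial_tangent_stiffness(st, col, dt = 1e9)
  expect_equal(k_drained, np$H_A * col$area / col$H, tolerance = 0.02)
  k_undrained <- axial_tangent_stiffness(st, col, dt = 0.5)
  expect_gt(k_drained, 0)
  expect_gt(k_undrained, k_drained)
})

test_that("column solver reports non-convergence diagnostics on breakdown", {
  col <- build_column()
  st <- column_state(col)
  # a grossly over-compressed prescribed displacement annihilates the
  # void space -> diagnostic error
  expect_error(column_step(col, st, dt = 1, disp = -9), "void ratio")
})
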