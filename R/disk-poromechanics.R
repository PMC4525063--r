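# One-dimensional axial osmo-poroelastic disk column.
#
# The disk is reduced to a layered axial column (cartilage endplate -
# nucleus pulposus - cartilage endplate) of biphasic tissue: a linear
# poroelastic solid skeleton (confined compression, aggregate modulus
# K + 4G/3) saturated with incompressible fluid.  Fluid flow follows
# Darcy's law driven by the gradient of (p - pi), where p is the fluid
# pressure and pi a fixed osmotic pressure field (Delta-pi in the NP,
# zero at the drained outer boundaries, linear ramp across the
# endplates).  At equilibrium under zero load, p relaxes to pi: the
# column swells.  Permeability is strain dependent through the void
# ratio.  Space: linear finite elements; time: backward Euler with a
# per-step fixed-point (Picard) update of the permeability.
#
# Sign conventions: z runs from the caudal (0) to the cranial (H) face;
# axial stress and the reported reaction force are tension-positive;
# applied loads in force mode are compression-positive (a weight).
# Units: N - mm - MPa - s; permeability mm^4/(N s) = mm^2/(MPa s).

#' Disk tissue parameter set
#'
#' Returns the poroelastic parameters of one disk subtissue (annulus
#' fibrosus AF, nucleus pulposus NP, or cartilage endplate CEP) from the
#' packaged disk parameter table, or a custom set.
#'
#' @param tissue `"AF"`, `"NP"` or `"CEP"`.
#' @param G,K Shear and (drained) bulk modulus (MPa); defaults from the
#'   packaged table.
#' @param e0 Initial void ratio (fluid volume / solid volume).
#' @param k0 Initial permeability (mm^4/(N s)).
#' @param M Dimensionless exponent of the strain-dependent permeability.
#' @return Object of class `disk_tissue_params`.
#' @export
disk_tissue_params <- function(tissue = c("NP", "CEP", "AF"),
                               G = NULL, K = NULL, e0 = NULL, k0 = NULL,
                               M = NULL) {
  tissue <- match.arg(tissue)
  path <- system.file("extdata", "disk_materials.csv", package = "spinewell",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  row <- tab[tab$tissue == tissue, ]
  p <- list(tissue = tissue,
            G = if (is.null(G)) row$G else G,
            K = if (is.null(K)) row$K else K,
            e0 = if (is.null(e0)) row$e0 else e0,
            k0 = if (is.null(k0)) row$k0 else k0,
            M = if (is.null(M)) row$M else M)
  if (any(unlist(p[c("G", "K", "e0", "k0")]) <= 0)) {
    stop("disk tissue parameters must be positive")
  }
  p$H_A <- p$K + 4 * p$G / 3             # confined-compression aggregate modulus
  structure(p, class = "disk_tissue_params")
}

#' Strain-dependent permeability
#'
#' `k = k0 * (e (1 + e0) / (e0 (1 + e)))^2 * exp(M ((1 + e)/(1 + e0) - 1))`.
#' Normalized so that `k(e0) = k0` exactly; strictly increasing in the
#' void ratio and vanishing as `e -> 0`.
#'
#' @param e Current void ratio (> 0); vectorized.
#' @param params A [disk_tissue_params()].
#' @return Permeability (mm^4/(N s)).
#' @export
permeability <- function(e, params) {
  if (any(!is.finite(e)) || any(e <= 0)) stop("void ratio must be > 0")
  e0 <- params$e0
  params$k0 * (e * (1 + e0) / (e0 * (1 + e)))^2 *
    exp(params$M * ((1 + e) / (1 + e0) - 1))
}

#' Build a layered CEP-NP-CEP disk column
#'
#' @param np_height Nucleus pulposus layer height (mm).
#' @param cep_height Height of each cartilage endplate layer (mm).
#' @param area Effective cross-sectional area (mm^2).
#' @param np_params,cep_params Tissue parameter sets
#'   ([disk_tissue_params()]).
#' @param delta_pi Osmotic pressure gradient between NP and the outer
#'   boundaries (MPa).
#' @param n_per_layer Nodes per layer (>= 5).
#' @param constant_permeability If `TRUE`, freeze the permeability of
#'   every element at its initial value (used for linear verification
#'   against the closed-form consolidation solution).
#' @return Object of class `disk_column`.
#' @export
build_column <- function(np_height = 8, cep_height = 0.8, area = 1800,
                         np_params = disk_tissue_params("NP"),
                         cep_params = disk_tissue_params("CEP"),
                         delta_pi = 0.15,
                         n_per_layer = 7,
                         constant_permeability = FALSE) {
  if (np_height <= 0 || cep_height <= 0 || area <= 0) {
    stop("non-physical column dimensions")
  }
  if (n_per_layer < 5) stop("grid resolution must be >= 5 nodes per layer")
  z_bot <- seq(0, cep_height, length.out = n_per_layer)
  z_np <- seq(cep_height, cep_height + np_height, length.out = n_per_layer)
  z_top <- seq(cep_height + np_height, np_height + 2 * cep_height,
               length.out = n_per_layer)
  z <- unique(c(z_bot, z_np, z_top))
  H <- np_height + 2 * cep_height
  nel <- length(z) - 1L
  zmid <- (z[-1] + z[-length(z)]) / 2
  layer <- ifelse(zmid < cep_height, "CEP",
                  ifelse(zmid <= cep_height + np_height, "NP", "CEP"))
  tis <- list(NP = np_params, CEP = cep_params)
  pi_field <- ifelse(z <= cep_height, delta_pi * z / cep_height,
                     ifelse(z <= cep_height + np_height, delta_pi,
                            delta_pi * (H - z) / cep_height))
  structure(
    list(z = z, H = H, area = area, layer = layer,
         np_height = np_height, cep_height = cep_height,
         tissues = tis, delta_pi = delta_pi, pi_field = pi_field,
         H_A = vapply(layer, function(l) tis[[l]]$H_A, numeric(1)),
         e0 = vapply(layer, function(l) tis[[l]]$e0, numeric(1)),
         k_init = vapply(layer, function(l) tis[[l]]$k0, numeric(1)),
         constant_permeability = constant_permeability,
         n_nodes = length(z), n_el = nel),
    class = "disk_column"
  )
}

#' Initial (reference) state of a disk column
#'
#' Zero displacement, zero fluid pressure, initial void ratios.
#'
#' @param column A [build_column()].
#' @return Object of class `column_state`.
#' @export
column_state <- function(column) {
  structure(
    list(time = 0,
         u = numeric(column$n_nodes),
         p = numeric(column$n_nodes),
         e = column$e0,
         reaction = 0,
         applied_force = 0),
    class = "column_state"
  )
}

# Element permeabilities for a given nodal displacement field.
.column_perm <- function(column, u) {
  if (column$constant_permeability) return(column$k_init)
  h <- diff(column$z)
  strain <- diff(u) / h
  e <- column$e0 + (1 + column$e0) * strain
  if (any(e <= 0)) stop("void ratio became non-positive")
  k <- numeric(column$n_el)
  for (l in unique(column$layer)) {
    sel <- column$layer == l
    k[sel] <- permeability(e[sel], column$tissues[[l]])
  }
  k
}

# One backward-Euler step of the coupled displacement / pressure system.
# Exactly one of `force` (applied axial load, N, compression positive)
# or `disp` (prescribed top displacement, mm, elongation positive) must
# be given.  Returns the new column_state; `reaction` is the axial force
# carried by the column (N, tension positive).
#' Advance a disk column by one implicit time step
#'
#' Low-level integrator used by [solve_consolidation()] and by the
#' coupled simulator.  See the package vignette for the discretization.
#'
#' @param column A [build_column()].
#' @param state Current [column_state()].
#' @param dt Time step (s, > 0).
#' @param force Applied axial load (N, compression positive), or `NULL`.
#' @param disp Prescribed top displacement (mm, elongation positive), or
#'   `NULL`.
#' @param max_iter,tol Fixed-point iteration controls for the
#'   permeability update (residual tolerance on the coupled system).
#' @param pi_scale Scale factor on the osmotic pressure field (1 = the
#'   column's `delta_pi` is active, 0 = no osmotic driving, i.e. the
#'   column starts in Darcy equilibrium with its surroundings).
#' @return New `column_state`.
#' @export
column_step <- function(column, state, dt, force = NULL, disp = NULL,
                        max_iter = 60, tol = 1e-10, pi_scale = 1) {
  stopifnot(inherits(column, "disk_column"), inherits(state, "column_state"))
  if (dt <= 0) stop("dt must be > 0")
  if (is.null(force) == is.null(disp)) {
    stop("give exactly one of force or disp")
  }
  n <- column$n_nodes
  h <- diff(column$z)
  HA <- column$H_A
  piv <- column$pi_field * pi_scale
  u_old <- state$u

  # constant element matrices
  idx <- cbind(seq_len(column$n_el), seq_len(column$n_el) + 1L)
  assemble_lap <- function(coefs) {
    Km <- matrix(0, n, n)
    for (e in seq_len(column$n_el)) {
      i <- idx[e, 1]; j <- idx[e, 2]
      c_e <- coefs[e] / h[e]
      Km[i, i] <- Km[i, i] + c_e; Km[j, j] <- Km[j, j] + c_e
      Km[i, j] <- Km[i, j] - c_e; Km[j, i] <- Km[j, i] - c_e
    }
    Km
  }
  Ku <- assemble_lap(HA)
  Q <- matrix(0, n, n)                    # Q[i,j] = int phi_i' phi_j
  for (e in seq_len(column$n_el)) {
    i <- idx[e, 1]; j <- idx[e, 2]
    Q[i, i] <- Q[i, i] - 0.5; Q[i, j] <- Q[i, j] - 0.5
    Q[j, i] <- Q[j, i] + 0.5; Q[j, j] <- Q[j, j] + 0.5
  }

  sigma_applied <- if (!is.null(force)) -force / column$area else NA_real_

  u <- state$u
  p <- state$p
  x <- c(u, p)
  iu <- seq_len(n); ip <- n + seq_len(n)

  for (iter in seq_len(max_iter)) {
    k_el <- .column_perm(column, u)
    Kp <- assemble_lap(k_el)
    A <- matrix(0, 2 * n, 2 * n)
    A[iu, iu] <- Ku
    A[iu, ip] <- -Q
    A[ip, iu] <- t(Q) / dt
    A[ip, ip] <- Kp
    b <- numeric(2 * n)
    if (!is.null(force)) b[n] <- sigma_applied
    b[ip] <- drop(t(Q) %*% u_old) / dt + drop(Kp %*% piv)

    # Dirichlet rows: u(0) = 0; p = 0 at both drained faces; top disp
    fix <- function(row, val) {
      A[row, ] <<- 0; A[row, row] <<- 1; b[row] <<- val
    }
    fix(1L, 0)
    fix(n + 1L, 0)
    fix(2L * n, 0)
    if (!is.null(disp)) fix(n, disp)

    x_new <- solve(A, b)
    du <- max(abs(x_new - x))
    x <- x_new
    u <- x[iu]; p <- x[ip]
    # residual of the nonlinear system with permeability re-evaluated
    k_chk <- .column_perm(column, u)
    Kp_chk <- assemble_lap(k_chk)
    r_p <- drop(t(Q) %*% (u - u_old)) / dt + drop(Kp_chk %*% (p - piv))
    r_p[c(1L, n)] <- 0
    res <- max(abs(r_p))
    if (res < tol && du < 1e-9 * (1 + max(abs(x)))) break
    if (iter == max_iter) {
      stop(sprintf(
        "consolidation step did not converge (t = %g s, residual = %g)",
        state$time + dt, res))
    }
  }

  strain <- diff(u) / h
  e_new <- column$e0 + (1 + column$e0) * strain
  sigma_top <- drop(Ku %*% u - Q %*% p)[n]
  structure(
    list(time = state$time + dt, u = u, p = p, e = e_new,
         reaction = sigma_top * column$area,
         applied_force = if (!is.null(force)) force else -sigma_top * column$area),
    class = "column_state"
  )
}

#' Consolidation / swelling history of a disk column
#'
#' Integrates the coupled displacement/pressure system under a
#' prescribed axial load history with backward Euler and an adaptive
#' step (geometric growth, capped), recording the state at every step.
#'
#' @param column A [build_column()].
#' @param load_history Function of time returning the applied axial load
#'   (N, compression positive); or a single number for a constant load.
#' @param duration Total simulated time (s).
#' @param dt Initial time step (s).
#' @param dt_max Maximum time step (s).
#' @param growth Step growth factor per accepted step.
#' @param record_times Optional times (s) that must coincide with step
#'   ends (steps are clipped), e.g. for comparison against analytic
#'   solutions.
#' @param state Optional starting [column_state()] (defaults to the
#'   reference state).
#' @return Object of class `consolidation_result`: list with the column,
#'   all recorded states, and a summary data frame (time, NP-center
#'   intradiscal pressure, top displacement, reaction force).
#' @export
solve_consolidation <- function(column, load_history = 0, duration,
                                dt = 1, dt_max = 600, growth = 1.2,
                                record_times = NULL, state = NULL) {
  if (dt <= 0) stop("dt must be > 0")
  fload <- if (is.function(load_history)) load_history else function(t) load_history
  st <- if (is.null(state)) column_state(column) else state
  t0 <- st$time
  states <- list(st)
  targets <- sort(unique(c(record_times, t0 + duration)))
  targets <- targets[targets > t0 + 1e-12]
  step <- dt
  tcur <- t0
  while (tcur < t0 + duration - 1e-9) {
    tnext <- min(tcur + step, targets[targets > tcur + 1e-12][1])
    st <- column_step(column, st, tnext - tcur, force = fload(tnext))
    states[[length(states) + 1L]] <- st
    tcur <- tnext
    step <- min(step * growth, dt_max)
  }
  summary <- data.frame(
    time = vapply(states, `[[`, numeric(1), "time"),
    idp = vapply(states, function(s) intradiscal_pressure(s, column),
                 numeric(1)),
    top_disp = vapply(states, function(s) s$u[column$n_nodes], numeric(1)),
    reaction = vapply(states, `[[`, numeric(1), "reaction")
  )
  structure(list(column = column, states = states, summary = summary),
            class = "consolidation_result")
}

#' Intradiscal pressure at the nucleus pulposus center
#'
#' Fluid pressure at the NP mid-height.  The solver's pressure variable
#' is the total fluid pressure (its zero-load equilibrium value equals
#' the osmotic field), so no separate osmotic term is added.
#'
#' @param state A [column_state()].
#' @param column The corresponding [build_column()].
#' @return Pressure (MPa).
#' @export
intradiscal_pressure <- function(state, column) {
  z_mid <- column$cep_height + column$np_height / 2
  stats::approx(column$z, state$p, xout = z_mid)$y
}

#' Axial tangent stiffness of a disk column
#'
#' Finite-difference derivative of the reaction force with respect to an
#' imposed top displacement over one implicit step of length `dt`.
#' Small `dt` probes the (stiff) undrained response, large `dt` the
#' drained elastic response.
#'
#' @param state Current [column_state()].
#' @param column A [build_column()].
#' @param dt Probing time step (s).
#' @param delta Displacement perturbation (mm).
#' @return Stiffness (N/mm, positive).
#' @export
axial_tangent_stiffness <- function(state, column, dt = 1, delta = 1e-4) {
  d0 <- state$u[column$n_nodes]
  r <- function(d) column_step(column, state, dt, disp = d)$reaction
  (r(d0 + delta) - r(d0 - delta)) / (2 * delta)
}
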