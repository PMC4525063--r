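# Quasi-static scenario engine for the L3-S1 segment.
#
# Rigid vertebrae L3, L4, L5 move in the sagittal plane (3 DOF each:
# anteroposterior translation ux, axial translation uz, sagittal
# rotation theta; flexion positive); S1, the sacral/iliac and femoral
# muscle insertions are fixed.  The thoracic rod node follows the axial
# translation of L3 (axial alignment of L3 and the rod is preserved).
# Each disk level is a 1D osmo-poroelastic column loaded by the relative
# axial displacement of the adjacent bodies; ligaments and facets are
# lumped into per-level rotational and shear springs.  Muscle fascicles
# are straight uniaxial elements of the active hyperelastic law
# (laterally confined contract by default, see the vignette).
#
# Time marching is staggered: at every global step the disk columns are
# advanced one backward-Euler increment inside a Newton solve of the
# sagittal equilibrium of the three vertebrae.

.BODIES <- c("L3", "L4", "L5")
.LEVELS <- c("L3/L4", "L4/L5", "L5/S1")

#' Assemble the coupled spine model
#'
#' @param geometry A [lumbar_geometry()] config.
#' @param network Optional pre-built [build_network()] (defaults to the
#'   network of `geometry`).
#' @param materials Named list of [muscle_material()] per group
#'   (defaults to [muscle_materials()]).
#' @param body_mass Total body mass (kg) for the standing load set.
#' @param g Gravitational acceleration (m/s^2).
#' @param disk Named list of arguments passed to [build_column()] for
#'   the three disk levels (all levels share the same column layout).
#' @param k_rot Lumped sagittal rotational stiffness per level
#'   (N mm/rad).  The default is a deliberately stiff calibration that
#'   lumps disk annulus, facets and ligaments so that standing rotations
#'   stay far below one degree; it is a calibration, not a prediction
#'   (see the vignette).
#' @param k_shear Lumped anteroposterior shear stiffness per level
#'   (N/mm).
#' @param muscles Include the muscle elements (`TRUE`) or run the
#'   osteoligamentous structure alone (`FALSE`).
#' @param lateral Lateral contract of the fascicle elements,
#'   `"confined"` (default; volumetric matrix stiffness participates) or
#'   `"free"` (isochoric).
#' @return Object of class `spine_model`.
#' @export
spine_model <- function(geometry = lumbar_geometry(),
                        network = build_network(geometry),
                        materials = muscle_materials(),
                        body_mass = 70.8,
                        g = 9.81,
                        disk = list(),
                        k_rot = 5e7,
                        k_shear = 2000,
                        muscles = TRUE,
                        lateral = c("confined", "free")) {
  lateral <- match.arg(lateral)
  stopifnot(inherits(geometry, "geometry_config"),
            inherits(network, "fascicle_network"))
  miss <- setdiff(unique(network$group), names(materials))
  if (length(miss)) stop("missing materials for groups: ",
                         paste(miss, collapse = ", "))
  columns <- lapply(.LEVELS, function(l) do.call(build_column, disk))
  names(columns) <- .LEVELS

  loads <- distribute_gravity_loads(body_mass, g = g)

  # precomputed per-fascicle arrays for fast force evaluation
  nf <- nrow(network)
  body_code <- function(b) {
    ifelse(b %in% .BODIES, match(b, .BODIES), ifelse(b == "rod", 4L, 0L))
  }
  par_of <- function(field) {
    vapply(network$group, function(gp) materials[[gp]][[field]], numeric(1))
  }
  cr_ref <- as.matrix(network[, c("cr_x", "cr_y", "cr_z")])
  ca_ref <- as.matrix(network[, c("ca_x", "ca_y", "ca_z")])
  zmid <- vapply(.LEVELS, function(l) {
    bodies <- switch(l, "L3/L4" = c("L3", "L4"), "L4/L5" = c("L4", "L5"),
                     "L5/S1" = c("L5", "S1"))
    mean(geometry$centers[bodies, "z"])
  }, numeric(1))
  crossing <- sapply(seq_along(.LEVELS), function(j) {
    pmin(cr_ref[, 3], ca_ref[, 3]) < zmid[j] &
      pmax(cr_ref[, 3], ca_ref[, 3]) > zmid[j]
  })
  attach_lv <- sapply(.BODIES, function(b) {
    network$cranial_body == b | network$caudal_body == b
  })

  structure(
    list(geometry = geometry, network = network, materials = materials,
         columns = columns, loads = loads, body_mass = body_mass, g = g,
         k_rot = k_rot, k_shear = k_shear, muscles = muscles,
         lateral = lateral,
         fas = list(cr_ref = cr_ref, ca_ref = ca_ref,
                    cr_body = body_code(network$cranial_body),
                    ca_body = body_code(network$caudal_body),
                    L0 = network$L0, csa = network$csa,
                    G = par_of("G"), K = par_of("K"),
                    sigma0 = par_of("sigma0"), A = par_of("A"),
                    c1 = par_of("c_ce1"), c2 = par_of("c_ce2"),
                    crossing = crossing, attach = attach_lv)),
    class = "spine_model"
  )
}

#' Reference state of a spine model
#'
#' @param model A [spine_model()].
#' @return Object of class `spine_state`: time, the 9 generalized
#'   coordinates (ux, uz, theta for L3, L4, L5), and the three disk
#'   column states.
#' @export
spine_state <- function(model) {
  structure(
    list(time = 0, q = numeric(9),
         disks = lapply(model$columns, column_state)),
    class = "spine_state"
  )
}

# Vectorized uniaxial fascicle response.  Returns total axial force (N,
# tension positive) and its parts for stretch lambda (vector) given the
# per-fascicle parameter arrays in model$fas.
.fascicle_forces_vec <- function(fas, lambda, lateral) {
  eps <- lambda - 1
  if (any(eps <= -1)) stop("invalid strain: fascicle annihilated")
  zeta <- ifelse(eps < 0, fas$c1 * eps, fas$c2 * eps)
  if (lateral == "free") {
    lfb <- lambda
    area <- fas$csa / lambda
    s_mat <- fas$G * (lambda^2 - 1 / lambda)
  } else {
    J <- lambda
    lfb <- lambda^(2 / 3)
    area <- fas$csa
    i1b <- J^(-2 / 3) * (2 + lambda^2)
    s_iso <- fas$G / J * (lambda^(4 / 3) - i1b / 3)
    s_vol <- fas$K * log(J) / J
    s_mat <- s_iso + s_vol
  }
  f_pe <- ifelse(lfb > 1, fas$A * (lfb - 1)^2, 0)
  f_se <- ifelse(lfb > 1 + zeta, 0.1 * (exp(100 * (lfb - 1 - zeta)) - 1), 0)
  fib_scale <- if (lateral == "free") 1 else (2 / 3) * lfb / lambda
  s_pe <- fas$sigma0 * f_pe * fib_scale
  s_se <- fas$sigma0 * f_se * fib_scale
  list(total = (s_mat + s_pe + s_se) * area,
       matrix = s_mat * area, passive = s_pe * area, active = s_se * area,
       eps = eps, zeta = zeta)
}

# Current endpoint positions for generalized coordinates q
# (q = ux,uz,th per body, bodies L3,L4,L5).  pts: n x 3 reference
# coordinates; codes: 0 fixed, 1..3 mobile body, 4 rod (z slaved to L3).
.current_points <- function(model, pts, codes, q) {
  out <- pts
  ctr <- model$geometry$centers
  for (b in 1:3) {
    sel <- codes == b
    if (!any(sel)) next
    th <- q[3 * b]; ux <- q[3 * b - 2]; uz <- q[3 * b - 1]
    c0 <- ctr[.BODIES[b], ]
    R <- .rot_y(th)
    loc <- sweep(pts[sel, , drop = FALSE], 2, c0)
    out[sel, ] <- sweep(loc %*% t(R), 2, c0 + c(ux, 0, uz), "+")
  }
  sel <- codes == 4L
  if (any(sel)) out[sel, 3] <- pts[sel, 3] + q[2]   # rod follows L3 axially
  out
}

# Full force evaluation at coordinates q.  Returns the 9-residual plus
# the per-fascicle diagnostics and trial disk states for dt.
.spine_forces <- function(model, state, q, dt, ramp, muscles = model$muscles,
                          pi_scale = 1) {
  fas <- model$fas
  ctr <- model$geometry$centers
  res <- numeric(9)

  # current vertebral centers
  cpos <- lapply(1:3, function(b) {
    ctr[.BODIES[b], ] + c(q[3 * b - 2], 0, q[3 * b - 1])
  })

  # gravity loads (ramped), applied at the eccentric point of each level
  for (j in seq_len(nrow(model$loads))) {
    b <- j                                  # L3/L4 -> L3, etc.
    W <- ramp * model$loads$magnitude[j]
    ecc <- model$loads$eccentricity[j]
    r <- drop(.rot_y(q[3 * b]) %*% c(ecc, 0, 0))
    res[3 * b - 1] <- res[3 * b - 1] - W        # Fz
    res[3 * b] <- res[3 * b] + r[1] * W         # My (flexion +)
  }

  # disk columns: axial elongation = relative axial displacement
  trial <- vector("list", 3)
  for (j in 1:3) {
    uz_up <- q[3 * j - 1]
    uz_low <- if (j < 3) q[3 * (j + 1) - 1] else 0
    d <- uz_up - uz_low
    trial[[j]] <- column_step(model$columns[[j]], state$disks[[j]], dt,
                              disp = d, pi_scale = pi_scale)
    R <- trial[[j]]$reaction
    res[3 * j - 1] <- res[3 * j - 1] - R        # tension pulls upper down
    if (j < 3) res[3 * (j + 1) - 1] <- res[3 * (j + 1) - 1] + R
  }

  # lumped rotational + shear springs per level
  for (j in 1:3) {
    up <- j; low <- j + 1
    dth <- q[3 * up] - if (j < 3) q[3 * low] else 0
    dux <- q[3 * up - 2] - if (j < 3) q[3 * low - 2] else 0
    res[3 * up] <- res[3 * up] - model$k_rot * dth
    res[3 * up - 2] <- res[3 * up - 2] - model$k_shear * dux
    if (j < 3) {
      res[3 * low] <- res[3 * low] + model$k_rot * dth
      res[3 * low - 2] <- res[3 * low - 2] + model$k_shear * dux
    }
  }

  # muscle fascicles
  mus <- NULL
  if (muscles) {
    cr <- .current_points(model, fas$cr_ref, fas$cr_body, q)
    ca <- .current_points(model, fas$ca_ref, fas$ca_body, q)
    dvec <- cr - ca
    L <- sqrt(rowSums(dvec^2))
    lambda <- L / fas$L0
    mus <- .fascicle_forces_vec(fas, lambda, model$lateral)
    u <- dvec / L
    Fcr <- -mus$total * u                     # force on cranial endpoint
    Fca <- mus$total * u
    add_point_force <- function(b, P, Fv) {
      if (b %in% 1:3) {
        res[3 * b - 2] <<- res[3 * b - 2] + Fv[1]
        rr <- P - cpos[[b]]
        res[3 * b - 1] <<- res[3 * b - 1] + Fv[3]
        res[3 * b] <<- res[3 * b] + (rr[3] * Fv[1] - rr[1] * Fv[3])
      } else if (b == 4L) {
        res[2] <<- res[2] + Fv[3]             # rod z force goes to L3
      }
    }
    for (i in seq_along(L)) {
      add_point_force(fas$cr_body[i], cr[i, ], Fcr[i, ])
      add_point_force(fas$ca_body[i], ca[i, ], Fca[i, ])
    }
    mus$u <- u
    mus$Fcr <- Fcr
  }

  list(res = res, trial = trial, mus = mus)
}

#' One quasi-static step of the coupled model
#'
#' Newton solve of the sagittal equilibrium of the three free vertebrae
#' (gravity, disk reactions, lumped passive springs, muscle forces) with
#' the disk columns advanced one backward-Euler increment of length
#' `dt`.
#'
#' @param model A [spine_model()].
#' @param state Current [spine_state()].
#' @param dt Time step (s).
#' @param ramp Load ramp factor in `[0, 1]` multiplying the gravity load
#'   set.
#' @param muscles Override the model's muscle flag for this step.
#' @param pi_scale Osmotic activation of the disk columns (1 in the
#'   rest and rest-then-standing scenarios, 0 in standing alone, where
#'   the disks start in Darcy equilibrium with their surroundings).
#' @param max_iter Newton iteration cap.
#' @param tol Relative residual tolerance.
#' @return Converged `spine_state` with diagnostics attached
#'   (`attr(, "forces")`).
#' @export
solve_quasi_static_step <- function(model, state, dt, ramp = 0,
                                    muscles = model$muscles, pi_scale = 1,
                                    max_iter = 40, tol = 1e-8) {
  q <- state$q
  scale_f <- max(1, sum(model$loads$magnitude))
  scl <- rep(c(scale_f, scale_f, scale_f * 100), 3)  # moments in N mm
  ev <- .spine_forces(model, state, q, dt, ramp, muscles, pi_scale)
  for (iter in seq_len(max_iter)) {
    rn <- max(abs(ev$res / scl))
    if (rn < tol) break
    # forward-difference Jacobian
    J <- matrix(0, 9, 9)
    for (k in 1:9) {
      h <- 1e-7 * max(1, abs(q[k]))
      qk <- q; qk[k] <- qk[k] + h
      evk <- .spine_forces(model, state, qk, dt, ramp, muscles, pi_scale)
      J[, k] <- (evk$res - ev$res) / h
    }
    dq <- tryCatch(solve(J, -ev$res), error = function(e) {
      stop("quasi-static step: singular Jacobian at t = ", state$time + dt)
    })
    # damped update
    step_ok <- FALSE
    for (damp in c(1, 0.5, 0.25, 0.1)) {
      qn <- q + damp * dq
      evn <- tryCatch(.spine_forces(model, state, qn, dt, ramp, muscles,
                                    pi_scale),
                      error = function(e) NULL)
      if (!is.null(evn) &&
          (max(abs(evn$res / scl)) < rn || damp == 0.1)) {
        q <- qn; ev <- evn; step_ok <- TRUE; break
      }
    }
    if (!step_ok || iter == max_iter) {
      if (max(abs(ev$res / scl)) >= tol && iter == max_iter) {
        stop(sprintf(
          "quasi-static solve did not converge (t = %g s, residual = %g)",
          state$time + dt, max(abs(ev$res / scl))))
      }
    }
  }
  new_state <- structure(
    list(time = state$time + dt, q = q, disks = ev$trial),
    class = "spine_state"
  )
  names(new_state$disks) <- .LEVELS
  attr(new_state, "forces") <- ev
  new_state
}

# Record one converged step into the scenario accumulator.
.record_step <- function(acc, model, st) {
  ev <- attr(st, "forces")
  n <- length(acc$time) + 1L
  acc$time[n] <- st$time
  acc$q[n, ] <- st$q
  acc$idp[n, ] <- vapply(1:3, function(j) {
    intradiscal_pressure(st$disks[[j]], model$columns[[j]])
  }, numeric(1))
  if (!is.null(ev$mus)) {
    acc$eps[n, ] <- ev$mus$eps
    acc$zeta[n, ] <- ev$mus$zeta
    acc$f_total[n, ] <- ev$mus$total
    acc$f_active[n, ] <- ev$mus$active
    acc$f_passive[n, ] <- ev$mus$passive
    acc$f_matrix[n, ] <- ev$mus$matrix
    # per-level resultants: vector sum over attached fascicles (force
    # exerted on the attached vertebra through whichever end attaches)
    # and over fascicles crossing the disk plane (axial force vector
    # along the line of action)
    for (j in 1:3) {
      on_cr <- model$fas$cr_body == j
      on_ca <- model$fas$ca_body == j
      Fv <- rbind(ev$mus$Fcr[on_cr, , drop = FALSE],
                  -ev$mus$Fcr[on_ca, , drop = FALSE])
      acc$level_attach[n, j] <- sqrt(sum(colSums(Fv)^2))
      sel_c <- model$fas$crossing[, j]
      Tv <- ev$mus$total[sel_c] * ev$mus$u[sel_c, , drop = FALSE]
      acc$level_cross[n, j] <- sqrt(sum(colSums(Tv)^2))
    }
  }
  acc
}

.new_acc <- function(model, n_max) {
  nf <- nrow(model$network)
  z3 <- matrix(NA_real_, n_max, 3, dimnames = list(NULL, .LEVELS))
  zf <- matrix(NA_real_, n_max, nf)
  list(time = numeric(0), q = matrix(NA_real_, n_max, 9),
       idp = z3, eps = zf, zeta = zf, f_total = zf, f_active = zf,
       f_passive = zf, f_matrix = zf,
       level_attach = z3, level_cross = z3)
}

.finish_result <- function(acc, model, scenario, final_state) {
  n <- length(acc$time)
  trim <- function(m) m[seq_len(n), , drop = FALSE]
  structure(
    list(scenario = scenario, time = acc$time,
         q = trim(acc$q), idp = trim(acc$idp),
         eps = trim(acc$eps), zeta = trim(acc$zeta),
         f_total = trim(acc$f_total), f_active = trim(acc$f_active),
         f_passive = trim(acc$f_passive), f_matrix = trim(acc$f_matrix),
         level_attach = trim(acc$level_attach),
         level_cross = trim(acc$level_cross),
         network = model$network, model = model,
         final_state = final_state),
    class = "scenario_result"
  )
}

#' Overnight rest: free disk swelling
#'
#' Eight hours (by default) of osmotically driven disk swelling with no
#' gravity load.  The swelling distracts the spine axially, stretches
#' the fascicles, and triggers stretch-induced (eccentric) activation.
#'
#' @param model A [spine_model()].
#' @param hours Simulated duration (h).
#' @param dt0,dt_max,growth Adaptive time-step controls (s).
#' @param state Optional initial [spine_state()].
#' @return A `scenario_result`.
#' @export
run_night_rest <- function(model, hours = 8, dt0 = 1, dt_max = 600,
                           growth = 1.2, state = NULL) {
  st <- if (is.null(state)) spine_state(model) else state
  t_end <- st$time + hours * 3600
  acc <- .new_acc(model, 400L)
  dt <- dt0
  while (st$time < t_end - 1e-9) {
    dt_eff <- min(dt, t_end - st$time)
    st <- solve_quasi_static_step(model, st, dt_eff, ramp = 0)
    acc <- .record_step(acc, model, st)
    dt <- min(dt * growth, dt_max)
  }
  .finish_result(acc, model, "night_rest", st)
}

#' Relaxed standing: ramped distributed gravity load
#'
#' Applies the distributed body-weight load set linearly over
#' `ramp_seconds`, optionally starting from the end state of a prior
#' overnight-rest simulation.
#'
#' @param model A [spine_model()].
#' @param ramp_seconds Load ramp duration (s).
#' @param n_steps Number of ramp steps (>= 30 recommended).
#' @param with_prior_rest Run [run_night_rest()] first and continue from
#'   its end state.
#' @param rest_hours Hours of prior rest if enabled.
#' @param muscles Override the model's muscle flag.
#' @return A `scenario_result` (the prior rest result, if any, is
#'   attached as attribute `"rest"`).
#' @export
run_standing <- function(model, ramp_seconds = 60, n_steps = 30,
                         with_prior_rest = FALSE, rest_hours = 8,
                         muscles = model$muscles) {
  rest <- NULL
  st <- spine_state(model)
  if (with_prior_rest) {
    rest <- run_night_rest(model, hours = rest_hours)
    st <- rest$final_state
  }
  t0 <- st$time
  dt <- ramp_seconds / n_steps
  acc <- .new_acc(model, n_steps + 1L)
  pi_scale <- if (with_prior_rest) 1 else 0
  for (i in seq_len(n_steps)) {
    st <- solve_quasi_static_step(model, st, dt,
                                  ramp = i / n_steps, muscles = muscles,
                                  pi_scale = pi_scale)
    acc <- .record_step(acc, model, st)
  }
  out <- .finish_result(acc, model,
                        if (with_prior_rest) "standing_after_rest"
                        else "standing", st)
  attr(out, "rest") <- rest
  out
}

#' Result tables of a scenario
#'
#' Flattens a `scenario_result` into three data frames mirroring the
#' reported outputs: per-fascicle strains/activations/forces at the
#' final time, per-level resultant muscle forces, and the intradiscal
#' pressure time series.
#'
#' @param result A `scenario_result`.
#' @return List of data frames `fascicles`, `levels`, `idp`.
#' @export
scenario_tables <- function(result) {
  stopifnot(inherits(result, "scenario_result"))
  n <- length(result$time)
  net <- result$network
  if (n == 0L) {
    return(list(
      fascicles = data.frame(id = character(), group = character(),
                             side = character(), eps = numeric(),
                             zeta = numeric(), total = numeric(),
                             active = numeric()),
      levels = data.frame(level = character(), resultant = numeric(),
                          crossing = numeric(), idp = numeric()),
      idp = data.frame(time = numeric())
    ))
  }
  fasc <- data.frame(
    id = net$id, group = net$group, side = net$side, level = net$cranial_body,
    eps = result$eps[n, ], zeta = result$zeta[n, ],
    total = result$f_total[n, ], active = result$f_active[n, ],
    passive = result$f_passive[n, ], matrix = result$f_matrix[n, ],
    stringsAsFactors = FALSE
  )
  levels <- data.frame(
    level = .LEVELS,
    resultant = result$level_attach[n, ],
    crossing = result$level_cross[n, ],
    idp = result$idp[n, ],
    stringsAsFactors = FALSE
  )
  idp <- data.frame(time = result$time, result$idp, check.names = FALSE)
  list(fascicles = fasc, levels = levels, idp = idp)
}

#' Compare two scenario results
#'
#' Per-level intradiscal-pressure percentage change and per-group
#' active-force percentage change of scenario `b` relative to `a`
#' (final states).
#'
#' @param a,b `scenario_result` objects with identical model topology.
#' @return List of data frames `idp` and `groups`.
#' @export
compare_scenarios <- function(a, b) {
  stopifnot(inherits(a, "scenario_result"), inherits(b, "scenario_result"))
  if (!identical(a$network$id, b$network$id)) {
    stop("topology mismatch between scenarios")
  }
  na <- length(a$time); nb <- length(b$time)
  ia <- unname(a$idp[na, ]); ib <- unname(b$idp[nb, ])
  idp <- data.frame(
    level = .LEVELS,
    a = ia, b = ib,
    pct_change = 100 * (ib - ia) / ia
  )
  grp <- unique(a$network$group)
  ga <- vapply(grp, function(g) sum(a$f_active[na, a$network$group == g]),
               numeric(1))
  gb <- vapply(grp, function(g) sum(b$f_active[nb, b$network$group == g]),
               numeric(1))
  groups <- data.frame(group = grp, a = ga, b = gb,
                       pct_change = 100 * (gb - ga) / ifelse(ga == 0, NA, ga))
  list(idp = idp, groups = groups)
}

#' @export
print.scenario_result <- function(x, ...) {
  n <- length(x$time)
  cat("scenario_result:", x$scenario, "-", n, "steps,",
      if (n) sprintf("t = %.0f s", x$time[n]) else "", "\n")
  if (n) {
    cat("final IDP (MPa):",
        paste(sprintf("%s %.3f", .LEVELS, x$idp[n, ]), collapse = ", "), "\n")
  }
  invisible(x)
}
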