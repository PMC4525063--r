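# Active, transversely isotropic, hyperelastic muscle law.
#
# The tissue is a fiber-reinforced composite: an isotropic Neo-Hookean
# matrix (deviatoric + volumetric split) plus a one-dimensional fiber
# family following the three-element Hill rheology.  The passive fiber
# branch (PE) is quadratic in the deviatoric fiber stretch; the active
# branch (SE + CE) is exponential and switches on when the deviatoric
# fiber stretch exceeds 1 + zeta, where zeta is the contractile strain
# (a strain-like activation variable, C_CE * epsilon).  No explicit
# neural activation input is needed: activation is driven by stretch.
#
# Unit convention: N - mm - MPa - s.

#' Muscle material parameter set
#'
#' Bundles the constitutive parameters of one back-muscle group: matrix
#' shear and bulk moduli, maximum tetanic stress, the passive fiber
#' constant, and the concentric/eccentric active parameters.
#'
#' @param group_label Group name, one of `"MF"`, `"LTpL"`, `"LTpTh"`,
#'   `"ILpL"`, `"PS"`.
#' @param G Matrix shear modulus (MPa).
#' @param K Matrix bulk modulus (MPa).  Default is `1000 * G`, i.e. a
#'   nearly incompressible matrix.
#' @param sigma0 Maximum tetanic stress (MPa); the stress scale of both
#'   fiber branches.
#' @param A Dimensionless passive fiber constant of the quadratic PE law.
#' @param c_ce1 Concentric active parameter (applies for shortening,
#'   `epsilon < 0`).
#' @param c_ce2 Eccentric active parameter (applies for lengthening,
#'   `epsilon > 0`).
#' @param c_ce_ref Reference (sarcomere-derived) active parameter of the
#'   group; retained so that the constancy of the `c_ce1 / c_ce_ref` and
#'   `c_ce2 / c_ce_ref` scaling across groups can be checked.
#'
#' @return An object of class `muscle_material`.
#' @seealso [muscle_materials()] for the shipped default parameter sets.
#' @export
muscle_material <- function(group_label,
                            G = 16.42e-4,
                            K = 1000 * G,
                            sigma0 = 0.46,
                            A = 4.0,
                            c_ce1 = NULL,
                            c_ce2 = NULL,
                            c_ce_ref = NA_real_) {
  stopifnot(is.character(group_label), length(group_label) == 1L)
  if (!is.numeric(G) || G <= 0) stop("G must be > 0")
  if (!is.numeric(K) || K <= 0) stop("K must be > 0")
  if (sigma0 <= 0) stop("sigma0 must be > 0")
  if (A < 0) stop("A must be >= 0")
  if (is.null(c_ce1) || is.null(c_ce2)) {
    stop("c_ce1 and c_ce2 must be supplied (see muscle_materials() for defaults)")
  }
  if (c_ce1 <= 0 || c_ce2 <= 0) stop("active parameters must be > 0")
  structure(
    list(group_label = group_label, G = G, K = K, sigma0 = sigma0, A = A,
         c_ce1 = c_ce1, c_ce2 = c_ce2, c_ce_ref = c_ce_ref),
    class = "muscle_material"
  )
}

#' Default muscle material sets for the five modeled groups
#'
#' Returns the shipped parameter sets of the multifidus (MF), longissimus
#' thoracis pars lumborum (LTpL) and pars thoracis (LTpTh), iliocostalis
#' lumborum pars lumborum (ILpL), and psoas major (PS).  The matrix and
#' PE parameters are common to all groups; the active parameters are
#' group specific, with concentric values above and eccentric values
#' below the sarcomere-derived reference ratio.  Values are read from the
#' packaged muscle parameter table (`inst/extdata/muscle_materials.csv`).
#'
#' @return Named list of [muscle_material()] objects.
#' @export
muscle_materials <- function() {
  path <- system.file("extdata", "muscle_materials.csv", package = "spinewell",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    muscle_material(group_label = r$group, G = r$G, K = r$K,
                    sigma0 = r$sigma0, A = r$A,
                    c_ce1 = r$c_ce1, c_ce2 = r$c_ce2, c_ce_ref = r$c_ce_ref)
  })
  names(out) <- tab$group
  out
}

#' Fiber kinematics from a deformation gradient
#'
#' Computes the kinematic quantities the constitutive law needs: the
#' Jacobian `J = det F`, the right Cauchy-Green tensor `C`, its
#' deviatoric part `Cbar = J^(-2/3) C`, the first deviatoric invariant
#' `I1bar`, the fiber stretch `lambda = sqrt(N' C N)`, and the deviatoric
#' fiber stretch `lambda_f_bar = J^(-1/3) lambda = sqrt(N' Cbar N)`.
#'
#' @param F 3x3 deformation gradient with `det F > 0`.
#' @param N Unit fiber direction in the undeformed configuration.
#' @return Object of class `fiber_kinematics`.
#' @export
fiber_kinematics <- function(F, N) {
  F <- as.matrix(F)
  if (!all(dim(F) == c(3L, 3L)) || any(!is.finite(F))) {
    stop("invalid kinematics: F must be a finite 3x3 matrix")
  }
  J <- det(F)
  if (!is.finite(J) || J <= 0) {
    stop("invalid kinematics: det F must be positive")
  }
  N <- as.numeric(N)
  nrm <- sqrt(sum(N^2))
  if (abs(nrm - 1) > 1e-12) {
    stop("invalid kinematics: N must be a unit vector (|N| = 1 within 1e-12)")
  }
  C <- crossprod(F)                      # F' F
  Cbar <- J^(-2 / 3) * C
  lambda <- sqrt(drop(t(N) %*% C %*% N))
  structure(
    list(F = F, N = N, J = J, C = C, Cbar = Cbar,
         I1bar = sum(diag(Cbar)),
         lambda = lambda,
         lambda_f_bar = J^(-1 / 3) * lambda),
    class = "fiber_kinematics"
  )
}

#' Passive fiber stress-stretch function (PE branch)
#'
#' Quadratic tension-only law: `A * (lambda_f_bar - 1)^2` for stretched
#' fibers, zero otherwise.  Continuous and C1 at `lambda_f_bar = 1`.
#'
#' @param lambda_f_bar Deviatoric fiber stretch (> 0); vectorized.
#' @param A Dimensionless passive constant.
#' @return Dimensionless stress factor (multiply by `sigma0` for MPa).
#' @export
passive_fiber_factor <- function(lambda_f_bar, A) {
  if (any(!is.finite(lambda_f_bar)) || any(lambda_f_bar <= 0)) {
    stop("invalid kinematics: lambda_f_bar must be positive")
  }
  ifelse(lambda_f_bar > 1, A * (lambda_f_bar - 1)^2, 0)
}

#' Contractile (active) stress-stretch function (SE branch)
#'
#' `0.1 * (exp(100 * (lambda_f_bar - 1 - zeta)) - 1)` when the deviatoric
#' fiber stretch exceeds the activation threshold `1 + zeta`, zero
#' otherwise.  Continuous at the threshold and strictly increasing on the
#' active branch.  A negative contractile strain `zeta` (concentric
#' activation) lowers the threshold below 1.
#'
#' @param lambda_f_bar Deviatoric fiber stretch (> 0); vectorized.
#' @param zeta Contractile strain `zeta^CE` (dimensionless).
#' @return Dimensionless stress factor (multiply by `sigma0` for MPa).
#' @export
active_fiber_factor <- function(lambda_f_bar, zeta) {
  if (any(!is.finite(lambda_f_bar)) || any(lambda_f_bar <= 0)) {
    stop("invalid kinematics: lambda_f_bar must be positive")
  }
  ifelse(lambda_f_bar > 1 + zeta,
         0.1 * (exp(100 * (lambda_f_bar - 1 - zeta)) - 1),
         0)
}

#' Contractile strain from the fascicle engineering strain
#'
#' Maps the engineering strain of a fascicle to the contractile strain
#' `zeta^CE` using the group's concentric (`epsilon < 0`) or eccentric
#' (`epsilon > 0`) active parameter.
#'
#' @param epsilon Engineering strain `(L - L0) / L0`; must be > -1.
#' @param material A [muscle_material()].
#' @return Object of class `activation_state` with fields `epsilon`,
#'   `zeta` and `branch` (`"concentric"`, `"eccentric"` or `"inactive"`).
#' @export
contractile_strain <- function(epsilon, material) {
  stopifnot(inherits(material, "muscle_material"), is.numeric(epsilon),
            length(epsilon) == 1L, is.finite(epsilon))
  if (epsilon <= -1) {
    stop("invalid strain: epsilon <= -1 (element annihilated)")
  }
  if (epsilon < 0) {
    zeta <- material$c_ce1 * epsilon
    branch <- "concentric"
  } else if (epsilon > 0) {
    zeta <- material$c_ce2 * epsilon
    branch <- "eccentric"
  } else {
    zeta <- 0
    branch <- "inactive"
  }
  structure(list(epsilon = epsilon, zeta = zeta, branch = branch),
            class = "activation_state")
}

#' Active parameter from sarcomere lengths
#'
#' The active parameter of a muscle group is the ratio between its
#' sarcomere length and the optimal sarcomere length (2.8 micrometer).
#'
#' @param L_S Sarcomere length (micrometer), > 0.
#' @param L0_S Optimal sarcomere length (micrometer), default 2.8.
#' @return Dimensionless active parameter `C_CE = L_S / L0_S`.
#' @export
active_parameter_from_sarcomere <- function(L_S, L0_S = 2.8) {
  if (any(L_S <= 0) || any(L0_S <= 0)) stop("sarcomere lengths must be > 0")
  L_S / L0_S
}

# Closed-form antiderivatives of the two fiber stress-stretch functions,
# normalized to vanish at their respective thresholds.  The fiber energy
# integrals from 1 to lambda_f_bar follow as differences, so no numerical
# quadrature is needed (quadrature is kept only as a test oracle).
.pe_antideriv <- function(x, A) {
  ifelse(x > 1, A * (x - 1)^3 / 3, 0)
}
.se_antideriv <- function(x, zeta) {
  y <- x - 1 - zeta
  ifelse(y > 0, 0.1 * ((exp(100 * y) - 1) / 100 - y), 0)
}

#' Strain energy density of the muscle material
#'
#' `U = (G/2) (I1bar - 3) + (K/2) (ln J)^2
#'    + sigma0 * int_1^lfb f_PE  + sigma0 * int_1^lfb f_SE`,
#' with both fiber integrals evaluated in closed form.  Vanishes in the
#' reference configuration with zero contractile strain.
#'
#' @param kin A [fiber_kinematics()] object.
#' @param material A [muscle_material()].
#' @param zeta Contractile strain `zeta^CE` (default 0, passive).
#' @return Strain energy density (MPa).
#' @export
strain_energy <- function(kin, material, zeta = 0) {
  stopifnot(inherits(kin, "fiber_kinematics"),
            inherits(material, "muscle_material"))
  lfb <- kin$lambda_f_bar
  u_matrix <- material$G / 2 * (kin$I1bar - 3) + material$K / 2 * log(kin$J)^2
  u_pe <- material$sigma0 * (.pe_antideriv(lfb, material$A) -
                               .pe_antideriv(1, material$A))
  u_se <- material$sigma0 * (.se_antideriv(lfb, zeta) -
                               .se_antideriv(1, zeta))
  u_matrix + u_pe + u_se
}

# Total fiber stress derivative U_F' = sigma0 (f_PE + f_SE), split into
# its PE and SE parts; used by the stress evaluations below.
.fiber_stress_parts <- function(lfb, material, zeta) {
  c(pe = material$sigma0 * passive_fiber_factor(lfb, material$A),
    se = material$sigma0 * active_fiber_factor(lfb, zeta))
}

#' Second Piola-Kirchhoff stress
#'
#' `S = 2 dU/dC`, obtained by exact differentiation of the strain energy:
#' an isochoric Neo-Hookean matrix term, a volumetric term `K ln J C^-1`,
#' and a fiber term proportional to the total fiber stress `U_F'`.
#'
#' @inheritParams strain_energy
#' @return Object of class `stress_result` with fields `S` (3x3, MPa),
#'   `sigma_PE`, `sigma_SE` (scalar fiber stresses, MPa), `U` (energy
#'   density, MPa).
#' @export
second_piola_kirchhoff <- function(kin, material, zeta = 0) {
  stopifnot(inherits(kin, "fiber_kinematics"),
            inherits(material, "muscle_material"))
  C <- kin$C
  Cinv <- solve(C)
  I3 <- diag(3)
  J <- kin$J
  lfb <- kin$lambda_f_bar

  S_iso <- material$G * J^(-2 / 3) * (I3 - sum(diag(C)) / 3 * Cinv)
  S_vol <- material$K * log(J) * Cinv
  parts <- .fiber_stress_parts(lfb, material, zeta)
  ufp <- sum(parts)
  NN <- tcrossprod(kin$N)
  S_fib <- ufp * (J^(-2 / 3) / lfb * NN - lfb / 3 * Cinv)

  S <- S_iso + S_vol + S_fib
  S <- (S + t(S)) / 2                    # symmetrize roundoff
  structure(
    list(S = S, sigma_PE = parts[["pe"]], sigma_SE = parts[["se"]],
         U = strain_energy(kin, material, zeta)),
    class = "stress_result"
  )
}

#' Cauchy stress
#'
#' Push-forward of the second Piola-Kirchhoff stress,
#' `sigma = J^-1 F S F'`, together with the deformed fiber direction
#' `n = F N / |F N|`.
#'
#' @inheritParams strain_energy
#' @return Object of class `stress_result` with fields `sigma` (3x3,
#'   MPa), `S`, `sigma_PE`, `sigma_SE`, `n` and `U`.
#' @export
cauchy_stress <- function(kin, material, zeta = 0) {
  res <- second_piola_kirchhoff(kin, material, zeta)
  FF <- kin$F
  sig <- FF %*% res$S %*% t(FF) / kin$J
  res$sigma <- (sig + t(sig)) / 2
  fn <- drop(FF %*% kin$N)
  res$n <- fn / sqrt(sum(fn^2))
  res
}

#' Axial force carried by a straight fascicle element
#'
#' Specializes the constitutive law to a unidirectional element of
#' stretch `lambda` and cross-sectional area `csa` (reference, mm^2).
#' Two lateral contracts are available:
#'
#' * `"free"` (default): isochoric, laterally traction-free element
#'   (`J = 1`, so the deviatoric fiber stretch equals `lambda`).  The
#'   matrix contributes the incompressible Neo-Hookean uniaxial stress
#'   `G (lambda^2 - 1/lambda)`; the current area is `csa / lambda`.
#' * `"confined"`: laterally confined element (`F = diag(1, 1, lambda)`,
#'   `J = lambda`), evaluated through the full Cauchy stress.  The
#'   volumetric matrix term then participates, which gives the element a
#'   physically meaningful compressive stiffness; the current area stays
#'   `csa`.  This is the contract the coupled simulator uses (see the
#'   package vignette for the rationale).
#'
#' Tension is positive.
#'
#' @param lambda Axial stretch ratio (> 0).
#' @param activation An `activation_state` (from [contractile_strain()])
#'   or a bare numeric contractile strain `zeta`.
#' @param material A [muscle_material()].
#' @param csa Reference cross-sectional area (mm^2, > 0).
#' @param lateral Lateral boundary contract, `"free"` or `"confined"`.
#' @return List with components `total`, `passive_fiber`, `active`,
#'   `matrix` (forces, N) and the corresponding axial stresses (MPa).
#' @export
fascicle_axial_force <- function(lambda, activation, material, csa,
                                 lateral = c("free", "confined")) {
  lateral <- match.arg(lateral)
  stopifnot(inherits(material, "muscle_material"))
  if (!is.numeric(lambda) || lambda <= 0) stop("lambda must be > 0")
  if (!is.numeric(csa) || csa <= 0) stop("csa must be > 0")
  zeta <- if (inherits(activation, "activation_state")) {
    activation$zeta
  } else {
    as.numeric(activation)
  }

  if (lateral == "free") {
    lfb <- lambda
    s_matrix <- material$G * (lambda^2 - 1 / lambda)
    s_pe <- material$sigma0 * passive_fiber_factor(lfb, material$A)
    s_se <- material$sigma0 * active_fiber_factor(lfb, zeta)
    area <- csa / lambda
  } else {
    FF <- diag(c(1, 1, lambda))
    kin <- fiber_kinematics(FF, c(0, 0, 1))
    # matrix part: same deformation with the fiber branches switched off
    mat0 <- material
    mat0$sigma0 <- .Machine$double.xmin   # fiber contribution negligible
    s_matrix <- cauchy_stress(kin, mat0, 0)$sigma[3, 3]
    # fiber Cauchy contribution along z for a unit U_F':
    # sigma_fib = (1/J) U_F' (lfb n x n - lfb/3 I); n = z here.
    lfb <- kin$lambda_f_bar
    unit_fib_zz <- (1 / kin$J) * (lfb - lfb / 3)
    parts <- .fiber_stress_parts(lfb, material, zeta)
    s_pe <- parts[["pe"]] * unit_fib_zz
    s_se <- parts[["se"]] * unit_fib_zz
    area <- csa
  }

  list(total = (s_matrix + s_pe + s_se) * area,
       passive_fiber = s_pe * area,
       active = s_se * area,
       matrix = s_matrix * area,
       stress = c(matrix = s_matrix, passive_fiber = s_pe, active = s_se),
       lambda_f_bar = lfb,
       zeta = zeta)
}
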