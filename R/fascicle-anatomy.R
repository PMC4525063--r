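# Synthetic L3-S1 geometry and the 46-fascicle back-muscle network.
#
# Coordinate convention (documented in the generated config as well):
# right-handed, x anterior, y left, z cranial, origin at the center of
# the S1 upper endplate.  Lengths in mm, angles in degrees.
#
# The published counts and topology of the network (23 sagittally
# symmetric pairs: 8 MF, 3 LTpL, 2 ILpL, 4 LTpTh, 6 PS per side; 13
# local + 10 global pairs) are fixed; the exact 3D insertion coordinates
# are synthesized from a small set of anatomically plausible per-vertebra
# landmark offsets, so the geometry is explicit, reproducible, and
# swappable for subject-specific data.

.rot_y <- function(theta) {
  # rotation about +y (to the left); positive theta tips the anterior
  # axis caudally, i.e. sagittal flexion
  ct <- cos(theta); st <- sin(theta)
  matrix(c(ct, 0, -st,
           0,  1,  0,
           st, 0,  ct), 3, 3, byrow = FALSE)
}

#' Synthetic lordotic L3-S1 geometry configuration
#'
#' Generates the geometric scaffold of the model: vertebral centers and
#' sagittal tilts for L3, L4, L5 and S1, landmark offset tables (spinous
#' process, lamina, transverse process, vertebral body), the fixed
#' sacral/iliac/femoral insertion nodes, the thoracic rod node, and the
#' per-fascicle cross-sectional-area table.
#'
#' The segmental lordosis angles are configurable; the lumbosacral
#' (L5/S1) wedge is proportional to the L4/L5 wedge through
#' `lordosis_ratio_l5s1`, a config parameter because only the
#' proportionality (not its value) is anatomically standardized.  The
#' thoracic rod node - the common rostral insertion of the LTpTh
#' fascicles, standing in for the dorsal third rib - sits on the vertical
#' (cranio-caudal) axis through L3 and is kinematically slaved to the
#' axial motion of L3, so that the axial alignment of L3 and the rod is
#' preserved in every simulated posture.
#'
#' @param lordosis_l34 L3/L4 segmental wedge angle (deg).
#' @param lordosis_l45 L4/L5 segmental wedge angle (deg).
#' @param lordosis_ratio_l5s1 Ratio of the L5/S1 wedge to the L4/L5
#'   wedge (dimensionless).
#' @param body_height Vertebral body height (mm).
#' @param disk_height Total disk height (NP plus both cartilage
#'   endplates, mm).
#' @param rod_height Height of the thoracic rod node above the L3
#'   center (mm).
#' @param csa Optional named numeric vector of per-fascicle
#'   cross-sectional areas (mm^2) overriding the shipped defaults; names
#'   are fascicle ids without the side suffix.
#' @return Object of class `geometry_config`.
#' @export
lumbar_geometry <- function(lordosis_l34 = 6,
                            lordosis_l45 = 8,
                            lordosis_ratio_l5s1 = 1.4,
                            body_height = 28,
                            disk_height = 9.6,
                            rod_height = 250,
                            csa = NULL) {
  stopifnot(body_height > 0, disk_height > 0, rod_height > 0,
            lordosis_ratio_l5s1 > 0)
  w34 <- lordosis_l34 * pi / 180
  w45 <- lordosis_l45 * pi / 180
  w5s1 <- lordosis_ratio_l5s1 * w45

  # sagittal tilt of each body: L3 vertical (uppermost level defines the
  # standing axis), tilts accumulate caudally with the wedge angles
  tilt <- c(L3 = 0, L4 = w34, L5 = w34 + w45, S1 = w34 + w45 + w5s1)

  # chain the centers from the S1 endplate upward; each step follows the
  # mean tilt of the segment it crosses
  step <- body_height + disk_height
  centers <- matrix(0, 4, 3,
                    dimnames = list(c("S1", "L5", "L4", "L3"), c("x", "y", "z")))
  pos <- c(0, 0, -body_height / 2)       # nominal S1 center below origin
  centers["S1", ] <- pos
  segs <- c("L5", "L4", "L3")
  seg_tilt <- c(L5 = (tilt[["S1"]] + tilt[["L5"]]) / 2,
                L4 = (tilt[["L5"]] + tilt[["L4"]]) / 2,
                L3 = (tilt[["L4"]] + tilt[["L3"]]) / 2)
  for (v in segs) {
    dirv <- c(sin(seg_tilt[[v]]), 0, cos(seg_tilt[[v]]))
    pos <- pos + step * dirv
    centers[v, ] <- pos
  }

  # landmark offsets in each vertebra's local frame (x anterior, z cranial)
  landmarks <- list(
    SP  = c(-55, 0, -5),                 # spinous process tip
    LAM = c(-32, 8, 0),                  # lamina
    TP  = c(-12, 38, 0),                 # transverse/accessory process
    VBU = c(12, 15, 6),                  # anterolateral body, upper
    VBL = c(12, 15, -6)                  # anterolateral body, lower
  )

  # fixed caudal insertion nodes (right side, y < 0 mirrored to left)
  fixed_nodes <- list(
    sacrum_upper = c(-48, 8, -20),
    sacrum_mid   = c(-45, 10, -35),
    sacrum_low   = c(-40, 12, -48),
    sacrum_ala   = c(-35, 25, -18),
    ilium        = c(-38, 45, -25),
    iliac_crest  = c(-30, 55, -20),
    femur        = c(5, 45, -120)
  )

  rod <- c(centers["L3", "x"], 0, centers["L3", "z"] + rod_height)

  csa_tab <- .default_csa()
  if (!is.null(csa)) {
    unknown <- setdiff(names(csa), names(csa_tab))
    if (length(unknown)) {
      stop("unknown fascicle ids in csa override: ",
           paste(unknown, collapse = ", "))
    }
    csa_tab[names(csa)] <- csa
  }

  structure(
    list(centers = centers, tilt = tilt, landmarks = landmarks,
         fixed_nodes = fixed_nodes, rod_node = rod,
         rod_height = rod_height,
         body_height = body_height, disk_height = disk_height,
         lordosis = c(l34 = lordosis_l34, l45 = lordosis_l45,
                      l5s1 = lordosis_ratio_l5s1 * lordosis_l45),
         csa = csa_tab),
    class = "geometry_config"
  )
}

# Default equivalent cross-sectional areas (mm^2).  Fascicle volumes and
# lengths are not part of this synthetic geometry, so these are shipped
# as plausible radiographically informed defaults; every force
# computation takes the CSA from the config so they can be replaced.
.default_csa <- function() {
  c(
    "MF-L3-LAM-A" = 60,  "MF-L3-SP-A" = 90,  "MF-L3-SP-B" = 110,
    "MF-L4-LAM-A" = 60,  "MF-L4-SP-A" = 90,  "MF-L4-SP-B" = 110,
    "MF-L5-LAM-A" = 60,  "MF-L5-SP-A" = 90,
    "LTpL-L3-TP" = 80,   "LTpL-L4-TP" = 110, "LTpL-L5-TP" = 90,
    "ILpL-L3-TP" = 100,  "ILpL-L4-TP" = 120,
    "LTpTh-L3-A" = 50,   "LTpTh-L3-B" = 50,  "LTpTh-L4-A" = 50,
    "LTpTh-L5-A" = 50,
    "PS-L3-VB-A" = 120,  "PS-L3-VB-B" = 120, "PS-L4-VB-A" = 120,
    "PS-L4-VB-B" = 120,  "PS-L5-VB-A" = 120, "PS-L5-VB-B" = 120
  )
}

# Fascicle definition table: one row per sagittal pair.  cranial/caudal
# refer to the force-carrying endpoints; bodies L3/L4/L5 are mobile, the
# others fixed (the rod is slaved axially to L3).  MF sub-groups: deep
# (LAM), intermediate (SP-A), superficial (SP-B).
.fascicle_defs <- function() {
  defs <- rbind(
    data.frame(id = "MF-L3-LAM-A", group = "MF", subgroup = "deep",
               cr_body = "L3", cr_lm = "LAM", ca_body = "L5", ca_lm = "LAM"),
    data.frame(id = "MF-L3-SP-A", group = "MF", subgroup = "intermediate",
               cr_body = "L3", cr_lm = "SP", ca_body = "sacrum_upper", ca_lm = ""),
    data.frame(id = "MF-L3-SP-B", group = "MF", subgroup = "superficial",
               cr_body = "L3", cr_lm = "SP", ca_body = "sacrum_low", ca_lm = ""),
    data.frame(id = "MF-L4-LAM-A", group = "MF", subgroup = "deep",
               cr_body = "L4", cr_lm = "LAM", ca_body = "sacrum_ala", ca_lm = ""),
    data.frame(id = "MF-L4-SP-A", group = "MF", subgroup = "intermediate",
               cr_body = "L4", cr_lm = "SP", ca_body = "sacrum_mid", ca_lm = ""),
    data.frame(id = "MF-L4-SP-B", group = "MF", subgroup = "superficial",
               cr_body = "L4", cr_lm = "SP", ca_body = "sacrum_low", ca_lm = ""),
    data.frame(id = "MF-L5-LAM-A", group = "MF", subgroup = "deep",
               cr_body = "L5", cr_lm = "LAM", ca_body = "sacrum_upper", ca_lm = ""),
    data.frame(id = "MF-L5-SP-A", group = "MF", subgroup = "intermediate",
               cr_body = "L5", cr_lm = "SP", ca_body = "sacrum_mid", ca_lm = ""),
    data.frame(id = "LTpL-L3-TP", group = "LTpL", subgroup = "",
               cr_body = "L3", cr_lm = "TP", ca_body = "ilium", ca_lm = ""),
    data.frame(id = "LTpL-L4-TP", group = "LTpL", subgroup = "",
               cr_body = "L4", cr_lm = "TP", ca_body = "ilium", ca_lm = ""),
    data.frame(id = "LTpL-L5-TP", group = "LTpL", subgroup = "",
               cr_body = "L5", cr_lm = "TP", ca_body = "ilium", ca_lm = ""),
    data.frame(id = "ILpL-L3-TP", group = "ILpL", subgroup = "",
               cr_body = "L3", cr_lm = "TP", ca_body = "iliac_crest", ca_lm = ""),
    data.frame(id = "ILpL-L4-TP", group = "ILpL", subgroup = "",
               cr_body = "L4", cr_lm = "TP", ca_body = "iliac_crest", ca_lm = ""),
    data.frame(id = "LTpTh-L3-A", group = "LTpTh", subgroup = "",
               cr_body = "rod", cr_lm = "", ca_body = "L3", ca_lm = "TP"),
    data.frame(id = "LTpTh-L3-B", group = "LTpTh", subgroup = "",
               cr_body = "rod", cr_lm = "", ca_body = "L3", ca_lm = "LAM"),
    data.frame(id = "LTpTh-L4-A", group = "LTpTh", subgroup = "",
               cr_body = "rod", cr_lm = "", ca_body = "L4", ca_lm = "TP"),
    data.frame(id = "LTpTh-L5-A", group = "LTpTh", subgroup = "",
               cr_body = "rod", cr_lm = "", ca_body = "L5", ca_lm = "TP"),
    data.frame(id = "PS-L3-VB-A", group = "PS", subgroup = "",
               cr_body = "L3", cr_lm = "VBU", ca_body = "femur", ca_lm = ""),
    data.frame(id = "PS-L3-VB-B", group = "PS", subgroup = "",
               cr_body = "L3", cr_lm = "VBL", ca_body = "femur", ca_lm = ""),
    data.frame(id = "PS-L4-VB-A", group = "PS", subgroup = "",
               cr_body = "L4", cr_lm = "VBU", ca_body = "femur", ca_lm = ""),
    data.frame(id = "PS-L4-VB-B", group = "PS", subgroup = "",
               cr_body = "L4", cr_lm = "VBL", ca_body = "femur", ca_lm = ""),
    data.frame(id = "PS-L5-VB-A", group = "PS", subgroup = "",
               cr_body = "L5", cr_lm = "VBU", ca_body = "femur", ca_lm = ""),
    data.frame(id = "PS-L5-VB-B", group = "PS", subgroup = "",
               cr_body = "L5", cr_lm = "VBL", ca_body = "femur", ca_lm = "")
  )
  defs$scope <- ifelse(defs$group %in% c("MF", "LTpL", "ILpL"),
                       "local", "global")
  defs
}

# Resolve an endpoint definition to reference coordinates for one side.
# side_sign: +1 left, -1 right.
.endpoint_ref <- function(config, body, lm, side_sign) {
  if (body %in% c("L3", "L4", "L5")) {
    off <- config$landmarks[[lm]]
    if (is.null(off)) stop("config error: unknown landmark '", lm, "'")
    off <- off * c(1, side_sign, 1)
    drop(config$centers[body, ] + .rot_y(config$tilt[[body]]) %*% off)
  } else if (body == "rod") {
    config$rod_node * c(1, 1, 1) + c(0, side_sign * 40, 0)
  } else {
    node <- config$fixed_nodes[[body]]
    if (is.null(node)) stop("config error: unknown fixed node '", body, "'")
    node * c(1, side_sign, 1)
  }
}

#' Build the 46-fascicle muscle network
#'
#' Expands the 23 sagittally symmetric fascicle-pair definitions over
#' both sides of the synthetic geometry and computes reference endpoint
#' coordinates, rest lengths and scopes.  The resulting network always
#' contains 16 MF, 6 LTpL, 4 ILpL, 8 LTpTh and 12 PS fascicles (26 local
#' and 20 global).
#'
#' @param config A [lumbar_geometry()] configuration.
#' @return Object of class `fascicle_network`: a data frame (one row per
#'   fascicle) with id, group, sub-group, side, scope, attached bodies,
#'   endpoint coordinates, rest length `L0` and `csa`, plus the
#'   generating config as attribute.
#' @export
build_network <- function(config) {
  stopifnot(inherits(config, "geometry_config"))
  defs <- .fascicle_defs()
  missing_csa <- setdiff(defs$id, names(config$csa))
  if (length(missing_csa)) {
    stop("config error: missing csa entries for ",
         paste(missing_csa, collapse = ", "))
  }
  rows <- list()
  for (i in seq_len(nrow(defs))) {
    d <- defs[i, ]
    for (side in c("left", "right")) {
      ss <- if (side == "left") 1 else -1
      cr <- .endpoint_ref(config, d$cr_body, d$cr_lm, ss)
      ca <- .endpoint_ref(config, d$ca_body, d$ca_lm, ss)
      L0 <- sqrt(sum((cr - ca)^2))
      if (L0 <= 1e-9) stop("config error: zero-length fascicle ", d$id)
      rows[[length(rows) + 1L]] <- data.frame(
        id = d$id, group = d$group, subgroup = d$subgroup, side = side,
        scope = d$scope,
        cranial_body = d$cr_body, caudal_body = d$ca_body,
        cr_x = cr[1], cr_y = cr[2], cr_z = cr[3],
        ca_x = ca[1], ca_y = ca[2], ca_z = ca[3],
        L0 = L0, csa = unname(config$csa[[d$id]]),
        stringsAsFactors = FALSE
      )
    }
  }
  net <- do.call(rbind, rows)
  rownames(net) <- NULL
  structure(net, class = c("fascicle_network", "data.frame"),
            config = config)
}

#' Equivalent cross-sectional area of a fascicle
#'
#' The equivalent CSA of a fascicle is its volume divided by its length.
#'
#' @param volume Fascicle volume (mm^3, >= 0).
#' @param length Fascicle length (mm, > 0).
#' @return Area (mm^2).
#' @export
equivalent_csa <- function(volume, length) {
  if (any(volume < 0)) stop("volume must be >= 0")
  if (any(length <= 0)) stop("length must be > 0")
  volume / length
}

#' Rigid vertebra pose
#'
#' Convenience constructor for the rigid poses consumed by
#' [fascicle_strain()] and [line_of_action()].  `theta` is a sagittal
#' rotation (radians, about +y through the vertebral center, flexion
#' positive); `R` may be given directly for general rigid motions.
#'
#' @param theta Sagittal rotation (rad).
#' @param dx,dy,dz Translation of the vertebral center (mm).
#' @param R Optional explicit 3x3 rotation matrix (overrides `theta`).
#' @return List with components `R` and `t`.
#' @export
vertebra_pose <- function(theta = 0, dx = 0, dy = 0, dz = 0, R = NULL) {
  if (is.null(R)) R <- .rot_y(theta)
  if (max(abs(crossprod(R) - diag(3))) > 1e-9 || abs(det(R) - 1) > 1e-9) {
    stop("R must be a proper rotation")
  }
  list(R = R, t = c(dx, dy, dz))
}

# Current position of a reference point attached to `body` under `poses`
# (named list of vertebra_pose for L3/L4/L5, optionally fixed-node
# bodies).  The rod is slaved to the axial (z) translation of L3.
.current_point <- function(p_ref, body, poses, config) {
  if (body %in% names(poses)) {
    pose <- poses[[body]]
    if (body %in% rownames(config$centers)) {
      ctr <- config$centers[body, ]
      drop(ctr + pose$t + pose$R %*% (p_ref - ctr))
    } else {
      # fixed node given an explicit pose (rigid-motion checks):
      # rotation about the model origin plus translation
      drop(pose$t + pose$R %*% p_ref)
    }
  } else if (body == "rod" && "L3" %in% names(poses)) {
    p_ref + c(0, 0, poses[["L3"]]$t[3])
  } else {
    p_ref
  }
}

#' Fascicle engineering strains under rigid vertebral poses
#'
#' Moves the mobile endpoints with the given rigid poses (fixed nodes
#' stay put; the thoracic rod follows the axial translation of L3) and
#' returns the engineering strain `(L - L0) / L0` of every fascicle.
#'
#' @param network A [build_network()] result.
#' @param poses Named list of [vertebra_pose()] objects for any of
#'   `"L3"`, `"L4"`, `"L5"`.  Missing bodies keep their reference pose.
#'   Entries for fixed bodies (e.g. `"femur"`, `"sacrum_upper"`, `"rod"`)
#'   are honored too, which permits whole-model rigid-motion checks.
#' @return Numeric vector of strains, named by `id.side`.
#' @export
fascicle_strain <- function(network, poses = list()) {
  stopifnot(inherits(network, "fascicle_network"))
  config <- attr(network, "config")
  n <- nrow(network)
  eps <- numeric(n)
  for (i in seq_len(n)) {
    cr <- .current_point(c(network$cr_x[i], network$cr_y[i], network$cr_z[i]),
                         network$cranial_body[i], poses, config)
    ca <- .current_point(c(network$ca_x[i], network$ca_y[i], network$ca_z[i]),
                         network$caudal_body[i], poses, config)
    eps[i] <- sqrt(sum((cr - ca)^2)) / network$L0[i] - 1
  }
  names(eps) <- paste(network$id, network$side, sep = ".")
  eps
}

#' Line of action and moment arm of a fascicle
#'
#' Returns the unit vector of the fascicle's line of action (caudal to
#' cranial endpoint) in the current pose, and its moment arm, i.e. the
#' perpendicular distance from a queried point (typically a vertebral
#' center) to the line.
#'
#' @param fascicle One row of a [build_network()] data frame.
#' @param poses As in [fascicle_strain()].
#' @param about 3-vector: point about which the moment arm is taken.
#' @param config The generating [lumbar_geometry()] config (taken from
#'   the fascicle's network attribute when called on a subset row).
#' @return List with `direction` (unit 3-vector) and `moment_arm` (mm).
#' @export
line_of_action <- function(fascicle, poses = list(), about,
                           config = attr(fascicle, "config")) {
  stopifnot(!is.null(config))
  cr <- .current_point(c(fascicle$cr_x[1], fascicle$cr_y[1], fascicle$cr_z[1]),
                       fascicle$cranial_body[1], poses, config)
  ca <- .current_point(c(fascicle$ca_x[1], fascicle$ca_y[1], fascicle$ca_z[1]),
                       fascicle$caudal_body[1], poses, config)
  d <- cr - ca
  L <- sqrt(sum(d^2))
  if (L <= 1e-12) stop("zero-length element")
  u <- d / L
  r <- as.numeric(about) - ca
  cr3 <- c(r[2] * u[3] - r[3] * u[2],
           r[3] * u[1] - r[1] * u[3],
           r[1] * u[2] - r[2] * u[1])
  list(direction = u, moment_arm = sqrt(sum(cr3^2)))
}

#' @export
print.fascicle_network <- function(x, ...) {
  cat("fascicle_network:", nrow(x), "fascicles (",
      sum(x$scope == "local"), "local /", sum(x$scope == "global"),
      "global )\n")
  print(table(x$group))
  invisible(x)
}
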