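# Multigenerational fiber bookkeeping: per-element local material axes from
# hexahedral node positions, fiber ply directions, per-generation reference
# configurations (deformation gradient snapshots at deposition), and the
# resulting fiber stretch / strain / stress fields. All stretches are
# computed through the relative deformation gradient F(t) F(u)^-1 against the
# deposition-time fiber direction; directions are never re-derived from the
# deformed geometry.

#' Local material axes of a hexahedral element
#'
#' From the eight corner positions (standard isoparametric ordering: nodes
#' 1-4 the bottom face, 5-8 stacked above), builds the orthonormal triad
#' `e1 = a/|a|`, `e3 = (a x d)/|a x d|`, `e2 = e3 x e1` with `a = n2 - n1`
#' (the in-plane fiber-reference edge) and `d = n5 - n1` (the through-
#' thickness edge). Meshes built by this package orient node edge 1-2
#' circumferentially, so `e1` is the circumferential direction, `e2` the
#' axial, and `e3` the radial.
#'
#' @param node_coords 8x3 matrix of corner positions (mm).
#' @return Object of class `local_axes`: unit vectors `e1`, `e2`, `e3` and
#'   the rotation `T_xB` whose rows are e1, e2, e3.
#' @export
local_material_axes <- function(node_coords) {
  node_coords <- as.matrix(node_coords)
  if (!all(dim(node_coords) == c(8, 3))) stop("need an 8x3 coordinate matrix")
  a <- node_coords[2, ] - node_coords[1, ]
  d <- node_coords[5, ] - node_coords[1, ]
  ad <- c(a[2] * d[3] - a[3] * d[2],
          a[3] * d[1] - a[1] * d[3],
          a[1] * d[2] - a[2] * d[1])
  nad <- sqrt(sum(ad^2))
  if (nad < 1e-12 * sqrt(sum(a^2)) * sqrt(sum(d^2)) || nad == 0)
    stop("degenerate element: edge directions a and d are parallel")
  e1 <- a / sqrt(sum(a^2))
  e3 <- ad / nad
  e2 <- c(e3[2] * e1[3] - e3[3] * e1[2],
          e3[3] * e1[1] - e3[1] * e1[3],
          e3[1] * e1[2] - e3[2] * e1[1])
  structure(list(e1 = e1, e2 = e2, e3 = e3,
                 T_xB = rbind(e1, e2, e3, deparse.level = 0)),
            class = "local_axes")
}

#' Global fiber direction of one ply
#'
#' Rotates the in-plane fiber direction `(cos(s theta), sin(s theta), 0)`
#' (angle measured from e1 toward e2, sign s selecting the +theta or -theta
#' ply) into global coordinates through the local axes.
#'
#' @param axes A `local_axes`.
#' @param theta Ply angle magnitude (degrees).
#' @param sign +1 or -1, selecting which ply of the angle-ply pair.
#' @return Unit 3-vector in global coordinates.
#' @export
fiber_direction_global <- function(axes, theta, sign = 1) {
  stopifnot(inherits(axes, "local_axes"), sign %in% c(-1, 1))
  th <- sign * theta * pi / 180
  v <- t(axes$T_xB) %*% c(cos(th), sin(th), 0)
  as.numeric(v / sqrt(sum(v^2)))
}

#' Relative deformation gradient between two instants
#'
#' `F_u(t) = F(t) F(u)^-1`: the deformation at time t measured against the
#' configuration at deposition time u (both gradients taken with respect to
#' time zero). Identity when t = u.
#'
#' @param F_t 3x3 deformation gradient at the time of interest.
#' @param F_u 3x3 deformation gradient at deposition (det > 0).
#' @return 3x3 relative deformation gradient.
#' @export
relative_deformation <- function(F_t, F_u) {
  if (abs(det(F_u)) < .Machine$double.xmin || det(F_u) <= 0)
    stop("singular or inverted deposition gradient")
  F_t %*% solve(F_u)
}

#' Fiber stretch under a relative deformation
#'
#' `lambda_n = sqrt(v . C v)` with `C = F_rel^T F_rel` and `v` the unit fiber
#' direction recorded at deposition.
#'
#' @param F_rel 3x3 relative deformation gradient.
#' @param v Unit fiber direction at deposition time.
#' @return Fiber stretch (> 0).
#' @export
fiber_stretch <- function(F_rel, v) {
  w <- F_rel %*% v
  sqrt(sum(w^2))
}

#' Push a time-zero fiber direction to the deposition configuration
#'
#' `v_dep = F(u) v0 / |F(u) v0|`: the time-zero ply direction carried into
#' the (deformed) configuration in which the fiber generation is deposited.
#'
#' @param F_u 3x3 deformation gradient at deposition (det > 0).
#' @param v_time0 Fiber direction at time zero.
#' @return Unit direction at deposition time.
#' @export
map_direction_to_deposition <- function(F_u, v_time0) {
  if (det(F_u) <= 0) stop("singular or inverted deposition gradient")
  w <- as.numeric(F_u %*% v_time0)
  w / sqrt(sum(w^2))
}

#' Create a fiber generation record
#'
#' One generation = one fiber family (one sign of the angle-ply pair) with a
#' per-element deformation-gradient snapshot at its deposition instant and
#' the per-element deposition-time unit direction.
#'
#' @param generation_id Integer index.
#' @param deposition_stage Character label of the protocol stage.
#' @param F_at_deposition ne x 3 x 3 array of per-element deformation
#'   gradients (relative to time zero) at deposition.
#' @param fiber_angle_sign +1 or -1.
#' @param v_dep ne x 3 matrix of unit fiber directions at deposition.
#' @param modulus_scale Fraction of the full fiber modulus active, in [0,1].
#' @return Object of class `fiber_generation`.
#' @export
fiber_generation <- function(generation_id, deposition_stage, F_at_deposition,
                             fiber_angle_sign, v_dep, modulus_scale = 1) {
  stopifnot(fiber_angle_sign %in% c(-1, 1))
  ne <- dim(F_at_deposition)[1]
  dets <- vapply(seq_len(ne), function(e) det(F_at_deposition[e, , ]), 0)
  if (any(dets <= 0)) stop("inverted deposition gradient in generation record")
  nrm <- sqrt(rowSums(v_dep^2))
  if (any(abs(nrm - 1) > 1e-8)) stop("deposition directions must be unit vectors")
  structure(list(generation_id = generation_id,
                 deposition_stage = deposition_stage,
                 F_at_deposition = F_at_deposition,
                 fiber_angle_sign = fiber_angle_sign,
                 v_dep = v_dep,
                 modulus_scale = modulus_scale),
            class = "fiber_generation")
}

#' Identity-reference fiber generations (classical fiber model)
#'
#' Builds the two +/- theta generations deposited at time zero with identity
#' deformation gradients, i.e. the classical (non-multigenerational) fiber
#' model used in swelling-only mode. Directions come from each element's
#' local axes and region ply angle; fiber-free elements carry a placeholder
#' direction and are masked by their missing fiber modulus.
#'
#' @param mesh A `disc_mesh` with assigned region parameters (see
#'   [assign_region_params()]).
#' @return List of two `fiber_generation` records.
#' @export
time_zero_generations <- function(mesh) {
  ne <- nrow(mesh$elem)
  Fid <- array(0, c(ne, 3, 3))
  Fid[, 1, 1] <- Fid[, 2, 2] <- Fid[, 3, 3] <- 1
  vplus <- matrix(0, ne, 3)
  vminus <- matrix(0, ne, 3)
  for (e in seq_len(ne)) {
    ax <- structure(list(T_xB = mesh$axes[e, , ]), class = "local_axes")
    th <- mesh$theta[e]
    if (is.na(th)) { vplus[e, ] <- c(1, 0, 0); vminus[e, ] <- c(1, 0, 0); next }
    vplus[e, ]  <- fiber_direction_global(ax, th, +1)
    vminus[e, ] <- fiber_direction_global(ax, th, -1)
  }
  list(fiber_generation(1L, "time_zero", Fid, +1, vplus),
       fiber_generation(2L, "time_zero", Fid, -1, vminus))
}

#' Per-element fiber stretch, strain and stress fields
#'
#' For every element and every generation, computes the fiber stretch through
#' the relative deformation gradient against that generation's deposition
#' snapshot, the fiber strain `stretch - 1`, and the one-dimensional fiber
#' stress from the region's fiber law (zero wherever the fiber is slack).
#' With all generations deposited at time zero this reduces exactly to the
#' classical fiber model.
#'
#' @param F_t ne x 3 x 3 array of current per-element deformation gradients
#'   (relative to time zero).
#' @param generations List of `fiber_generation` records (one per family).
#' @param mesh A `disc_mesh` with assigned region parameters.
#' @return Data frame with columns `element`, `generation`, `region`,
#'   `lambda_n`, `eps_n`, `sigma_n` (fiber-free elements are omitted).
#' @export
compute_fiber_field <- function(F_t, generations, mesh) {
  if (length(generations) == 0) stop("configuration error: no generation records")
  ne <- nrow(mesh$elem)
  fib <- which(!is.na(mesh$theta))
  out <- vector("list", length(generations))
  for (g in seq_along(generations)) {
    gen <- generations[[g]]
    if (dim(gen$F_at_deposition)[1] != ne)
      stop("configuration error: generation record does not cover the mesh")
    lam <- eps <- sig <- numeric(length(fib))
    for (i in seq_along(fib)) {
      e <- fib[i]
      Frel <- F_t[e, , ] %*% solve(gen$F_at_deposition[e, , ])
      lam[i] <- fiber_stretch(Frel, gen$v_dep[e, ])
      pars <- mesh$materials[[mesh$region[e]]]
      sig[i] <- gen$modulus_scale * fiber_stress_1d(lam[i], pars)
    }
    out[[g]] <- data.frame(element = fib, generation = gen$generation_id,
                           region = mesh$region[fib],
                           lambda_n = lam, eps_n = lam - 1, sigma_n = sig)
  }
  do.call(rbind, out)
}
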