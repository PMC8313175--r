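# Parameterized hexahedral disc meshes. Cross-sections are meshed with an
# O-grid: a central square block (NP core) surrounded by concentric rings
# carrying the radial region sequence NP -> NPtrans -> IAF -> AFtrans -> OAF,
# with the two transitional bands exactly one element thick. The human disc
# is the same topology scaled anisotropically to an ellipse. A radial cut
# plane (duplicated, tied node pairs spanning the full AF thickness and
# height at theta = 0) supports the incision experiment.
#
# Coordinates: z axial (superior +), x left-right, y anterior-posterior; mm.
# Element node ordering is the standard isoparametric hexahedron (bottom
# face 1-4, top face 5-8) oriented so edge 1-2 runs circumferentially and
# edge 1-5 axially; local material axes therefore give e1 = circumferential.

#' Geometry specification
#'
#' Parameter set for the mesh builders. `n_sectors` must be a multiple of 4
#' (O-grid core constraint). The transitional bands (AFtrans, NPtrans) are
#' always one element thick with thickness `trans_thickness`.
#'
#' @param shape "bovine_cylinder" or "human_parametric".
#' @param height Disc height H (mm).
#' @param outer_radius Outer radius (mm) of the cylinder, or the left-right
#'   semi-axis for the human shape.
#' @param aspect_ratio Ratio of left-right to anterior-posterior extent for
#'   the human shape (1 = circular).
#' @param np_fraction NP radius as a fraction of the outer radius.
#' @param n_sectors Circumferential element count (multiple of 4).
#' @param n_np_rings,n_iaf_rings,n_oaf_rings Ring counts per region.
#' @param n_axial Axial element layers.
#' @param trans_thickness Thickness (mm) of each 1-element transitional band.
#' @param bulge Initial outward mid-height offset of the lateral boundary as
#'   a fraction of local radius (0 = straight-walled).
#' @return Object of class `geometry_spec`.
#' @export
geometry_spec <- function(shape = c("bovine_cylinder", "human_parametric"),
                          height = if (match.arg(shape) == "bovine_cylinder") 7 else 11,
                          outer_radius = if (match.arg(shape) == "bovine_cylinder") 10 else 19.3,
                          aspect_ratio = if (match.arg(shape) == "bovine_cylinder") 1 else 38.6 / 27.8,
                          np_fraction = 0.5,
                          n_sectors = 16, n_np_rings = 2, n_iaf_rings = 2,
                          n_oaf_rings = 2, n_axial = 4,
                          trans_thickness = 0.4, bulge = 0) {
  shape <- match.arg(shape)
  if (n_sectors %% 4 != 0 || n_sectors < 8)
    stop("config error: n_sectors must be a multiple of 4, at least 8")
  if (height <= 0 || outer_radius <= 0 || aspect_ratio <= 0)
    stop("config error: dimensions must be positive")
  if (np_fraction <= 0 || np_fraction >= 1)
    stop("config error: np_fraction must lie in (0, 1)")
  if (min(n_np_rings, n_iaf_rings, n_oaf_rings, n_axial) < 1)
    stop("config error: ring/layer counts must be >= 1")
  r_np <- np_fraction * outer_radius
  if (2 * trans_thickness >= (1 - np_fraction) * outer_radius)
    stop("config error: transitional layers too thick for the AF")
  structure(list(shape = shape, height = height, outer_radius = outer_radius,
                 aspect_ratio = aspect_ratio, np_fraction = np_fraction,
                 n_sectors = n_sectors, n_np_rings = n_np_rings,
                 n_iaf_rings = n_iaf_rings, n_oaf_rings = n_oaf_rings,
                 n_axial = n_axial, trans_thickness = trans_thickness,
                 bulge = bulge),
            class = "geometry_spec")
}

# O-grid cylinder builder shared by both shapes (circular cross-section,
# outer radius R). Returns the full disc_mesh skeleton.
.build_ogrid_cylinder <- function(spec) {
  m <- spec$n_sectors / 4L
  R <- spec$outer_radius
  r_np <- spec$np_fraction * R
  tt <- spec$trans_thickness
  s <- 0.5 * r_np                       # core square half-width
  nz <- spec$n_axial
  H <- spec$height

  # square boundary nodes ordered by angle from theta = 0
  gs <- seq(-s, s, length.out = m + 1)
  bidx <- which(outer(seq_len(m + 1), seq_len(m + 1),
                      function(i, j) i == 1 | i == m + 1 | j == 1 | j == m + 1),
                arr.ind = TRUE)
  bxy <- cbind(gs[bidx[, 1]], gs[bidx[, 2]])
  ang <- atan2(bxy[, 2], bxy[, 1]) %% (2 * pi)
  ord <- order(ang)
  bxy <- bxy[ord, , drop = FALSE]
  bgrid <- bidx[ord, , drop = FALSE]     # grid (i,j) of each sector's node
  nsec <- nrow(bxy)                      # = 4m
  theta <- atan2(bxy[, 2], bxy[, 1]) %% (2 * pi)

  # radial stations outside the core square: station 0 is the square
  # boundary itself; NP blends to the circle r_np; then circular rings.
  # The AF span between the two 1-element transitional bands is split
  # equally between IAF and OAF.
  r_npt_out <- r_np + tt
  r_iaf_out <- r_npt_out + (R - r_np - 2 * tt) / 2
  r_aft_out <- r_iaf_out + tt
  radii_af <- c(r_npt_out,
                seq(r_npt_out, r_iaf_out, length.out = spec$n_iaf_rings + 1)[-1],
                r_aft_out,
                seq(r_aft_out, R, length.out = spec$n_oaf_rings + 1)[-1])
  nK <- as.integer(spec$n_np_rings + length(radii_af))  # last station index K

  # per-plane node coordinates -------------------------------------------
  # core interior nodes
  core_ij <- expand.grid(i = 2:m, j = 2:m)
  core_xy <- cbind(gs[core_ij$i], gs[core_ij$j])
  n_core <- nrow(core_xy)
  # station nodes: (K+1) stations x nsec sectors
  stat_xy <- matrix(0, (nK + 1) * nsec, 2)
  for (k in 0:nK) {
    if (k == 0) {
      xy <- bxy
    } else if (k <= spec$n_np_rings) {
      t <- k / spec$n_np_rings
      xy <- (1 - t) * bxy + t * r_np * cbind(cos(theta), sin(theta))
    } else {
      r <- radii_af[k - spec$n_np_rings]
      xy <- r * cbind(cos(theta), sin(theta))
    }
    stat_xy[k * nsec + seq_len(nsec), ] <- xy
  }
  npp <- as.integer(n_core + (nK + 1L) * nsec)   # nodes per plane

  zs <- seq(0, H, length.out = nz + 1)
  nodes <- matrix(0, npp * (nz + 1), 3)
  for (l in 0:nz) {
    rowids <- l * npp + seq_len(npp)
    nodes[rowids, 1:2] <- rbind(core_xy, stat_xy)
    nodes[rowids, 3] <- zs[l + 1]
  }
  if (spec$bulge != 0) {
    zeta <- nodes[, 3] / H
    nodes[, 1:2] <- nodes[, 1:2] * (1 + spec$bulge * 4 * zeta * (1 - zeta))
  }

  # node-id helpers -------------------------------------------------------
  core_id_grid <- matrix(NA_integer_, m + 1, m + 1)
  core_id_grid[cbind(core_ij$i, core_ij$j)] <- seq_len(n_core)
  for (jj in seq_len(nsec))
    core_id_grid[bgrid[jj, 1], bgrid[jj, 2]] <- n_core + jj  # station 0 ids
  gid_core <- function(i, j, l) as.integer(l * npp + core_id_grid[cbind(i, j)])
  gid_stat <- function(k, j, l) {        # j is 1-based sector, wraps
    j <- ((j - 1) %% nsec) + 1
    as.integer(l * npp + n_core + k * nsec + j)
  }

  # elements ---------------------------------------------------------------
  elem <- NULL
  region <- character(0)
  add <- function(conn, reg) {
    elem <<- rbind(elem, conn)
    region <<- c(region, rep(reg, nrow(conn)))
  }
  band_regions <- c(rep("NP", spec$n_np_rings), "NPtrans",
                    rep("IAF", spec$n_iaf_rings), "AFtrans",
                    rep("OAF", spec$n_oaf_rings))
  for (l in 0:(nz - 1)) {
    # core square cells (NP)
    cc <- expand.grid(i = 1:m, j = 1:m)
    conn <- cbind(gid_core(cc$i, cc$j, l), gid_core(cc$i + 1, cc$j, l),
                  gid_core(cc$i + 1, cc$j + 1, l), gid_core(cc$i, cc$j + 1, l),
                  gid_core(cc$i, cc$j, l + 1), gid_core(cc$i + 1, cc$j, l + 1),
                  gid_core(cc$i + 1, cc$j + 1, l + 1), gid_core(cc$i, cc$j + 1, l + 1))
    add(conn, "NP")
    # ring cells
    for (k in 0:(nK - 1)) {
      js <- seq_len(nsec)
      conn <- cbind(gid_stat(k + 1, js, l), gid_stat(k + 1, js + 1, l),
                    gid_stat(k, js + 1, l), gid_stat(k, js, l),
                    gid_stat(k + 1, js, l + 1), gid_stat(k + 1, js + 1, l + 1),
                    gid_stat(k, js + 1, l + 1), gid_stat(k, js, l + 1))
      add(conn, band_regions[k + 1])
    }
  }
  storage.mode(elem) <- "integer"

  # radial cut plane at theta = 0 (sector 1): duplicate stations covering
  # the full AF thickness (NP/NPtrans interface outward), all planes.
  cut_stations <- spec$n_np_rings:nK
  master <- integer(0)
  for (l in 0:nz)
    master <- c(master, vapply(cut_stations, gid_stat, integer(1), j = 1, l = l))
  ndup <- length(master)
  dup <- nrow(nodes) + seq_len(ndup)
  nodes <- rbind(nodes, nodes[master, , drop = FALSE])
  # elements on the minus side of the cut (sector band nsec, i.e. the band
  # between theta_{nsec} and theta_1=0) reference the duplicates once cut.
  elem_cut <- elem
  dup_of <- integer(nrow(nodes)); dup_of[master] <- dup
  # identify minus-side band elements: ring elements whose sector is nsec
  # (their nodes 2,3,6,7 sit at sector 1). Replace those node slots when the
  # node is a cut master.
  minus_slots <- c(2, 3, 6, 7)
  for (e in seq_len(nrow(elem))) {
    for (sl in minus_slots) {
      nd <- elem[e, sl]
      if (dup_of[nd] > 0L) {
        # is this element on the minus side? its node-1 sector must be nsec
        # (ring elements only; core cells never touch cut stations)
        # node-1 of ring elements is gid_stat(k+1, js, l); recover sector:
        per <- (elem[e, 1] - 1) %% npp + 1
        if (per > n_core) {
          sec1 <- ((per - n_core - 1) %% nsec) + 1
          if (sec1 == nsec) elem_cut[e, sl] <- dup_of[nd]
        }
      }
    }
  }

  # boundary node sets
  bottom <- which(abs(nodes[, 3]) < 1e-9)
  top <- which(abs(nodes[, 3] - H) < 1e-9)
  outer <- integer(0)
  for (l in 0:nz)
    outer <- c(outer, vapply(seq_len(nsec), gid_stat, integer(1), k = nK, l = l))
  # include outer duplicates
  outer <- c(outer, dup[master %in% outer])

  mesh <- structure(list(
    nodes = nodes, elem = elem, elem_cut = elem_cut, region = region,
    spec = spec, cut_released = FALSE,
    sets = list(bottom = bottom, top = top, outer = outer,
                cut_master = master, cut_dup = dup,
                n_primary = npp * (nz + 1)),
    materials = NULL, theta = NULL, axes = NULL
  ), class = "disc_mesh")
  mesh
}

# Local axes + ply angles for every element, from reference coordinates.
.attach_axes <- function(mesh) {
  ne <- nrow(mesh$elem)
  axes <- array(0, c(ne, 3, 3))
  for (e in seq_len(ne)) {
    ax <- local_material_axes(mesh$nodes[mesh$elem[e, ], , drop = FALSE])
    axes[e, , ] <- ax$T_xB
  }
  mesh$axes <- axes
  mesh
}

#' Build the bovine caudal disc cylinder mesh
#'
#' Concentric O-grid cylinder with the full radial region sequence
#' NP, NPtrans (1 element), IAF, AFtrans (1 element), OAF and a tied radial
#' cut plane at theta = 0 spanning the AF thickness and the full height.
#'
#' @param spec A `geometry_spec` with shape "bovine_cylinder" (default).
#' @return A `disc_mesh`.
#' @export
build_bovine_cylinder <- function(spec = geometry_spec("bovine_cylinder")) {
  if (spec$shape != "bovine_cylinder")
    stop("config error: spec shape is not bovine_cylinder")
  .attach_axes(.build_ogrid_cylinder(spec))
}

#' Build the parameterized human disc mesh
#'
#' The same O-grid topology as the bovine cylinder, scaled anisotropically
#' to an elliptical cross-section (left-right semi-axis = `outer_radius`,
#' anterior-posterior semi-axis = `outer_radius / aspect_ratio`). In the
#' circular limit (`aspect_ratio = 1`) it coincides with
#' [build_bovine_cylinder()] up to the spec label. The default dimensions
#' follow from requiring the preload area formula to return the packaged
#' 270 N dynamic preload (see [preload_from_lengths()]).
#'
#' @param spec A `geometry_spec` with shape "human_parametric" (default).
#' @return A `disc_mesh`.
#' @export
build_human_parametric <- function(spec = geometry_spec("human_parametric")) {
  if (spec$shape != "human_parametric")
    stop("config error: spec shape is not human_parametric")
  mesh <- .build_ogrid_cylinder(spec)
  mesh$nodes[, 2] <- mesh$nodes[, 2] / spec$aspect_ratio
  .attach_axes(mesh)
}

#' Assign per-region material parameters to a mesh
#'
#' Attaches a region -> `material_params` table and distributes the fiber
#' ply angle to every element (NA for fiber-free regions).
#'
#' @param mesh A `disc_mesh`.
#' @param table Named list of `material_params` covering every region label
#'   present in the mesh; default [default_material_table()].
#' @return The mesh with `materials` and `theta` populated.
#' @export
assign_region_params <- function(mesh, table = default_material_table()) {
  regions <- unique(mesh$region)
  missing <- setdiff(regions, names(table))
  if (length(missing) > 0)
    stop("config error: no material parameters for region(s) ",
         paste(missing, collapse = ", "))
  mesh$materials <- table
  mesh$theta <- unname(vapply(mesh$region, function(r) table[[r]]$theta, 0))
  mesh
}

#' Release the radial cut
#'
#' Unties the duplicated cut-plane node pairs: elements on the minus side of
#' the cut switch to the duplicate node ids, so the two cut faces become
#' independent degrees of freedom.
#'
#' @param mesh A `disc_mesh` with a cut plane.
#' @return The mesh with the cut released.
#' @export
release_cut <- function(mesh) {
  if (is.null(mesh$sets$cut_master) || length(mesh$sets$cut_master) == 0)
    stop("no cut plane defined")
  mesh$elem_tied <- mesh$elem
  mesh$elem <- mesh$elem_cut
  mesh$cut_released <- TRUE
  mesh
}

#' Re-tie the radial cut
#'
#' Inverse of [release_cut()]: restores the tied connectivity.
#' @param mesh A `disc_mesh` previously released.
#' @return The mesh with the cut re-tied.
#' @export
retie_cut <- function(mesh) {
  if (!isTRUE(mesh$cut_released)) stop("cut is not released")
  mesh$elem <- mesh$elem_tied
  mesh$elem_tied <- NULL
  mesh$cut_released <- FALSE
  mesh
}

#' Scaled Jacobian mesh quality at element centroids
#'
#' @param mesh A `disc_mesh`.
#' @return Numeric vector, one scaled Jacobian per element.
#' @export
mesh_quality <- function(mesh) {
  # trilinear map Jacobian at the centroid from the 8 corner positions
  dN <- matrix(c(-1, 1, 1, -1, -1, 1, 1, -1,
                 -1, -1, 1, 1, -1, -1, 1, 1,
                 -1, -1, -1, -1, 1, 1, 1, 1) / 8, 8, 3)
  vapply(seq_len(nrow(mesh$elem)), function(e) {
    X <- mesh$nodes[mesh$elem[e, ], , drop = FALSE]
    Jm <- t(X) %*% dN
    cn <- apply(Jm, 2, function(v) sqrt(sum(v^2)))
    det(Jm) / prod(cn)
  }, 0)
}

#' Element volumes of the reference mesh
#' @param mesh A `disc_mesh`.
#' @return Numeric vector of element volumes (mm^3).
#' @export
element_volumes <- function(mesh) {
  g <- 1 / sqrt(3)
  gp <- as.matrix(expand.grid(c(-g, g), c(-g, g), c(-g, g)))
  vapply(seq_len(nrow(mesh$elem)), function(e) {
    X <- mesh$nodes[mesh$elem[e, ], , drop = FALSE]
    v <- 0
    for (q in seq_len(8)) {
      xi <- gp[q, ]
      sgn <- matrix(c(-1, 1, 1, -1, -1, 1, 1, -1,
                      -1, -1, 1, 1, -1, -1, 1, 1,
                      -1, -1, -1, -1, 1, 1, 1, 1), 8, 3)
      dN <- sapply(1:3, function(d) {
        oth <- setdiff(1:3, d)
        sgn[, d] / 8 * (1 + sgn[, oth[1]] * xi[oth[1]]) *
          (1 + sgn[, oth[2]] * xi[oth[2]])
      })
      v <- v + det(t(X) %*% dN)
    }
    v
  }, 0)
}
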