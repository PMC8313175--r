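# Multigenerational fiber kinematics: local axes, ply directions, relative
# deformation gradients, fiber stretch, and the per-element field computation.

unit_cube_nodes <- function() {
  rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
        c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
}

test_that("local material axes of axis-aligned, rotated and sheared elements", {
  # a = n2 - n1 = x, d = n5 - n1 = z: e1 = x, e3 = (a x d)/|a x d| = -y,
  # e2 = e3 x e1 = z (the e1-e2 plane is the span of a and d)
  ax <- local_material_axes(unit_cube_nodes())
  expect_equal(ax$e1, c(1, 0, 0))
  expect_equal(ax$e2, c(0, 0, 1))
  expect_equal(ax$e3, c(0, -1, 0))
  expect_equal(det(ax$T_xB), 1, tolerance = 1e-12)
  # 90 degree rotation about z rotates e1 and e3; e2 stays axial
  Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  axr <- local_material_axes(unit_cube_nodes() %*% t(Rz))
  expect_equal(axr$e1, c(0, 1, 0))
  expect_equal(axr$e2, c(0, 0, 1))
  expect_equal(axr$e3, c(1, 0, 0))
  # sheared hexahedron: triad matches an independent Gram-Schmidt build
  set.seed(3)
  S <- diag(3) + matrix(runif(9, -0.2, 0.2), 3, 3)
  nodes <- unit_cube_nodes() %*% t(S)
  axs <- local_material_axes(nodes)
  a <- nodes[2, ] - nodes[1, ]
  d <- nodes[5, ] - nodes[1, ]
  e1 <- a / sqrt(sum(a^2))
  d_perp <- d - sum(d * e1) * e1           # Gram-Schmidt
  e2gs <- d_perp / sqrt(sum(d_perp^2))     # in-plane(a,d), orthogonal to a
  # e3 = a x d normalized is orthogonal to both; e2 = e3 x e1 lies in
  # span(a, d) and is orthogonal to e1, hence equals the Gram-Schmidt vector
  expect_equal(axs$e1, e1, tolerance = 1e-12)
  expect_equal(axs$e2, e2gs, tolerance = 1e-10)
  expect_equal(crossprod(axs$T_xB), diag(3), tolerance = 1e-10,
               ignore_attr = TRUE)
  # degenerate element: a parallel to d
  bad <- unit_cube_nodes()
  bad[5, ] <- bad[1, ] + 2 * (bad[2, ] - bad[1, ])
  expect_error(local_material_axes(bad), "degenerate")
})

test_that("global fiber directions from ply angle and sign", {
  # identity axes: the ply vector is (cos theta, sin theta, 0) verbatim
  axid <- structure(list(e1 = c(1, 0, 0), e2 = c(0, 1, 0), e3 = c(0, 0, 1),
                         T_xB = diag(3)), class = "local_axes")
  expect_equal(fiber_direction_global(axid, 0, 1), c(1, 0, 0))
  expect_equal(fiber_direction_global(axid, 90, 1), c(0, 1, 0),
               tolerance = 1e-12)
  expect_equal(fiber_direction_global(axid, 90, -1), c(0, -1, 0),
               tolerance = 1e-12)
  v <- fiber_direction_global(axid, 31, 1)
  expect_equal(v, c(cos(31 * pi / 180), sin(31 * pi / 180), 0),
               tolerance = 1e-12)
  expect_equal(sum(v^2), 1, tolerance = 1e-12)
  # cube axes: theta measured from e1 toward e2 (= z for the unit cube)
  ax <- local_material_axes(unit_cube_nodes())
  expect_equal(fiber_direction_global(ax, 90, 1), c(0, 0, 1),
               tolerance = 1e-12)
  th <- 31 * pi / 180
  expect_equal(fiber_direction_global(ax, 31, 1),
               c(cos(th), 0, sin(th)), tolerance = 1e-12)
})

test_that("relative deformation gradient between instants", {
  F_t <- diag(c(1.2, 1, 1))
  F_u <- diag(c(1.1, 1, 1))
  expect_equal(relative_deformation(F_t, F_t), diag(3))
  expect_equal(relative_deformation(F_t, diag(3)), F_t)
  expect_equal(relative_deformation(F_t, F_u), diag(c(1.2 / 1.1, 1, 1)),
               tolerance = 1e-12)
  expect_error(relative_deformation(F_t, diag(c(-1, 1, 1))), "inverted")
})

test_that("fiber stretch through the relative gradient", {
  expect_equal(fiber_stretch(diag(3), c(1, 0, 0)), 1)
  expect_equal(fiber_stretch(diag(c(1.1, 1, 1)), c(1, 0, 0)), 1.1)
  # simple shear, fiber at 45 degrees: explicit C construction
  g <- 0.2
  F <- diag(3); F[1, 2] <- g
  v <- c(1, 1, 0) / sqrt(2)
  C <- t(F) %*% F
  expect_equal(fiber_stretch(F, v), sqrt(drop(t(v) %*% C %*% v)),
               tolerance = 1e-14)
})

test_that("direction push-forward to the deposition configuration", {
  v0 <- c(1, 0, 0)
  expect_equal(map_direction_to_deposition(diag(3), v0), v0)
  expect_equal(map_direction_to_deposition(2 * diag(3), v0), v0)
  th <- 20 * pi / 180
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
               3, 3, byrow = TRUE)
  expect_equal(map_direction_to_deposition(Rz, v0), drop(Rz %*% v0),
               tolerance = 1e-12)
})

test_that("fiber field: deposition instant, mirror symmetry, classical limit", {
  mesh <- assign_region_params(build_bovine_cylinder(tiny_bovine_spec()))
  ne <- nrow(mesh$elem)
  gens <- time_zero_generations(mesh)
  # deposition instant: F_t equal to the deposition gradients -> lambda = 1
  Fid <- array(0, c(ne, 3, 3))
  Fid[, 1, 1] <- Fid[, 2, 2] <- Fid[, 3, 3] <- 1
  ff <- compute_fiber_field(Fid, gens, mesh)
  expect_equal(ff$lambda_n, rep(1, nrow(ff)))
  expect_equal(ff$sigma_n, rep(0, nrow(ff)))
  expect_true(all(ff$region %in% c("OAF", "AFtrans", "IAF", "NPtrans")))
  # uniform axial compression: the +/- theta sets share identical stretches
  Fc <- Fid; Fc[, 3, 3] <- 0.9
  ffc <- compute_fiber_field(Fc, gens, mesh)
  g1 <- ffc[ffc$generation == 1, ]
  g2 <- ffc[ffc$generation == 2, ]
  expect_equal(g1$lambda_n, g2$lambda_n, tolerance = 1e-12)
  # stretch along the fiber engages stress consistent with the 1d law
  Ft <- Fid; Ft[, 1, 1] <- 1.05; Ft[, 2, 2] <- 1.05; Ft[, 3, 3] <- 1.05
  fft <- compute_fiber_field(Ft, gens, mesh)
  expect_equal(fft$lambda_n, rep(1.05, nrow(fft)), tolerance = 1e-12)
  oaf_rows <- fft$region == "OAF" & fft$generation == 1
  expect_equal(fft$sigma_n[oaf_rows],
               rep(fiber_stress_1d(1.05, mesh$materials$OAF),
                   sum(oaf_rows)), tolerance = 1e-12)
  # slack wherever lambda <= 1
  Fs <- Fid; Fs[, 1, 1] <- 0.95; Fs[, 2, 2] <- 0.95; Fs[, 3, 3] <- 0.95
  ffs <- compute_fiber_field(Fs, gens, mesh)
  expect_true(all(ffs$sigma_n == 0))
  # missing generation coverage is a configuration error
  short <- gens[[1]]
  short$F_at_deposition <- short$F_at_deposition[1:2, , , drop = FALSE]
  short$v_dep <- short$v_dep[1:2, , drop = FALSE]
  expect_error(compute_fiber_field(Fid, list(short), mesh), "configuration")
})

test_that("torsion stretches the aligned ply and buckles the opposing one", {
  mesh <- assign_region_params(build_bovine_cylinder(tiny_bovine_spec()))
  ne <- nrow(mesh$elem)
  gens <- time_zero_generations(mesh)
  # kinematic twist field: rotation per unit height about z
  H <- mesh$spec$height
  phi <- 10 * pi / 180 / H    # strong twist rate so engagement is clear
  Ft <- array(0, c(ne, 3, 3))
  for (e in seq_len(ne)) {
    ctr <- colMeans(mesh$nodes[mesh$elem[e, ], , drop = FALSE])
    # F for u = phi * z * (e_z x x): grad adds phi*(dz-direction) terms
    F <- diag(3)
    F[1, 3] <- -phi * ctr[2]
    F[2, 3] <- phi * ctr[1]
    Ft[e, , ] <- F
  }
  ff <- compute_fiber_field(Ft, gens, mesh)
  af <- ff$region %in% c("OAF", "IAF", "AFtrans")
  m1 <- mean(ff$lambda_n[af & ff$generation == 1])
  m2 <- mean(ff$lambda_n[af & ff$generation == 2])
  # one family stretches, the opposing one buckles on average
  expect_true((m1 > 1 & m2 < 1) || (m2 > 1 & m1 < 1))
})
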