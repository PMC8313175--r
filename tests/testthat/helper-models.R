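# Shared test helpers: tiny meshes, random admissible deformations, and
# finite-difference oracles for the constitutive laws.

# single-hex mesh (unit cube scaled) behaving like a disc_mesh
single_element_mesh <- function(region = "NP", L = 1,
                                table = default_material_table()) {
  nodes <- rbind(c(0, 0, 0), c(L, 0, 0), c(L, L, 0), c(0, L, 0),
                 c(0, 0, L), c(L, 0, L), c(L, L, L), c(0, L, L))
  mesh <- structure(list(
    nodes = nodes, elem = matrix(1:8, 1, 8), region = region,
    spec = list(height = L, outer_radius = L),
    sets = list(top = 5:8, bottom = 1:4),
    materials = table,
    theta = table[[region]]$theta,
    axes = array(diag(3), c(1, 3, 3)),
    cut_released = FALSE
  ), class = "disc_mesh")
  mesh
}

# small bovine cylinder for fast solver tests
tiny_bovine_spec <- function() {
  geometry_spec("bovine_cylinder", n_sectors = 8, n_np_rings = 1,
                n_iaf_rings = 1, n_oaf_rings = 1, n_axial = 2)
}

# random admissible deformation gradient (moderate strain, positive J)
random_F <- function() {
  repeat {
    F <- diag(3) + matrix(stats::runif(9, -0.15, 0.15), 3, 3)
    if (det(F) > 0.3) return(F)
  }
}

random_rotation <- function() {
  A <- matrix(stats::rnorm(9), 3, 3)
  qr_d <- qr(A)
  Q <- qr.Q(qr_d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Cauchy stress from an energy density W(F) by central finite differences:
# P_ij = dW/dF_ij, sigma = P F^T / J
fd_cauchy_from_energy <- function(W, F, h = 1e-6) {
  P <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    Fp <- F; Fp[i, j] <- Fp[i, j] + h
    Fm <- F; Fm[i, j] <- Fm[i, j] - h
    P[i, j] <- (W(Fp) - W(Fm)) / (2 * h)
  }
  P %*% t(F) / det(F)
}

# dof helper mirroring the solver's layout
dofs_of <- function(nodes, comps = 1:3) {
  as.vector(t(outer(3 * (nodes - 1), comps, `+`)))
}
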