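# Equilibrium solver: trivial and patch consistency, swelling balance,
# energy conservation, determinism, release/incision behavior on
# residual-free bodies, and multigen neutrality.

confined_bc <- function(mesh, top_free_z = TRUE) {
  nd <- nrow(mesh$nodes)
  fixed <- rep(FALSE, 3 * nd)
  fixed[dofs_of(1:nd, 1:2)] <- TRUE          # lateral confinement
  fixed[dofs_of(mesh$sets$bottom, 3)] <- TRUE
  if (!top_free_z) fixed[dofs_of(mesh$sets$top, 3)] <- TRUE
  fixed
}

test_that("zero loads and zero swelling give the trivial equilibrium", {
  mesh <- single_element_mesh("NP")
  st <- model_state(mesh)
  fixed <- confined_bc(mesh)
  out <- equilibrium_solve(mesh, st, fixed)
  expect_equal(max(abs(out$u)), 0)
  expect_true(out$converged)
})

test_that("single-element prescribed stretch matches the material law", {
  mesh <- single_element_mesh("OAF")
  st <- model_state(mesh)
  lam <- 0.97
  fixed <- confined_bc(mesh, top_free_z = FALSE)
  uval <- numeric(24)
  uval[dofs_of(mesh$sets$top, 3)] <- lam - 1
  out <- equilibrium_solve(mesh, st, fixed, uval)
  # reaction on the top face equals Cauchy stress times deformed area
  a <- resdisc:::.assemble(mesh, out, FALSE, solver_options())
  Fz <- sum(a$f[dofs_of(mesh$sets$top, 3)])
  sig <- holmes_mow_stress(diag(c(1, 1, lam)),
                           default_material_table()$OAF)[3, 3]
  expect_equal(Fz, sig * 1, tolerance = 1e-9)   # deformed area = 1 x 1
})

test_that("two-element column under force control is in a uniform state", {
  # stack two unit elements; free lateral faces; axial force via border
  tab <- default_material_table()
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
                 c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1),
                 c(0, 0, 2), c(1, 0, 2), c(1, 1, 2), c(0, 1, 2))
  mesh <- structure(list(
    nodes = nodes, elem = rbind(1:8, 5:12), region = c("NP", "NP"),
    spec = list(height = 2, outer_radius = 1),
    sets = list(top = 9:12, bottom = 1:4),
    materials = tab, theta = c(NA_real_, NA_real_),
    axes = array(rep(diag(3), each = 2), c(2, 3, 3)),
    cut_released = FALSE), class = "disc_mesh")
  st <- model_state(mesh)
  nd <- nrow(nodes)
  fixed <- rep(FALSE, 3 * nd)
  fixed[dofs_of(mesh$sets$bottom, 3)] <- TRUE
  # pin in-plane rigid modes only
  fixed[dofs_of(1, 1:2)] <- TRUE
  fixed[dofs_of(2, 2)] <- TRUE
  load <- -0.02   # compressive axial force (N)
  out <- equilibrium_solve(mesh, st, fixed,
                           border = list(dofs = dofs_of(9:12, 3), load = load))
  S <- state_cauchy_stress(mesh, out)
  # both elements share one uniform stress tensor
  expect_equal(S[1, , ], S[2, , ], tolerance = 1e-8)
  # lateral components vanish (free faces), axial equals load/deformed area
  expect_equal(S[1, 1, 1], 0, tolerance = 1e-8)
  expect_equal(S[1, 2, 2], 0, tolerance = 1e-8)
  Fm <- state_deformation_gradients(mesh, out)[1, , ]
  area <- det(Fm) / Fm[3, 3]
  expect_equal(S[1, 3, 3], load / area, tolerance = 1e-7)
})

test_that("confined single-element swelling matches the scalar balance", {
  for (reg in c("NP", "OAF")) {
    mesh <- single_element_mesh(reg)
    st <- model_state(mesh)
    fixed <- confined_bc(mesh)
    for (a in seq(0.25, 1, by = 0.25)) {
      st$alpha <- a
      st <- equilibrium_solve(mesh, st, fixed)
    }
    lz <- 1 + st$u[dofs_of(5, 3)]
    p <- default_material_table()[[reg]]
    env <- disc_environment()
    bal <- function(l) {
      holmes_mow_stress(deformation_state(diag(c(1, 1, l))), p)[3, 3] -
        donnan_pressure(fixed_charge_density(l, p), env)
    }
    lz_oracle <- uniroot(bal, c(1, 5), tol = 1e-14)$root
    expect_equal(lz, lz_oracle, tolerance = 1e-6)
  }
})

test_that("swelling with zero fixed charge is the identity state", {
  tab <- default_material_table()
  tab <- lapply(tab, function(p) { p$c0F <- 0; p })
  mesh <- assign_region_params(build_bovine_cylinder(tiny_bovine_spec()), tab)
  st <- model_state(mesh)
  st <- activate_time_zero_fibers(mesh, st)
  st <- swell_to_equilibrium(mesh, st, nsub = 2)
  expect_equal(max(abs(st$u)), 0, tolerance = 1e-10)
})

test_that("external work equals stored energy on a drained elastic path", {
  mesh <- single_element_mesh("NP")
  tab <- default_material_table()
  p <- tab$NP
  st <- model_state(mesh)
  st$alpha <- 0                      # pure elastic path, no osmotic term
  fixed <- confined_bc(mesh, top_free_z = FALSE)
  lam_end <- 0.9
  nstep <- 40
  W_ext <- 0
  F_prev <- 0
  for (k in seq_len(nstep)) {
    lam <- 1 + k / nstep * (lam_end - 1)
    uval <- numeric(24)
    uval[dofs_of(mesh$sets$top, 3)] <- lam - 1
    st <- equilibrium_solve(mesh, st, fixed, uval)
    a <- resdisc:::.assemble(mesh, st, FALSE, solver_options())
    F_now <- sum(a$f[dofs_of(mesh$sets$top, 3)])
    W_ext <- W_ext + 0.5 * (F_prev + F_now) * (lam_end - 1) / nstep
    F_prev <- F_now
  }
  W_stored <- holmes_mow_energy(diag(c(1, 1, lam_end)), p) * 1  # V0 = 1
  expect_equal(W_ext, W_stored, tolerance = 0.01)
})

test_that("identical configurations produce bit-identical results", {
  run_once <- function() {
    mesh <- assign_region_params(build_bovine_cylinder(tiny_bovine_spec()))
    st <- model_state(mesh)
    st <- activate_time_zero_fibers(mesh, st)
    st <- swell_to_equilibrium(mesh, st, nsub = 3)
    st$u
  }
  expect_identical(run_once(), run_once())
})

test_that("release and incision of a residual-free body do nothing", {
  mesh <- assign_region_params(build_bovine_cylinder(tiny_bovine_spec()))
  st <- model_state(mesh)          # unswollen, fiber-free: no stored energy
  st <- release_platens(mesh, st, nsub = 1)
  expect_equal(max(abs(st$u)), 0, tolerance = 1e-9)
  cut <- simulate_incision(mesh, st, nsub = 1)
  expect_equal(opening_gap(cut$mesh, cut$state), 0, tolerance = 1e-8)
})

test_that("multigen deposition at the unswollen neutral state is exact", {
  # Omega = 0 deposition on the undeformed disc: generation snapshots are
  # identity, so the multigen machinery must reproduce the classical
  # time-zero fiber model exactly through the subsequent swelling
  mesh <- assign_region_params(build_bovine_cylinder(tiny_bovine_spec()))
  st0 <- model_state(mesh)
  stm <- run_multigen_deposition(mesh, st0, Omega = 0, nsub_twist = 1,
                                 nsub_ramp = 2)
  # deposited generations: lambda = 1 in every element, exactly
  Ft <- state_deformation_gradients(mesh, stm)
  ff <- compute_fiber_field(Ft, stm$generations, mesh)
  expect_equal(max(abs(ff$lambda_n - 1)), 0, tolerance = 1e-13)
  # now swell both models identically
  stm <- swell_to_equilibrium(mesh, stm, nsub = 3)
  sts <- activate_time_zero_fibers(mesh, model_state(mesh))
  sts <- swell_to_equilibrium(mesh, sts, nsub = 3)
  expect_equal(stm$u, sts$u, tolerance = 1e-10)
})

test_that("deposited generations have unit stretch at their twist state", {
  mesh <- assign_region_params(build_bovine_cylinder(tiny_bovine_spec()))
  st <- model_state(mesh)
  st <- swell_to_equilibrium(mesh, st, nsub = 5)
  st <- run_multigen_deposition(mesh, st, Omega = 2, nsub_twist = 2,
                                nsub_ramp = 3)
  # each generation's own snapshot: lambda = 1 by construction (exact)
  for (g in st$generations) {
    ff <- compute_fiber_field(g$F_at_deposition, list(g), mesh)
    expect_equal(max(abs(ff$lambda_n - 1)), 0, tolerance = 1e-12)
  }
  # after return to neutral and modulus ramp both families exist
  expect_length(st$generations, 2)
  expect_equal(vapply(st$generations, `[[`, 0, "modulus_scale"), c(1, 1))
})

test_that("torsion of a symmetric disc gives an antisymmetric torque", {
  mesh <- assign_region_params(build_bovine_cylinder(tiny_bovine_spec()))
  st <- model_state(mesh)
  st <- activate_time_zero_fibers(mesh, st)
  st <- swell_to_equilibrium(mesh, st, nsub = 5)
  plus <- run_test_case(mesh, st, "torsion", n_points = 2, max_rotation = 1)
  minus <- run_test_case(mesh, st, "torsion", n_points = 2, max_rotation = -1)
  expect_equal(plus$curve$response, -minus$curve$response, tolerance = 1e-6)
  # zero-load slow ramp on an unloaded, unswollen disc: zero displacement
  st0 <- model_state(mesh)
  ramp0 <- run_test_case(mesh, st0, "slow_ramp", n_points = 2, max_load = 0)
  expect_equal(ramp0$curve$response, c(0, 0), tolerance = 1e-9)
})

test_that("preload in force control balances the applied axial load", {
  mesh <- assign_region_params(build_bovine_cylinder(tiny_bovine_spec()))
  st <- model_state(mesh)
  st <- activate_time_zero_fibers(mesh, st)
  st <- swell_to_equilibrium(mesh, st, nsub = 5)
  expect_identical(apply_preload(mesh, st, 0), st)
  st2 <- apply_preload(mesh, st, 5, nsub = 2)
  a <- resdisc:::.assemble(mesh, st2, FALSE, solver_options())
  topz <- dofs_of(mesh$sets$top, 3)
  expect_equal(sum(a$f[topz]), -5, tolerance = 1e-6)
  # a heavier preload settles the platen lower than a lighter one
  st3 <- apply_preload(mesh, st, 20, nsub = 2)
  expect_lt(st3$platen$dz, st2$platen$dz)
  # compressive axial Cauchy stress throughout the NP under load
  S <- state_cauchy_stress(mesh, st3)
  np <- which(mesh$region == "NP")
  expect_true(all(S[np, 3, 3] < 0))
})
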