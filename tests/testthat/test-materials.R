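# Constitutive laws: Lame conversion, Holmes-Mow matrix, Neo-Hookean,
# permeability, Donnan swelling, and the toe-region power-law fiber.

test_that("Lame parameters from engineering constants", {
  expect_equal(lame_from_engineering(1, 0), list(lambda = 0, mu = 0.5))
  # NP and OAF rows of the default table, frozen from direct substitution
  np <- lame_from_engineering(0.065, 0.24)
  expect_equal(np$lambda, 0.065 * 0.24 / (1.24 * 0.52), tolerance = 1e-12)
  expect_equal(np$lambda, 0.0241935, tolerance = 1e-5)
  expect_equal(np$mu, 0.0262097, tolerance = 1e-5)
  oaf <- lame_from_engineering(0.018, 0.24)
  expect_equal(oaf$lambda, 0.0066997, tolerance = 1e-4)
  expect_equal(oaf$mu, 0.0072581, tolerance = 1e-4)
  expect_error(lame_from_engineering(1, 0.5), "invalid parameter")
  expect_error(lame_from_engineering(1, -1), "invalid parameter")
  expect_error(lame_from_engineering(-1, 0.3), "invalid parameter")
})

test_that("deformation state invariants are consistent with F", {
  set.seed(11)
  for (k in 1:20) {
    F <- random_F()
    s <- deformation_state(F)
    C <- t(F) %*% F
    expect_equal(s$J, det(F), tolerance = 1e-12)
    expect_equal(s$I1, sum(diag(C)), tolerance = 1e-12)
    expect_equal(s$I2, 0.5 * (sum(diag(C))^2 - sum(C * C)), tolerance = 1e-12)
  }
  expect_error(deformation_state(diag(c(-1, 1, 1))), "inverted")
})

test_that("Holmes-Mow energy: reference value, objectivity, known state", {
  tab <- default_material_table()
  expect_equal(holmes_mow_energy(diag(3), tab$NP), 0)
  set.seed(2)
  F <- random_F()
  R <- random_rotation()
  expect_equal(holmes_mow_energy(R %*% F, tab$NP),
               holmes_mow_energy(F, tab$NP), tolerance = 1e-12)
  # independent scalar evaluation at a simple stretch state
  p <- tab$NP
  lm <- lame_from_engineering(p$E_m, p$nu)
  lam <- lm$lambda; mu <- lm$mu
  F1 <- diag(c(1.05, 1, 1))
  I1 <- 1.05^2 + 2; I2 <- 2 * 1.05^2 + 1; J <- 1.05
  Q <- p$beta_m * ((2 * mu - lam) * (I1 - 3) + lam * (I2 - 3) -
                     (lam + 2 * mu) * log(J^2)) / (lam + 2 * mu)
  Wref <- (lam + 2 * mu) / (4 * p$beta_m) * (exp(Q) - 1)
  expect_equal(holmes_mow_energy(F1, p), Wref, tolerance = 1e-12)
})

test_that("Holmes-Mow stress: zero at reference, objective, energy-consistent", {
  tab <- default_material_table()
  for (reg in c("NP", "OAF", "CEP")) {
    p <- tab[[reg]]
    expect_equal(holmes_mow_stress(diag(3), p), matrix(0, 3, 3),
                 tolerance = 1e-14)
    set.seed(5)
    R <- random_rotation()
    expect_equal(max(abs(holmes_mow_stress(R, p))), 0, tolerance = 1e-12)
    F <- diag(c(1.05, 1, 1))
    sig <- holmes_mow_stress(F, p)
    expect_equal(sig, t(sig))
    fd <- fd_cauchy_from_energy(function(Fx) holmes_mow_energy(Fx, p), F)
    expect_equal(sig, fd, tolerance = 1e-5)
    # objectivity at a generic state
    F <- random_F()
    R <- random_rotation()
    expect_equal(holmes_mow_stress(R %*% F, p),
                 R %*% holmes_mow_stress(F, p) %*% t(R), tolerance = 1e-10)
  }
})

test_that("Neo-Hookean stress: reference, linearization, energy consistency", {
  expect_equal(neo_hookean_stress(diag(3), 10000, 0.3), matrix(0, 3, 3))
  # small-strain limit matches linear elasticity
  E <- 10000; nu <- 0.3
  lm <- lame_from_engineering(E, nu)
  eps <- 1e-6
  F <- diag(c(1 + eps, 1, 1))
  sig <- neo_hookean_stress(F, E, nu)
  lin <- lm$lambda * eps * diag(3) + 2 * lm$mu * diag(c(eps, 0, 0))
  expect_equal(sig, lin, tolerance = 1e-3)
  # finite-difference consistency at a finite strain
  F <- diag(c(1.01, 1, 1))
  fd <- fd_cauchy_from_energy(function(Fx) neo_hookean_energy(Fx, E, nu), F)
  expect_equal(neo_hookean_stress(F, E, nu), fd, tolerance = 1e-5)
})

test_that("strain-dependent permeability", {
  oaf <- default_material_table()$OAF
  expect_equal(permeability(1, oaf), oaf$k0)
  expect_equal(permeability(1.2, oaf),
               0.0047 * ((1.2 - 0.3) / 0.7)^2 * exp(5.75 * (1.2^2 - 1) / 2),
               tolerance = 1e-12)
  expect_equal(permeability(1.2, oaf), 0.02753, tolerance = 1e-3)
  expect_lt(permeability(0.9, oaf), oaf$k0)
  Js <- seq(0.5, 2, by = 0.05)
  expect_true(all(diff(permeability(Js, oaf)) > 0))
  expect_error(permeability(0.2, oaf), "pore collapse")
})

test_that("fixed charge density dilution", {
  np <- default_material_table()$NP
  expect_equal(fixed_charge_density(1, np), np$c0F)
  p <- material_params("NP", 0.065, 0.24, 0.95, 0.00056, 3.79, 379,
                       phi0_s = 0.2)
  expect_equal(fixed_charge_density(2, p), 0.8 / 1.8 * 379, tolerance = 1e-12)
  expect_equal(fixed_charge_density(2, p), 168.4, tolerance = 1e-3)
  Js <- seq(0.5, 4, by = 0.1)
  expect_true(all(diff(fixed_charge_density(Js, np)) < 0))
  expect_lt(fixed_charge_density(1e6, np), 1e-2)
  expect_error(fixed_charge_density(0.1, np), "invalid deformation")
})

test_that("Donnan osmotic pressure", {
  env <- disc_environment()
  expect_equal(donnan_pressure(0, env), 0)
  env0 <- disc_environment(bath_osmolarity = 0)
  cf <- c(10, 100, 379)
  expect_equal(donnan_pressure(cf, env0),
               8.314462618 * 310 * cf * 1e-6, tolerance = 1e-12)
  # NP reference fixed charge in a 300 mOsm/L bath at body temperature
  expect_equal(donnan_pressure(379, env),
               8.314462618 * 310 * (sqrt(379^2 + 300^2) - 300) * 1e-6,
               tolerance = 1e-12)
  expect_equal(donnan_pressure(379, env), 0.47, tolerance = 0.01)
  cfs <- seq(0, 500, by = 10)
  expect_true(all(diff(donnan_pressure(cfs, env)) > 0))
  expect_error(donnan_pressure(-1, env), "invalid input")
})

test_that("fiber energy: slack, toe, continuity at both branch points", {
  oaf <- default_material_table()$OAF
  expect_equal(fiber_energy(0.95, oaf), 0)
  expect_equal(fiber_energy(1, oaf), 0)
  # continuity at the transition stretch: toe value equals Psi0
  l0 <- oaf$lambda0
  I0 <- l0^2
  psi0 <- oaf$E_f / (4 * oaf$beta_f * (oaf$beta_f - 1)) * (I0 - 1)^2
  expect_equal(fiber_energy(l0, oaf), psi0, tolerance = 1e-14)
  expect_equal(fiber_energy(l0 + 1e-12, oaf), psi0, tolerance = 1e-8)
  # toe-branch value at lambda = 1.02 against independent evaluation
  In <- 1.02^2
  wref <- oaf$E_f / (4 * oaf$beta_f * (oaf$beta_f - 1)) *
    (I0 - 1)^(2 - oaf$beta_f) * (In - 1)^oaf$beta_f
  expect_equal(fiber_energy(1.02, oaf), wref, tolerance = 1e-12)
  # fiber-free regions carry no fiber energy
  expect_equal(fiber_energy(1.2, default_material_table()$NP), 0)
})

test_that("fiber stress: derivative of energy, continuous, nondecreasing", {
  tab <- default_material_table()
  for (reg in c("OAF", "IAF", "NPtrans")) {
    p <- tab[[reg]]
    expect_equal(fiber_stress_1d(0.95, p), 0)
    expect_equal(fiber_stress_1d(1, p), 0)
    # C0 at both branch points
    expect_equal(fiber_stress_1d(1 + 1e-9, p), 0, tolerance = 1e-6)
    l0 <- p$lambda0
    expect_equal(fiber_stress_1d(l0 - 1e-9, p), fiber_stress_1d(l0 + 1e-9, p),
                 tolerance = 1e-6)
    # sigma = dPsi/dlambda away from branch points
    h <- 1e-7
    for (lam in c(1.01, (1 + l0) / 2, l0 * 1.05, l0 * 1.5)) {
      fd <- (fiber_energy(lam + h, p) - fiber_energy(lam - h, p)) / (2 * h)
      expect_equal(fiber_stress_1d(lam, p), fd, tolerance = 1e-5)
    }
    lams <- seq(1, 1.3, by = 0.002)
    expect_true(all(diff(fiber_stress_1d(lams, p)) >= 0))
  }
  # linear branch has slope E_f
  oaf <- tab$OAF
  s1 <- fiber_stress_1d(1.10, oaf)
  s2 <- fiber_stress_1d(1.12, oaf)
  expect_equal((s2 - s1) / 0.02, oaf$E_f, tolerance = 1e-9)
})

test_that("total Cauchy stress assembles matrix, fiber and Donnan terms", {
  tab <- default_material_table()
  env <- disc_environment()
  # identity, no fixed charge, slack fibers -> zero
  p0 <- material_params("OAF", 0.018, 0.24, 3.4, 0.0047, 5.75, 0,
                        E_f = 15.6, lambda0 = 1.028, theta = 31, beta_f = 4)
  sig <- total_cauchy_stress(diag(3),
                             list(list(stretch = 0.9, direction = c(1, 0, 0))),
                             p0, env)
  expect_equal(sig, matrix(0, 3, 3))
  # identity with fixed charge -> isotropic compression -pi I
  np <- tab$NP
  sig <- total_cauchy_stress(diag(3), list(), np, env)
  expect_equal(sig, -donnan_pressure(np$c0F, env) * diag(3), tolerance = 1e-12)
  # uniaxial stretch along a single fiber: matrix + rank-one fiber term
  oaf <- tab$OAF
  lam <- 1.05
  F <- diag(c(lam, 1, 1))
  m <- c(1, 0, 0)
  sig <- total_cauchy_stress(F, list(list(stretch = lam, direction = m)),
                             oaf, env, swelling_activation = 0)
  expected <- holmes_mow_stress(F, oaf) +
    lam * fiber_stress_1d(lam, oaf) / det(F) * tcrossprod(m)
  expect_equal(sig, expected, tolerance = 1e-12)
  expect_equal(sig, t(sig))
})
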