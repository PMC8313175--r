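# One-dimensional transient biphasic consolidation: a confined column of
# Holmes-Mow solid with strain-dependent hydraulic permeability, loaded by a
# step traction on a free-draining top surface over an impermeable base.
# This is the reduced-dimension engine that exercises the transport law in a
# time-accurate setting; the organ-scale protocols are drained equilibria.
#
# Weak form (Lagrangian, linear elements, backward Euler):
#   int sigma_e(lambda) w' dZ - int p w' dZ = -sigma0 w(top)
#   int (lambda^{n+1} - lambda^n)/dt q dZ + int k(J) p' q' dZ = 0
# with lambda = 1 + u', J = lambda, u(0) = 0, p(top) = 0.

# uniaxial-strain (confined) Holmes-Mow axial Cauchy stress for
# F = diag(1, 1, l); closed-form scalar, vectorized in l
.hm_confined_stress <- function(lz, params) {
  lm <- lame_from_engineering(params$E_m, params$nu)
  lam <- lm$lambda; mu <- lm$mu
  hA <- lam + 2 * mu
  bm <- params$beta_m
  I1 <- 2 + lz^2
  I2 <- 1 + 2 * lz^2
  Q <- ((2 * mu - lam) * (I1 - 3) + lam * (I2 - 3) - hA * log(lz^2)) / hA
  exp(bm * Q) / (2 * lz) *
    ((2 * mu - lam + lam * I1) * lz^2 - lam * lz^4 - hA)
}

#' Terzaghi consolidation ratio
#'
#' Average degree of consolidation `U(Tv)` of the classical linear
#' consolidation problem (single drainage path), by series summation.
#'
#' @param Tv Dimensionless time factor `cv t / h^2` (vectorized).
#' @param n_terms Series terms.
#' @return Degree of consolidation in `[0, 1]`.
#' @export
terzaghi_consolidation_ratio <- function(Tv, n_terms = 200) {
  vapply(Tv, function(tv) {
    m <- 0:(n_terms - 1)
    M <- pi * (2 * m + 1) / 2
    1 - sum(2 / M^2 * exp(-M^2 * tv))
  }, 0)
}

#' Transient confined consolidation of a tissue column
#'
#' Implicit time integration of the coupled displacement-pressure system for
#' a confined column with Holmes-Mow elasticity and strain-dependent
#' permeability, under a step compressive traction applied at the
#' free-draining top; the bottom is fixed and impermeable. Converges to the
#' drained (fully consolidated) elastic solution as t grows. Osmotic
#' swelling is not active in the column (the transport benchmark isolates
#' the seepage physics).
#'
#' @param params A `material_params` (its `E_m`, `nu`, `beta_m`, `k0`, `M`,
#'   `phi0_s` are used).
#' @param height Column height (mm).
#' @param load Applied compressive traction magnitude (MPa).
#' @param times Output times (s), strictly increasing.
#' @param n_elem Number of column elements.
#' @param grade Mesh grading exponent toward the draining surface (1 = uniform).
#' @param n_substeps Implicit substeps inserted between consecutive output
#'   times.
#' @return List: `times`, `settlement` (mm, positive down), `pressure`
#'   (matrix, node x time), `z` (node coordinates), `drained_settlement`.
#' @export
transient_confined_consolidation <- function(params, height = 1, load = 0.001,
                                             times = NULL, n_elem = 60,
                                             grade = 2, n_substeps = 4) {
  L <- height
  if (is.null(times)) {
    lm <- lame_from_engineering(params$E_m, params$nu)
    cv <- params$k0 * (lm$lambda + 2 * lm$mu)
    tref <- L^2 / cv
    times <- tref * 10^seq(-2.5, 0.5, length.out = 25)
  }
  # node coordinates, graded toward the top (draining) surface
  s <- seq(0, 1, length.out = n_elem + 1)
  z <- L * (1 - (1 - s)^grade)
  nn <- n_elem + 1
  hs <- diff(z)

  sig_e <- function(lam) .hm_confined_stress(lam, params)
  dsig <- function(lam) {
    h <- 1e-7
    (sig_e(lam + h) - sig_e(lam - h)) / (2 * h)
  }
  kfun <- function(J) permeability(J, params)
  dkfun <- function(J) {
    h <- 1e-7
    (kfun(J + h) - kfun(J - h)) / (2 * h)
  }

  # unknowns x = c(u[2..nn], p[1..nn-1]); u(bottom) = 0, p(top) = 0
  nu_f <- nn - 1
  unpack <- function(x) {
    list(u = c(0, x[seq_len(nu_f)]), p = c(x[nu_f + seq_len(nu_f)], 0))
  }
  residual <- function(x, lam_old, dt) {
    w <- unpack(x)
    lam <- 1 + diff(w$u) / hs
    pm <- (w$p[-nn] + w$p[-1]) / 2
    tot <- sig_e(lam) - pm
    dl <- (lam - lam_old) / dt
    k <- kfun(lam)
    g <- diff(w$p) / hs
    ru <- c(-tot, 0) + c(0, tot)
    ru[nn] <- ru[nn] + load
    rp <- c(dl * hs / 2, 0) + c(0, dl * hs / 2) +
      c(-k * g, 0) + c(0, k * g)
    c(ru[-1], rp[-nn])
  }
  # analytic Jacobian (element-wise chain rule on the same expressions)
  jac <- function(x, lam_old, dt) {
    w <- unpack(x)
    lam <- 1 + diff(w$u) / hs
    k <- kfun(lam)
    dk <- dkfun(lam)
    ds <- dsig(lam)
    g <- diff(w$p) / hs
    n <- 2 * nu_f
    J <- matrix(0, n, n)
    iu <- function(node) if (node >= 2) node - 1 else 0       # u unknown col
    ip <- function(node) if (node <= nn - 1) nu_f + node else 0
    ru_row <- function(node) if (node >= 2) node - 1 else 0
    rp_row <- function(node) if (node <= nn - 1) nu_f + node else 0
    add <- function(r, c, v) if (r > 0 && c > 0) J[r, c] <<- J[r, c] + v
    for (e in seq_len(n_elem)) {
      dl_du <- 1 / hs[e]                       # dlam/du_{e+1}; -1/hs for u_e
      # momentum rows: ru[e] -= tot_e ; ru[e+1] += tot_e
      for (pair in list(c(e, -1), c(e + 1, 1))) {
        r <- ru_row(pair[1]); sgn <- pair[2]
        add(r, iu(e + 1), sgn * ds[e] * dl_du)
        add(r, iu(e),    -sgn * ds[e] * dl_du)
        add(r, ip(e),     sgn * (-0.5))
        add(r, ip(e + 1), sgn * (-0.5))
      }
      # continuity rows: mass on both nodes, Darcy antisymmetric
      for (pair in list(c(e, 1), c(e + 1, 1))) {
        r <- rp_row(pair[1])
        add(r, iu(e + 1), dl_du / dt * hs[e] / 2)
        add(r, iu(e),    -dl_du / dt * hs[e] / 2)
      }
      # Darcy: rp[e] -= k g ; rp[e+1] += k g, with k = k(lam_e)
      for (pair in list(c(e, -1), c(e + 1, 1))) {
        r <- rp_row(pair[1]); sgn <- pair[2]
        add(r, ip(e + 1), sgn * k[e] / hs[e])
        add(r, ip(e),    -sgn * k[e] / hs[e])
        add(r, iu(e + 1), sgn * dk[e] * dl_du * g[e])
        add(r, iu(e),    -sgn * dk[e] * dl_du * g[e])
      }
    }
    J
  }

  # initial condition: undrained step response (no settlement, p = load)
  u <- numeric(nn)
  p <- rep(load, nn)
  p[nn] <- 0
  x <- c(u[-1], p[-nn])
  lam_old <- rep(1, n_elem)
  settle <- numeric(length(times))
  pmat <- matrix(0, nn, length(times))
  t_cur <- 0
  for (i in seq_along(times)) {
    steps <- rep((times[i] - t_cur) / n_substeps, n_substeps)
    for (dt in steps) {
      for (newton in 1:20) {
        r <- residual(x, lam_old, dt)
        if (sqrt(sum(r^2)) < 1e-12 * max(1, load)) break
        dx <- solve(jac(x, lam_old, dt), -r)
        x <- x + dx
        if (sqrt(sum(dx^2)) < 1e-14) break
      }
      w <- unpack(x)
      lam_old <- 1 + diff(w$u) / hs
      t_cur <- t_cur + dt
    }
    w <- unpack(x)
    settle[i] <- -w$u[nn]
    pmat[, i] <- w$p
  }
  # drained limit: uniform stretch with sigma_e(lambda) = -load
  lam_d <- stats::uniroot(function(l) sig_e(l) + load, c(0.2, 1),
                          tol = 1e-12)$root
  list(times = times, settlement = settle, pressure = pmat, z = z,
       drained_settlement = (1 - lam_d) * L)
}
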