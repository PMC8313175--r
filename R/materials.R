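# Constitutive laws for disc tissue: Holmes-Mow extrafibrillar matrix,
# compressible Neo-Hookean (vertebral bone), strain-dependent hydraulic
# permeability, Donnan equilibrium osmotic pressure, and toe-region
# power-law / linear annulus fibers. All functions are pure maps from
# deformation/composition state to energy (MPa), Cauchy stress (MPa) or
# transport quantities. Units: mm-N-MPa-s-mM throughout.

# Universal gas constant, J/(mol K). mM == mol/m^3, so R*T*c is in Pa.
.GAS_CONSTANT <- 8.314462618

#' Lame parameters from engineering constants
#'
#' Converts a Young's modulus and Poisson's ratio into the first and second
#' Lame parameters used by the Holmes-Mow strain energy.
#'
#' @param E_m Young's modulus (MPa), positive.
#' @param nu Poisson's ratio, strictly inside (-1, 0.5).
#' @return Named list with `lambda` and `mu` (MPa).
#' @examples
#' lame_from_engineering(0.065, 0.24)
#' @export
lame_from_engineering <- function(E_m, nu) {
  if (!is.numeric(E_m) || E_m <= 0) stop("invalid parameter: E_m must be > 0")
  if (!is.numeric(nu) || nu <= -1 || nu >= 0.5)
    stop("invalid parameter: nu must lie strictly in (-1, 0.5)")
  list(
    lambda = E_m * nu / ((1 + nu) * (1 - 2 * nu)),
    mu     = E_m / (2 * (1 + nu))
  )
}

#' Material parameter set for one disc region
#'
#' Bundles the constitutive constants of one tissue region. Fiber fields
#' (`E_f`, `lambda0`, `theta`, `beta_f`) are `NA` for fiber-free regions
#' (NP, CEP, VB). `phi0_s` is the reference solid volume fraction; the
#' reference water fraction is `1 - phi0_s`.
#'
#' @param region_label One of "OAF","AFtrans","IAF","NPtrans","NP","CEP","VB".
#' @param E_m Matrix Young's modulus (MPa).
#' @param nu Poisson's ratio.
#' @param beta_m Matrix exponential stiffening coefficient (>= 0).
#' @param k0 Reference hydraulic permeability (mm^4/(N s)).
#' @param M Permeability strain-dependence exponent.
#' @param c0F Reference fixed charge density (mM).
#' @param E_f Fiber modulus (MPa) or NA.
#' @param lambda0 Fiber transition stretch (> 1) or NA.
#' @param theta Fiber angle magnitude (degrees, the +/- ply pair) or NA.
#' @param beta_f Fiber toe-region power-law exponent (> 1) or NA.
#' @param phi0_s Reference solid volume fraction, in (0, 1).
#' @return Object of class `material_params`.
#' @export
material_params <- function(region_label, E_m, nu, beta_m, k0, M, c0F,
                            E_f = NA_real_, lambda0 = NA_real_,
                            theta = NA_real_, beta_f = NA_real_,
                            phi0_s = 0.3) {
  labels <- c("OAF", "AFtrans", "IAF", "NPtrans", "NP", "CEP", "VB")
  if (!region_label %in% labels)
    stop("invalid parameter: unknown region_label '", region_label, "'")
  if (E_m <= 0) stop("invalid parameter: E_m must be > 0")
  if (nu <= -1 || nu >= 0.5) stop("invalid parameter: nu out of (-1, 0.5)")
  if (beta_m < 0) stop("invalid parameter: beta_m must be >= 0")
  if (k0 <= 0) stop("invalid parameter: k0 must be > 0")
  if (c0F < 0) stop("invalid parameter: c0F must be >= 0")
  if (phi0_s <= 0 || phi0_s >= 1)
    stop("invalid parameter: phi0_s must lie in (0, 1)")
  has_fibers <- !is.na(E_f)
  if (has_fibers) {
    if (E_f <= 0) stop("invalid parameter: E_f must be > 0")
    if (is.na(lambda0) || lambda0 <= 1)
      stop("invalid parameter: lambda0 must be > 1")
    if (is.na(beta_f) || beta_f <= 1)
      stop("invalid parameter: beta_f must be > 1")
    if (is.na(theta) || theta <= 0 || theta >= 90)
      stop("invalid parameter: theta must lie in (0, 90) degrees")
  }
  structure(list(
    region_label = region_label, E_m = E_m, nu = nu, beta_m = beta_m,
    k0 = k0, M = M, c0F = c0F, E_f = E_f, lambda0 = lambda0,
    theta = theta, beta_f = beta_f,
    phi0_s = phi0_s, phi0_w = 1 - phi0_s,
    has_fibers = has_fibers
  ), class = "material_params")
}

#' Default per-region material table
#'
#' The packaged tissue-level constants for every disc region: matrix modulus,
#' Poisson ratio, exponential stiffening, permeability and its strain
#' dependence, fixed charge density, and (for annulus regions) the fiber
#' modulus, transition stretch, ply angle and toe exponent. Reference water
#' fractions default to 0.80 for NP/NPtrans, 0.70 for the annulus regions,
#' 0.60 for CEP (typical reported disc tissue water contents; configurable
#' by rebuilding entries with [material_params()]). The VB row is a stiff
#' Neo-Hookean bone surrogate used only when compliant platens are requested.
#'
#' @return Named list of `material_params`, keyed by region label.
#' @export
default_material_table <- function() {
  list(
    OAF     = material_params("OAF",     0.018, 0.24, 3.40, 0.00470, 5.75,  44,
                              E_f = 15.6, lambda0 = 1.028, theta = 31.0,
                              beta_f = 4, phi0_s = 0.30),
    AFtrans = material_params("AFtrans", 0.023, 0.20, 2.80, 0.00360, 4.60,  50,
                              E_f = 10.3, lambda0 = 1.025, theta = 38.5,
                              beta_f = 4, phi0_s = 0.30),
    IAF     = material_params("IAF",     0.026, 0.16, 2.10, 0.00250, 3.50,  55,
                              E_f = 6.9,  lambda0 = 1.023, theta = 41.5,
                              beta_f = 4, phi0_s = 0.30),
    NPtrans = material_params("NPtrans", 0.045, 0.20, 1.50, 0.00160, 2.71, 217,
                              E_f = 3.0,  lambda0 = 1.020, theta = 44.5,
                              beta_f = 4, phi0_s = 0.20),
    NP      = material_params("NP",      0.065, 0.24, 0.95, 0.00056, 3.79, 379,
                              phi0_s = 0.20),
    CEP     = material_params("CEP",     0.305, 0.18, 0.29, 0.00056, 3.79, 248,
                              phi0_s = 0.40),
    VB      = material_params("VB",      10000, 0.30, 0.00, 0.00056, 0.00,   0,
                              phi0_s = 0.40)
  )
}

#' Osmotic environment
#'
#' External bath and physical constants entering the Donnan pressure.
#' Defaults: 300 mOsm/L bath, body temperature 310 K, ideal osmotic
#' coefficient 1.
#'
#' @param bath_osmolarity External bath osmolarity (mOsm/L, i.e. mM), >= 0.
#' @param temperature Absolute temperature (K).
#' @param osmotic_coefficient Osmotic coefficient Phi in (0, 1].
#' @return Object of class `disc_environment`.
#' @export
disc_environment <- function(bath_osmolarity = 300, temperature = 310,
                             osmotic_coefficient = 1) {
  if (bath_osmolarity < 0) stop("invalid parameter: bath_osmolarity < 0")
  if (temperature <= 0) stop("invalid parameter: temperature must be > 0")
  if (osmotic_coefficient <= 0 || osmotic_coefficient > 1)
    stop("invalid parameter: osmotic_coefficient must lie in (0, 1]")
  structure(list(
    bath_osmolarity = bath_osmolarity,
    temperature = temperature,
    osmotic_coefficient = osmotic_coefficient,
    gas_constant = .GAS_CONSTANT
  ), class = "disc_environment")
}

#' Deformation state from a deformation gradient
#'
#' Computes the determinant and the first two invariants of the right
#' Cauchy-Green tensor C = F^T F.
#'
#' @param F 3x3 deformation gradient with positive determinant.
#' @return Object of class `deformation_state` with fields `F`, `J`, `I1`, `I2`.
#' @export
deformation_state <- function(F) {
  F <- as.matrix(F)
  if (!all(dim(F) == c(3, 3))) stop("F must be a 3x3 matrix")
  J <- det(F)
  if (J <= 0) stop("inverted element: det(F) <= 0")
  C <- crossprod(F)
  I1 <- sum(diag(C))
  I2 <- 0.5 * (I1^2 - sum(C * C))
  structure(list(F = F, J = J, I1 = I1, I2 = I2), class = "deformation_state")
}

.as_state <- function(state) {
  if (inherits(state, "deformation_state")) state else deformation_state(state)
}

#' Holmes-Mow strain energy density
#'
#' Isotropic, exponentially stiffening hyperelastic matrix,
#' `W = (lambda + 2 mu)/(4 beta_m) * (exp(Q) - 1)` with
#' `Q = beta_m/(lambda + 2 mu) * ((2 mu - lambda)(I1 - 3) + lambda (I2 - 3)
#'  - (lambda + 2 mu) ln(J^2))`. Frame-indifferent (depends on F only through
#' the invariants); zero at the reference configuration.
#'
#' @param state A `deformation_state` (or a 3x3 F).
#' @param params A `material_params`.
#' @return Energy density (MPa).
#' @export
holmes_mow_energy <- function(state, params) {
  s <- .as_state(state)
  lm <- lame_from_engineering(params$E_m, params$nu)
  lam <- lm$lambda; mu <- lm$mu
  hA <- lam + 2 * mu   # zero-strain aggregate modulus
  bm <- params$beta_m
  Q <- ((2 * mu - lam) * (s$I1 - 3) + lam * (s$I2 - 3) -
          hA * log(s$J^2)) / hA
  if (bm == 0) return(hA / 4 * Q)  # limit beta_m -> 0
  hA / (4 * bm) * (exp(bm * Q) - 1)
}

#' Holmes-Mow Cauchy stress
#'
#' Analytic Cauchy stress of [holmes_mow_energy()]:
#' `sigma = exp(beta_m Q)/(2J) * ((2 mu - lambda + lambda I1) b
#'  - lambda b^2 - (lambda + 2 mu) I)` with b the left Cauchy-Green tensor.
#' Symmetric; zero at F = identity.
#'
#' @inheritParams holmes_mow_energy
#' @return 3x3 Cauchy stress tensor (MPa).
#' @export
holmes_mow_stress <- function(state, params) {
  s <- .as_state(state)
  lm <- lame_from_engineering(params$E_m, params$nu)
  lam <- lm$lambda; mu <- lm$mu
  hA <- lam + 2 * mu
  bm <- params$beta_m
  Q <- ((2 * mu - lam) * (s$I1 - 3) + lam * (s$I2 - 3) -
          hA * log(s$J^2)) / hA
  b <- tcrossprod(s$F)
  eQ <- exp(bm * Q)
  sig <- eQ / (2 * s$J) *
    ((2 * mu - lam + lam * s$I1) * b - lam * (b %*% b) - hA * diag(3))
  0.5 * (sig + t(sig))
}

#' Compressible Neo-Hookean Cauchy stress
#'
#' Standard compressible Neo-Hookean law
#' `W = mu/2 (I1 - 3) - mu ln J + lambda/2 (ln J)^2`, used for the vertebral
#' bone surrogate (compliant platens).
#'
#' @param state A `deformation_state` (or 3x3 F).
#' @param E Young's modulus (MPa).
#' @param nu Poisson's ratio.
#' @return 3x3 Cauchy stress tensor (MPa).
#' @export
neo_hookean_stress <- function(state, E, nu) {
  s <- .as_state(state)
  lm <- lame_from_engineering(E, nu)
  b <- tcrossprod(s$F)
  (lm$mu * (b - diag(3)) + lm$lambda * log(s$J) * diag(3)) / s$J
}

#' Neo-Hookean strain energy density
#'
#' @inheritParams neo_hookean_stress
#' @return Energy density (MPa).
#' @export
neo_hookean_energy <- function(state, E, nu) {
  s <- .as_state(state)
  lm <- lame_from_engineering(E, nu)
  lm$mu / 2 * (s$I1 - 3) - lm$mu * log(s$J) + lm$lambda / 2 * log(s$J)^2
}

#' Strain-dependent hydraulic permeability
#'
#' `k(J) = k0 * ((J - phi0_s)/(1 - phi0_s))^2 * exp(M (J^2 - 1)/2)`;
#' strictly increasing in J for M > 0, equal to k0 at J = 1.
#'
#' @param J Volume ratio, must exceed the solid fraction `phi0_s`.
#' @param params A `material_params`.
#' @return Permeability (mm^4/(N s)).
#' @export
permeability <- function(J, params) {
  phi0 <- params$phi0_s
  if (any(J <= phi0)) stop("pore collapse: J <= phi0_s")
  params$k0 * ((J - phi0) / (1 - phi0))^2 * exp(params$M * (J^2 - 1) / 2)
}

#' Instantaneous fixed charge density
#'
#' Dilution of the matrix-bound charge with tissue volume change:
#' `cF(J) = phi0_w / (J - 1 + phi0_w) * c0F`. Strictly decreasing in J,
#' tending to zero as the tissue swells without bound.
#'
#' @param J Volume ratio; `J - 1 + phi0_w` must be positive.
#' @param params A `material_params`.
#' @return Fixed charge density (mM).
#' @export
fixed_charge_density <- function(J, params) {
  pw <- params$phi0_w
  den <- J - 1 + pw
  if (any(den <= 0)) stop("invalid deformation: fluid volume non-positive")
  pw / den * params$c0F
}

#' Donnan equilibrium osmotic pressure
#'
#' `pi = R T Phi (sqrt(cF^2 + cbar^2) - cbar)` with concentrations in mM
#' (= mol/m^3) and the result converted from Pa to MPa. Non-negative and
#' strictly increasing in cF.
#'
#' @param cF Fixed charge density (mM), >= 0.
#' @param env A `disc_environment`.
#' @return Osmotic pressure (MPa).
#' @export
donnan_pressure <- function(cF, env) {
  if (any(cF < 0)) stop("invalid input: cF must be >= 0")
  cb <- env$bath_osmolarity
  env$gas_constant * env$temperature * env$osmotic_coefficient *
    (sqrt(cF^2 + cb^2) - cb) * 1e-6
}

# Toe-region / linear fiber law. With I_n = lambda^2, I_0 = lambda0^2:
#   I_n <  1        : slack, zero energy and stress
#   1 <= I_n <= I_0 : toe power law
#       Psi = E_f/(4 b (b-1)) (I0-1)^(2-b) (In-1)^b
#       sigma = dPsi/dlambda = E_f/(2(b-1)) (I0-1)^(2-b) lambda (In-1)^(b-1)
#   I_n >  I_0      : linear with modulus E_f
#       sigma = sigma(lambda0) + E_f (lambda - lambda0)
#       Psi   = Psi0 + sigma(lambda0)(lambda - lambda0) + E_f/2 (lambda-lambda0)^2
# Both branches are continuous at I_n = 1 and I_n = I_0 (toe branch wins ties).

#' Fiber strain energy density
#'
#' Piecewise toe-region power-law / linear fiber energy as a function of the
#' fiber stretch. Slack fibers (stretch below 1) store no energy; the toe
#' branch runs up to the transition stretch `lambda0`; above it the fiber is
#' linear with modulus `E_f`, offset so the energy is continuous.
#'
#' @param lambda_n Fiber stretch (> 0). Vectorized.
#' @param params A `material_params` with fiber constants.
#' @return Energy density (MPa).
#' @export
fiber_energy <- function(lambda_n, params) {
  if (any(lambda_n <= 0)) stop("invalid input: lambda_n must be > 0")
  if (!isTRUE(params$has_fibers)) return(rep(0, length(lambda_n)))
  Ef <- params$E_f; b <- params$beta_f; l0 <- params$lambda0
  I0 <- l0^2
  In <- lambda_n^2
  A <- Ef / (4 * b * (b - 1)) * (I0 - 1)^(2 - b)
  psi0 <- Ef / (4 * b * (b - 1)) * (I0 - 1)^2
  sig0 <- Ef / (2 * (b - 1)) * l0 * (I0 - 1)
  out <- numeric(length(lambda_n))
  toe <- In >= 1 & In <= I0
  lin <- In > I0
  out[toe] <- A * (In[toe] - 1)^b
  dl <- lambda_n[lin] - l0
  out[lin] <- psi0 + sig0 * dl + Ef / 2 * dl^2
  out
}

#' One-dimensional fiber stress
#'
#' The derivative of [fiber_energy()] with respect to the fiber stretch:
#' zero when slack, toe power law up to the transition stretch, then linear
#' with slope `E_f`. Continuous at both branch points and nondecreasing for
#' stretches above 1.
#'
#' @inheritParams fiber_energy
#' @return Fiber stress dPsi/dlambda (MPa).
#' @export
fiber_stress_1d <- function(lambda_n, params) {
  if (any(lambda_n <= 0)) stop("invalid input: lambda_n must be > 0")
  if (!isTRUE(params$has_fibers)) return(rep(0, length(lambda_n)))
  Ef <- params$E_f; b <- params$beta_f; l0 <- params$lambda0
  I0 <- l0^2
  In <- lambda_n^2
  sig0 <- Ef / (2 * (b - 1)) * l0 * (I0 - 1)
  out <- numeric(length(lambda_n))
  toe <- In >= 1 & In <= I0
  lin <- In > I0
  out[toe] <- Ef / (2 * (b - 1)) * (I0 - 1)^(2 - b) *
    lambda_n[toe] * (In[toe] - 1)^(b - 1)
  out[lin] <- sig0 + Ef * (lambda_n[lin] - l0)
  out
}

#' Total Cauchy stress of the solid-fluid-fiber mixture at a material point
#'
#' Assembles the matrix stress, the rank-one contribution of each fiber
#' family, and the Donnan swelling stress `-pi I`:
#' `sigma = sigma_matrix(F) + sum_i lambda_i sigma_f(lambda_i)/J m_i x m_i
#'  - pi(cF(J)) I`.
#'
#' @param state A `deformation_state` (or 3x3 F).
#' @param fiber_stretches List of `list(stretch =, direction =)` pairs; each
#'   direction is a unit vector in the current configuration.
#' @param params A `material_params`.
#' @param env A `disc_environment`.
#' @param swelling_activation Scale factor in `[0, 1]` applied to `c0F`
#'   (swelling ramp level); default 1.
#' @return 3x3 symmetric Cauchy stress tensor (MPa).
#' @export
total_cauchy_stress <- function(state, fiber_stretches = list(), params, env,
                                swelling_activation = 1) {
  s <- .as_state(state)
  sig <- holmes_mow_stress(s, params)
  for (fb in fiber_stretches) {
    lam <- fb$stretch
    m <- fb$direction / sqrt(sum(fb$direction^2))
    sig <- sig + (lam * fiber_stress_1d(lam, params) / s$J) * tcrossprod(m)
  }
  c0F_eff <- swelling_activation * params$c0F
  if (c0F_eff > 0) {
    pw <- params$phi0_w
    cF <- pw / (s$J - 1 + pw) * c0F_eff
    sig <- sig - donnan_pressure(cF, env) * diag(3)
  }
  0.5 * (sig + t(sig))
}
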